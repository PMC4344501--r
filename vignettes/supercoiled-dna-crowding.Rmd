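---
title: "Modelling crowded supercoiled DNA rings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crowded supercoiled DNA rings: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(supercoilr)
```

# The physical model

`supercoilr` simulates circular DNA molecules as coarse-grained bead-spring
rings.  One bead represents about 9 bp and has a diameter of one reduced
length unit $\sigma_{LJ}$, corresponding to 3 nm — the effective diameter
of B-DNA at physiological ionic strength, where electrostatic repulsion is
almost completely screened.  The energy unit $\epsilon_0$ equals
$1\,k_BT \approx 4\times10^{-21}$ J, and all simulations run at $k_BT = 1$.
A 3 kb plasmid maps onto a ring of 334 beads.

The Hamiltonian has four standard terms plus an optional regulatory-contact
well:

* **Excluded volume.**  A purely repulsive truncated Lennard-Jones
  potential, $U = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right]$ for
  $r < r_{cut} = 1.0\,\sigma$ and zero beyond.  Because the untruncated LJ
  form vanishes at $r=\sigma$, the potential is continuous (and zero) at
  the cutoff; the force is not, which is the standard price of this
  "repulsive-only cut" form and is immaterial for overdamped dynamics.
* **Bonds.**  Harmonic, $U = (k/2)(r - r_0)^2$ with $r_0 = 1\,\sigma$.
  The stiffness $k = 800\,\epsilon_0/\sigma^2$ is a modelling choice (it is
  not dictated by DNA physics): it keeps bond-length fluctuations near 3.5%
  ($\sigma_r = 1/\sqrt{800}$) while remaining integrable at the default
  time step.
* **Bending.**  $U = \kappa(1 - \cos\theta)$ per junction with
  $\kappa = 17\,\epsilon_0$.  For this discrete form
  $\langle\cos\theta\rangle = \coth\kappa - 1/\kappa$, so tangent
  correlations decay with persistence length
  $L_p = -b/\ln(\coth\kappa - 1/\kappa) \approx 16.5$ beads
  $\approx 49.5$ nm, the calibration to the 50 nm persistence length of
  B-DNA (`persistence_length(17, 3)`).  A harmonic-in-$\theta$ bending term
  would give an almost identical $L_p$ at this stiffness; the
  $1-\cos\theta$ form was chosen because its stationary angle distribution
  is known in closed form, which the test suite exploits.
* **Twist.**  Torsionally constrained rings carry one material normal per
  edge.  The twist angle at a junction is measured by parallel-transporting
  the incoming edge's normal across the junction (a rotation about
  $\mathbf{u}_{i-1}\times\mathbf{u}_i$, i.e. through the mid-edge frame)
  and reading the signed rotation to the outgoing normal about the local
  tangent.  This mid-edge construction stays well defined up to
  180-degree bends.  The energy is harmonic, $U = (k_t/2)\sum_i\phi_i^2$,
  with $k_t = 31.7\,\epsilon_0/\mathrm{rad}^2$ by default, corresponding
  to a torsional persistence length of $31.7 \times 3\,\mathrm{nm}
  \approx 95$ nm of DNA.  $k_t$ is configurable; shape and contact
  observables are insensitive to it within the plausible 75–110 nm range
  because twist is much stiffer than bend at these discretisations.
* **Enhancer–promoter well.**  A full (attractive) LJ of depth
  $8\,k_BT$, truncated at two bead diameters and shifted so the potential
  reaches zero continuously at the cutoff (an unshifted truncation would
  inject an energy jump at $r_{cut}$).  It acts only on the designated
  bead pair of each molecule, 167 beads apart on the 334-bead ring.
  A pair is *in contact* when the centre–centre distance is below
  $2\,\sigma$, i.e. the surface-to-surface gap is below one bead diameter.

Supercoiling enters through the linking deficit $\Delta Lk$ relative to
the torsionally relaxed ring: $\sigma = \Delta Lk/(n_{bp}/h)$ with helical
repeat $h = 10.5$ bp/turn, so $\Delta Lk = -7$ and $-14$ on 3 kb
correspond to $\sigma \approx -0.025$ and $-0.05$.  Nicked
(torsionally unconstrained) molecules simply carry no twist term.

# Propagators

## Brownian dynamics

`bd_run()` integrates the overdamped Langevin equation with the
Euler–Maruyama scheme,
$\mathbf{r} \leftarrow \mathbf{r} + (dt/\gamma)\mathbf{F} +
\sqrt{2\,dt/\gamma}\,\boldsymbol\xi$, at $\gamma = 1$ and $dt = 5\times
10^{-4}\,\tau$.  The step size is set by the bond stiffness: at
$k = 800$ the stiffest relaxation rate is $\sim k/\gamma$, and
$dt \le 10^{-3}$ keeps the scheme stable (the constructor refuses larger
steps).  The residual discretisation bias at the default step is a
few-percent inflation of the stiffest-mode fluctuations; its effect on the
measured persistence length is about $-3\%$, well inside the calibration
tolerance.  A per-step displacement above $0.5\,\sigma$ aborts the run as
an instability.

Material frames evolve in two sub-steps that together conserve the
linking number: (i) each edge's normal is parallel-transported from the
old to the new tangent — for a closed discrete ribbon the identity
$Lk = Tw + Wr$ then holds *exactly*, so backbone motion exchanges twist
and writhe without changing $Lk$; (ii) a rotational Langevin update about
the tangent relaxes twist along the chain
($\dot\psi_i = -k_t(\phi_i - \phi_{i+1})/\gamma_t + $ noise,
$\gamma_t = 1$), which redistributes but does not create twist.  The
positional force of the twist energy uses the discrete-rods
curvature-binormal gradient
$\nabla\phi_i \propto 2\,\mathbf{e}_{i-1}\times\mathbf{e}_i /
(|\mathbf{e}_{i-1}||\mathbf{e}_i| + \mathbf{e}_{i-1}\cdot\mathbf{e}_i)$,
validated in the tests against finite differences of the transported
energy.  This coupling is what drives an initially flat, uniformly
twisted ring to writhe into plectonemes.

Periodic boundaries are handled by propagating *unwrapped* coordinates
and applying the minimum-image convention inside the non-bonded terms
only; image flags are derived when states are exported.  Short-range
neighbours come from a Verlet list (skin $0.5\,\sigma$) built through a
cell grid when the box holds at least three cells per edge and by direct
search otherwise.

## Monte Carlo

`mc_sample()` is a Metropolis sampler of the *same* Hamiltonian, used for
two purposes: as an independent cross-check of the BD ensembles (the two
propagators share no sampling machinery) and as a far cheaper route to
global-shape equilibrium, which BD reaches only on the slow Rouse
timescale ($\sim N^2$ steps for a 334-bead ring).

Moves are crankshaft rotations of random sub-arcs about the chord through
their endpoints, single-bead displacements, and whole-molecule
translations in periodic systems.  Crankshaft amplitudes are capped so no
bead moves farther than `max_disp` ($1.2\,\sigma$ by default) in one
move.  The cap is what preserves topology: the excluded volume keeps
non-bonded beads $\gtrsim 0.8\,\sigma$ apart, so hopping to the far side
of another strand would require a single-move jump of at least
$\sim 1.6\,\sigma$.  Within that bound, larger caps decorrelate faster;
$1.2\,\sigma$ roughly halves the shape autocorrelation time relative to
$0.5\,\sigma$ at equal cost.  Single-bead moves use their own small
amplitude ($0.06\,\sigma$) because they work against the stiff bonds.

For torsionally constrained rings the sampler integrates the twist out in
the homogeneous-twist approximation: twist equilibrates along the chain
much faster than the backbone moves, so the twist free energy is
$2\pi^2 k_t(\Delta Lk - Wr)^2/N$ and only the writhe must be tracked.
Writhe changes are computed incrementally — a crankshaft arc moves
rigidly, so only (moved edge, static edge) pairs of the Gauss double sum
change — and the exact polygon writhe is recomputed at intervals to stop
floating-point drift.  The BD and MC routes treat torsion in completely
different ways, which makes their agreement on the $Tw/Wr$ partition (a
test in the suite) a meaningful validation of both.

# System preparation

`init_system()` places molecules on a lattice.  Dilute systems
($\phi = 0$) use planar circles in an infinite box; such molecules are
propagated independently (identical statistics to a very large box,
without paying for it).  Crowded systems use a cubic box of edge
$L = (M n (\pi/6)/\phi)^{1/3}$; since a planar 334-bead circle (diameter
$\sim 107\,\sigma$) never fits a lattice cell, each ring starts as a
compact space-filling fold: straight passes aligned with the longest cell
axis, visited along a Hamiltonian cycle of the pass grid with rounded
U-turns, which closes on itself without an external return path.  Folds of
different molecules are confined to disjoint cells, so the start is
guaranteed unknotted, uncatenated and overlap-free at any supported
occupancy.  For $\Delta Lk \ne 0$ the material frame is wound on top of
the parallel-transported (twist-free) frame field so that $Lk$ equals
$\Delta Lk$ exactly whatever the fold's initial writhe.

An alternative preparation path mirrors the box-compression protocol:
`compress_box()` shrinks the box by 0.5% per $10^4$-step relaxation
interval (rescaling molecule centroids, not internal coordinates) until
the target occupancy is hit exactly.  The default pipeline uses direct
placement because it reaches the same ensemble after equilibration at a
small fraction of the cost; the compression entry point remains for
protocol studies.

Because the constructed starts (flat circles, compact folds) are far from
the equilibrium shape basin, `run_condition()` first relaxes them with a
few thousand MC sweeps before handing over to BD; for constrained rings
the material frames are rebuilt afterwards at the same $\Delta Lk$.

# Equilibration and the eight-fold rule

Equilibration is detected from the per-molecule radius-of-gyration time
series: the first frame at which every molecule's windowed mean (window
5% of the series) lies within one standard error of that molecule's
final-half mean.  A run is accepted only if it is at least eight times
longer than the detected equilibration time; otherwise the condition
aborts with a "not equilibrated" error.  Production statistics use only
post-equilibration frames.

# Analyses

* **Topology.**  Writhe is the exact Gauss double sum over segment pairs,
  each pair evaluated as the signed solid angle of the spherical
  quadrilateral of connecting directions (two Van Oosterom–Strackee
  triangles).  This form is numerically stable: coplanar pairs contribute
  exactly zero, so a planar ring has writhe 0 to machine precision.
  Adjacent pairs are skipped; their contribution vanishes in the
  continuum limit.  Twist is $\sum_i \phi_i/2\pi$.  The suite checks the
  closed form against dense quadrature of the Gauss integral and checks
  $Lk = Tw + Wr$ conservation along BD trajectories to $\pm 0.05$ turns.
* **Shape.**  The characteristic inertial ellipsoid has the same mass and
  principal moments of inertia as the rigid bead conformation, with the
  ellipsoid's mass spread over its surface.  The hollow-shell relations
  $I_a = (m/3)(b^2+c^2)$ (cyclic) invert to $a = \sqrt{3\lambda_1}$ etc.,
  with $\lambda_i$ the gyration-tensor eigenvalues.  Asphericity
  $A = [(a-b)^2 + (a-c)^2 + (b-c)^2] / [2(a+b+c)^2]$ and prolateness
  $P = (2a-b-c)(2b-a-c)(2c-a-b) /
  [2(a^2+b^2+c^2-ab-ac-bc)^{3/2}]$ are scale-free, so the shell-vs-solid
  moment convention cancels in both; $P$ at $a=b=c$ is a 0/0 limit and
  returns 0 by convention.  The synthetic `ellipsoid_shell()` fixture
  samples the affine image of a uniform spherical shell — the mass
  distribution whose moments satisfy the shell relations *exactly* —
  rather than a uniform-area surface cloud, whose moments differ by
  several percent and which would therefore not round-trip through the
  solver.
* **2D asphericity.**  For traced, surface-deposited molecules,
  $A = (\lambda_1-\lambda_2)^2/(\lambda_1+\lambda_2)^2$ with $\lambda_i$
  the principal components (eigenvalues) of the 2D gyration tensor.  The
  eigenvalue convention (not its square root) is used: it gives 0 for
  isotropic clouds, 1 for collinear points, and values in the 0.5–0.7
  range for moderately elongated closed contours, the regime reported for
  surface-crowded molecules.
* **Intra-molecular thickness.**  At each bead the local tangent is the
  normalised chord through its flanking beads.  For every azimuth around
  the tangent (36 by default) the probe finds, by bisection to
  $10^{-3}\,\sigma$, the largest sphere that is externally tangent to the
  chain cylinder there (centre offset $\rho + \sigma/2$) and clears every
  other bead by $\rho + \sigma/2$.  The thickness is
  $2\min_u\rho(u) + \sigma$, capped at $2 \times 15\,\sigma + \sigma$.
  The *minimum* over azimuths implements the requirement that the sphere
  fit at *any* azimuthal angle; the existential reading would ignore
  one-sided obstruction and could not produce the near-$\sigma$
  thickness of closely apposed superhelical segments.  With this
  geometry two touching strands give exactly one bead diameter.  A
  $\pm 10$-bead window around the probed bead (about 30 nm, under one
  persistence length) is excluded so local curvature does not cap the
  probe; beads of *other* molecules obstruct by default in crowded
  systems (flag `include_other_rings`).
* **Contacts.**  The contact fraction is the fraction of sampled frames
  with the enhancer–promoter pair closer than $2\,\sigma$, averaged over
  molecules, with a block-averaged standard error (blocks along time, so
  frame-to-frame correlation does not understate the error).
  `make_linear_control()` builds the open-chain control with the same
  genomic separation and affinity but no closure and no twist term.

# Synthetic fixtures and what passing tests mean

The `planar_circle()`, `twisted_circle()`, `plectoneme()`,
`ellipsoid_shell()`, `parallel_strands()` and `equilibrium_chain()`
generators provide conformations with *known* topology, shape and
thickness, so every analysis stage is validated without simulation:
writhe against quadrature, the ellipsoid solver against constructed axes,
the thickness probe against a geometric bound, the samplers against the
ideal-chain closed forms.  What the fixtures deliberately do not emulate:
sequence-dependent stiffness, electrostatics beyond the effective
diameter, solvent hydrodynamics, AFM image noise or pixelation, and DNA
melting or alternative secondary structures.  Passing the suite therefore
certifies the model as specified — a torsionally constrained,
excluded-volume worm-like ring at screened physiological ionic
conditions — not any finer structure of real DNA.

# Problem sizes used by the checks

The reference study conditions (20 molecules of 334 beads, occupancies up
to 20%, runs of $10^6$–$10^7$ saved configurations) are available through
`condition_config(full = TRUE)` and run for hours.  The test suite and the
acceptance script use desk-scale versions chosen so that each targeted
statistic resolves well inside its stated tolerance: persistence-length
calibration from 50 independent 200-bead chains (5,000 pooled frames; the
standard error on $L_p$ is then a small fraction of the 10% band); the
dilute-ring mean asphericity from a 334-bead ring over 44,000 MC sweeps
sampled every 20 (2,200 conformations, a few hundred effectively
independent, standard error about 0.005 against a 0.02 tolerance);
directional crowding and contact claims from scaled-down systems with
explicit block-averaged errors.  Crowded full-grid statistics
(the 12-condition grid) are not recomputed at desk scale; the directional
assertions on scaled systems stand in for them.

# Crowded-ring equilibration is glassy at desk scale

One negative methodological result deserves emphasis.  Equilibrating the
*shape* of crowded rings (occupancy 10% and above) is far harder than
equilibrating dilute ones: rings must start from compact cell-confined
folds (nothing larger can be placed without overlap or linking), and the
collective swelling/rearrangement out of that start is glassy — on
128-bead test systems, independent 50,000-sweep MC runs end at visibly
different mean asphericities, and Brownian dynamics needs several Rouse
times (tens of CPU minutes) before its shape statistics stop drifting.
Compression from dilute conditions, the obvious alternative, fails for a
geometric reason: a dilute semiflexible ring is *larger than the crowded
box*, so the affine centroid rescaling that implements compression
changes minimum-image surface distances non-uniformly and drives deep
overlaps at any practical shrink rate.  Consequently the package's
desk-scale checks certify crowded-shape statistics only directionally
and with explicit convergence caveats; quantitative crowded-shape
results should use the full-scale profile (`condition_config(full =
TRUE)`) with run lengths validated by the eight-fold equilibration rule.

# Known limitations

* The Euler–Maruyama scheme biases stiff-mode fluctuations at the few-
  percent level at the default step; halve `dt` where that matters.
* The homogeneous-twist MC approximation ignores twist-gradient
  fluctuations; it is accurate when $k_t \gg \kappa b^2/N$, which holds
  here, and it is cross-checked against explicit-frame BD in the suite.
* The MC topology guarantee is geometric (displacement caps), not an
  explicit knot/link test; caps above $\sim 1.5\,\sigma$ void it.
* Thickness probing is $O(n_{azimuth} \times n_{beads})$ per bead and is
  the most expensive analysis; use bead strides for ensemble profiles.
* The equilibration detector assumes the final half of the run is
  representative; monotone drifts are caught, slow oscillations on the
  scale of the whole run would not be.
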