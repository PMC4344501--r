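# supercoilr

Coarse-grained simulation and analysis of circular DNA under
physiological self-crowding.

DNA inside bacteria is circular, negatively supercoiled, and packed to
10–20% volume occupancy.  Those three facts interact: unlinked circular
molecules cannot thread each other's loops, so crowding compresses and
elongates them (topological exclusion), reshapes their plectonemes, and
changes how often distant sites on the same molecule meet.  `supercoilr`
is an R package for studying these effects quantitatively.  It is aimed
at polymer/biophysics researchers who want a self-contained, validated
bead-spring model of 3 kb-scale plasmids rather than a general-purpose MD
engine.

## The model in brief

A plasmid is a ring of $N$ beads of diameter $\sigma = 3$ nm (about 9 bp
each) with, in reduced units ($k_BT = \epsilon_0 = 1$):

- purely repulsive truncated Lennard-Jones excluded volume
  ($r_{cut} = 1\,\sigma$),
- harmonic bonds ($k = 800\,\epsilon_0/\sigma^2$, $r_0 = 1\,\sigma$),
- bending energy $\kappa(1-\cos\theta)$ with $\kappa = 17\,\epsilon_0$,
  giving persistence length $L_p = -b/\ln(\coth\kappa - 1/\kappa)
  \approx 50$ nm,
- a harmonic ribbon-twist energy on per-edge material frames for
  torsionally constrained rings, so that the linking number
  $Lk = Tw + Wr$ is imposed by construction and conserved by the
  dynamics,
- optionally, an attractive $8\,k_BT$ truncated-shifted LJ well between
  an enhancer and a promoter bead 167 beads apart.

Supercoiling is set by the linking deficit: $\Delta Lk = -7$ or $-14$ on
a 3000 bp / 334-bead ring gives supercoiling densities
$\sigma \approx -0.025$ and $-0.05$.  Crowding is set by the volume
occupancy $\phi$ of a periodic box (up to 20%, the bacterial-nucleoid
regime).

Two propagators sample the same Hamiltonian: an overdamped Brownian
dynamics integrator (`bd_run()`) with explicit material-frame torsion,
and a Metropolis Monte Carlo sampler (`mc_sample()`) with
topology-preserving capped crankshaft moves and a fixed-$Lk$ writhe
energy.  Analyses cover twist/writhe/linking number (`writhe()`,
`twist()`), inertial-ellipsoid asphericity and prolateness
(`inertial_ellipsoid()`, `asphericity()`, `prolateness()`,
`asphericity_2d()`), the tangent-sphere intra-molecular thickness probe
(`local_thickness()`), and enhancer–promoter contact statistics
(`contact_fraction()`).  Deterministic fixtures (`plectoneme()`,
`twisted_circle()`, `ellipsoid_shell()`, ...) carry known ground truth
for validation.

## A worked example

Simulate one supercoiled plasmid in dilute solution and watch twist flow
into writhe:

```r
library(supercoilr)

topo  <- ring_topology(n_beads = 334, delta_lk = -7)   # sigma ~ -0.025
state <- init_system(topo, m_rings = 1, phi = 0)       # planar, Tw = -7
traj  <- bd_run(state, force_field(),
                run_protocol(n_steps = 5e4, sample_every = 2500,
                             seed = 11))

tw <- sapply(traj$twist,  function(v) sum(v) / (2 * pi))
wr <- sapply(traj$frames, writhe)
round(cbind(tw = tw, wr = wr, lk = tw + wr)[1:5, ], 4)
#>           tw      wr lk
#> [1,] -6.9494 -0.0506 -7
#> [2,] -6.8793 -0.1207 -7
#> [3,] -6.8886 -0.1114 -7
#> [4,] -6.8239 -0.1761 -7
#> [5,] -6.9443 -0.0557 -7
```

Every frame satisfies $Tw + Wr = -7$ to the printed precision: the ring
trades twist for writhe (the `wr` column grows in magnitude as it starts
to supercoil in space) while the linking number stays fixed — no strand
passage can occur.

Shape of an equilibrated dilute nicked ring by Monte Carlo:

```r
st   <- system_state(list(planar_circle(334)))
burn <- mc_sample(st, n_sweeps = 6000, sample_every = 6000, seed = 41)
tr   <- mc_sample(burn$final_state, n_sweeps = 44000, sample_every = 20)
asp  <- sapply(tr$frames, function(p) asphericity(inertial_ellipsoid(p)))
mean(asp)
#> [1] 0.1055906
```

The mean asphericity of about 0.11 says the equilibrium shapes are mildly
anisotropic — far from both the perfect sphere (0) and a thin rod
(close to 1).  Under 10–20% crowding this value rises substantially for
nicked rings, the topological-exclusion signature.

The full experimental grid (3 supercoiling levels x 4 occupancies) is
driven by `condition_config()` / `run_condition()` / `report_conditions()`,
with YAML configs, extended-XYZ trajectory output and per-frame metric
tables.  Desk-scale defaults are deliberate; `condition_config(full =
TRUE)` selects the reference scale (hours of CPU).  A thin command-line
wrapper is available at `inst/cli/supercoilr-cli.R` with verbs
`simulate`, `fixtures` and `report`.

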