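#' Characteristic inertial ellipsoid of a point set
#'
#' Semiaxes (a >= b >= c) of the ellipsoid that has the same mass and the
#' same principal rotational moments of inertia as the rigid, equal-mass
#' bead conformation, with the ellipsoid's mass spread uniformly over its
#' surface (hollow-shell convention).  From the principal moments
#' \eqn{I_1 \le I_2 \le I_3} about the centroid, the shell relations
#' \eqn{I_a = (m/3)(b^2 + c^2)} (cyclic) invert to
#' \eqn{a^2 = (3/2m)(I_b + I_c - I_a)} and so on.
#'
#' @param points n x 3 matrix of equal-mass coordinates (n >= 3; coplanar
#'   sets give c close to 0).
#' @return Named numeric vector `c(a =, b =, c =)` with `a >= b >= c`,
#'   class `ellipsoid_axes`.  Non-physical (slightly negative) squared
#'   semiaxes from degenerate moment triples are clamped to 0 with a
#'   warning.
#' @examples
#' inertial_ellipsoid(ellipsoid_shell(4, 2, 1, 10000, seed = 1))
#' @export
inertial_ellipsoid <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  n <- nrow(points)
  d <- sweep(points, 2, colMeans(points))
  gyr <- crossprod(d) / n               # gyration tensor (per unit mass)
  lam <- eigen(gyr, symmetric = TRUE)$values   # lam1 >= lam2 >= lam3
  # principal moments per unit mass: I_k = sum of the other two eigenvalues
  I <- c(lam[2] + lam[3], lam[1] + lam[3], lam[1] + lam[2]) # I1<=I2<=I3
  sq <- 1.5 * c(I[2] + I[3] - I[1], I[1] + I[3] - I[2], I[1] + I[2] - I[3])
  if (any(sq < 0)) {
    if (any(sq < -1e-8 * max(abs(sq))))
      warning("non-physical moment triple: negative squared semiaxis clamped to 0")
    sq <- pmax(sq, 0)
  }
  ax <- sort(sqrt(sq), decreasing = TRUE)
  structure(c(a = ax[1], b = ax[2], c = ax[3]), class = "ellipsoid_axes")
}

#' Asphericity of an ellipsoid
#'
#' \deqn{A(a,b,c) = \frac{(a-b)^2 + (a-c)^2 + (b-c)^2}{2(a+b+c)^2}}
#' A perfect sphere has asphericity 0; a thin straight rod approaches 1.
#'
#' @param axes semiaxes `(a, b, c)` with `a >= b >= c >= 0`, e.g. from
#'   [inertial_ellipsoid()].
#' @return Dimensionless asphericity in `[0, 1]`.
#' @examples
#' asphericity(c(1, 1, 1)) # 0
#' asphericity(c(2, 1, 1)) # 0.0625
#' @export
asphericity <- function(axes) {
  axes <- as.numeric(axes)
  stopifnot(length(axes) == 3)
  if (all(axes == 0)) stop("degenerate ellipsoid: all semiaxes zero")
  a <- axes[1]; b <- axes[2]; cc <- axes[3]
  ((a - b)^2 + (a - cc)^2 + (b - cc)^2) / (2 * (a + b + cc)^2)
}

#' Prolateness of an ellipsoid
#'
#' \deqn{P(a,b,c) = \frac{(2a-b-c)(2b-a-c)(2c-a-b)}
#'                       {2(a^2+b^2+c^2-ab-ac-bc)^{3/2}}}
#' Ranges from -1 for perfectly oblate ellipsoids (a = b > c) to +1 for
#' perfectly prolate ones (a > b = c); the degenerate sphere (a = b = c,
#' a 0/0 limit) returns 0 by convention.
#'
#' @inheritParams asphericity
#' @return Dimensionless prolateness in `[-1, 1]`.
#' @examples
#' prolateness(c(2, 1, 1))   # +1 (prolate)
#' prolateness(c(1, 1, 0.5)) # -1 (oblate)
#' @export
prolateness <- function(axes) {
  axes <- as.numeric(axes)
  stopifnot(length(axes) == 3)
  a <- axes[1]; b <- axes[2]; cc <- axes[3]
  denom <- a^2 + b^2 + cc^2 - a * b - a * cc - b * cc
  if (denom <= .Machine$double.eps * max(1, a^2)) return(0)
  (2 * a - b - cc) * (2 * b - a - cc) * (2 * cc - a - b) / (2 * denom^1.5)
}

#' Two-dimensional asphericity of a traced contour
#'
#' For point sets traced from surface-deposited molecules:
#' \eqn{A = (a - b)^2/(a + b)^2} with a, b the principal components
#' (eigenvalues) of the 2D radius-of-gyration tensor.  Isotropic clouds
#' give 0, collinear points give 1.
#'
#' @param points n x 2 matrix of traced coordinates (n >= 3).
#' @return Dimensionless 2D asphericity in `[0, 1]`.
#' @export
asphericity_2d <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  d <- sweep(points, 2, colMeans(points))
  if (all(abs(d) < 1e-12)) stop("all points identical")
  lam <- eigen(crossprod(d) / nrow(d), symmetric = TRUE)$values
  (lam[1] - lam[2])^2 / (lam[1] + lam[2])^2
}

#' Frequency density profile
#'
#' Histogram of values normalised so the profile integrates to 1 over the
#' binned range, the form in which shape, thickness and writhe
#' distributions are reported.
#'
#' @param values numeric vector (>= 1 value).
#' @param bins number of bins, a vector of breakpoints, or `NULL` for
#'   Freedman-Diaconis binning.
#' @return A data.frame with columns `bin_center` and `density`.
#' @export
frequency_density <- function(values, bins = NULL) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to bin")
  breaks <- if (is.null(bins)) {
    if (length(values) < 2 || diff(range(values)) == 0) {
      v <- values[1]
      w <- max(abs(v) * 1e-3, 1e-3)
      c(v - w / 2, v + w / 2)
    } else "FD"
  } else bins
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(bin_center = h$mids, density = h$density)
}
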