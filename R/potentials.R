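#' Toy potentials
#'
#' Closed-form potentials standing in for the all-atom force field so that
#' every sampling and free-energy stage can be validated against quadrature.
#' A `toy_potential` bundles an energy function, its analytic gradient and
#' Laplacian, a dimensionality, and metadata used by the compiled sampler.
#'
#' @name toy_potential
NULL

new_toy_potential <- function(kind, params, dim, energy, gradient, laplacian,
                              feature_length, radial_xy = FALSE) {
  structure(
    list(kind = kind, params = params, dim = dim,
         energy = energy, gradient = gradient, laplacian = laplacian,
         feature_length = feature_length, radial_xy = radial_xy),
    class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("toy_potential '%s' (%dD): %s\n", x$kind, x$dim,
              paste(names(x$params), signif(unlist(x$params), 6),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tilted quartic double well in one dimension
#'
#' `U(x) = a (x^2 - 1)^2 + b x` (kJ/mol, x in nm). For `|b| << a` the wells sit
#' near x = +/-1 nm and the basin free-energy difference is controlled by the
#' tilt `b`; the symmetric case `b = 0` has zero basin free-energy difference.
#' Serves as the 1D validation system for well-tempered hill deposition.
#'
#' @param a barrier-scale coefficient in kJ/mol, must be > 0
#' @param b linear tilt in kJ/mol/nm
#' @return a `toy_potential` with callable `$energy(x)`, `$gradient(x)`,
#'   `$laplacian(x)`; coordinates may be a numeric vector (vectorised)
#' @examples
#' dw <- build_double_well_1d(5, 1)
#' dw$energy(0)   # barrier top: a + 0
#' dw$energy(-1)  # left well:  -b
#' @export
build_double_well_1d <- function(a, b = 0) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a))
  if (a <= 0) stop("double well requires a > 0")
  new_toy_potential(
    "double_well_1d", list(a = a, b = b), dim = 1L,
    energy    = function(x) a * (x^2 - 1)^2 + b * x,
    gradient  = function(x) 4 * a * x * (x^2 - 1) + b,
    laplacian = function(x) 12 * a * x^2 - 4 * a,
    feature_length = 2)
}

#' Gaussian binding pocket with a repulsive floor, in three dimensions
#'
#' `U(x,y,z) = -D exp(-(x^2+y^2+z^2)/(2 sigma^2)) + (z<0) k z^2 / 2`.
#' The attractive well emulates a ligand-binding site at the funnel anchor;
#' the harmonic floor keeps the ligand on the z >= 0 side; the potential
#' decays to zero along the funnel axis, so the solvated plateau of the
#' projected free energy F(z) is flat by construction.
#'
#' @param D well depth in kJ/mol, must be > 0
#' @param sigma_pocket pocket width in nm
#' @param wall_stiffness floor stiffness in kJ/mol/nm^2
#' @return a `toy_potential`; `$energy`/`$gradient` take a length-3 vector or
#'   an n x 3 matrix of coordinates in nm
#' @export
build_funnel_pocket_3d <- function(D, sigma_pocket = 0.3, wall_stiffness = 1000) {
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D))
  if (D <= 0) stop("funnel pocket requires D > 0")
  if (sigma_pocket <= 0) stop("sigma_pocket must be > 0")
  if (wall_stiffness < 0) stop("wall_stiffness must be >= 0")
  s2 <- sigma_pocket^2
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3)
  new_toy_potential(
    "funnel_pocket_3d",
    list(D = D, sigma_pocket = sigma_pocket, wall_stiffness = wall_stiffness),
    dim = 3L,
    energy = function(x) {
      x <- as_mat(x)
      r2 <- rowSums(x^2)
      z <- x[, 3]
      -D * exp(-r2 / (2 * s2)) + ifelse(z < 0, 0.5 * wall_stiffness * z^2, 0)
    },
    gradient = function(x) {
      x <- as_mat(x)
      r2 <- rowSums(x^2)
      g <- x * (D / s2) * exp(-r2 / (2 * s2))
      zneg <- x[, 3] < 0
      g[zneg, 3] <- g[zneg, 3] + wall_stiffness * x[zneg, 3]
      if (nrow(g) == 1) drop(g) else g
    },
    laplacian = function(x) {
      x <- as_mat(x)
      r2 <- rowSums(x^2)
      lap <- (D / s2) * exp(-r2 / (2 * s2)) * (3 - r2 / s2)
      lap + ifelse(x[, 3] < 0, wall_stiffness, 0)
    },
    feature_length = sigma_pocket, radial_xy = TRUE)
}

#' Isotropic harmonic well
#'
#' `U = k |x - x0|^2 / 2` in any dimension; `k = 0` gives free diffusion.
#' Used for equilibrium-variance, configurational-temperature and
#' reweighting-identity checks where every moment is known analytically.
#'
#' @param k spring constant in kJ/mol/nm^2 (>= 0)
#' @param dim dimensionality (1, 2 or 3)
#' @param center minimum position, length `dim`
#' @return a `toy_potential`
#' @export
build_harmonic <- function(k, dim = 1L, center = rep(0, dim)) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, length(center) == dim)
  dim <- as.integer(dim)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = dim)
  new_toy_potential(
    "harmonic", list(k = k, center = center), dim = dim,
    energy = function(x) {
      x <- as_mat(x)
      0.5 * k * rowSums(sweep(x, 2, center)^2)
    },
    gradient = function(x) {
      x <- as_mat(x)
      g <- k * sweep(x, 2, center)
      if (nrow(g) == 1) drop(g) else g
    },
    laplacian = function(x) {
      x <- as_mat(x)
      rep(k * dim, nrow(x))
    },
    feature_length = if (k > 0) 1 else Inf)
}

#' Configurational temperature estimator
#'
#' `T_conf = <|grad U|^2> / (kB <lap U>)`, an equipartition-style diagnostic:
#' on samples drawn from the Boltzmann distribution at temperature T it
#' converges to T for any smooth confining potential.
#'
#' @param potential a `toy_potential`
#' @param coords matrix of sampled configurations (rows) or vector for 1D
#' @return estimated temperature in K
#' @export
configurational_temperature <- function(potential, coords) {
  if (potential$dim == 1L) {
    g2 <- potential$gradient(coords)^2
    lap <- potential$laplacian(coords)
  } else {
    coords <- if (is.matrix(coords)) coords else matrix(coords, ncol = potential$dim)
    g <- potential$gradient(coords)
    g <- if (is.matrix(g)) g else matrix(g, ncol = potential$dim)
    g2 <- rowSums(g^2)
    lap <- potential$laplacian(coords)
  }
  mean(g2) / (kB * mean(lap))
}
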