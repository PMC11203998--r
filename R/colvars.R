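#' Funnel geometry
#'
#' Cone-plus-cylinder restraint frame: a cone of half-angle `alpha` opens from
#' the cylinder radius `R_cyl` at the cone-to-cylinder switching point `z_cc`
#' down towards the anchor, and a cylinder of radius `R_cyl` continues to the
#' harmonic upper wall at `z_wall`. CV1 is the projection of the ligand
#' heavy-atom centre of mass onto `axis`, measured from `anchor`. Defaults are
#' the integrin-binding setup: half-angle 0.35 rad, switch at 2.0 nm, cylinder
#' radius 1.0 Angstrom, upper wall at 5.5 nm with kappa 35,100 kJ/mol/nm^2.
#'
#' @param anchor funnel origin, length-3 nm
#' @param axis funnel axis direction (normalised internally)
#' @param alpha cone half-angle in rad, in (0, pi/2)
#' @param z_cc cone-to-cylinder switching point in nm (> 0)
#' @param R_cyl cylinder radius in nm (> 0)
#' @param z_wall axial upper-wall position in nm (> z_cc)
#' @param kappa_wall axial wall stiffness in kJ/mol/nm^2
#' @param kappa_funnel lateral (cone/cylinder) wall stiffness in kJ/mol/nm^2
#' @return a `funnel_geometry` object
#' @export
funnel_geometry <- function(anchor = c(0, 0, 0), axis = c(0, 0, 1),
                            alpha = 0.35, z_cc = 2.0, R_cyl = 0.1,
                            z_wall = 5.5, kappa_wall = 35100,
                            kappa_funnel = 35100) {
  stopifnot(length(anchor) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be non-zero")
  axis <- axis / nrm
  if (!(alpha > 0 && alpha < pi / 2)) stop("alpha must lie in (0, pi/2)")
  if (z_cc <= 0) stop("z_cc must be > 0")
  if (R_cyl <= 0) stop("R_cyl must be > 0")
  if (z_wall <= z_cc) stop("z_wall must exceed z_cc")
  if (kappa_wall < 0 || kappa_funnel < 0) stop("wall stiffness must be >= 0")
  structure(list(anchor = anchor, axis = axis, alpha = alpha, z_cc = z_cc,
                 R_cyl = R_cyl, z_wall = z_wall, kappa_wall = kappa_wall,
                 kappa_funnel = kappa_funnel),
            class = "funnel_geometry")
}

#' @export
print.funnel_geometry <- function(x, ...) {
  cat(sprintf(
    "funnel: alpha=%.3g rad, cone->cylinder at %.3g nm, R_cyl=%.3g nm,\n        wall at %.3g nm (kappa %g), lateral kappa %g\n",
    x$alpha, x$z_cc, x$R_cyl, x$z_wall, x$kappa_wall, x$kappa_funnel))
  invisible(x)
}

#' Funnel cross-section radius
#'
#' `R(z) = (z_cc - z) tan(alpha) + R_cyl` in the cone (z <= z_cc) and
#' `R(z) = R_cyl` in the cylinder; continuous at `z_cc` with the kink there
#' intended (one-sided slopes -tan(alpha) and 0).
#'
#' @param z axial position(s) in nm
#' @param funnel a `funnel_geometry`
#' @return radius in nm, vectorised over `z`
#' @export
funnel_radius <- function(z, funnel) {
  ifelse(z <= funnel$z_cc,
         (funnel$z_cc - z) * tan(funnel$alpha) + funnel$R_cyl,
         funnel$R_cyl)
}

#' Rational switching function parameters
#'
#' Defaults `d0 = 0`, `r0 = 1` nm, `n = 6`, `m = 12` (m = 2n), the values used
#' for the contact-map collective variable.
#'
#' @param d0,r0 offset and switch distance in nm (`r0 > 0`)
#' @param n,m exponents (integers, `m > n > 0`)
#' @export
switching_params <- function(d0 = 0, r0 = 1, n = 6L, m = 12L) {
  if (r0 <= 0) stop("r0 must be > 0")
  n <- as.integer(n); m <- as.integer(m)
  if (!(m > n && n > 0)) stop("require m > n > 0")
  structure(list(d0 = d0, r0 = r0, n = n, m = m), class = "switching_params")
}

#' Rational switching function
#'
#' `s(r) = (1 - x^n) / (1 - x^m)` with `x = (r - d0)/r0`; a smooth, strictly
#' decreasing map of distance onto (0, 1]. The removable singularity at
#' `x = 1` equals `n/m`; a guard band of `1e-4 r0` around it evaluates a
#' third-order series expansion, because the rational form loses up to six
#' digits to cancellation there while the series is accurate to round-off.
#' For `r <= d0` the function saturates at 1 with zero gradient.
#'
#' @param r distance(s) in nm, `r >= 0`
#' @param p a `switching_params`
#' @return list with `value` and `gradient` (ds/dr, per nm), vectorised
#' @export
rational_switch <- function(r, p = switching_params()) {
  if (any(r < 0)) stop("rational_switch requires r >= 0")
  x <- (r - p$d0) / p$r0
  n <- p$n; m <- p$m
  s <- numeric(length(x)); ds <- numeric(length(x))

  lo <- x <= 0
  s[lo] <- 1; ds[lo] <- 0

  guard <- abs(x - 1) < 1e-4
  reg <- !lo & !guard
  xr <- x[reg]
  xn <- xr^n; xm <- xr^m
  s[reg] <- (1 - xn) / (1 - xm)
  ds[reg] <- (-n * xn / xr * (1 - xm) + m * xm / xr * (1 - xn)) /
    (1 - xm)^2 / p$r0

  if (any(guard)) {
    # cubic series about x = 1: s = (n/m)(1 + c1 e + c2 e^2 + c3 e^3)
    e <- x[guard] - 1
    a1 <- (n - 1) / 2; a2 <- (n - 1) * (n - 2) / 6
    a3 <- (n - 1) * (n - 2) * (n - 3) / 24
    b1 <- (m - 1) / 2; b2 <- (m - 1) * (m - 2) / 6
    b3 <- (m - 1) * (m - 2) * (m - 3) / 24
    c1 <- a1 - b1
    c2 <- a2 - a1 * b1 + b1^2 - b2
    c3 <- a3 - a2 * b1 + a1 * (b1^2 - b2) + (-b1^3 + 2 * b1 * b2 - b3)
    s[guard] <- (n / m) * (1 + c1 * e + c2 * e^2 + c3 * e^3)
    ds[guard] <- (n / m) * (c1 + 2 * c2 * e + 3 * c3 * e^2) / p$r0
  }
  list(value = s, gradient = ds)
}

#' Funnel-axis centre-of-mass projection (CV1)
#'
#' Mass-weighted centre of mass over the ligand's heavy beads, projected onto
#' the funnel axis: `CV1 = (COM - anchor) . axis` in nm. Also returns the
#' radial distance of the COM from the axis (consumed by the funnel
#' restraint) and, on request, the gradient of CV1 with respect to every
#' coordinate.
#'
#' @param coords n x 3 matrix of bead coordinates in nm
#' @param heavy indices of heavy beads used for the COM
#' @param masses per-bead masses (full length n)
#' @param funnel a `funnel_geometry`
#' @param gradient if TRUE, include `d_cv1` (n x 3 matrix)
#' @return list: `cv1` (nm), `radial` (nm), `com` (length 3), optional `d_cv1`
#' @export
cv_funnel_projection <- function(coords, heavy, masses, funnel,
                                 gradient = FALSE) {
  coords <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  if (length(heavy) < 1) stop("need at least one heavy bead")
  mh <- masses[heavy]
  M <- sum(mh)
  if (M <= 0) stop("zero total mass over heavy beads")
  com <- drop(mh %*% coords[heavy, , drop = FALSE]) / M
  rel <- com - funnel$anchor
  z <- sum(rel * funnel$axis)
  perp <- rel - z * funnel$axis
  out <- list(cv1 = z, radial = sqrt(sum(perp^2)), com = com)
  if (gradient) {
    g <- matrix(0, nrow(coords), 3)
    g[heavy, ] <- outer(mh / M, funnel$axis)
    out$d_cv1 <- g
  }
  out
}

#' Contact-map specification
#'
#' Atom-index pairs with per-pair switching parameters and reference switched
#' values `s_ref`, defining the contact-map distance CV2. The integrin setup
#' uses eight such pairs. Two formula variants exist (see [cmdist()]).
#'
#' @param pairs 2-column integer matrix of bead indices (one row per contact)
#' @param switching a single `switching_params` or a list of one per pair
#' @param s_ref reference switched values, each in (0, 1]
#' @param variant `"printed"` (difference of sums of squares, the protocol's
#'   stated form) or `"squared_difference"` (sum of squared deviations)
#' @export
contact_map_spec <- function(pairs, switching = switching_params(), s_ref,
                             variant = c("printed", "squared_difference")) {
  variant <- match.arg(variant)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (inherits(switching, "switching_params"))
    switching <- rep(list(switching), nrow(pairs))
  if (length(switching) != nrow(pairs) || length(s_ref) != nrow(pairs))
    stop("need one switching parameter set and one s_ref per pair")
  if (any(s_ref <= 0 | s_ref > 1)) stop("s_ref values must lie in (0, 1]")
  structure(list(pairs = pairs, switching = switching, s_ref = s_ref,
                 variant = variant),
            class = "contact_map_spec")
}

#' Contact-map distance (CV2)
#'
#' Deviation of the current switched contact map from its reference map.
#' The `"printed"` variant is `sum(s_ref^2) - sum(s^2)` (difference of sums of
#' squares: permutation-insensitive, can be negative); the
#' `"squared_difference"` variant is `sum((s - s_ref)^2)`. The variant used is
#' recorded in the result.
#'
#' @param coords n x 3 coordinate matrix in nm
#' @param spec a `contact_map_spec`
#' @param gradient if TRUE, include `d_cv2`, the n x 3 gradient
#' @return list: `cv2` (dimensionless), `s` per-pair switched values,
#'   `variant`, optional `d_cv2`
#' @export
cmdist <- function(coords, spec, gradient = FALSE) {
  coords <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  np <- nrow(spec$pairs)
  if (any(spec$pairs < 1 | spec$pairs > nrow(coords)))
    stop("contact_map_spec refers to bead indices outside the coordinate set")
  s <- numeric(np); dsdr <- numeric(np)
  dvec <- matrix(0, np, 3); rlen <- numeric(np)
  for (i in seq_len(np)) {
    a <- spec$pairs[i, 1]; b <- spec$pairs[i, 2]
    d <- coords[a, ] - coords[b, ]
    r <- sqrt(sum(d^2))
    sw <- rational_switch(r, spec$switching[[i]])
    s[i] <- sw$value; dsdr[i] <- sw$gradient
    rlen[i] <- r; dvec[i, ] <- d
  }
  cv2 <- switch(spec$variant,
                printed = sum(spec$s_ref^2) - sum(s^2),
                squared_difference = sum((s - spec$s_ref)^2))
  out <- list(cv2 = cv2, s = s, variant = spec$variant)
  if (gradient) {
    # dCV2/ds_i, then chain rule through r_i
    dcds <- switch(spec$variant,
                   printed = -2 * s,
                   squared_difference = 2 * (s - spec$s_ref))
    g <- matrix(0, nrow(coords), 3)
    for (i in seq_len(np)) {
      if (rlen[i] == 0) next  # measure-zero coincident pair: no direction
      rhat <- dvec[i, ] / rlen[i]
      contrib <- dcds[i] * dsdr[i] * rhat
      a <- spec$pairs[i, 1]; b <- spec$pairs[i, 2]
      g[a, ] <- g[a, ] + contrib
      g[b, ] <- g[b, ] - contrib
    }
    out$d_cv2 <- g
  }
  out
}
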