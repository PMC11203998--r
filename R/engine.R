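#' Run funnel metadynamics with the compiled engine
#'
#' Propagates one or more walkers of a point ligand on a toy potential with
#' the full bias stack: well-tempered hill deposition on CV1 (the funnel-axis
#' projection; the bare coordinate for 1D systems), funnel restraint walls,
#' and an optional moving restraint. Walkers share one hills ledger,
#' serviced round-robin one deposition stride at a time: each walker sees
#' every hill deposited by the others before its own next segment (the
#' multiple-walker eventual-consistency contract). Per-walker RNG streams
#' are counter-based, keyed by (seed, walker id), so the stream of walker w
#' does not depend on how many walkers run.
#'
#' @param x0 initial coordinates: numeric vector (single walker) or a
#'   walkers x dim matrix, in nm
#' @param potential a `toy_potential` (kinds: double_well_1d,
#'   funnel_pocket_3d, harmonic)
#' @param params an `integrator_params`
#' @param metad a `wt_metad_params`, or `NULL` to run without deposition;
#'   its `grid_min`/`grid_max` must be set (CV1 grid range)
#' @param funnel a `funnel_geometry` (required for 3D runs; also defines the
#'   CV1 frame) or `NULL`
#' @param restraint a `moving_restraint_schedule` or `NULL`
#' @param static_bias optional `hills_ledger` applied as a fixed bias (no
#'   tempering, not included in the returned ledger)
#' @param seed integer seed for the walker RNG streams
#' @param t0 start time in ps
#' @return list: `colvar` data.frame (time, walker, cv1, coordinates, bias),
#'   `ledger` (`hills_ledger` of deposited hills), `grid` (`bias_grid` cache
#'   or NULL), `x_final`, `v_final`, `n_clipped`, `max_displacement`
#' @export
run_metad <- function(x0, potential, params, metad = NULL, funnel = NULL,
                      restraint = NULL, static_bias = NULL, seed = 1L,
                      t0 = 0) {
  x0 <- if (is.matrix(x0)) x0 else matrix(x0, nrow = 1)
  dim <- ncol(x0)
  if (dim != potential$dim) stop("x0 dimensionality does not match the potential")
  if (dim == 3 && is.null(funnel))
    stop("3D runs need a funnel_geometry (it defines the CV1 frame)")
  pot_kind <- switch(potential$kind,
                     double_well_1d = 1L, funnel_pocket_3d = 2L,
                     harmonic = 3L,
                     stop("unsupported potential kind for the compiled engine"))
  pot_params <- switch(potential$kind,
    double_well_1d = c(potential$params$a, potential$params$b),
    funnel_pocket_3d = c(potential$params$D, potential$params$sigma_pocket,
                         potential$params$wall_stiffness),
    harmonic = c(potential$params$k, potential$params$center))

  do_metad <- !is.null(metad)
  if (do_metad && (is.null(metad$grid_min) || is.null(metad$grid_max)))
    stop("metad parameters must declare grid_min and grid_max for CV1")
  sh <- matrix(0, 0, 3)
  if (!is.null(static_bias)) {
    if (length(static_bias$cv_names) != 1)
      stop("static bias must be a 1-CV ledger")
    sh <- cbind(drop(ledger_centers(static_bias)),
                drop(ledger_sigmas(static_bias)),
                static_bias$records$height)
    sh <- matrix(sh, ncol = 3)
  }
  grid_lo <- if (do_metad) metad$grid_min[1] else if (nrow(sh) > 0)
    min(sh[, 1] - 6 * sh[, 2]) else 0
  grid_hi <- if (do_metad) metad$grid_max[1] else if (nrow(sh) > 0)
    max(sh[, 1] + 6 * sh[, 2]) else 1
  spacing <- if (do_metad) metad$grid_spacing[1] else
    if (nrow(sh) > 0) min(sh[, 2]) / 8 else 0.1

  fp <- if (is.null(funnel)) numeric(12) else
    c(funnel$anchor, funnel$axis, funnel$alpha, funnel$z_cc, funnel$R_cyl,
      funnel$z_wall, funnel$kappa_wall, funnel$kappa_funnel)

  res <- metad_engine(
    x0, pot_kind, pot_params, params$scheme, params$dt, params$friction,
    params$temperature, params$mass, as.double(params$n_steps),
    params$save_stride,
    do_metad,
    if (do_metad) metad$h0 else 0,
    if (do_metad) metad$sigma[1] else 0.1,
    if (do_metad) metad$stride else 0L,
    if (do_metad) metad$gamma else Inf,
    grid_lo, grid_hi, spacing,
    !is.null(funnel), fp,
    !is.null(restraint),
    if (is.null(restraint)) numeric(0) else restraint$times,
    if (is.null(restraint)) numeric(0) else restraint$centers,
    if (is.null(restraint)) numeric(0) else restraint$kappas,
    sh, as.integer(seed), t0)

  colvar <- as.data.frame(res$colvar)
  names(colvar) <- c("time", "walker", "cv1",
                     c("x", "y", "z")[seq_len(dim)], "bias")
  hm <- res$hills
  hl <- data.frame(time = hm[, 1], cv1 = hm[, 2], sigma_cv1 = hm[, 3],
                   height = hm[, 4],
                   biasf = rep(if (do_metad) metad$gamma else Inf, nrow(hm)),
                   walker = as.integer(hm[, 5]))
  ledger <- hills_ledger("cv1", hl[order(hl$time, hl$walker), , drop = FALSE])
  grid <- NULL
  if (!is.null(res$grid) && length(res$grid) > 0) {
    g <- res$grid
    grid <- structure(list(
      x = seq(g$lo, g$hi, length.out = length(g$V)),
      V = g$V, V1 = g$V1, V2 = g$V2, spacing = g$spacing),
      class = "bias_grid")
  }
  if (res$max_displacement > 0.5 * potential$feature_length)
    warning(sprintf("max per-step displacement %.3g nm exceeds half the feature length; dt too large",
                    res$max_displacement))
  list(colvar = colvar, ledger = ledger, grid = grid,
       x_final = res$x_final, v_final = res$v_final,
       n_clipped = res$n_clipped, max_displacement = res$max_displacement,
       time_final = res$time_final)
}
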