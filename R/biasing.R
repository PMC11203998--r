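#' Well-tempered metadynamics parameters
#'
#' Defaults are the binding-protocol settings: initial height 2.0 kJ/mol,
#' widths 0.1 nm (CV1) and 0.5 (CV2), deposition every 500 steps (1 ps at a
#' 2 fs step in the original protocol; at toy time steps the stride is kept in
#' steps), bias factor gamma = 20, T = 310 K.
#'
#' @param h0 initial Gaussian height, kJ/mol (> 0)
#' @param sigma per-CV Gaussian widths (named or in CV order); all > 0
#' @param stride deposition interval in integrator steps (>= 1)
#' @param gamma bias factor (> 1; `Inf` gives untempered metadynamics)
#' @param temperature system temperature in K
#' @param grid_min,grid_max,grid_spacing per-CV grid extents for the cached
#'   bias (spacing defaults to `sigma / 8`)
#' @export
wt_metad_params <- function(h0 = 2.0, sigma = c(cv1 = 0.1), stride = 500L,
                            gamma = 20, temperature = 310,
                            grid_min = NULL, grid_max = NULL,
                            grid_spacing = sigma / 8) {
  if (h0 <= 0) stop("h0 must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (gamma <= 1) stop("gamma must be > 1")
  if (stride < 1) stop("stride must be >= 1")
  structure(list(h0 = h0, sigma = sigma, stride = as.integer(stride),
                 gamma = gamma, temperature = temperature,
                 grid_min = grid_min, grid_max = grid_max,
                 grid_spacing = grid_spacing),
            class = "wt_metad_params")
}

#' Hills ledger
#'
#' Time-ordered record of deposited Gaussians: one row per hill with the
#' deposition time (ps), the CV-space centre, per-CV widths, the deposited
#' (already tempered) height in kJ/mol, the bias factor, and the walker id.
#' The ledger is the complete state of the metadynamics bias; any cached grid
#' must agree with direct summation over these records.
#'
#' @param cv_names character vector of CV names (ledger dimensionality)
#' @param records optional data.frame with columns `time`, one per CV name,
#'   `sigma_<cv>`, `height`, `biasf`, `walker`
#' @export
hills_ledger <- function(cv_names = "cv1", records = NULL) {
  cols <- c("time", cv_names, paste0("sigma_", cv_names),
            "height", "biasf", "walker")
  if (is.null(records)) {
    records <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    if (!all(cols %in% names(records)))
      stop("ledger records missing columns: ",
           paste(setdiff(cols, names(records)), collapse = ", "))
    records <- records[, cols, drop = FALSE]
    if (is.unsorted(records$time)) stop("ledger times must be non-decreasing")
  }
  structure(list(cv_names = cv_names, records = records),
            class = "hills_ledger")
}

n_hills <- function(ledger) nrow(ledger$records)

#' @export
print.hills_ledger <- function(x, ...) {
  cat(sprintf("hills_ledger: %d hills on (%s), %d walker(s)\n",
              n_hills(x), paste(x$cv_names, collapse = ", "),
              length(unique(x$records$walker))))
  invisible(x)
}

ledger_centers <- function(ledger)
  as.matrix(ledger$records[, ledger$cv_names, drop = FALSE])

ledger_sigmas <- function(ledger)
  as.matrix(ledger$records[, paste0("sigma_", ledger$cv_names), drop = FALSE])

#' Metadynamics bias value and gradient
#'
#' `V(s) = sum_k h_k prod_j exp(-(s_j - c_kj)^2 / (2 sigma_kj^2))`, truncated
#' beyond 6 sigma per hill and per CV. `method = "direct"` sums the ledger
#' records (the reference path, used for hill-height bookkeeping);
#' `method = "grid"` evaluates a quintic-Hermite interpolant of a node cache
#' built by [build_bias_grid()] (1-CV ledgers) and agrees with direct
#' summation to well under 1e-6 kJ/mol.
#'
#' @param s CV values: vector (one point per element for 1-CV ledgers) or
#'   matrix with one row per point
#' @param ledger a `hills_ledger`
#' @param method `"direct"` or `"grid"`
#' @param grid a cached grid from [build_bias_grid()] (required for `"grid"`)
#' @return list `value` (kJ/mol) and `gradient` (points x n_cv matrix)
#' @export
bias_value_and_gradient <- function(s, ledger, method = c("direct", "grid"),
                                    grid = NULL) {
  method <- match.arg(method)
  ncv <- length(ledger$cv_names)
  s <- if (is.matrix(s)) s else matrix(s, ncol = ncv)
  if (method == "grid") {
    if (is.null(grid)) stop("grid method requires a grid from build_bias_grid()")
    if (ncv != 1) stop("grid fast path is implemented for 1-CV ledgers")
    return(grid_eval(grid, drop(s)))
  }
  np <- nrow(s)
  V <- numeric(np)
  G <- matrix(0, np, ncv)
  if (n_hills(ledger) == 0) return(list(value = V, gradient = G))
  cen <- ledger_centers(ledger)
  sig <- ledger_sigmas(ledger)
  h <- ledger$records$height
  for (p in seq_len(np)) {
    d <- sweep(cen, 2, s[p, ], "-")            # hills x ncv
    z <- d / sig
    keep <- rowSums(abs(z) > 6) == 0           # 6-sigma truncation
    if (!any(keep)) next
    g <- h[keep] * exp(-rowSums((z[keep, , drop = FALSE])^2) / 2)
    V[p] <- sum(g)
    for (j in seq_len(ncv))
      G[p, j] <- sum(g * d[keep, j] / sig[keep, j]^2)
  }
  list(value = V, gradient = G)
}

#' Build the cached bias grid for a 1-CV ledger
#'
#' Stores the exact direct-summation value, first and second derivative of
#' the bias at uniform nodes; [bias_value_and_gradient()] with
#' `method = "grid"` interpolates these with a two-point quintic Hermite
#' rule. At the nodes the cache equals direct summation to round-off.
#'
#' @param ledger a 1-CV `hills_ledger`
#' @param lo,hi grid extent (defaults pad the hill centres by 6 sigma)
#' @param spacing node spacing (default `min sigma / 8`)
#' @export
build_bias_grid <- function(ledger, lo = NULL, hi = NULL, spacing = NULL) {
  if (length(ledger$cv_names) != 1) stop("grid cache supports 1-CV ledgers")
  cen <- drop(ledger_centers(ledger))
  sig <- drop(ledger_sigmas(ledger))
  h <- ledger$records$height
  if (is.null(spacing)) spacing <- min(sig) / 8
  if (is.null(lo)) lo <- min(cen - 6 * sig)
  if (is.null(hi)) hi <- max(cen + 6 * sig)
  x <- seq(lo, hi, by = spacing)
  V <- numeric(length(x)); V1 <- numeric(length(x)); V2 <- numeric(length(x))
  for (k in seq_along(h)) {
    d <- cen[k] - x
    keep <- abs(d / sig[k]) <= 6     # same truncation test as the direct path
    if (!any(keep)) next
    g <- h[k] * exp(-d[keep]^2 / (2 * sig[k]^2))
    V[keep] <- V[keep] + g
    V1[keep] <- V1[keep] + g * d[keep] / sig[k]^2
    V2[keep] <- V2[keep] + g * (d[keep]^2 / sig[k]^2 - 1) / sig[k]^2
  }
  structure(list(x = x, V = V, V1 = V1, V2 = V2, spacing = spacing),
            class = "bias_grid")
}

# quintic Hermite evaluation of a bias_grid at points s (value + d/ds)
grid_eval <- function(grid, s) {
  x <- grid$x; hstep <- grid$spacing
  i <- pmin(pmax(findInterval(s, x), 1L), length(x) - 1L)
  t <- (s - x[i]) / hstep
  # quintic Hermite basis on [0,1] matching f, f', f'' at both ends
  t2 <- t^2; t3 <- t2 * t; t4 <- t3 * t; t5 <- t4 * t
  H00 <- 1 - 10 * t3 + 15 * t4 - 6 * t5
  H10 <- t - 6 * t3 + 8 * t4 - 3 * t5
  H20 <- 0.5 * t2 - 1.5 * t3 + 1.5 * t4 - 0.5 * t5
  H01 <- 10 * t3 - 15 * t4 + 6 * t5
  H11 <- -4 * t3 + 7 * t4 - 3 * t5
  H21 <- 0.5 * t3 - t4 + 0.5 * t5
  dH00 <- -30 * t2 + 60 * t3 - 30 * t4
  dH10 <- 1 - 18 * t2 + 32 * t3 - 15 * t4
  dH20 <- t - 4.5 * t2 + 6 * t3 - 2.5 * t4
  dH01 <- 30 * t2 - 60 * t3 + 30 * t4
  dH11 <- -12 * t2 + 28 * t3 - 15 * t4
  dH21 <- 1.5 * t2 - 4 * t3 + 2.5 * t4
  f0 <- grid$V[i]; f1 <- grid$V[i + 1L]
  g0 <- grid$V1[i]; g1 <- grid$V1[i + 1L]
  c0 <- grid$V2[i]; c1 <- grid$V2[i + 1L]
  val <- H00 * f0 + H10 * hstep * g0 + H20 * hstep^2 * c0 +
    H01 * f1 + H11 * hstep * g1 + H21 * hstep^2 * c1
  der <- (dH00 * f0 + dH01 * f1) / hstep +
    dH10 * g0 + dH11 * g1 +
    hstep * (dH20 * c0 + dH21 * c1)
  list(value = val, gradient = matrix(der, ncol = 1))
}

#' Deposit a well-tempered hill
#'
#' Appends a Gaussian at the current CV point with height
#' `h = h0 exp(-V(s) / (kB DeltaT))`, `DeltaT = (gamma - 1) T`, where `V(s)`
#' is the bias already accumulated at `s` (direct summation over the ledger,
#' 6-sigma truncated). `gamma = Inf` keeps the height at `h0` (untempered
#' limit). Points outside the declared grid range are clipped with a warning.
#'
#' @param ledger a `hills_ledger`
#' @param s_now current CV values (length = number of CVs)
#' @param params a `wt_metad_params`
#' @param time deposition time in ps
#' @param walker walker id (integer)
#' @return the updated ledger
#' @export
deposit_hill <- function(ledger, s_now, params, time = 0, walker = 0L) {
  ncv <- length(ledger$cv_names)
  stopifnot(length(s_now) == ncv)
  if (!is.null(params$grid_min)) {
    below <- s_now < params$grid_min; above <- s_now > params$grid_max
    if (any(below | above)) {
      warning("hill centre outside grid range; clipped")
      s_now <- pmin(pmax(s_now, params$grid_min), params$grid_max)
    }
  }
  V <- bias_value_and_gradient(s_now, ledger)$value
  if (!is.finite(V)) stop("non-finite accumulated bias at deposition point")
  h <- if (is.infinite(params$gamma)) params$h0 else
    params$h0 * exp(-V / (kB * (params$gamma - 1) * params$temperature))
  sig <- rep(params$sigma, length.out = ncv)
  row <- as.data.frame(c(list(time = as.numeric(time)),
                         setNames(as.list(s_now), ledger$cv_names),
                         setNames(as.list(sig), paste0("sigma_", ledger$cv_names)),
                         list(height = h, biasf = params$gamma,
                              walker = as.integer(walker))))
  ledger$records <- rbind(ledger$records, row)
  ledger
}

#' Replay a ledger's well-tempered heights
#'
#' Recomputes every stored height from the record order alone: for hill k the
#' bias at its centre is the 6-sigma-truncated sum over hills 1..k-1, and the
#' height follows the well-tempered law. A correctly produced ledger replays
#' to its stored heights to round-off (<= 1e-12 kJ/mol), which is the
#' determinism contract of the shared-bias protocol.
#'
#' @param ledger a `hills_ledger`
#' @param h0 initial hill height used during the run
#' @param temperature run temperature in K
#' @return numeric vector of recomputed heights
#' @export
replay_hill_heights <- function(ledger, h0, temperature) {
  cen <- ledger_centers(ledger)
  sig <- ledger_sigmas(ledger)
  h <- ledger$records$height
  gamma <- ledger$records$biasf
  out <- numeric(length(h))
  for (k in seq_along(h)) {
    if (k == 1) V <- 0 else {
      d <- sweep(cen[seq_len(k - 1), , drop = FALSE], 2, cen[k, ], "-")
      z <- d / sig[seq_len(k - 1), , drop = FALSE]
      keep <- rowSums(abs(z) > 6) == 0
      V <- sum(h[seq_len(k - 1)][keep] *
                 exp(-rowSums(z[keep, , drop = FALSE]^2) / 2))
    }
    out[k] <- if (is.infinite(gamma[k])) h0 else
      h0 * exp(-V / (kB * (gamma[k] - 1) * temperature))
  }
  out
}

#' Time-averaged bias ledger for reweighting
#'
#' Returns a ledger whose heights represent the metadynamics bias averaged
#' over the final fraction of the deposition history (uniform average over
#' ledger prefixes): hills deposited before the averaging window keep full
#' weight, later hills are down-weighted linearly by how many of the
#' averaged snapshots contain them. Reweighting against this averaged bias
#' suppresses the late-time fluctuations of a single final-bias snapshot
#' while remaining a static, deterministic bias.
#'
#' @param ledger a `hills_ledger`
#' @param fraction trailing fraction of depositions to average over (0, 1]
#' @return a `hills_ledger` with re-weighted heights
#' @export
time_averaged_ledger <- function(ledger, fraction = 0.3) {
  stopifnot(fraction > 0, fraction <= 1)
  rec <- ledger$records
  K <- nrow(rec)
  if (K == 0) return(ledger)
  m <- max(1L, ceiling(fraction * K))  # snapshots V_k, k = K-m+1 .. K
  w <- pmin(1, (K - seq_len(K) + 1) / m)
  rec$height <- rec$height * w
  hills_ledger(ledger$cv_names, rec)
}

#' Funnel restraint energy and force on the ligand COM
#'
#' Zero inside the funnel; outside, harmonic in the violation: lateral term
#' `kappa_funnel (d_radial - R(z))^2 / 2` beyond the cone/cylinder surface,
#' axial upper wall `kappa_wall (z - z_wall)^2 / 2` beyond the cylinder cap,
#' and a lower axial guard `kappa_wall z^2 / 2` for z < 0 that closes the
#' sampling domain behind the anchor. Each onset is C1-continuous.
#'
#' @param com ligand COM position, length-3 nm
#' @param funnel a `funnel_geometry`
#' @return list `energy` (kJ/mol) and `force` (length-3, kJ/mol/nm, acting on
#'   the COM)
#' @export
funnel_restraint <- function(com, funnel) {
  rel <- com - funnel$anchor
  z <- sum(rel * funnel$axis)
  perp <- rel - z * funnel$axis
  d <- sqrt(sum(perp^2))
  E <- 0; F <- c(0, 0, 0)
  R <- funnel_radius(z, funnel)
  if (d > R) {
    exc <- d - R
    E <- E + 0.5 * funnel$kappa_funnel * exc^2
    rhat <- perp / d
    dRdz <- if (z <= funnel$z_cc) -tan(funnel$alpha) else 0
    # d(exc)/dcom = rhat - dR/dz * axis
    F <- F - funnel$kappa_funnel * exc * (rhat - dRdz * funnel$axis)
  }
  if (z > funnel$z_wall) {
    E <- E + 0.5 * funnel$kappa_wall * (z - funnel$z_wall)^2
    F <- F - funnel$kappa_wall * (z - funnel$z_wall) * funnel$axis
  }
  if (z < 0) {
    E <- E + 0.5 * funnel$kappa_wall * z^2
    F <- F - funnel$kappa_wall * z * funnel$axis
  }
  list(energy = E, force = F)
}

#' Moving-restraint schedule (steered pulling on CV1)
#'
#' Piecewise-linear keyframes of harmonic-centre position and spring
#' constant. The binding-protocol presets start the centre at 0.4 nm with
#' zero spring, reach 4.5 nm and 1000 kJ/mol/nm^2 at 5 ns, and then either
#' hold (`"hold"`) or relax the spring back to zero at 10 ns (`"release"`) —
#' both readings of the original schedule are provided.
#'
#' @param times keyframe times in ps (strictly increasing)
#' @param centers keyframe CV1 centres in nm
#' @param kappas keyframe spring constants in kJ/mol/nm^2 (>= 0)
#' @export
moving_restraint_schedule <- function(times, centers, kappas) {
  stopifnot(length(times) == length(centers), length(times) == length(kappas))
  if (any(diff(times) <= 0)) stop("keyframe times must be strictly increasing")
  if (any(kappas < 0)) stop("kappa must be >= 0")
  structure(list(times = times, centers = centers, kappas = kappas),
            class = "moving_restraint_schedule")
}

#' @rdname moving_restraint_schedule
#' @param preset `"hold"` or `"release"`
#' @export
smd_schedule_preset <- function(preset = c("hold", "release")) {
  preset <- match.arg(preset)
  if (preset == "hold")
    moving_restraint_schedule(c(0, 5000), c(0.4, 4.5), c(0, 1000))
  else
    moving_restraint_schedule(c(0, 5000, 10000), c(0.4, 4.5, 4.5),
                              c(0, 1000, 0))
}

#' Moving-restraint energy and generalized force on CV1
#'
#' Centre and spring constant are interpolated linearly between bracketing
#' keyframes; `E = kappa(t) (cv1 - centre(t))^2 / 2`. Beyond the last
#' keyframe the last values are held (with a warning).
#'
#' @param cv1 current CV1 value in nm
#' @param schedule a `moving_restraint_schedule`
#' @param t time in ps (>= first keyframe)
#' @return list `energy`, `force` (dE/dcv1 negated), `center`, `kappa`
#' @export
moving_restraint <- function(cv1, schedule, t) {
  if (t < schedule$times[1]) stop("t precedes the first keyframe")
  nt <- length(schedule$times)
  if (t >= schedule$times[nt]) {
    if (t > schedule$times[nt]) warning("t beyond last keyframe; holding last values")
    ce <- schedule$centers[nt]; ka <- schedule$kappas[nt]
  } else {
    i <- findInterval(t, schedule$times)
    w <- (t - schedule$times[i]) / (schedule$times[i + 1] - schedule$times[i])
    ce <- schedule$centers[i] + w * (schedule$centers[i + 1] - schedule$centers[i])
    ka <- schedule$kappas[i] + w * (schedule$kappas[i + 1] - schedule$kappas[i])
  }
  list(energy = 0.5 * ka * (cv1 - ce)^2, force = -ka * (cv1 - ce),
       center = ce, kappa = ka)
}

#' Merge walker ledgers
#'
#' Union of hill records sorted by (time, walker id); duplicate
#' (time, walker) keys are rejected with both sources named.
#'
#' @param ledgers list of `hills_ledger` objects on identical CVs
#' @return one merged `hills_ledger`
#' @export
merge_walker_ledgers <- function(ledgers) {
  stopifnot(length(ledgers) >= 1)
  cvn <- ledgers[[1]]$cv_names
  for (l in ledgers)
    if (!identical(l$cv_names, cvn)) stop("ledgers disagree on CV names")
  rec <- do.call(rbind, lapply(ledgers, function(l) l$records))
  key <- paste(rec$time, rec$walker, sep = "@")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    src <- which(vapply(ledgers, function(l)
      any(paste(l$records$time, l$records$walker, sep = "@") == d), logical(1)))
    stop(sprintf("duplicate hill key (time=%s) present in ledgers %s",
                 d, paste(src, collapse = " and ")))
  }
  rec <- rec[order(rec$time, rec$walker), , drop = FALSE]
  rownames(rec) <- NULL
  hills_ledger(cvn, rec)
}

#' Walker starting positions along the funnel axis
#'
#' Regularly spaced CV1 start points for the multiple-walker protocol; the
#' binding setup uses ten walkers from 1.6 to 4.1 nm at 0.3 nm spacing.
#'
#' @param n number of walkers
#' @param from first CV1 position in nm
#' @param spacing spacing in nm
#' @export
walker_start_positions <- function(n = 10L, from = 1.6, spacing = 0.3) {
  from + spacing * (seq_len(n) - 1)
}
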