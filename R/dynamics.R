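#' Integrator parameters
#'
#' `scheme = "baoab"` is the default Langevin splitting (accurate
#' configurational sampling at comparatively large time steps);
#' `"overdamped"` is Euler--Maruyama Brownian dynamics with diffusion
#' constant `D = kT / (mass * friction)` per dimension. Time is in ps,
#' friction in 1/ps, temperature in K.
#'
#' @param scheme `"baoab"` or `"overdamped"`
#' @param dt time step in ps (> 0)
#' @param friction friction in 1/ps (> 0)
#' @param temperature temperature in K (>= 0)
#' @param mass particle mass (amu-scale; kJ/mol ps^2 / nm^2 units)
#' @param n_steps number of steps
#' @param save_stride record a frame every this many steps (>= 1)
#' @export
integrator_params <- function(scheme = c("baoab", "overdamped"), dt = 0.002,
                              friction = 1, temperature = 310, mass = 1,
                              n_steps = 1000L, save_stride = 500L) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction <= 0) stop("friction must be > 0")
  if (save_stride < 1) stop("save_stride must be >= 1")
  structure(list(scheme = scheme, dt = dt, friction = friction,
                 temperature = temperature, mass = mass,
                 n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride)),
            class = "integrator_params")
}

#' Simulation state
#'
#' @param coords coordinates in nm (length 1 or 3 for the toy particle)
#' @param velocities velocities in nm/ps (ignored in overdamped mode)
#' @param time current time in ps
#' @param walker walker id
#' @export
sim_state <- function(coords, velocities = rep(0, length(coords)), time = 0,
                      walker = 0L) {
  structure(list(coords = coords, velocities = velocities, time = time,
                 walker = as.integer(walker)),
            class = "sim_state")
}

#' Total force on the toy particle
#'
#' Negative gradient of: the physical potential, the metadynamics bias
#' (chain rule through each collective variable), the funnel restraint
#' (3D systems), and the moving restraint on CV1. Aborts with component
#' attribution if any contribution is non-finite.
#'
#' @param state a `sim_state`
#' @param potential a `toy_potential`
#' @param cvs list of CV functions `function(coords) -> list(value, grad)`;
#'   order must match the ledger's CVs. `NULL` for unbiased runs.
#' @param ledger a `hills_ledger` or `NULL`
#' @param funnel a `funnel_geometry` or `NULL` (3D only)
#' @param restraint a `moving_restraint_schedule` or `NULL` (applies to the
#'   first CV)
#' @return force vector in kJ/mol/nm
#' @export
total_force <- function(state, potential, cvs = NULL, ledger = NULL,
                        funnel = NULL, restraint = NULL) {
  x <- state$coords
  f <- -potential$gradient(x)
  if (!all(is.finite(f))) stop("non-finite force from the potential")
  cv_out <- NULL
  if (!is.null(cvs)) {
    cv_out <- lapply(cvs, function(cv) cv(x))
    s <- vapply(cv_out, `[[`, numeric(1), "value")
    if (!is.null(ledger) && n_hills(ledger) > 0) {
      bv <- bias_value_and_gradient(matrix(s, nrow = 1), ledger)
      for (j in seq_along(cvs)) {
        fb <- -bv$gradient[1, j] * cv_out[[j]]$grad
        if (!all(is.finite(fb))) stop("non-finite force from the bias (CV ", j, ")")
        f <- f + fb
      }
    }
    if (!is.null(restraint)) {
      mr <- moving_restraint(s[1], restraint, state$time)
      fr <- mr$force * cv_out[[1]]$grad
      if (!all(is.finite(fr))) stop("non-finite force from the moving restraint")
      f <- f + fr
    }
  }
  if (!is.null(funnel)) {
    if (length(x) != 3) stop("funnel restraint requires 3D coordinates")
    fw <- funnel_restraint(x, funnel)
    if (!all(is.finite(fw$force))) stop("non-finite force from the funnel restraint")
    f <- f + fw$force
  }
  f
}

#' One Langevin step
#'
#' Advances the state by `dt` under the given force field function, using
#' BAOAB splitting or overdamped Euler--Maruyama. Warns when a single-step
#' displacement exceeds half the potential's smallest feature length (time
#' step too large for the landscape).
#'
#' @param state a `sim_state`
#' @param force_fn `function(state) -> force vector`
#' @param params an `integrator_params`
#' @param feature_length smallest landscape feature in nm (for the step-size
#'   warning); `Inf` disables the check
#' @return the advanced `sim_state`
#' @export
langevin_step <- function(state, force_fn, params, feature_length = Inf) {
  d <- length(state$coords)
  kTm <- kB * params$temperature
  x_old <- state$coords
  if (params$scheme == "overdamped") {
    F <- force_fn(state)
    mob <- params$dt / (params$mass * params$friction)
    state$coords <- state$coords + mob * F +
      sqrt(2 * kTm * mob) * stats::rnorm(d)
  } else {
    F <- force_fn(state)
    v <- state$velocities + 0.5 * params$dt * F / params$mass
    x <- state$coords + 0.5 * params$dt * v
    c1 <- exp(-params$friction * params$dt)
    v <- c1 * v + sqrt(kTm / params$mass * (1 - c1^2)) * stats::rnorm(d)
    x <- x + 0.5 * params$dt * v
    state$coords <- x
    F2 <- force_fn(state)
    state$velocities <- v + 0.5 * params$dt * F2 / params$mass
  }
  state$time <- state$time + params$dt
  disp <- sqrt(sum((state$coords - x_old)^2))
  if (is.finite(feature_length) && disp > 0.5 * feature_length)
    warning(sprintf(
      "step displacement %.3g nm exceeds half the feature length %.3g nm; dt too large",
      disp, feature_length))
  state
}

#' Propagate one walker (reference implementation)
#'
#' Pure-R walker loop: every step evaluates CVs and the total force; every
#' `deposition stride` steps a well-tempered hill is deposited at the current
#' CV point; every `save_stride` steps a COLVAR row (time, CVs, bias) is
#' recorded. When `shared` is an environment holding `$ledger`, hills from
#' other walkers deposited there are read before each bias evaluation --
#' the multiple-walker eventual-consistency contract. For long runs use the
#' compiled engine ([run_metad()]); this path is the testable reference.
#'
#' @param state initial `sim_state`
#' @param potential a `toy_potential`
#' @param params an `integrator_params`
#' @param metad a `wt_metad_params` or `NULL` for unbiased runs
#' @param cvs CV function list (see [total_force()]); default: the bare
#'   coordinate for 1D systems
#' @param funnel optional `funnel_geometry`
#' @param restraint optional `moving_restraint_schedule`
#' @param shared optional environment with `$ledger` shared across walkers;
#'   if `NULL` a private ledger is created
#' @param seed optional integer seed (set before the loop)
#' @return list: `state` (final), `trajectory` (frames x dim matrix),
#'   `colvar` (data.frame time/CVs/bias), `ledger`
#' @export
run_walker <- function(state, potential, params, metad = NULL, cvs = NULL,
                       funnel = NULL, restraint = NULL, shared = NULL,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(state$coords)
  if (is.null(cvs)) {
    if (d == 1) cvs <- list(function(x) list(value = x, grad = 1))
    else if (!is.null(funnel)) {
      fn <- funnel
      cvs <- list(function(x) {
        pr <- cv_funnel_projection(matrix(x, 1, 3), 1L, 1, fn, gradient = TRUE)
        list(value = pr$cv1, grad = drop(pr$d_cv1))
      })
    } else stop("supply CV functions for multi-dimensional biased runs")
  }
  if (is.null(shared)) {
    shared <- new.env(parent = emptyenv())
    shared$ledger <- hills_ledger(paste0("cv", seq_along(cvs)))
  }
  force_fn <- function(st) total_force(st, potential, cvs, shared$ledger,
                                       funnel, restraint)
  n_save <- params$n_steps %/% params$save_stride
  traj <- matrix(NA_real_, n_save, d)
  col <- matrix(NA_real_, n_save, 2 + length(cvs))
  isave <- 0L
  for (step in seq_len(params$n_steps)) {
    state <- langevin_step(state, force_fn, params, potential$feature_length)
    s <- vapply(cvs, function(cv) cv(state$coords)$value, numeric(1))
    if (!is.null(metad) && step %% metad$stride == 0)
      shared$ledger <- deposit_hill(shared$ledger, s, metad,
                                    time = state$time, walker = state$walker)
    if (step %% params$save_stride == 0) {
      isave <- isave + 1L
      traj[isave, ] <- state$coords
      V <- bias_value_and_gradient(matrix(s, 1), shared$ledger)$value
      col[isave, ] <- c(state$time, s, V)
    }
  }
  colvar <- as.data.frame(col)
  names(colvar) <- c("time", paste0("cv", seq_along(cvs)), "bias")
  list(state = state, trajectory = traj, colvar = colvar,
       ledger = shared$ledger)
}
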