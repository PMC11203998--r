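#' Free-energy surface container
#'
#' Gridded free energy over 1-2 variables, min-normalised to 0 over visited
#' bins, with provenance (`"from_bias"`, `"reweighted"` or `"reference"`)
#' and temperature. `axes` hold bin centres (strictly increasing); `breaks`
#' the bin edges used to assign frames to bins (midpoints between centres
#' when the surface was not built from a histogram).
#'
#' @param variables character vector of variable names
#' @param axes named list of bin-centre vectors
#' @param F numeric array of free energies in kJ/mol
#' @param provenance origin of the surface
#' @param temperature temperature in K
#' @param visited logical array of visited bins (default: finite F)
#' @param breaks optional named list of bin-edge vectors
#' @export
free_energy_surface <- function(variables, axes, F, provenance, temperature,
                                visited = NULL, breaks = NULL) {
  F <- if (length(variables) == 1) as.numeric(F) else as.matrix(F)
  for (ax in axes) if (any(diff(ax) <= 0)) stop("grid axes must be strictly increasing")
  if (is.null(visited)) visited <- is.finite(F)
  if (!any(visited)) stop("free-energy surface has no visited bins")
  F[visited] <- F[visited] - min(F[visited])
  F[!visited] <- NA_real_
  if (is.null(breaks))
    breaks <- lapply(axes, function(ax) {
      if (length(ax) == 1) c(ax - 0.5, ax + 0.5)
      else c(ax[1] - diff(ax[1:2]) / 2, ax[-length(ax)] + diff(ax) / 2,
             ax[length(ax)] + diff(ax)[length(ax) - 1] / 2)
    })
  structure(list(variables = variables, axes = axes, F = F,
                 visited = visited, provenance = provenance,
                 temperature = temperature, breaks = breaks),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface (%s) over %s: %s bins, max %.3g kJ/mol\n",
              x$provenance, paste(x$variables, collapse = " x "),
              paste(lengths(x$axes), collapse = " x "),
              max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Free-energy surface from the deposited bias
#'
#' Well-tempered estimator: `F(s) = -(gamma/(gamma-1)) V(s) + C` with `V`
#' the accumulated bias (direct summation over the ledger) and `C` fixing
#' the minimum at zero.
#'
#' @param ledger a non-empty `hills_ledger`
#' @param params the `wt_metad_params` of the run (gamma, temperature)
#' @param axes named list of grid-node vectors, one per ledger CV
#' @return a `free_energy_surface` with provenance `"from_bias"`
#' @export
fes_from_bias <- function(ledger, params, axes) {
  if (n_hills(ledger) == 0) stop("cannot build a FES from an empty ledger")
  ncv <- length(ledger$cv_names)
  stopifnot(length(axes) == ncv)
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  V <- bias_direct_sum(pts, ledger_centers(ledger), ledger_sigmas(ledger),
                       ledger$records$height)
  gamma <- params$gamma
  fac <- if (is.infinite(gamma)) 1 else gamma / (gamma - 1)
  F <- -fac * V
  if (ncv == 2) F <- matrix(F, nrow = length(axes[[1]]))
  free_energy_surface(ledger$cv_names, axes, F, "from_bias",
                      params$temperature)
}

#' Reweighted free-energy surface from COLVAR records
#'
#' Final-bias (static-bias) reweighting: each frame gets weight
#' `w proportional to exp(+V_final(s_frame)/kT)` where `V_final` is the bias
#' at the end of the run evaluated at the frame's biased-CV values; the
#' weighted histogram over the target variables gives `F = -kT ln p`,
#' min-normalised, with unvisited bins flagged. With zero bias the weights
#' are all equal and the result is exactly the empirical histogram.
#' Adding any constant to the bias leaves the surface unchanged.
#'
#' @param colvar data.frame of frame records; must contain the ledger's CV
#'   columns and the `variables` columns
#' @param ledger the final `hills_ledger` (may be empty for identity
#'   reweighting)
#' @param temperature temperature in K
#' @param variables names of the 1-2 target variables to histogram
#' @param breaks named list of bin-edge vectors, one per target variable
#' @param method `"direct"` evaluates `V_final` per frame by direct
#'   summation; `"grid"` (1-CV ledgers) uses the quintic-Hermite grid cache,
#'   which agrees with direct summation to well under 1e-6 kJ/mol and is
#'   much faster on large ledgers
#' @return a `free_energy_surface` with provenance `"reweighted"`
#' @export
reweight_fes <- function(colvar, ledger, temperature, variables, breaks,
                         method = c("direct", "grid")) {
  method <- match.arg(method)
  stopifnot(length(variables) %in% 1:2, length(breaks) == length(variables))
  missing_cols <- setdiff(c(ledger$cv_names, variables), names(colvar))
  if (length(missing_cols))
    stop("colvar records lack columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(colvar)
  if (n_hills(ledger) > 0) {
    s <- as.matrix(colvar[, ledger$cv_names, drop = FALSE])
    if (method == "grid") {
      g <- build_bias_grid(ledger)
      V <- grid_eval(g, drop(s))$value
    } else {
      V <- bias_direct_sum(s, ledger_centers(ledger), ledger_sigmas(ledger),
                           ledger$records$height)
    }
  } else V <- numeric(n)
  w <- exp((V - max(V)) / (kB * temperature))
  if (all(w == 0)) stop("all reweighting weights are zero")

  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- matrix(0L, n, length(variables))
  for (j in seq_along(variables)) {
    idx[, j] <- findInterval(colvar[[variables[j]]], breaks[[j]],
                             rightmost.closed = TRUE)
    idx[idx[, j] < 1 | idx[, j] > nb[j], j] <- NA_integer_
  }
  keep <- stats::complete.cases(idx)
  lin <- if (length(variables) == 1) idx[keep, 1] else
    idx[keep, 1] + (idx[keep, 2] - 1L) * nb[1]
  wsum <- numeric(prod(nb))
  tab <- tapply(w[keep], lin, sum)
  wsum[as.integer(names(tab))] <- tab
  F <- -kB * temperature * log(wsum)
  visited <- wsum > 0
  centers <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  names(centers) <- variables
  if (length(variables) == 2) {
    F <- matrix(F, nrow = nb[1])
    visited <- matrix(visited, nrow = nb[1])
  }
  free_energy_surface(variables, centers, F, "reweighted", temperature,
                      visited = visited, breaks = breaks)
}

#' Locate the free-energy minimum
#'
#' Grid node of minimum F over visited bins; exact ties resolve to the
#' lexicographically smallest grid index (first axis most significant).
#'
#' @param fes a `free_energy_surface`
#' @return list `index` (integer vector), `coords` (named), `value` (kJ/mol)
#' @export
locate_minimum <- function(fes) {
  Fv <- fes$F
  m <- min(Fv[fes$visited])
  hit <- which(fes$visited & Fv == m, arr.ind = length(fes$variables) > 1)
  if (length(fes$variables) == 1) {
    i <- min(hit)
    idx <- i
  } else {
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    idx <- as.integer(hit[1, ])
  }
  coords <- vapply(seq_along(fes$variables),
                   function(j) fes$axes[[j]][idx[j]], numeric(1))
  names(coords) <- fes$variables
  list(index = as.integer(idx), coords = coords, value = m)
}

#' Bound region in CV space
#'
#' A box over the FES variables combined with a free-energy cutoff above the
#' minimum; the binding protocol uses the basin box around the bound state
#' and a 10 kJ/mol window.
#'
#' @param box named list of `c(lo, hi)` intervals, one per FES variable
#'   (a variable omitted from the box is unconstrained)
#' @param cutoff free-energy window above the minimum in kJ/mol (> 0);
#'   `Inf` disables the energy filter
#' @export
bound_region <- function(box, cutoff = 10) {
  if (!(cutoff > 0)) stop("cutoff must be > 0")
  for (b in box) if (length(b) != 2 || b[1] > b[2])
    stop("each box entry must be c(lo, hi)")
  structure(list(box = box, cutoff = cutoff), class = "bound_region")
}

#' Extract bound frames
#'
#' Frames whose CV values lie inside the region's box AND whose FES bin has
#' `F <= min + cutoff`. Frames falling in unvisited bins are excluded.
#' Deterministic and order-preserving; returns 1-based frame indices into
#' `colvar` (file output writes 0-based indices, see [write_frame_index()]).
#' An empty selection warns rather than errs.
#'
#' @param colvar data.frame with the FES variables as columns
#' @param fes a `free_energy_surface` (already min-normalised)
#' @param region a `bound_region`
#' @return integer vector of frame indices (1-based)
#' @export
extract_bound_frames <- function(colvar, fes, region) {
  nv <- length(fes$variables)
  n <- nrow(colvar)
  ok <- rep(TRUE, n)
  idx <- matrix(NA_integer_, n, nv)
  for (j in seq_len(nv)) {
    v <- colvar[[fes$variables[j]]]
    if (is.null(v)) stop("colvar lacks variable ", fes$variables[j])
    b <- region$box[[fes$variables[j]]]
    if (!is.null(b)) ok <- ok & v >= b[1] & v <= b[2]
    br <- fes$breaks[[j]]
    ij <- findInterval(v, br, rightmost.closed = TRUE)
    ij[ij < 1 | ij > length(fes$axes[[j]])] <- NA_integer_
    idx[, j] <- ij
  }
  inside <- ok & stats::complete.cases(idx)
  Fbin <- rep(NA_real_, n)
  lin <- if (nv == 1) idx[inside, 1] else
    idx[inside, 1] + (idx[inside, 2] - 1L) * length(fes$axes[[1]])
  Fbin[inside] <- fes$F[lin]
  sel <- which(inside & !is.na(Fbin) & Fbin <= region$cutoff)
  if (length(sel) == 0) warning("bound-frame selection is empty")
  sel
}

#' Basin free-energy difference from a 1D FES
#'
#' `dF = F(s > divide) - F(s < divide)` with
#' `F(basin) = -kT ln sum_basin exp(-F(s)/kT) ds`: the same functional the
#' quadrature oracle evaluates on the bare potential.
#'
#' @param fes a 1D `free_energy_surface`
#' @param divide basin divide on the FES variable
#' @return basin free-energy difference in kJ/mol
#' @export
basin_delta_f <- function(fes, divide = 0) {
  stopifnot(length(fes$variables) == 1)
  x <- fes$axes[[1]]
  dx <- c(diff(x), diff(x)[length(x) - 1])
  kTv <- kB * fes$temperature
  Fv <- fes$F
  vis <- fes$visited
  left <- vis & x < divide
  right <- vis & x > divide
  if (!any(left) || !any(right)) stop("a basin side has no visited bins")
  Fl <- -kTv * log(sum(exp(-Fv[left] / kTv) * dx[left]))
  Fr <- -kTv * log(sum(exp(-Fv[right] / kTv) * dx[right]))
  Fr - Fl
}
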