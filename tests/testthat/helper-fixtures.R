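# shared fixtures and small numeric oracles

# central finite difference of a scalar function of a vector
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(got, want, floor = 1e-8) {
  abs(got - want) / pmax(abs(want), floor)
}

# time-averaged basin free-energy difference over the final 20% of a ledger
avg_basin_delta_f <- function(ledger, params, axes, every = 100) {
  nh <- nrow(ledger$records)
  ks <- seq(ceiling(0.8 * nh), nh, by = every)
  mean(vapply(ks, function(k) {
    led <- hills_ledger(ledger$cv_names, ledger$records[seq_len(k), , drop = FALSE])
    basin_delta_f(fes_from_bias(led, params, axes))
  }, numeric(1)))
}

# random hills ledger on one CV
random_ledger_1d <- function(n, seed, lo = -1.5, hi = 1.5, sigma = 0.1) {
  set.seed(seed)
  hills_ledger("cv1", data.frame(
    time = seq_len(n), cv1 = runif(n, lo, hi),
    sigma_cv1 = rep(sigma, n),
    height = runif(n, 0.5, 2), biasf = rep(20, n),
    walker = rep(0L, n)))
}

# eight-contact map mimicking the binding-site reference set
example_cmap <- function(variant = "printed", n_beads = 16L, seed = 3) {
  set.seed(seed)
  pairs <- cbind(1:8, 9:16)
  coords <- matrix(runif(n_beads * 3, 0, 2), ncol = 3)
  r_ref <- sqrt(rowSums((coords[pairs[, 1], ] - coords[pairs[, 2], ])^2))
  s_ref <- rational_switch(r_ref, switching_params())$value
  list(spec = contact_map_spec(pairs, switching_params(), s_ref, variant),
       coords = coords)
}
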