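test_that("FES from bias applies the well-tempered scale factor", {
  expect_error(fes_from_bias(hills_ledger("cv1"), wt_metad_params(), list(cv1 = 0:1)),
               "empty ledger")
  # single hill: F = -(gamma/(gamma-1)) V, min-normalised
  mp <- wt_metad_params(h0 = 2, sigma = c(cv1 = 0.1), gamma = 20)
  led <- deposit_hill(hills_ledger("cv1"), 0.5, mp)
  ax <- list(cv1 = seq(0, 1, by = 0.05))
  fes <- fes_from_bias(led, mp, ax)
  V <- bias_value_and_gradient(ax$cv1, led)$value
  raw <- -(20 / 19) * V
  expect_equal(fes$F, raw - min(raw), tolerance = 1e-12)
  # a bias range of 9.5 kJ/mol maps to a 10 kJ/mol free-energy range
  expect_equal(max(fes$F) - min(fes$F), (20 / 19) * (max(V) - min(V)),
               tolerance = 1e-12)
  # near-uniform bias gives a flat surface
  mpw <- wt_metad_params(h0 = 2, sigma = c(cv1 = 5000), gamma = 20)
  ledw <- deposit_hill(hills_ledger("cv1"), 0, mpw)
  fesw <- fes_from_bias(ledw, mpw, ax)
  expect_lt(max(fesw$F), 1e-6)
})

test_that("minimum location breaks exact ties lexicographically", {
  f1 <- free_energy_surface("cv1", list(cv1 = 2.5), 0, "reference", 310)
  expect_equal(locate_minimum(f1)$coords, c(cv1 = 2.5))
  # constructed paraboloid: minimum at the centre node
  ax <- list(cv1 = seq(-1, 1, by = 0.25), cv2 = seq(-1, 1, by = 0.25))
  F2 <- outer(ax$cv1^2, ax$cv2^2, "+")
  m <- locate_minimum(free_energy_surface(c("cv1", "cv2"), ax, F2,
                                          "reference", 310))
  expect_equal(unname(m$coords), c(0, 0))
  expect_equal(m$value, 0)
  # two exactly equal minima: lexicographically first index wins
  F3 <- matrix(5, 3, 3)
  F3[2, 3] <- 0; F3[3, 1] <- 0
  m3 <- locate_minimum(free_energy_surface(
    c("cv1", "cv2"), list(cv1 = 1:3, cv2 = 1:3), F3, "reference", 310))
  expect_equal(m3$index, c(2L, 3L))
})

test_that("zero-bias reweighting is exactly the empirical histogram", {
  set.seed(4)
  x <- rnorm(5000, 0, 0.4)
  colvar <- data.frame(time = seq_along(x), cv1 = x)
  brk <- seq(-2, 2, by = 0.1)
  fes <- reweight_fes(colvar, hills_ledger("cv1"), 310, "cv1",
                      list(cv1 = brk))
  h <- hist(x[x >= -2 & x <= 2], breaks = brk, plot = FALSE)$counts
  Fh <- -kT(310) * log(h)
  Fh <- Fh - min(Fh[is.finite(Fh)])
  expect_identical(fes$visited, h > 0)
  expect_equal(fes$F[fes$visited], Fh[h > 0], tolerance = 1e-12)
})

test_that("reweighting is invariant to adding a constant to the bias", {
  set.seed(5)
  colvar <- data.frame(time = 1:2000, cv1 = rnorm(2000, 0.2, 0.3))
  led <- random_ledger_1d(20, seed = 6, lo = -0.5, hi = 0.8)
  # an extra quasi-constant hill (sigma >> sampled range) shifts V by ~h
  rec <- led$records
  rec <- rbind(rec, data.frame(time = 21, cv1 = 0, sigma_cv1 = 1e6,
                               height = 37, biasf = 20, walker = 0L))
  led_shift <- hills_ledger("cv1", rec)
  brk <- list(cv1 = seq(-1, 1.5, by = 0.1))
  f1 <- reweight_fes(colvar, led, 310, "cv1", brk)
  f2 <- reweight_fes(colvar, led_shift, 310, "cv1", brk)
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
})

test_that("grid-cached and direct reweighting agree", {
  set.seed(15)
  colvar <- data.frame(time = 1:3000, cv1 = runif(3000, -1.2, 1.2))
  led <- random_ledger_1d(200, seed = 16)
  brk <- list(cv1 = seq(-1.5, 1.5, by = 0.1))
  fd <- reweight_fes(colvar, led, 310, "cv1", brk)
  fg <- reweight_fes(colvar, led, 310, "cv1", brk, method = "grid")
  expect_equal(fd$F, fg$F, tolerance = 1e-7)
})

test_that("bias and reweighting estimators agree on the double-well dF", {
  dw <- build_double_well_1d(5, 1)
  ip <- integrator_params("overdamped", dt = 0.002, friction = 1,
                          temperature = 310, n_steps = 2e6, save_stride = 100)
  mp <- wt_metad_params(grid_min = -2.5, grid_max = 2.5)
  r <- run_metad(-0.9, dw, ip, metad = mp, seed = 41)
  ax <- list(cv1 = seq(-1.8, 1.8, by = 0.02))
  df_bias <- basin_delta_f(fes_from_bias(r$ledger, mp, ax))
  cv <- r$colvar[r$colvar$time > 1000, ]
  frw <- reweight_fes(cv, r$ledger, 310, "cv1",
                      list(cv1 = seq(-1.8, 1.8, by = 0.05)))
  df_rw <- basin_delta_f(frw)
  expect_lt(abs(df_bias - df_rw), 1.0)
})

test_that("bound-frame extraction equals brute-force filtering", {
  # labelled synthetic surface over two variables
  ax <- list(cv1 = seq(0.25, 4.75, by = 0.5), cv2 = seq(-0.45, 0.45, by = 0.1))
  set.seed(7)
  F <- matrix(runif(length(ax$cv1) * length(ax$cv2), 0, 25),
              nrow = length(ax$cv1))
  F[3, 4] <- 0
  fes <- free_energy_surface(c("cv1", "cv2"), ax, F, "reweighted", 310)
  colvar <- data.frame(time = 1:500,
                       cv1 = runif(500, 0, 5), cv2 = runif(500, -0.5, 0.5))
  reg <- bound_region(list(cv1 = c(0.5, 2.5), cv2 = c(-0.2, 0.4)),
                      cutoff = 10)
  got <- extract_bound_frames(colvar, fes, reg)
  # exhaustive reference filter
  want <- integer(0)
  for (i in seq_len(500)) {
    v1 <- colvar$cv1[i]; v2 <- colvar$cv2[i]
    if (v1 < 0.5 || v1 > 2.5 || v2 < -0.2 || v2 > 0.4) next
    i1 <- findInterval(v1, fes$breaks$cv1, rightmost.closed = TRUE)
    i2 <- findInterval(v2, fes$breaks$cv2, rightmost.closed = TRUE)
    if (i1 < 1 || i1 > length(ax$cv1) || i2 < 1 || i2 > length(ax$cv2)) next
    if (fes$F[i1, i2] <= 10) want <- c(want, i)
  }
  expect_identical(got, want)
  expect_true(!is.unsorted(got))

  # frame at the minimum bin is always included
  at_min <- data.frame(time = 1, cv1 = ax$cv1[3], cv2 = ax$cv2[4])
  expect_identical(extract_bound_frames(at_min, fes, reg_full <- bound_region(
    list(cv1 = range(ax$cv1) + c(-1, 1), cv2 = range(ax$cv2) + c(-1, 1)),
    cutoff = 10)), 1L)

  # strict cutoff: a bin at min + 10.1 is excluded at cutoff 10
  ax1 <- list(cv1 = c(0.5, 1.5))
  fs <- free_energy_surface("cv1", ax1, c(0, 10.1), "reweighted", 310)
  cv <- data.frame(time = 1:2, cv1 = c(0.5, 1.5))
  expect_identical(
    extract_bound_frames(cv, fs, bound_region(list(cv1 = c(0, 2)), 10)), 1L)

  # cutoff -> Inf with a full-grid box returns every frame
  expect_identical(
    extract_bound_frames(colvar, fes,
                         bound_region(list(cv1 = c(0, 5), cv2 = c(-0.5, 0.5)),
                                      cutoff = Inf)),
    which(!is.na(colvar$cv1)))

  # empty selection warns, not errs
  expect_warning(
    out <- extract_bound_frames(
      data.frame(time = 1, cv1 = 4.75, cv2 = 0.45), fes,
      bound_region(list(cv1 = c(0, 0.1)), 10)),
    "empty")
  expect_length(out, 0)
})

test_that("basin free-energy difference from an analytic surface is exact", {
  kTv <- kT(310)
  x <- seq(-2, 2, by = 0.004)
  U <- 5 * (x^2 - 1)^2 + 1 * x
  fes <- free_energy_surface("cv1", list(cv1 = x), U - min(U), "reference", 310)
  expect_equal(basin_delta_f(fes), double_well_delta_f(5, 1, 310),
               tolerance = 2e-3)
})
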