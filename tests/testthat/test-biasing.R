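test_that("well-tempered deposition follows the height law", {
  mp <- wt_metad_params(h0 = 2, sigma = c(cv1 = 0.1), gamma = 20,
                        temperature = 310)
  led <- hills_ledger("cv1")
  led <- deposit_hill(led, 0.7, mp, time = 1)
  expect_equal(led$records$height[1], 2.0)          # first hill: V = 0
  led <- deposit_hill(led, 0.7, mp, time = 2)
  kBdT <- kB * 19 * 310
  expect_equal(led$records$height[2], 2 * exp(-2 / kBdT), tolerance = 1e-12)
  # untempered limit: heights stay at h0
  mpinf <- wt_metad_params(h0 = 2, sigma = c(cv1 = 0.1), gamma = Inf)
  ledi <- deposit_hill(hills_ledger("cv1"), 0, mpinf)
  ledi <- deposit_hill(ledi, 0, mpinf, time = 1)
  expect_equal(ledi$records$height, c(2, 2))
})

test_that("heights strictly decrease along repeated deposition at one point", {
  mp <- wt_metad_params(sigma = c(cv1 = 0.1))
  led <- hills_ledger("cv1")
  for (i in 1:25) led <- deposit_hill(led, -0.2, mp, time = i)
  expect_true(all(diff(led$records$height) < 0))
})

test_that("ledger replay reproduces stored heights to round-off", {
  dw <- build_double_well_1d(5, 1)
  ip <- integrator_params("overdamped", dt = 0.002, friction = 1,
                          temperature = 310, n_steps = 2e5, save_stride = 500)
  mp <- wt_metad_params(grid_min = -2.5, grid_max = 2.5)
  r <- run_metad(0.9, dw, ip, metad = mp, seed = 3)
  rep_r <- replay_hill_heights(r$ledger, 2.0, 310)
  expect_lt(max(abs(rep_r - r$ledger$records$height)), 1e-12)
  # compiled replay agrees with the R replay oracle
  rep_c <- replay_heights_cpp(ledger_centers(r$ledger),
                              ledger_sigmas(r$ledger),
                              r$ledger$records$biasf, 2.0, 310)
  expect_lt(max(abs(rep_c - rep_r)), 1e-13)
})

test_that("bias evaluation: empty ledger, single hill, grid fast path", {
  led0 <- hills_ledger("cv1")
  expect_equal(bias_value_and_gradient(0.3, led0)$value, 0)
  led1 <- deposit_hill(led0, 0.5, wt_metad_params(sigma = c(cv1 = 0.1)))
  expect_equal(bias_value_and_gradient(0.5, led1)$value, 2.0)
  # grid-interpolated path vs direct summation on a random 100-hill ledger
  led <- random_ledger_1d(100, seed = 7)
  g <- build_bias_grid(led)
  set.seed(8)
  pts <- runif(50, -1.4, 1.4)
  dv <- bias_value_and_gradient(pts, led)
  gv <- bias_value_and_gradient(pts, led, method = "grid", grid = g)
  expect_lt(max(abs(dv$value - gv$value)), 1e-6)
  # grid cache equals direct summation at the nodes to round-off
  at_nodes <- bias_value_and_gradient(g$x, led)$value
  expect_lt(max(abs(at_nodes - g$V)), 1e-9)
})

test_that("bias gradient matches finite differences", {
  led <- random_ledger_1d(40, seed = 13)
  for (s in c(-1.2, -0.3, 0.4, 1.1)) {
    g <- bias_value_and_gradient(s, led)$gradient[1, 1]
    g_fd <- fd_grad(function(v) bias_value_and_gradient(v, led)$value, s)
    expect_lt(rel_err(g, g_fd, floor = 1e-4), 1e-6)
  }
})

test_that("funnel restraint is zero inside, harmonic outside, C1 at onset", {
  fun <- funnel_geometry()
  expect_equal(funnel_restraint(c(0, 0, 1), fun)$energy, 0)
  expect_equal(funnel_restraint(c(0, 0, 1), fun)$force, c(0, 0, 0))
  # axial wall: z = 5.6 nm with the wall at 5.5 and kappa 35,100
  fr <- funnel_restraint(c(0, 0, 5.6), fun)
  expect_equal(fr$energy, 0.5 * 35100 * 0.1^2, tolerance = 1e-9)
  expect_equal(fr$energy, 175.5, tolerance = 1e-6)
  # exactly on the lateral surface: zero energy and force
  z <- 1.0
  R <- funnel_radius(z, fun)
  on_surface <- funnel_restraint(c(R, 0, z), fun)
  expect_equal(on_surface$energy, 0)
  expect_equal(on_surface$force, c(0, 0, 0))
  # interior points across cone and cylinder are all zero
  set.seed(2)
  for (i in 1:50) {
    zz <- runif(1, 0.05, 5.4)
    rr <- runif(1, 0, 0.98 * funnel_radius(zz, fun))
    th <- runif(1, 0, 2 * pi)
    expect_identical(
      funnel_restraint(c(rr * cos(th), rr * sin(th), zz), fun)$energy, 0)
  }
  # outside points are strictly positive
  expect_gt(funnel_restraint(c(1, 0, 3), fun)$energy, 0)
  expect_gt(funnel_restraint(c(0, 0, -0.2), fun)$energy, 0)
})

test_that("funnel restraint force matches finite differences off the kink", {
  fun <- funnel_geometry()
  pts <- list(c(0.5, 0.3, 0.8),    # cone-wall violation
              c(0.15, 0.05, 3.0),  # cylinder-wall violation
              c(0.05, 0, 5.7),     # axial upper wall
              c(0.02, 0.01, -0.1)) # lower guard
  for (p in pts) {
    f <- funnel_restraint(p, fun)$force
    f_fd <- -fd_grad(function(v) funnel_restraint(v, fun)$energy, p)
    expect_lt(max(rel_err(f, f_fd, floor = 1e-3)), 1e-5)
  }
})

test_that("moving restraint interpolates keyframes linearly", {
  sch <- smd_schedule_preset("hold")
  # start: centre 0.4 nm, zero spring -> zero energy everywhere
  m0 <- moving_restraint(3.7, sch, 0)
  expect_equal(m0$center, 0.4)
  expect_equal(m0$energy, 0)
  # midpoint of the pull: centre 2.45 nm, kappa 500
  m1 <- moving_restraint(2.0, sch, 2500)
  expect_equal(m1$center, 2.45)
  expect_equal(m1$kappa, 500)
  expect_equal(m1$energy, 0.5 * 500 * (2.0 - 2.45)^2)
  # at the centre the generalized force vanishes
  expect_equal(moving_restraint(2.45, sch, 2500)$force, 0)
  # beyond the last keyframe: hold with warning
  expect_warning(mh <- moving_restraint(4.5, sch, 9000), "beyond last")
  expect_equal(mh$kappa, 1000)
  # the release preset relaxes the spring to zero at 10 ns
  rel <- smd_schedule_preset("release")
  expect_equal(moving_restraint(4.5, rel, 10000)$kappa, 0)
  expect_equal(moving_restraint(4.5, rel, 7500)$kappa, 500)
  expect_error(moving_restraint(1, sch, -5), "precedes")
  expect_error(moving_restraint_schedule(c(0, 0), c(1, 2), c(0, 0)),
               "strictly increasing")
})

test_that("walker ledgers merge time-ordered with duplicate detection", {
  mp <- wt_metad_params(sigma = c(cv1 = 0.1))
  la <- deposit_hill(hills_ledger("cv1"), 0.1, mp, time = 1, walker = 0L)
  la <- deposit_hill(la, 0.2, mp, time = 3, walker = 0L)
  lb <- deposit_hill(hills_ledger("cv1"), -0.1, mp, time = 2, walker = 1L)
  lb <- deposit_hill(lb, -0.2, mp, time = 4, walker = 1L)
  m <- merge_walker_ledgers(list(la, lb))
  expect_equal(m$records$time, 1:4)
  expect_equal(m$records$walker, c(0L, 1L, 0L, 1L))
  # identity merge
  m1 <- merge_walker_ledgers(list(la, hills_ledger("cv1")))
  expect_equal(m1$records, la$records)
  # duplicate (time, walker) key rejected naming the sources
  expect_error(merge_walker_ledgers(list(la, la)), "duplicate hill key")
})

test_that("walker start positions step 0.3 nm from 1.6 nm (walker 5 at 3.1)", {
  s <- walker_start_positions()
  expect_length(s, 10)
  expect_equal(s, seq(1.6, by = 0.3, length.out = 10))
  expect_equal(s[6], 3.1)  # walker id 5, counting from 0
  expect_equal(diff(s), rep(0.3, 9))
})

test_that("deposition outside the declared grid clips with a warning", {
  mp <- wt_metad_params(sigma = c(cv1 = 0.1), grid_min = -1, grid_max = 1)
  expect_warning(led <- deposit_hill(hills_ledger("cv1"), 1.7, mp), "clipped")
  expect_equal(led$records$cv1, 1)
})

test_that("time-averaged ledger equals the mean over ledger prefixes", {
  led <- random_ledger_1d(10, seed = 44)
  avg <- time_averaged_ledger(led, fraction = 0.5)
  # oracle: average the direct-summation bias over the trailing prefixes
  pts <- c(-0.8, 0.1, 1.2)
  K <- 10; j0 <- 5
  Vk <- sapply((j0 + 1):K, function(k)
    bias_value_and_gradient(pts, hills_ledger("cv1", led$records[1:k, ]))$value)
  want <- rowMeans(Vk)
  got <- bias_value_and_gradient(pts, avg)$value
  expect_equal(got, want, tolerance = 1e-12)
  # full-history average keeps every hill partially weighted
  full <- time_averaged_ledger(led, fraction = 1)
  expect_equal(full$records$height, led$records$height * (10:1) / 10)
  expect_identical(time_averaged_ledger(hills_ledger("cv1"), 0.3)$records,
                   hills_ledger("cv1")$records)
})
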