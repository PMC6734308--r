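test_that("tip position is height minus deflection, exactly and linearly", {
  h <- seq(10e-6, 0, length.out = 50L)

  # zero deflection: tip position equals piezo height
  cur0 <- fd_curve(h, rep(0, 50), spring_constant = 1)
  expect_identical(compute_tip_position(cur0)$tip_position, h)

  # k = 1 N/m, F = 1 nN at 10 um -> tip position 10 um - 1 nm
  f <- rep(0, 50); f[1] <- 1e-9
  cur1 <- compute_tip_position(fd_curve(h, f, spring_constant = 1))
  expect_equal(cur1$tip_position[1], 10e-6 - 1e-9)

  # doubling k halves the deflection correction everywhere
  f <- seq(0, 5e-9, length.out = 50L)
  c1 <- compute_tip_position(fd_curve(h, f, spring_constant = 0.05))
  c2 <- compute_tip_position(fd_curve(h, f, spring_constant = 0.10))
  expect_equal(h - c2$tip_position, (h - c1$tip_position) / 2)

  bad <- fd_curve(h, f, spring_constant = 0.05)
  bad$spring_constant <- -1
  expect_error(compute_tip_position(bad), "positive")
})

test_that("baseline statistics match closed forms", {
  h <- seq(10e-6, 0, length.out = 100L)

  # constant force: mean = c, sd = 0, slope = 0
  bl <- estimate_baseline(fd_curve(h, rep(2e-9, 100), spring_constant = 1))
  expect_equal(bl$mean_force, 2e-9)
  expect_equal(bl$sd_force, 0)
  expect_equal(bl$slope, 0)
  expect_true(all(bl$region <= 50))  # first half of the approach only

  # exact linear force on the baseline: least-squares slope recovers m
  m <- 3e-4
  cur <- compute_tip_position(fd_curve(h, m * h, spring_constant = 1e6))
  bl <- estimate_baseline(cur)
  expect_equal(bl$slope, m, tolerance = 1e-9)

  # Gaussian noise: sd_force estimates sigma (n = 500 in the region)
  set.seed(42)
  sigma <- 5e-11
  cur <- fd_curve(seq(10e-6, 0, length.out = 1000L),
                  rnorm(1000, 0, sigma), spring_constant = 0.05)
  expect_equal(estimate_baseline(cur)$sd_force, sigma, tolerance = 0.2)

  expect_error(estimate_baseline(
    fd_curve(h[1:10], rep(0, 10), spring_constant = 1)), "at least 20")
})

test_that("offset correction zeroes the baseline and is idempotent", {
  h <- seq(10e-6, 0, length.out = 100L)
  cur <- fd_curve(h, rep(3e-9, 100), spring_constant = 1)
  corr <- correct_offset(cur, estimate_baseline(cur))
  expect_equal(corr$force, rep(0, 100))
  expect_length(corr, 100L)

  set.seed(7)
  cur <- fd_curve(h, rnorm(100, 1e-9, 1e-10), spring_constant = 1)
  bl1 <- estimate_baseline(cur)
  once <- correct_offset(cur, bl1)
  bl2 <- estimate_baseline(once)
  expect_equal(mean(once$force[bl2$region]), 0, tolerance = 1e-12)
  twice <- correct_offset(once, bl2)
  expect_equal(twice$force, once$force)
})

test_that("contact point is found near truth and shifts with the frame", {
  cur <- clean_curve(E = 1000, delta_c = 0, n_points = 500L,
                     noise = 0.002, seed = 3L)
  pp <- preprocess_curve(cur)
  spacing <- diff(range(cur$piezo_height)) / 500
  expect_lt(abs(pp$delta_c0 - 0), 5 * spacing)

  # translation equivariance of the estimate
  shifted <- cur
  shifted$piezo_height <- cur$piezo_height + 1e-6
  pp2 <- preprocess_curve(shifted)
  expect_equal(pp2$delta_c0 - pp$delta_c0, 1e-6, tolerance = 1e-3)

  # the returned curve is re-zeroed at the estimate
  c1 <- compute_tip_position(cur)
  bl <- estimate_baseline(c1)
  c1 <- correct_offset(c1, bl)
  res <- estimate_contact_point(c1, estimate_baseline(c1))
  i <- which.min(abs(res$curve$tip_position))
  expect_equal(res$curve$tip_position[i], 0, tolerance = 1e-8)

  # pure noise, no indentation: no contact detected
  set.seed(9)
  flat <- fd_curve(seq(10e-6, 0, length.out = 300L),
                   rnorm(300, 0, 1e-11), spring_constant = 0.05)
  flat <- compute_tip_position(flat)
  expect_error(estimate_contact_point(flat, estimate_baseline(flat)),
               "no contact detected")
})

test_that("contact estimate converges to truth as noise vanishes", {
  err <- vapply(c(0.02, 0.002, 0), function(noise) {
    pp <- preprocess_curve(clean_curve(E = 1000, delta_c = 0,
                                       n_points = 500L, noise = noise,
                                       seed = 11L))
    abs(pp$delta_c0)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))   # non-increasing with noise
  expect_lt(err[3], 1e-7)
})
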