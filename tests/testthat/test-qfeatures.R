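# residual-series fixture: 200 approach + 200 indentation points on a
# symmetric tip-position axis, contact at zero
fixture_axis <- function(n = 400L, span = 2e-6)
  seq(span, -span, length.out = n)

noise_fit <- function(sigma = 1e-11, seed = 1L, n = 400L) {
  set.seed(seed)
  dt <- fixture_axis(n)
  f <- rnorm(n, 0, sigma)
  f[dt < 0] <- f[dt < 0] + 2e-9   # constant indentation force, zero "model"
  manual_fit(f, dt, max_force = 2e-9)
}

inject_pulse <- function(fit, start, width, amplitude) {
  idt <- which(fit$delta < fit$params$delta_c)
  span <- idt[start:(start + width - 1L)]
  fit$residuals[span] <- fit$residuals[span] + amplitude
  fit$force[span] <- fit$force[span] + amplitude
  fit
}

test_that("spike detector finds constructed pulses and nothing else", {
  # structureless residuals: no spikes
  fit <- noise_fit(seed = 2L)
  expect_identical(nrow(detect_spikes(fit)), 0L)

  # exactly flat residuals (noiseless fit): no spikes
  flat <- manual_fit(rep(0, 400), fixture_axis(), max_force = 1e-9)
  expect_identical(nrow(detect_spikes(flat)), 0L)

  # one rectangular 10-point pulse at 20 MAD: one interval, >= 8 points
  fit <- noise_fit(seed = 3L)
  sigma_mad <- mad(fit$residuals[fit$delta < 0] - 2e-9)
  fit1 <- inject_pulse(fit, 60L, 10L, 20 * sigma_mad)
  iv <- detect_spikes(fit1)
  expect_identical(nrow(iv), 1L)
  expect_gte(iv[1, "end"] - iv[1, "start"] + 1L, 8L)

  # six well-separated pulses: six intervals, sorted and disjoint
  fit6 <- noise_fit(seed = 4L)
  for (s in seq(10L, 185L, by = 35L))
    fit6 <- inject_pulse(fit6, s, 5L, 25 * sigma_mad)
  iv6 <- detect_spikes(fit6)
  expect_identical(nrow(iv6), 6L)
  expect_true(all(diff(as.vector(t(iv6))) > 0))
})

test_that("binary filters apply the literal size and spike bounds", {
  fit599 <- fitted_clean(n_points = 599L, seed = 5L)
  expect_false(binary_features(fit599)[["enough_points"]])

  fit600 <- fitted_clean(n_points = 600L, seed = 5L)
  flags <- binary_features(fit600)
  expect_true(all(flags))          # 600 points, delta_c inside, 0 spikes

  # six spikes fail the filter, five pass (boundary inclusive)
  sigma_mad <- 1.4826e-11
  f5 <- noise_fit(seed = 6L)
  for (s in seq(10L, 150L, by = 35L))
    f5 <- inject_pulse(f5, s, 5L, 25 * sigma_mad)
  f6 <- inject_pulse(f5, 185L, 5L, 25 * sigma_mad)
  expect_identical(nrow(detect_spikes(f5)), 5L)
  expect_identical(nrow(detect_spikes(f6)), 6L)
  expect_true(binary_features(f5)[["few_spikes"]])
  expect_false(binary_features(f6)[["few_spikes"]])

  # fitted contact point outside the data range
  bad <- fitted_clean(n_points = 600L, seed = 5L)
  bad$params$delta_c <- min(bad$delta) - 1e-6
  expect_false(binary_features(bad)[["cp_in_range"]])
})

test_that("clean fits give the expected feature signature", {
  fit <- fitted_clean(n_points = 700L, seed = 7L, noise = 0.002)
  qf <- continuous_features(fit)
  expect_s3_class(qf, "quality_features")
  expect_named(qf$continuous, feature_names())
  expect_true(all(qf$computable))
  expect_identical(unname(qf$continuous["spike_area"]), 0)
  expect_lt(abs(qf$continuous["flatness_apr"] - 0.5), 0.2)
  expect_lt(abs(qf$continuous["slope_bln"]), 5e-3)
  expect_lt(qf$continuous["variation_bln"], 5e-3)
  expect_true(qf$continuous["relative_apr"] > 0)
  expect_true(qf$continuous["flatness_apr"] >= 0 &&
              qf$continuous["flatness_apr"] <= 1)
})

test_that("baseline slope feature is the normalized least-squares slope", {
  dt <- fixture_axis(400L, 4e-6)
  m <- 5e-4                               # injected tilt [N/m]
  f <- numeric(400L)
  apr <- dt >= 0
  f[apr] <- m * (dt[1] - dt[apr])         # linear drift along the approach
  f[!apr] <- 2e-9
  fit <- manual_fit(f, dt, max_force = 2e-9)
  qf <- continuous_features(fit)
  # closed form: f = m*dt[1] + m*d on the depth axis d = -dt, so the
  # least-squares slope on the baseline is +m
  bln_d <- -dt[apr][1:100]
  expected <- m * diff(range(bln_d)) / 2e-9
  expect_equal(unname(qf$continuous["slope_bln"]), expected,
               tolerance = 1e-9)
})

test_that("curvature at the contact point images the parabola coefficient", {
  dt <- fixture_axis(400L, 2e-6)
  q <- 1e3                                # F = q d^2 around the contact
  d <- -dt
  f <- ifelse(abs(d) <= 1e-6, q * d^2, q * 1e-12)
  f[d > 1e-6] <- 2e-9
  fit <- manual_fit(f, dt, max_force = 2e-9)
  qf <- continuous_features(fit)
  expect_equal(unname(qf$continuous["curvature_cp"]),
               2 * q * (18.64e-6)^2 / 2e-9, tolerance = 1e-6)
})

test_that("a contact-point force step inflates the residuals there", {
  clean <- curve_sample(clean_curve(n_points = 500L, seed = 8L,
                                    noise = 0.005))$features
  offset_cur <- generate_curve(1000, 0, n_points = 500L, seed = 8L,
                               artifact = artifact_spec(contact_offset = 0.2,
                                                        noise_sd = 0.005))
  offs <- curve_sample(offset_cur)$features
  expect_gt(offs$continuous["residuals_cp"], clean$continuous["residuals_cp"])
})

test_that("features are invariant under a common force rescaling", {
  fit <- noise_fit(seed = 9L)
  fit <- inject_pulse(fit, 80L, 6L, 4e-10)
  scaled <- fit
  for (fld in c("residuals", "force")) scaled[[fld]] <- 1000 * scaled[[fld]]
  scaled$max_force <- 1000 * scaled$max_force
  q1 <- continuous_features(fit)
  q2 <- continuous_features(scaled)
  expect_equal(q2$continuous, q1$continuous, tolerance = 1e-12)
})

test_that("log filter compresses unbounded features and keeps fractions", {
  x <- setNames(c(0.02, -0.5, 0.4, 1.3, 0.1, 0.7, 3, 0.2, 0.6, 0.9,
                  -0.01, 0.05), feature_names())
  y <- log_filter(x)
  expect_equal(unname(y["spike_area"]), log1p(100 * 0.02))
  expect_equal(unname(y["curvature_cp"]), -log1p(100 * 0.5))
  expect_equal(unname(y["slope_bln"]), -log1p(100 * 0.01))
  expect_equal(unname(y["relative_apr"]), log(3))
  expect_equal(unname(y["flatness_apr"]), 0.4)   # bounded: untouched
  expect_equal(unname(y["monotony_idt"]), 0.1)
})

test_that("samples tables round-trip through TSV", {
  feats <- lapply(c(10L, 11L), function(s)
    curve_sample(clean_curve(n_points = 400L, seed = s,
                             noise = 0.01))$features)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_samples(feats, c(7L, 9L), path)
  back <- read_samples(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$rating, c(7L, 9L))
  expect_equal(as.numeric(back[1, feature_names()]),
               unname(feats[[1]]$continuous), tolerance = 1e-12)
  expect_error(read_samples(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})
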