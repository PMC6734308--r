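test_that("generated curves are reproducible and physically consistent", {
  c1 <- generate_curve(1000, 0, seed = 42L, n_points = 300L,
                       artifact = artifact_spec(noise_sd = 0.05))
  c2 <- generate_curve(1000, 0, seed = 42L, n_points = 300L,
                       artifact = artifact_spec(noise_sd = 0.05))
  expect_identical(c1$piezo_height, c2$piezo_height)
  expect_identical(c1$force, c2$force)

  # tip-position computation recovers the simulated ramp exactly
  tp <- compute_tip_position(c1)$tip_position
  expect_equal(tp, seq(6e-6, -2e-6, length.out = 300L), tolerance = 1e-12)

  # generator does not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_curve(500, seed = 9L, n_points = 50L))
  expect_identical(rnorm(1), before)

  expect_error(generate_curve(-5, seed = 1L), "E_true >= 0")
  expect_error(generate_curve(1000, n_points = 1L, seed = 1L), "n_points")
})

test_that("pipeline round-trip recovers the true modulus on clean curves", {
  errs <- vapply(1:25, function(s) {
    fit <- curve_sample(generate_curve(1000, 0, n_points = 400L, seed = s,
      artifact = artifact_spec(noise_sd = 0.005)))$fit
    abs(fit$params$E - 1000) / 1000
  }, numeric(1))
  expect_lt(median(errs), 0.01)
})

test_that("procedural ratings anchor, clip, and never reward artifacts", {
  expect_identical(ground_truth_rating(artifact_spec()), 10L)
  huge <- artifact_spec(spike_count = 5L, spike_amplitude = 1, tilt = 1e-2,
                        contact_offset = 1, noise_sd = 1)
  expect_identical(ground_truth_rating(huge), 0L)

  # single moderate artifacts land in the "just usable" band 4..6
  cfg <- fd_config()
  expect_true(ground_truth_rating(artifact_spec(noise_sd = 0.1)) %in% 4:6)
  expect_true(ground_truth_rating(artifact_spec(contact_offset = 0.2)) %in% 4:6)
  expect_true(ground_truth_rating(
    artifact_spec(tilt = cfg$penalty$tilt0)) %in% 4:6)

  # monotone non-increasing in every artifact magnitude
  base <- artifact_spec(spike_count = 2L, spike_amplitude = 0.05,
                        tilt = 5e-5, contact_offset = 0.05, noise_sd = 0.02)
  r0 <- ground_truth_rating(base)
  for (fld in c("spike_amplitude", "tilt", "contact_offset", "noise_sd")) {
    worse <- base
    worse[[fld]] <- 2 * worse[[fld]]
    expect_lte(ground_truth_rating(worse), r0)
  }
})

test_that("requested spikes show up as distinct detected spikes", {
  cur <- generate_curve(1000, 0, n_points = 700L, seed = 13L,
                        artifact = artifact_spec(spike_count = 6L,
                                                 spike_amplitude = 0.2,
                                                 spike_width = 6L,
                                                 noise_sd = 0.005))
  fit <- curve_sample(cur)$fit
  expect_gte(nrow(detect_spikes(fit)), 6L)
  expect_false(binary_features(fit)[["few_spikes"]])
})

test_that("the synthetic population spans and mixes all rating classes", {
  gen <- generate_training_set(500, seed = 1L, n_points = 10L)
  expect_length(gen$curves, 500L)
  tab <- table(factor(gen$ratings, levels = 0:10))
  expect_true(all(tab > 0))                 # every class populated
  expect_lt(max(tab) / sum(tab), 0.5)       # no dominant class
  # reproducible
  gen2 <- generate_training_set(20, seed = 1L, n_points = 10L)
  expect_identical(gen$ratings[1:20], gen2$ratings)
})

test_that("synthetic maps image the stiffness layout and artifact regions", {
  E_layout <- matrix(rep(c(2000, 500), each = 8), 4, 4)
  sev <- matrix(0, 4, 4)
  sev[, 4] <- 6
  map <- generate_map(E_layout, sev, seed = 2L, n_points = 350L)
  expect_identical(map$grid_shape, c(4L, 4L))
  res <- analyze_map(map)
  stiff <- res$E[res$col <= 2]
  soft <- res$E[res$col > 2]
  expect_gt(median(stiff, na.rm = TRUE) / median(soft, na.rm = TRUE), 2)
  # medians of the clean columns recover the layout within 10%
  expect_lt(abs(median(stiff, na.rm = TRUE) - 2000) / 2000, 0.1)
  expect_lt(abs(median(res$E[res$col == 3], na.rm = TRUE) - 500) / 500, 0.1)

  # artifact-laden column rates below the clean interior
  ts <- synthetic_training_set(150, seed = 3L, n_points = 650L)
  rater <- train_rater(ts, seed = 4L)
  res_r <- analyze_map(map, rater)
  expect_lt(median(res_r$rating[res_r$col == 4]),
            median(res_r$rating[res_r$col == 1]))

  expect_error(generate_map(E_layout, matrix(0, 2, 2)), "must match")
})
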