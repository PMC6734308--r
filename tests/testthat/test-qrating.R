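make_samples <- function(n, seed = 1L, n_points = 650L) {
  gen <- generate_training_set(n, seed = seed, n_points = n_points)
  list(samples = lapply(gen$curves, function(cu) curve_sample(cu)$features),
       ratings = gen$ratings)
}

test_that("occurrence weights balance the rating histogram", {
  # uniform counts: all weights 1
  expect_equal(compute_weights(rep(0:4, each = 3)), rep(1, 15))
  # two classes 90/10: weights 10/18 and 90/18, ratio 1:9, mean 1
  r <- c(rep(7L, 90), rep(2L, 10))
  w <- compute_weights(r)
  expect_equal(unique(w[r == 7L]), 10 / 18)
  expect_equal(unique(w[r == 2L]), 90 / 18)
  expect_equal(unique(w[r == 2L]) / unique(w[r == 7L]), 9)
  expect_equal(mean(w), 1)
  # single class: all weights 1
  expect_equal(compute_weights(rep(5L, 4)), rep(1, 4))
  expect_error(compute_weights(integer(0)), "empty")
  # weighted histogram over present classes is uniform
  set.seed(1)
  r <- sample(0:10, 500, replace = TRUE, prob = (1:11)^2)
  w <- compute_weights(r)
  mass <- tapply(w, r, sum)
  expect_equal(as.numeric(mass), rep(mean(mass), length(mass)))
})

test_that("assembly drops by the binary rules and reports counts", {
  ms <- make_samples(8, seed = 20L)
  samples <- ms$samples
  # two size violations
  short <- make_samples(2, seed = 30L, n_points = 599L)
  all_s <- c(samples, short$samples)
  ratings <- c(ms$ratings, short$ratings)
  ts <- assemble_training_set(all_s, ratings)
  expect_identical(unname(ts$drop_report["enough_points"]), 2L)
  expect_lte(length(ts$ratings), 8L)
  expect_identical(dim(ts$features), c(length(ts$ratings), 12L))
  expect_equal(mean(ts$weights), 1)

  # dropping is order-independent
  perm <- rev(seq_along(all_s))
  ts2 <- assemble_training_set(all_s[perm], ratings[perm],
                               ids = paste0("s", seq_along(all_s))[perm])
  expect_setequal(ts2$provenance, ts$provenance)

  expect_error(assemble_training_set(short$samples, c(11L, 3L)), "0..10")
  expect_error(assemble_training_set(short$samples, short$ratings),
               "no usable samples")
})

test_that("raters memorize, are deterministic, and ignore row order", {
  ts <- synthetic_training_set(120, seed = 2L, n_points = 650L)

  # interpolation regime: deep trees reproduce their training labels
  for (kind in c("extra_trees", "decision_tree")) {
    rater <- train_rater(ts, kind = kind, seed = 3L)
    expect_lt(mean((predict(rater, ts$features) - ts$ratings)^2), 0.1)
  }

  # same seed -> identical predictions; training row order irrelevant
  r1 <- train_rater(ts, seed = 5L)
  r2 <- train_rater(ts, seed = 5L)
  perm <- sample(length(ts$ratings))
  ts_perm <- fdrate:::.subset_ts(ts, perm)
  r3 <- train_rater(ts_perm, seed = 5L)
  probe <- ts$features[1:20, ]
  expect_identical(predict(r1, probe), predict(r2, probe))
  expect_identical(predict(r1, probe), predict(r3, probe))

  expect_error(train_rater(ts, kind = "neural_net"), "unknown regressor")
  degenerate <- ts
  degenerate$features[] <- 1
  expect_error(train_rater(degenerate), "degenerate")
})

test_that("every regressor kind trains and predicts within bounds", {
  ts <- synthetic_training_set(150, seed = 4L, n_points = 650L)
  for (kind in rater_kinds()) {
    rater <- train_rater(ts, kind = kind, seed = 6L)
    pred <- predict(rater, ts$features)
    expect_true(all(pred >= 0 & pred <= 10), info = kind)
    # better than the constant-mean predictor on its own training set
    expect_lt(mean((pred - ts$ratings)^2),
              mean((mean(ts$ratings) - ts$ratings)^2), label = kind)
  }
})

test_that("rating a curve clips, and unrateable samples yield -1", {
  ts <- synthetic_training_set(100, seed = 7L, n_points = 650L)
  rater <- train_rater(ts, seed = 8L)
  feats <- curve_sample(clean_curve(n_points = 650L, seed = 40L,
                                    noise = 0.005))$features
  r <- rate_curve(rater, feats)
  expect_true(r >= 0 && r <= 10)

  broken <- feats
  broken$computable["curvature_cp"] <- FALSE
  expect_identical(rate_curve(rater, broken), -1)

  # clean curves rate at least as high as artifact-heavy twins
  diffs <- vapply(41:50, function(s) {
    good <- curve_sample(clean_curve(n_points = 650L, seed = s,
                                     noise = 0.005))$features
    bad <- curve_sample(generate_curve(1000, 0, n_points = 650L, seed = s,
      artifact = artifact_spec(contact_offset = 0.3, noise_sd = 0.15,
                               tilt = 2e-4)))$features
    rate_curve(rater, good) - rate_curve(rater, bad)
  }, numeric(1))
  expect_gt(median(diffs), 0)
})

test_that("classification and top-n sorting follow the thresholds", {
  expect_identical(as.character(classify_rating(4.6)), "good")
  expect_identical(as.character(classify_rating(4.4)), "poor")
  expect_identical(as.character(classify_rating(5, threshold = 6)), "poor")

  expect_identical(select_top_n(c(3, 9, 9, 1), 2), c(2L, 3L))
  expect_identical(select_top_n(c(3, 9, 9, 1), 4), c(2L, 3L, 1L, 4L))
  expect_identical(select_top_n(c(5, 2), 1), 1L)
  expect_error(select_top_n(c(1, 2), 3), "exceeds")
})

test_that("raters persist losslessly", {
  ts <- synthetic_training_set(80, seed = 9L, n_points = 650L)
  rater <- train_rater(ts, seed = 10L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_rater(rater, path)
  back <- load_rater(path)
  expect_identical(predict(back, ts$features), predict(rater, ts$features))
  expect_error(load_rater(withr::local_tempfile(fileext = ".rds")),
               "not found")
})
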