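# Performance protocols for the rating regressors: MSE against the
# training fraction, averaged ROC graphs, accuracy / false-positive-rate
# threshold scans, and rounded prediction-vs-manual tables.
#
# All randomness flows from one integer seed through a per-repeat counter
# (`seed + counter`), so every protocol is bit-reproducible and every
# regressor kind sees the same random splits.

.repeat_seed <- function(seed, block, rep) {
  s <- (seed + 99991 * block + rep) %% 2147483647
  as.integer(max(s, 1))
}

.split_indices <- function(n, n_train, seed) {
  set.seed(seed)
  sample(n, n_train)
}

#' Binary classification metrics (tp rate, fp rate, accuracy)
#'
#' Positives are samples whose manual rating exceeds `truth_threshold`;
#' a sample is predicted positive when its predicted rating exceeds
#' `pred_threshold`. Then
#' `tp_rate = positives correctly classified / total positives`,
#' `fp_rate = negatives incorrectly classified / total negatives`, and
#' `accuracy = (true positives + true negatives) / n`.
#'
#' @param predicted numeric predicted ratings.
#' @param manual numeric manual ratings, same length.
#' @param pred_threshold classification threshold on predictions.
#' @param truth_threshold threshold defining the true classes (default
#'   4.5).
#' @return A list: `tp_rate`, `fp_rate`, `accuracy`, the 2x2 `counts`,
#'   and `undefined` flags (`tp_rate` with no positives, `fp_rate` with
#'   no negatives; the undefined rate is `NA`).
#' @export
binary_metrics <- function(predicted, manual, pred_threshold = 4.5,
                           truth_threshold = 4.5) {
  stopifnot(length(predicted) == length(manual), length(manual) > 0L)
  pos <- manual > truth_threshold
  hat <- predicted > pred_threshold
  tp <- sum(pos & hat); fn <- sum(pos & !hat)
  fp <- sum(!pos & hat); tn <- sum(!pos & !hat)
  list(tp_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       accuracy = (tp + tn) / length(manual),
       counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
       undefined = c(tp_rate = tp + fn == 0, fp_rate = fp + tn == 0))
}

#' Mean squared rating error against the training fraction
#'
#' For each regressor kind and each training fraction, the samples are
#' split at random into a training and a testing fraction, the regressor
#' is trained and applied to the test samples, and the mean squared
#' difference between predicted and manual ratings is recorded; the split
#' is repeated `repeats` times and mean and standard deviation are
#' reported. All kinds see identical splits.
#'
#' @param ts a `training_set`.
#' @param kinds regressor kinds to evaluate.
#' @param fractions training fractions in (0, 1).
#' @param repeats number of random splits per fraction (protocol default
#'   100).
#' @param seed integer master seed.
#' @param hyper hyper-parameter overrides passed to [train_rater].
#' @return Data frame: `kind`, `fraction`, `mse_mean`, `mse_sd`,
#'   `repeats`.
#' @export
mse_vs_fraction <- function(ts, kinds = "extra_trees",
                            fractions = c(0.2, 0.4, 0.6, 0.8),
                            repeats = 100L, seed = 1L, hyper = list()) {
  stopifnot(inherits(ts, "training_set"), repeats >= 1L,
            all(fractions > 0 & fractions < 1))
  n <- length(ts$ratings)
  out <- list()
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    n_train <- round(frac * n)
    if (n_train < 1L || n_train >= n)
      stop(sprintf("fraction %g yields an empty training or test split", frac))
    mse <- matrix(NA_real_, repeats, length(kinds),
                  dimnames = list(NULL, kinds))
    for (r in seq_len(repeats)) {
      sr <- .repeat_seed(seed, fi, r)
      idx <- .split_indices(n, n_train, sr)
      tr <- .subset_ts(ts, idx)
      te_x <- ts$features[-idx, , drop = FALSE]
      te_y <- ts$ratings[-idx]
      for (k in kinds) {
        rater <- train_rater(tr, kind = k, hyper = hyper, seed = sr)
        mse[r, k] <- mean((predict(rater, te_x) - te_y)^2)
      }
    }
    for (k in kinds)
      out[[length(out) + 1L]] <- data.frame(
        kind = k, fraction = frac, mse_mean = mean(mse[, k]),
        mse_sd = stats::sd(mse[, k]), repeats = repeats)
  }
  do.call(rbind, out)
}

.subset_ts <- function(ts, idx) {
  structure(list(features = ts$features[idx, , drop = FALSE],
                 ratings = ts$ratings[idx],
                 weights = compute_weights(ts$ratings[idx]),
                 provenance = ts$provenance[idx],
                 drop_report = ts$drop_report),
            class = "training_set")
}

#' Averaged ROC graph over random equal splits
#'
#' Per repetition the samples are split at random into two equal parts,
#' the regressor is trained on the first and applied to the second, and a
#' full ROC sweep over `threshold_grid` is computed; tp and fp rates are
#' then averaged at fixed threshold across repetitions (threshold-wise
#' averaging). The grid threshold maximizing the mean accuracy is
#' reported.
#'
#' @param ts a `training_set`.
#' @param kind regressor kind.
#' @param repeats number of random splits (protocol default 100).
#' @param split training share of each split (default 0.5, equal parts).
#' @param threshold_grid prediction thresholds spanning \[0, 10\].
#' @param truth_threshold threshold defining the true classes.
#' @param seed integer master seed.
#' @param hyper hyper-parameter overrides.
#' @return A list: `roc` (data frame `threshold`, `fp_rate`, `tp_rate`,
#'   `accuracy`, sorted by fp rate), `best_threshold`, `best_accuracy`,
#'   `auc` (trapezoidal), `repeats`.
#' @export
averaged_roc <- function(ts, kind = "extra_trees", repeats = 100L,
                         split = 0.5,
                         threshold_grid = seq(0, 10, by = 0.25),
                         truth_threshold = 4.5, seed = 1L, hyper = list()) {
  stopifnot(inherits(ts, "training_set"), repeats >= 1L)
  n <- length(ts$ratings)
  n_train <- round(split * n)
  acc <- tpm <- fpm <- matrix(NA_real_, repeats, length(threshold_grid))
  for (r in seq_len(repeats)) {
    sr <- .repeat_seed(seed, 1000L, r)
    idx <- .split_indices(n, n_train, sr)
    rater <- train_rater(.subset_ts(ts, idx), kind = kind, hyper = hyper,
                         seed = sr)
    pred <- predict(rater, ts$features[-idx, , drop = FALSE])
    manual <- ts$ratings[-idx]
    for (ti in seq_along(threshold_grid)) {
      m <- binary_metrics(pred, manual, threshold_grid[ti], truth_threshold)
      tpm[r, ti] <- m$tp_rate
      fpm[r, ti] <- m$fp_rate
      acc[r, ti] <- m$accuracy
    }
  }
  roc <- data.frame(threshold = threshold_grid,
                    fp_rate = colMeans(fpm, na.rm = TRUE),
                    tp_rate = colMeans(tpm, na.rm = TRUE),
                    accuracy = colMeans(acc, na.rm = TRUE))
  best <- which.max(roc$accuracy)
  roc_sorted <- roc[order(roc$fp_rate, roc$tp_rate), ]
  auc <- sum(diff(c(0, roc_sorted$fp_rate, 1)) *
             (c(0, roc_sorted$tp_rate) + c(roc_sorted$tp_rate, 1)) / 2)
  list(roc = roc_sorted, best_threshold = threshold_grid[best],
       best_accuracy = roc$accuracy[best], auc = auc, repeats = repeats)
}

#' Accuracy and false-positive rate against the classification threshold
#'
#' The same split-train-predict machinery as [averaged_roc], reporting the
#' mean accuracy and fp rate per candidate threshold. The fp rate is
#' non-increasing in the threshold.
#'
#' @inheritParams averaged_roc
#' @param thresholds candidate classification thresholds.
#' @return Data frame: `threshold`, `accuracy`, `fp_rate`.
#' @export
threshold_scan <- function(ts, kind = "extra_trees",
                           thresholds = seq(0, 10, by = 0.25),
                           repeats = 20L, split = 0.5,
                           truth_threshold = 4.5, seed = 1L,
                           hyper = list()) {
  r <- averaged_roc(ts, kind = kind, repeats = repeats, split = split,
                    threshold_grid = thresholds,
                    truth_threshold = truth_threshold, seed = seed,
                    hyper = hyper)
  out <- r$roc[order(r$roc$threshold), c("threshold", "accuracy", "fp_rate")]
  rownames(out) <- NULL
  out
}

#' Rounded prediction-vs-manual tables against the training-set size
#'
#' Splits off a fixed test fraction of `n_test` samples, then trains on
#' nested subfractions of the remaining pool (the rows of a smaller
#' subfraction are a subset of every larger one) and cross-tabulates the
#' manual ratings against the predictions rounded to integers (halves
#' away from zero).
#'
#' @param ts a `training_set`.
#' @param kind regressor kind.
#' @param n_test number of test samples (default 200).
#' @param subfractions shares of the training pool used (default 1/3,
#'   2/3, 1).
#' @param truth_threshold threshold for the accuracy summary.
#' @param seed integer seed.
#' @param hyper hyper-parameter overrides.
#' @return A list, one entry per subfraction: `subfraction`, `n_train`,
#'   `table` (counts of manual x rounded predicted rating), `mse`,
#'   `accuracy`.
#' @export
prediction_table <- function(ts, kind = "extra_trees", n_test = 200L,
                             subfractions = c(1 / 3, 2 / 3, 1),
                             truth_threshold = 4.5, seed = 1L,
                             hyper = list()) {
  stopifnot(inherits(ts, "training_set"))
  n <- length(ts$ratings)
  if (n_test + 2L > n) stop("insufficient samples for the requested test size")
  set.seed(.repeat_seed(seed, 2000L, 0L))
  test_idx <- sample(n, n_test)
  pool <- sample(setdiff(seq_len(n), test_idx))  # one permutation, nested use
  lapply(subfractions, function(frac) {
    n_train <- max(2L, ceiling(frac * length(pool)))
    idx <- pool[seq_len(n_train)]
    rater <- train_rater(.subset_ts(ts, idx), kind = kind, hyper = hyper,
                         seed = .repeat_seed(seed, 2000L, 1L))
    pred <- predict(rater, ts$features[test_idx, , drop = FALSE])
    manual <- ts$ratings[test_idx]
    rounded <- round_half_away(pred)
    list(subfraction = frac, n_train = n_train,
         table = table(manual = factor(manual, levels = 0:10),
                       predicted = factor(rounded, levels = 0:10)),
         mse = mean((pred - manual)^2),
         accuracy = binary_metrics(pred, manual, truth_threshold,
                                   truth_threshold)$accuracy)
  })
}
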