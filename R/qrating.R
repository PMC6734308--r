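# Supervised rating of FD-curve quality: training-set assembly with
# occurrence weighting, regressor training (Extra Trees as the primary
# scheme), rating prediction, binary good/poor classification, and
# quality-based sorting.
#
# The regression machinery is delegated to established implementations
# behind this module's surface: ranger (extra trees / random forest),
# xgboost (gradient boosting), rpart (single tree and the AdaBoost.R2
# base learner), e1071 (SVR) with MASS::lda for the SVR preprocessing.

#' Regressor kinds available for rating
#' @return Character vector of kind names.
#' @export
rater_kinds <- function() {
  c("extra_trees", "random_forest", "gradient_boosting", "adaboost",
    "decision_tree", "svr_linear", "svr_rbf")
}

#' Occurrence weights for a rating vector
#'
#' Balances the rating histogram: a sample of rating class `c` receives
#' weight `n_total / (n_classes_present * count(c))`, so every class
#' present carries the same total weight and the mean weight is 1.
#'
#' @param ratings integer ratings.
#' @return Positive weights, one per sample, mean exactly 1.
#' @export
compute_weights <- function(ratings) {
  if (length(ratings) == 0L) stop("cannot weight an empty rating vector")
  counts <- table(ratings)
  w <- length(ratings) / (length(counts) * counts[as.character(ratings)])
  as.numeric(w)
}

#' Assemble a training set from quality samples
#'
#' Drops samples failing any binary usability flag or with any
#' non-computable feature, applies the [log_filter] to the surviving
#' feature vectors, and attaches occurrence weights.
#'
#' @param samples list of `quality_features` (see [continuous_features]).
#' @param ratings integer manual ratings 0..10, one per sample.
#' @param ids optional per-sample identifiers.
#' @param config configuration list from [fd_config].
#' @return A `training_set` object: `features` (n x 12 matrix, filtered),
#'   `ratings`, `weights`, `provenance`, and `drop_report` (samples
#'   dropped per rule; a sample failing several rules is counted under
#'   each).
#' @export
assemble_training_set <- function(samples, ratings, ids = NULL,
                                  config = fd_config()) {
  stopifnot(length(samples) == length(ratings))
  ratings <- as.integer(ratings)
  if (any(ratings < 0L | ratings > 10L))
    stop("ratings must be integers in 0..10")
  if (is.null(ids)) ids <- paste0("s", seq_along(samples))
  flags <- t(vapply(samples, function(s) s$binary, logical(3)))
  computable <- vapply(samples, function(s) all(s$computable), logical(1))
  drop_report <- c(cp_in_range = sum(!flags[, "cp_in_range"]),
                   enough_points = sum(!flags[, "enough_points"]),
                   few_spikes = sum(!flags[, "few_spikes"]),
                   not_computable = sum(!computable))
  keep <- rowSums(!flags) == 0L & computable
  if (!any(keep)) stop("no usable samples")
  feats <- t(vapply(samples[keep], function(s) log_filter(s, config),
                    numeric(12L)))
  colnames(feats) <- feature_names()
  structure(list(features = feats,
                 ratings = ratings[keep],
                 weights = compute_weights(ratings[keep]),
                 provenance = ids[keep],
                 drop_report = drop_report),
            class = "training_set")
}

#' Build a training set from a samples table
#'
#' Counterpart of [read_samples]: reconstructs `quality_features` rows and
#' assembles them (drop rules, log filter, weights) exactly as
#' [assemble_training_set] does.
#'
#' @param df data frame from [read_samples].
#' @param config configuration list.
#' @return A `training_set`.
#' @export
training_set_from_table <- function(df, config = fd_config()) {
  samples <- lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, feature_names()])
    names(vals) <- feature_names()
    structure(list(binary = c(cp_in_range = df$cp_in_range[i] > 0,
                              enough_points = df$enough_points[i] > 0,
                              few_spikes = df$few_spikes[i] > 0),
                   continuous = vals,
                   computable = is.finite(vals),
                   n_spikes = NA_integer_),
              class = "quality_features")
  })
  ids <- if ("id" %in% names(df)) as.character(df$id) else NULL
  assemble_training_set(samples, df$rating, ids = ids, config = config)
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d samples, ratings %d..%d, dropped: %s\n",
              length(x$ratings), min(x$ratings), max(x$ratings),
              paste(sprintf("%s=%d", names(x$drop_report), x$drop_report),
                    collapse = ", ")))
  invisible(x)
}

# --- AdaBoost.R2 over rpart stumps-with-depth ------------------------------

.adaboost_r2_fit <- function(x, y, w, n_estimators = 50L, maxdepth = 6L,
                             seed = 1L) {
  df <- data.frame(x, y = y)
  w <- w / sum(w)
  learners <- list()
  betas <- numeric(0)
  set.seed(seed)
  for (m in seq_len(n_estimators)) {
    fitm <- rpart::rpart(y ~ ., df, weights = w * length(y),
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = 0, minsplit = 5,
                           xval = 0))
    pred <- stats::predict(fitm, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) { learners[[m]] <- fitm; betas[m] <- 1e-10; break }
    L <- err / emax                       # linear loss
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) break
    beta <- Lbar / (1 - Lbar)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
    learners[[m]] <- fitm
    betas[m] <- beta
  }
  if (length(learners) == 0L) {          # fall back to a single tree
    learners[[1]] <- rpart::rpart(y ~ ., df, weights = w * length(y),
                                  control = rpart::rpart.control(
                                    maxdepth = maxdepth, cp = 0, xval = 0))
    betas[1] <- 0.5
  }
  list(learners = learners, log_inv_beta = log(1 / betas))
}

.adaboost_r2_predict <- function(model, newdata) {
  preds <- vapply(model$learners, function(l) stats::predict(l, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  lw <- model$log_inv_beta
  # weighted median across learners, per sample
  apply(preds, 1L, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

# --- rater -----------------------------------------------------------------

.svr_recipe <- function(x, ratings) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- scale(x, center, scale)
  keep <- apply(xs, 2, stats::sd) > 1e-10
  lda_fit <- tryCatch(
    suppressWarnings(MASS::lda(xs[, keep, drop = FALSE],
                               grouping = factor(ratings))),
    error = function(e) NULL)
  list(center = center, scale = scale, keep = keep, lda = lda_fit)
}

.svr_apply <- function(recipe, x) {
  xs <- scale(x, recipe$center, recipe$scale)[, recipe$keep, drop = FALSE]
  if (is.null(recipe$lda)) xs else xs %*% recipe$lda$scaling
}

#' Train a quality rater
#'
#' Fits one of the supported regressors to a training set. Tree-based
#' kinds use the per-sample occurrence weights; the SVR kinds first scale
#' the features to unit variance and project them onto the linear
#' discriminant axes of the rating classes (fitted on the training set
#' only). Training rows are put into a canonical order internally, so the
#' fitted rater is invariant to the row order of the training set at a
#' fixed seed.
#'
#' @param ts a `training_set`.
#' @param kind regressor kind, one of [rater_kinds()].
#' @param hyper named list of hyper-parameter overrides (`num_trees`,
#'   `max_depth`, `n_estimators`, `nrounds`, `eta`, `cost`, ...).
#' @param seed integer seed; the same seed yields identical predictions.
#' @return A `fd_rater` object.
#' @export
train_rater <- function(ts, kind = "extra_trees", hyper = list(),
                        seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (!kind %in% rater_kinds())
    stop(sprintf("unknown regressor kind '%s' (available: %s)", kind,
                 paste(rater_kinds(), collapse = ", ")))
  if (length(ts$ratings) == 0L) stop("empty training set")
  if (all(apply(ts$features, 2, stats::sd) < 1e-14))
    stop("degenerate training set: all features constant")
  h <- utils::modifyList(list(num_trees = 100L, min_node = 1L,
                              nrounds = 150L, eta = 0.1, max_depth = 6L,
                              n_estimators = 50L, cost = 1), hyper)
  # canonical row order: lexicographic over features then rating
  ord <- do.call(order, c(lapply(seq_len(ncol(ts$features)),
                                 function(j) ts$features[, j]),
                          list(ts$ratings)))
  x <- ts$features[ord, , drop = FALSE]
  y <- ts$ratings[ord]
  w <- ts$weights[ord]
  recipe <- NULL
  set.seed(seed)
  model <- switch(kind,
    extra_trees = ranger::ranger(
      x = x, y = y, num.trees = h$num_trees, mtry = ncol(x),
      min.node.size = h$min_node, splitrule = "extratrees",
      num.random.splits = 1L, replace = FALSE, sample.fraction = 1,
      case.weights = w, seed = seed, num.threads = 1L),
    random_forest = ranger::ranger(
      x = x, y = y, num.trees = h$num_trees, min.node.size = h$min_node,
      case.weights = w, seed = seed, num.threads = 1L),
    gradient_boosting = xgboost::xgboost(
      x = x, y = y, weights = w, nrounds = h$nrounds,
      learning_rate = h$eta, max_depth = 3L, nthreads = 1L,
      objective = "reg:squarederror", seed = seed, verbosity = 0L),
    adaboost = .adaboost_r2_fit(x, y, w, n_estimators = h$n_estimators,
                                maxdepth = h$max_depth, seed = seed),
    decision_tree = rpart::rpart(
      y ~ ., data.frame(x, y = y), weights = w,
      control = rpart::rpart.control(cp = 0, minsplit = 2L,
                                     maxdepth = 30L, xval = 0)),
    svr_linear = ,
    svr_rbf = {
      recipe <- .svr_recipe(x, y)
      e1071::svm(.svr_apply(recipe, x), y,
                 kernel = if (kind == "svr_linear") "linear" else "radial",
                 cost = h$cost)
    })
  structure(list(kind = kind, model = model, recipe = recipe,
                 feature_names = colnames(x), seed = seed, hyper = h),
            class = "fd_rater")
}

#' @export
print.fd_rater <- function(x, ...) {
  cat(sprintf("<fd_rater> kind %s, seed %d\n", x$kind, x$seed))
  invisible(x)
}

#' Predict ratings for a feature matrix
#'
#' @param object a `fd_rater`.
#' @param newdata numeric matrix of log-filtered features (columns in
#'   [feature_names] order).
#' @param ... unused.
#' @return Numeric ratings clipped to \[0, 10\].
#' @export
predict.fd_rater <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  pred <- switch(object$kind,
    extra_trees = ,
    random_forest = stats::predict(object$model, data = newdata,
                                   num.threads = 1L)$predictions,
    gradient_boosting = stats::predict(object$model, newdata),
    adaboost = .adaboost_r2_predict(object$model,
                                    as.data.frame(newdata)),
    decision_tree = stats::predict(object$model, as.data.frame(newdata)),
    svr_linear = ,
    svr_rbf = as.numeric(stats::predict(object$model,
                                        .svr_apply(object$recipe, newdata))))
  pmin(pmax(as.numeric(pred), 0), 10)
}

#' Rate one curve from its quality features
#'
#' @param rater a `fd_rater`.
#' @param feats a `quality_features` object.
#' @param config configuration list (log-filter constants).
#' @return Rating in \[0, 10\], or the sentinel `-1` when any feature is
#'   not computable (unrateable curve; maps render such pixels as
#'   missing).
#' @export
rate_curve <- function(rater, feats, config = fd_config()) {
  stopifnot(inherits(rater, "fd_rater"), inherits(feats, "quality_features"))
  if (!all(feats$computable)) return(-1)
  predict(rater, matrix(log_filter(feats, config), nrow = 1,
                        dimnames = list(NULL, feature_names())))
}

#' Classify a rating as good or poor
#'
#' @param rating numeric rating(s) in \[0, 10\].
#' @param threshold classification threshold; the default 4.5 sits between
#'   "just usable" (5) and the next lower class. A rating is `"good"` iff
#'   it exceeds the threshold. Raising the threshold (e.g. to 6) trades
#'   fewer selected curves for a lower false-positive rate.
#' @return Factor with levels `poor`, `good`.
#' @export
classify_rating <- function(rating, threshold = 4.5) {
  factor(ifelse(rating > threshold, "good", "poor"),
         levels = c("poor", "good"))
}

#' Select the indices of the n top-rated curves
#'
#' @param ratings numeric ratings.
#' @param n number of curves to keep (<= length of `ratings`).
#' @return Integer indices of the `n` largest ratings; ties are broken by
#'   original order (stable).
#' @export
select_top_n <- function(ratings, n) {
  if (n > length(ratings)) stop("n exceeds the number of ratings")
  utils::head(order(-ratings, seq_along(ratings)), n)
}

#' Persist a trained rater
#'
#' Stores the rater (kind, hyper-parameters, seed, fitted state) in a
#' single-object container readable by [load_rater].
#'
#' @param rater a `fd_rater`.
#' @param path output path.
#' @export
save_rater <- function(rater, path) {
  stopifnot(inherits(rater, "fd_rater"))
  saveRDS(list(format = "fdrate-rater", version = 1L, rater = rater), path)
  invisible(path)
}

#' Load a rater written by [save_rater]
#' @param path file path.
#' @return A `fd_rater`.
#' @export
load_rater <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "fdrate-rater"))
    stop("not a rater container")
  obj$rater
}

#' Fit and rate every pixel of an FD map
#'
#' Runs the per-curve pipeline ([curve_sample]) on each recorded pixel and
#' returns per-pixel images of the fitted modulus and, when a rater is
#' supplied, the predicted quality rating (`-1` marks unrateable pixels,
#' `NA` missing ones).
#'
#' @param map an `fd_map`.
#' @param rater optional `fd_rater`.
#' @param config configuration list.
#' @return A data frame: `row`, `col`, `E` \[Pa\], `delta_c` \[m\],
#'   `converged`, `min_height` \[m\], and `rating`.
#' @export
analyze_map <- function(map, rater = NULL, config = fd_config()) {
  stopifnot(inherits(map, "fd_map"))
  rows <- map$grid_shape[1]; cols <- map$grid_shape[2]
  out <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  out$E <- NA_real_; out$delta_c <- NA_real_
  out$converged <- NA; out$min_height <- NA_real_; out$rating <- NA_real_
  for (i in seq_len(nrow(out))) {
    cur <- map_get_pixel(map, out$row[i], out$col[i])
    if (is.null(cur)) next
    smp <- curve_sample(cur, config = config)
    out$converged[i] <- smp$fit$converged
    out$min_height[i] <- min(cur$piezo_height)
    if (smp$fit$converged) {
      out$E[i] <- smp$fit$params$E
      out$delta_c[i] <- smp$fit$params$delta_c
    }
    if (!is.null(rater))
      out$rating[i] <- rate_curve(rater, smp$features, config)
  }
  out
}
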