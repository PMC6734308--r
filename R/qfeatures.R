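# Quality features extracted from a contact-model fit: three binary
# usability flags plus twelve continuous features, which together form the
# "sample" of an FD curve used for supervised rating.
#
# Conventions (in terms of the fitted contact point delta_c):
#   d      indentation depth, delta_c - tip_position
#   IDT    indentation part, d > 0
#   APR    approach part, d <= 0
#   BLN    baseline, first 50% of APR in acquisition order
#   r      unweighted fit residuals (data - model)
#   F_max  maximum force over IDT; d_max maximum indentation depth
# All continuous features are normalized to be dimensionless, so scaling
# force and model by a common factor leaves every feature unchanged.

#' Names of the twelve continuous quality features
#' @return Character vector in canonical table order.
#' @export
feature_names <- function() {
  c("spike_area", "curvature_cp", "flatness_apr", "maxima_idt",
    "monotony_idt", "overall_idt", "relative_apr", "residuals_cp",
    "residuals_75idt", "residuals_apr", "slope_bln", "variation_bln")
}

#' Detect spikes in the indentation residuals
#'
#' A spike is a maximal run of at least `min_run` consecutive indentation
#' points whose residual deviates from a running median by more than
#' `mad_mult` MADs of the indentation residuals (with a small absolute
#' floor so numerically flat series report none). Intervals are disjoint
#' and sorted.
#'
#' @param fit an `fd_fit` from [fit_curve].
#' @param config configuration list from [fd_config] (`spike` entries).
#' @return Integer matrix with columns `start`, `end`: index intervals
#'   into the indentation part, possibly zero rows.
#' @export
detect_spikes <- function(fit, config = fd_config()) {
  stopifnot(inherits(fit, "fd_fit"))
  sp <- config$spike
  idt <- which(fit$delta < fit$params$delta_c)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (length(idt) < sp$min_run) return(empty)
  r <- fit$residuals[idt]
  if (anyNA(r)) return(empty)
  win <- min(sp$median_window, length(r) - (1 - length(r) %% 2))
  med <- if (win >= 3) stats::runmed(r, win, endrule = "median") else r
  dev <- abs(r - med)
  f_scale <- if (is.finite(fit$max_force) && fit$max_force > 0)
    fit$max_force else max(abs(fit$force))
  thr <- max(sp$mad_mult * stats::mad(r), sp$abs_floor * f_scale)
  runs <- rle(dev > thr)
  ends <- cumsum(runs$lengths)
  keep <- which(runs$values & runs$lengths >= sp$min_run)
  if (length(keep) == 0L) return(empty)
  cbind(start = ends[keep] - runs$lengths[keep] + 1L, end = ends[keep])
}

#' Binary usability features of a fitted curve
#'
#' The three preprocessing filters: the fitted contact point lies inside
#' the data range, the combined approach + indentation size is at least
#' 600 points, and the indentation part exhibits at most five distinct
#' spikes. All three true means the curve is usable.
#'
#' @inheritParams detect_spikes
#' @return Named logical vector `cp_in_range`, `enough_points`,
#'   `few_spikes`.
#' @export
binary_features <- function(fit, config = fd_config()) {
  stopifnot(inherits(fit, "fd_fit"))
  dc <- fit$params$delta_c
  c(cp_in_range = min(fit$delta) <= dc && dc <= max(fit$delta),
    enough_points = length(fit$force) >= config$binary$min_points,
    few_spikes = nrow(detect_spikes(fit, config)) <= config$binary$max_spikes)
}

# local indentation-depth spacing for the spike-area integral
.local_spacing <- function(d) {
  n <- length(d)
  if (n == 1L) return(0)
  dd <- abs(diff(d))
  (c(dd[1], dd) + c(dd, dd[n - 1L])) / 2
}

#' Continuous quality features of a fitted curve
#'
#' Computes the twelve dimensionless features (see [feature_names] for the
#' canonical order) from the unweighted fit residuals, the force data, and
#' the fitted contact point. Any feature that cannot be computed (empty
#' region, zero normalization, non-finite result) has its `computable`
#' flag set to `FALSE` instead of raising.
#'
#' @inheritParams detect_spikes
#' @return A `quality_features` object: `binary` (3 flags), `continuous`
#'   (12 named raw values), `computable` (12 flags), `n_spikes`.
#' @export
continuous_features <- function(fit, config = fd_config()) {
  stopifnot(inherits(fit, "fd_fit"))
  dc <- fit$params$delta_c
  R <- fit$params$R
  d <- dc - fit$delta            # indentation depth axis (positive past contact)
  idt <- which(d > 0)
  apr <- which(d <= 0)
  bln <- apr[seq_len(max(1L, floor(length(apr) / 2)))]
  r <- fit$residuals
  f <- fit$force
  f_max <- fit$max_force
  d_max <- fit$max_indentation
  spikes <- detect_spikes(fit, config)

  vals <- stats::setNames(rep(NA_real_, 12L), feature_names())
  ok <- function(x) length(x) == 1L && is.finite(x)
  usable <- length(idt) > 0L && length(apr) > 0L &&
    is.finite(f_max) && f_max > 0 && is.finite(d_max) && d_max > 0 &&
    !anyNA(r)

  if (usable) {
    # 1: area of spikes in the indentation part
    if (nrow(spikes) == 0L) vals["spike_area"] <- 0
    else {
      dd <- .local_spacing(d[idt])
      area <- 0
      for (j in seq_len(nrow(spikes))) {
        span <- spikes[j, "start"]:spikes[j, "end"]
        area <- area + sum(abs(r[idt][span]) * dd[span])
      }
      vals["spike_area"] <- area / (f_max * d_max)
    }
    # 2: curvature of the FD data at the contact point
    cp <- which(abs(d) <= 1e-6)
    if (length(cp) >= 3L) {
      q <- stats::lm.fit(cbind(1, d[cp], d[cp]^2), f[cp])$coefficients[3]
      vals["curvature_cp"] <- 2 * q * R^2 / f_max
    }
    # 3: fraction of positive-gradient smoothed residuals in the approach
    if (length(apr) >= 2L) {
      g <- diff(.moving_average(r[apr], 15L))
      vals["flatness_apr"] <- mean(g > 0)
    }
    # 4: sum of residual maxima in three intervals over [0.25, 1] d_max
    edges <- seq(0.25 * d_max, d_max, length.out = 4L)
    bins <- findInterval(d[idt], edges, rightmost.closed = TRUE)
    present <- intersect(1:3, unique(bins))
    if (length(present) == 3L)
      vals["maxima_idt"] <- sum(vapply(present, function(b)
        max(abs(r[idt][bins == b])), numeric(1))) / f_max
    # 5: fraction of negative smoothed force gradient in the indentation
    if (length(idt) >= 2L) {
      gf <- diff(.moving_average(f[idt], 15L))   # d increases along idt
      vals["monotony_idt"] <- mean(gf < 0)
    }
    # 6: mean absolute residual over the indentation part
    vals["overall_idt"] <- sum(abs(r[idt])) / (length(idt) * f_max)
    # 7: approach size relative to indentation size
    vals["relative_apr"] <- length(apr) / length(idt)
    # 8: mean absolute residual around the contact point (+-2 um)
    cp2 <- which(abs(d) <= 2e-6)
    if (length(cp2) > 0L)
      vals["residuals_cp"] <- mean(abs(r[cp2])) / f_max
    # 9: mean absolute residual over the deep 75% of the indentation
    deep <- idt[d[idt] >= 0.25 * d_max]
    if (length(deep) > 0L)
      vals["residuals_75idt"] <- sum(abs(r[deep])) / (length(deep) * f_max)
    # 10: mean absolute residual over the approach part
    vals["residuals_apr"] <- sum(abs(r[apr])) / (length(apr) * f_max)
    # 11: normalized baseline slope
    if (length(bln) >= 2L && stats::sd(d[bln]) > 0) {
      sl <- stats::cov(d[bln], f[bln]) / stats::var(d[bln])
      vals["slope_bln"] <- sl * diff(range(d[bln])) / f_max
    }
    # 12: force variation between the ends of the baseline
    if (length(bln) >= 2L) {
      k <- max(1L, ceiling(0.1 * length(bln)))
      vals["variation_bln"] <- abs(mean(f[utils::head(bln, k)]) -
                                   mean(f[utils::tail(bln, k)])) / f_max
    }
  }
  computable <- is.finite(vals)
  structure(list(binary = binary_features(fit, config),
                 continuous = vals,
                 computable = computable,
                 n_spikes = nrow(spikes)),
            class = "quality_features")
}

#' @export
print.quality_features <- function(x, ...) {
  cat("<quality_features>\n  binary:",
      paste(sprintf("%s=%s", names(x$binary), x$binary), collapse = ", "),
      sprintf("\n  %d/12 continuous features computable, %d spike(s)\n",
              sum(x$computable), x$n_spikes))
  invisible(x)
}

#' Log-filter a feature vector for training
#'
#' Compresses the spread of the unbounded features:
#' nonnegative unbounded features map through `x -> log(1 + scale * x)`,
#' signed features through `sign(x) * log(1 + scale * |x|)`, the size
#' ratio `relative_apr` through `log(x)`, and the bounded fractions
#' (`flatness_apr`, `monotony_idt`) pass unchanged.
#'
#' @param x named numeric vector of raw features ([feature_names] order)
#'   or a `quality_features` object.
#' @param config configuration list (uses `filter$scale`).
#' @return Named numeric vector of filtered features.
#' @export
log_filter <- function(x, config = fd_config()) {
  if (inherits(x, "quality_features")) x <- x$continuous
  s <- config$filter$scale
  out <- x
  for (nm in c("spike_area", "maxima_idt", "overall_idt", "residuals_cp",
               "residuals_75idt", "residuals_apr"))
    out[nm] <- log1p(s * x[nm])
  for (nm in c("curvature_cp", "slope_bln"))
    out[nm] <- sign(x[nm]) * log1p(s * abs(x[nm]))
  out["relative_apr"] <- log(x["relative_apr"])
  out
}

#' Run the full per-curve pipeline to a quality sample
#'
#' Preprocesses a raw curve ([preprocess_curve]), fits the contact model
#' ([fit_curve]), and extracts the quality features
#' ([continuous_features]).
#'
#' @param curve an `fd_curve`.
#' @param model contact-model name (see [fd_models]).
#' @param params a [contact_params] with the indenter geometry.
#' @param config configuration list from [fd_config].
#' @return A list: `fit` (`fd_fit`) and `features` (`quality_features`).
#' @export
curve_sample <- function(curve, model = "spherical_approx",
                         params = contact_params(), config = fd_config()) {
  pp <- preprocess_curve(curve)
  dc0 <- if (is.finite(pp$delta_c0)) pp$delta_c0 else NULL
  fit <- fit_curve(pp$curve, model = model, params = params, delta_c0 = dc0)
  list(fit = fit, features = continuous_features(fit, config))
}

# --- samples table I/O -----------------------------------------------------

#' Write a samples table (features + ratings) to TSV
#'
#' One row per curve: the three binary flags, the twelve raw continuous
#' features in canonical order, the manual rating (NA allowed), and an
#' identifier.
#'
#' @param samples list of `quality_features`.
#' @param ratings integer ratings 0..10 (or NA), one per sample.
#' @param path output path.
#' @param ids optional character identifiers (default `"s1"`, `"s2"`, ...).
#' @export
write_samples <- function(samples, ratings, path, ids = NULL) {
  stopifnot(length(samples) == length(ratings))
  if (is.null(ids)) ids <- paste0("s", seq_along(samples))
  df <- do.call(rbind, lapply(samples, function(s)
    data.frame(t(c(as.integer(s$binary), s$continuous)))))
  names(df) <- c(names(samples[[1]]$binary), feature_names())
  df$rating <- ratings
  df$id <- ids
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples table written by [write_samples]
#' @param path TSV path.
#' @return A data frame with flag, feature, `rating` and `id` columns.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  needed <- c("cp_in_range", "enough_points", "few_spikes", feature_names(),
              "rating")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop(sprintf("format error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  df
}
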