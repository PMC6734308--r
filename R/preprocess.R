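# Preprocessing of FD curves: tip-sample separation, baseline offset
# correction, and a rough contact-point estimate used to initialize the fit.

#' Compute the tip position (tip-sample separation)
#'
#' Corrects the piezo height for cantilever bending:
#' `tip_position = piezo_height - force / spring_constant`, per point.
#' All other fields are unchanged.
#'
#' @param curve an `fd_curve` with `spring_constant > 0`.
#' @return The curve with `tip_position` filled in.
#' @export
compute_tip_position <- function(curve) {
  validate_fd_curve(curve)
  curve$tip_position <- curve$piezo_height - curve$force / curve$spring_constant
  curve
}

.approach_indices <- function(curve) which(curve$segment == "approach")

# Baseline region: first 50% of the approach part in acquisition order --
# far from contact by construction.
.baseline_region <- function(curve) {
  ap <- .approach_indices(curve)
  ap[seq_len(max(1L, floor(length(ap) / 2)))]
}

#' Estimate the force baseline of an approach curve
#'
#' Statistics of the pre-contact force: mean, standard deviation, and the
#' least-squares slope of force against tip position, computed on the
#' baseline region (the first half of the approach part in acquisition
#' order, which is far from contact by construction).
#'
#' @param curve an `fd_curve` with at least 20 approach points; the tip
#'   position is computed on the fly if absent.
#' @return A `baseline_info` object: `mean_force` \[N\], `sd_force` \[N\],
#'   `slope` \[N/m\], and `region` (indices of the points used).
#' @export
estimate_baseline <- function(curve) {
  validate_fd_curve(curve)
  if (length(.approach_indices(curve)) < 20L)
    stop("baseline estimation requires at least 20 approach points")
  if (is.null(curve$tip_position)) curve <- compute_tip_position(curve)
  region <- .baseline_region(curve)
  f <- curve$force[region]
  d <- curve$tip_position[region]
  slope <- if (stats::sd(d) == 0) 0 else stats::cov(d, f) / stats::var(d)
  structure(list(mean_force = mean(f),
                 sd_force = if (length(f) > 1L) stats::sd(f) else 0,
                 slope = slope,
                 region = region),
            class = "baseline_info")
}

#' Correct the force offset using the baseline average
#'
#' Subtracts `baseline$mean_force` from the force series, so the baseline
#' region of the corrected curve has zero mean. Point count and tip
#' position are preserved.
#'
#' @param curve an `fd_curve`.
#' @param baseline a `baseline_info` from [estimate_baseline].
#' @return The offset-corrected curve.
#' @export
correct_offset <- function(curve, baseline) {
  validate_fd_curve(curve)
  stopifnot(inherits(baseline, "baseline_info"))
  curve$force <- curve$force - baseline$mean_force
  curve
}

# centered moving average, window clipped at the edges
.moving_average <- function(x, window = 15L) {
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rough contact-point estimate from a baseline threshold crossing
#'
#' Smooths the approach force with a centered moving average and returns
#' the tip position of the first point from which the smoothed force stays
#' above `mean + sd_mult * sd` of the baseline for at least `persist`
#' consecutive points. This is a deliberately rough estimate: the final
#' contact point is a fitted parameter of [fit_curve].
#'
#' @param curve an offset-corrected `fd_curve` with tip position computed.
#' @param baseline the `baseline_info` of the *corrected* curve.
#' @param sd_mult threshold in baseline standard deviations (default 3).
#' @param persist required number of consecutive above-threshold points
#'   (default 10).
#' @param window moving-average window in points (default 15).
#' @param rel_floor small relative floor added to the threshold, as a
#'   fraction of the smoothed force range above the baseline; keeps the
#'   crossing from triggering half a smoothing window early on
#'   noise-free data (default 1e-3).
#' @return A list: `delta_c` — the estimated contact-point tip position
#'   \[m\]; `curve` — the input with tip position shifted so the estimate
#'   maps to zero.
#' @export
estimate_contact_point <- function(curve, baseline, sd_mult = 3,
                                   persist = 10L, window = 15L,
                                   rel_floor = 1e-3) {
  validate_fd_curve(curve)
  stopifnot(inherits(baseline, "baseline_info"))
  if (is.null(curve$tip_position))
    stop("tip position must be computed before contact-point estimation")
  ap <- .approach_indices(curve)
  sm <- .moving_average(curve$force[ap], window)
  thr <- baseline$mean_force + sd_mult * baseline$sd_force +
    rel_floor * max(max(sm) - baseline$mean_force, 0)
  above <- sm > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persist)
  if (length(hit) == 0L) stop("no contact detected")
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  delta_c <- curve$tip_position[ap[first]]
  curve$tip_position <- curve$tip_position - delta_c
  list(delta_c = delta_c, curve = curve)
}

#' Preprocess a curve for fitting
#'
#' Convenience wrapper chaining [compute_tip_position], [estimate_baseline],
#' [correct_offset] and a recomputed baseline; the rough contact point is
#' estimated but the tip-position axis is left unshifted (the fit treats
#' the contact point as a free parameter).
#'
#' @param curve an `fd_curve`.
#' @return A list: `curve` (tip position computed, offset corrected),
#'   `baseline` (of the corrected curve), `delta_c0` (rough contact-point
#'   tip position, or `NA` if no contact was detected).
#' @export
preprocess_curve <- function(curve) {
  curve <- compute_tip_position(curve)
  bl <- estimate_baseline(curve)
  curve <- correct_offset(curve, bl)
  bl <- estimate_baseline(curve)
  delta_c0 <- tryCatch(estimate_contact_point(curve, bl)$delta_c,
                       error = function(e) NA_real_)
  list(curve = curve, baseline = bl, delta_c0 = delta_c0)
}
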