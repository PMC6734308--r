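# Least-squares fitting of a contact model to a preprocessed FD curve.
#
# The model force is linear in the apparent Young's modulus E, so E is
# profiled out in closed form at every candidate contact point delta_c;
# delta_c itself is located by a deterministic coarse grid search followed
# by golden-section refinement. Residuals near the contact point are
# down-weighted by a linear ramp before entering the objective.

.fd_model_registry <- list(
  parabolic = function(delta, params) force_parabolic(delta, params),
  spherical_approx = function(delta, params) force_spherical_approx(delta, params)
)

#' Names of the available contact models
#' @return Character vector of model names usable with [fit_curve].
#' @export
fd_models <- function() names(.fd_model_registry)

#' Linear ramp weights suppressing residuals near the contact point
#'
#' Residuals are weighted 1 outside the interval
#' `(delta_c - half_width, delta_c + half_width)` on the tip-position axis.
#' Inside, the weight rises linearly from 0 at the baseline-side edge
#' (tip position `delta_c + half_width`; the tip position decreases toward
#' the sample) to 1 at the indentation-side edge, so that the
#' indentation-side residuals, which drive the quality features, keep full
#' weight.
#'
#' @param tip_position tip-position series \[m\].
#' @param delta_c contact-point tip position \[m\].
#' @param half_width half-width of the suppression interval \[m\]; the
#'   default 2 um is about 10% of the standard indenter radius.
#' @return Weights in \[0, 1\], same length as `tip_position`.
#' @export
ramp_weights <- function(tip_position, delta_c, half_width = 2e-6) {
  stopifnot(half_width > 0)
  w <- rep(1, length(tip_position))
  inside <- abs(tip_position - delta_c) <= half_width
  w[inside] <- (delta_c + half_width - tip_position[inside]) / (2 * half_width)
  w
}

# model shape at E = 1 (force is linear in E); indentation depth is
# d = delta_c - tip_position, clamped to 0 before contact and capped just
# below R where the series approximation loses validity
.model_shape <- function(tip_position, delta_c, params, model_fun) {
  d <- pmax(delta_c - tip_position, 0)
  d <- pmin(d, params$R * 0.999)
  p1 <- params
  p1$E <- 1
  model_fun(d, p1)
}

#' Fit a contact model to a preprocessed FD curve
#'
#' Minimizes the ramp-weighted sum of squared force residuals over the free
#' parameters `E` (apparent Young's modulus) and `delta_c` (contact point);
#' the model force is clamped to zero before contact. `E` has a closed-form
#' weighted least-squares solution at fixed `delta_c`, which is profiled
#' out; `delta_c` is then minimized over a deterministic grid spanning the
#' contact-point search window, refined by golden-section search.
#'
#' @param curve an `fd_curve`, tip position computed and offset corrected
#'   (see [preprocess_curve]); only the approach part is used.
#' @param model model name, one of [fd_models()]. Default
#'   `"spherical_approx"`.
#' @param params a [contact_params] carrying `nu` and `R` (the `E` and
#'   `delta_c` slots are ignored and replaced by the fit).
#' @param delta_c0 initial contact-point tip position \[m\]; when `NULL`,
#'   taken from [estimate_contact_point], falling back to the median tip
#'   position when no contact is detected.
#' @param half_width ramp half-width \[m\] passed to [ramp_weights].
#' @param search_width half-width of the `delta_c` search window around
#'   `delta_c0` \[m\] (clipped to the data range).
#' @return A `fd_fit` object: fitted `params`, unweighted `residuals` \[N\],
#'   `weights`, `delta` (approach tip positions \[m\]), `force` (approach
#'   forces \[N\]), `model_name`, `converged`, `max_force` \[N\],
#'   `max_indentation` \[m\], and the weighted `sse`. Non-convergence is
#'   reported through `converged = FALSE`, never as an error.
#' @export
fit_curve <- function(curve, model = "spherical_approx",
                      params = contact_params(), delta_c0 = NULL,
                      half_width = 2e-6, search_width = 3e-6) {
  validate_fd_curve(curve)
  if (!model %in% names(.fd_model_registry))
    stop(sprintf("unknown model '%s' (available: %s)", model,
                 paste(fd_models(), collapse = ", ")))
  model_fun <- .fd_model_registry[[model]]
  if (is.null(curve$tip_position)) curve <- compute_tip_position(curve)
  ap <- extract_approach(curve)
  dt <- ap$tip_position
  f <- ap$force

  failed <- function(reason) {
    structure(list(params = params, residuals = rep(NA_real_, length(f)),
                   weights = rep(1, length(f)), delta = dt, force = f,
                   model_name = model, converged = FALSE, reason = reason,
                   max_force = NA_real_, max_indentation = NA_real_,
                   sse = NA_real_),
              class = "fd_fit")
  }
  if (all(f == 0)) return(failed("degenerate input: all-zero force"))

  if (is.null(delta_c0)) {
    bl <- tryCatch(estimate_baseline(ap), error = function(e) NULL)
    delta_c0 <- if (is.null(bl)) stats::median(dt) else
      tryCatch(estimate_contact_point(ap, bl)$delta_c,
               error = function(e) stats::median(dt))
  }

  # profile objective: closed-form E* at fixed delta_c
  profile <- function(dc) {
    g <- .model_shape(dt, dc, params, model_fun)
    w <- ramp_weights(dt, dc, half_width)
    denom <- sum(w * g * g)
    E <- if (denom > 0) max(0, sum(w * f * g) / denom) else 0
    list(E = E, sse = sum(w * (f - E * g)^2))
  }
  objective <- function(dc) profile(dc)$sse

  rng <- range(dt)
  span <- diff(rng)
  lo <- max(rng[1] - 0.1 * span, delta_c0 - search_width)
  hi <- min(rng[2] + 0.1 * span, delta_c0 + search_width)
  grid <- sort(unique(c(seq(lo, hi, length.out = 61L), delta_c0)))
  sses <- vapply(grid, objective, numeric(1))
  i <- which.min(sses)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  dc_hat <- if (bracket[1] < bracket[2])
    stats::optimize(objective, bracket, tol = 1e-10)$minimum else grid[i]
  if (objective(dc_hat) > sses[i]) dc_hat <- grid[i]  # keep grid optimum

  sol <- profile(dc_hat)
  fitted_params <- contact_params(E = sol$E, nu = params$nu, R = params$R,
                                  delta_c = dc_hat)
  g <- .model_shape(dt, dc_hat, params, model_fun)
  resid <- f - sol$E * g
  idt <- dt < dc_hat
  converged <- is.finite(sol$E) && sol$E >= 0 && sum(idt) >= 10L
  structure(list(params = fitted_params,
                 residuals = resid,
                 weights = ramp_weights(dt, dc_hat, half_width),
                 delta = dt, force = f, model_name = model,
                 converged = converged,
                 reason = if (converged) NA_character_ else
                   "insufficient indentation (fewer than 10 points beyond the contact point)",
                 max_force = if (any(idt)) max(f[idt]) else NA_real_,
                 max_indentation = if (any(idt)) max(dc_hat - dt[idt]) else NA_real_,
                 sse = sol$sse),
            class = "fd_fit")
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> model %s, converged: %s\n", x$model_name, x$converged))
  if (x$converged)
    cat(sprintf("  E = %.4g Pa, delta_c = %.4g um, F_max = %.4g nN, d_max = %.4g um\n",
                x$params$E, x$params$delta_c * 1e6, x$max_force * 1e9,
                x$max_indentation * 1e6))
  invisible(x)
}
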