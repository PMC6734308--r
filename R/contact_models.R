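# Force-indentation laws for a spherical indenter on an elastic half-space.
#
# Three routes to the same physics:
#  * force_parabolic():        F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2),
#                              the parabolic (small-indentation) limit;
#  * sneddon_exact():          the exact parametric solution in the contact
#                              radius a, evaluated by bracketed root finding;
#  * force_spherical_approx(): the parabolic force times a truncated power
#                              series in delta/R that corrects it toward the
#                              exact solution.
# All inputs and outputs are SI base units (m, N, Pa).

#' Contact-model parameter set
#'
#' Bundles the parameters of the spherical-indenter contact model: the
#' apparent Young's modulus `E`, Poisson's ratio `nu`, the indenter radius
#' `R`, and the contact-point tip position `delta_c`.
#'
#' @param E apparent Young's modulus \[Pa\], >= 0.
#' @param nu Poisson's ratio, in \[0, 1); 0.5 (incompressible) is the
#'   conventional value for soft biological matter.
#' @param R indenter radius \[m\]. Default 18.64 um, the polystyrene-bead
#'   probe radius used for soft-tissue indentation.
#' @param delta_c contact-point tip position \[m\].
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(E = 1000, nu = 0.5, R = 18.64e-6, delta_c = 0) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E), E >= 0)
  stopifnot(is.numeric(nu), length(nu) == 1L, nu >= 0, nu < 1)
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R > 0)
  stopifnot(is.numeric(delta_c), length(delta_c) == 1L, is.finite(delta_c))
  structure(list(E = E, nu = nu, R = R, delta_c = delta_c),
            class = "contact_params")
}

#' @export
print.contact_params <- function(x, ...) {
  cat(sprintf("<contact_params> E = %g Pa, nu = %g, R = %g um, delta_c = %g um\n",
              x$E, x$nu, x$R * 1e6, x$delta_c * 1e6))
  invisible(x)
}

#' Parabolic-indenter (Hertz) force law
#'
#' `F = (4/3) E/(1 - nu^2) sqrt(R) delta^(3/2)` — the leading-order force
#' for a sphere of radius `R` indenting an elastic half-space, valid for
#' indentation depths small compared to `R`.
#'
#' @param delta indentation depth(s) \[m\], >= 0.
#' @param params a [contact_params] object.
#' @return Force \[N\], same length as `delta`.
#' @export
force_parabolic <- function(delta, params) {
  stopifnot(inherits(params, "contact_params"))
  if (any(delta < 0)) stop("indentation depth must be >= 0")
  (4 / 3) * params$E / (1 - params$nu^2) * sqrt(params$R) * delta^1.5
}

# Correction-factor coefficients of the truncated power series in delta/R
# (see series_coefficients() for their derivation from the exact solution).
.approx_coefs <- c(-1 / 10, -1 / 840, 11 / 15120, 1357 / 6652800)

#' Series-corrected spherical-indenter force law
#'
#' The parabolic force multiplied by a fourth-order polynomial correction in
#' `delta/R`, approximating the exact spherical-indenter solution
#' ([sneddon_exact]) to better than 1e-4 of the maximum force over the
#' working range `delta <= R/2`.
#'
#' @inheritParams force_parabolic
#' @return Force \[N\].
#' @export
force_spherical_approx <- function(delta, params) {
  stopifnot(inherits(params, "contact_params"))
  if (any(delta < 0)) stop("indentation depth must be >= 0")
  if (any(delta >= params$R))
    stop("series approximation is only valid for delta < R")
  x <- delta / params$R
  bracket <- 1 + .approx_coefs[1] * x + .approx_coefs[2] * x^2 +
    .approx_coefs[3] * x^3 + .approx_coefs[4] * x^4
  force_parabolic(delta, params) * bracket
}

#' Exact spherical-indenter force law
#'
#' Evaluates the exact parametric solution for a rigid sphere indenting an
#' elastic half-space,
#' `F = E/(1-nu^2) * ((R^2 + a^2)/2 * log((R+a)/(R-a)) - a R)` with the
#' contact radius `a` defined implicitly through
#' `delta = a/2 * log((R+a)/(R-a))`. The implicit equation is solved for
#' `a` in `[0, R)` by bisection; `delta(a)` is strictly increasing and spans
#' `[0, Inf)` on that interval, so a bracket always exists.
#'
#' @inheritParams force_parabolic
#' @param tol relative tolerance on `a/R` for the bisection. Default 1e-12.
#' @return Force \[N\], same length as `delta`.
#' @export
sneddon_exact <- function(delta, params, tol = 1e-12) {
  stopifnot(inherits(params, "contact_params"))
  if (any(delta < 0)) stop("indentation depth must be >= 0")
  stopifnot(tol > 0)
  R <- params$R
  pref <- params$E / (1 - params$nu^2)
  delta_of_a <- function(a) a / 2 * log((R + a) / (R - a))
  vapply(delta, function(d) {
    if (d == 0) return(0)
    lo <- 0
    hi <- R * (1 - 1e-15)
    # shrink upper bracket first so the bisection starts tight
    while (delta_of_a(hi / 2) > d) hi <- hi / 2
    while (hi - lo > tol * R) {
      mid <- (lo + hi) / 2
      if (delta_of_a(mid) < d) lo <- mid else hi <- mid
    }
    a <- (lo + hi) / 2
    pref * ((R^2 + a^2) / 2 * log((R + a) / (R - a)) - a * R)
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Exact rational power-series toolbox.
#
# A series is a list(num, den): parallel numeric vectors holding the reduced
# fraction of the coefficient of t^k at position k + 1. Numerators and
# denominators are kept as exact doubles (integers below 2^53), reduced by
# gcd after every operation; intermediate magnitudes through order ~8 stay
# far below the exact-integer limit.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (num == 0) return(c(0, 1))
  g <- .gcd(num, den)
  s <- if (den < 0) -1 else 1
  c(s * num / g, s * den / g)
}

.rat_add <- function(a, b) .rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
.rat_mul <- function(a, b) .rat(a[1] * b[1], a[2] * b[2])
.rat_div <- function(a, b) {
  if (b[1] == 0) stop("division by zero fraction")
  .rat(a[1] * b[2], a[2] * b[1])
}

.rs_new <- function(n, const = c(0, 1)) {
  num <- numeric(n + 1); den <- rep(1, n + 1)
  num[1] <- const[1]; den[1] <- const[2]
  list(num = num, den = den)
}

.rs_coef <- function(s, k) c(s$num[k + 1], s$den[k + 1])
.rs_set <- function(s, k, r) { s$num[k + 1] <- r[1]; s$den[k + 1] <- r[2]; s }

.rs_order <- function(s) length(s$num) - 1L

.rs_add <- function(a, b) {
  n <- .rs_order(a)
  out <- .rs_new(n)
  for (k in 0:n) out <- .rs_set(out, k, .rat_add(.rs_coef(a, k), .rs_coef(b, k)))
  out
}

.rs_scale <- function(a, r) {
  n <- .rs_order(a)
  out <- .rs_new(n)
  for (k in 0:n) out <- .rs_set(out, k, .rat_mul(.rs_coef(a, k), r))
  out
}

.rs_mul <- function(a, b) {
  n <- .rs_order(a)
  out <- .rs_new(n)
  for (k in 0:n) {
    acc <- c(0, 1)
    for (j in 0:k) acc <- .rat_add(acc, .rat_mul(.rs_coef(a, j), .rs_coef(b, k - j)))
    out <- .rs_set(out, k, acc)
  }
  out
}

.rs_inv <- function(a) {
  # reciprocal series; requires nonzero constant term
  n <- .rs_order(a)
  a0 <- .rs_coef(a, 0)
  if (a0[1] == 0) stop("cannot invert series with zero constant term")
  out <- .rs_new(n)
  out <- .rs_set(out, 0, .rat_div(c(1, 1), a0))
  for (k in seq_len(n)) {
    acc <- c(0, 1)
    for (j in 1:k) acc <- .rat_add(acc, .rat_mul(.rs_coef(a, j), .rs_coef(out, k - j)))
    out <- .rs_set(out, k, .rat_div(.rat_mul(c(-1, 1), acc), a0))
  }
  out
}

.rs_compose <- function(a, b) {
  # a(b(t)); requires b to have zero constant term
  n <- .rs_order(a)
  if (.rs_coef(b, 0)[1] != 0) stop("inner series must have zero constant term")
  out <- .rs_new(n)
  bk <- .rs_new(n, c(1, 1))   # b^0
  for (k in 0:n) {
    out <- .rs_add(out, .rs_scale(bk, .rs_coef(a, k)))
    if (k < n) bk <- .rs_mul(bk, b)
  }
  out
}

.rs_pow_3_2 <- function(a) {
  # (1 + t)^(3/2) composed with (a - 1); requires unit constant term
  n <- .rs_order(a)
  if (!identical(.rs_coef(a, 0), c(1, 1)))
    stop("series must have unit constant term")
  t <- a
  t <- .rs_set(t, 0, c(0, 1))
  out <- .rs_new(n, c(1, 1))
  tk <- .rs_new(n, c(1, 1))
  coef <- c(1, 1)
  for (k in seq_len(n)) {
    # binomial coefficient C(3/2, k), built incrementally (always rational)
    coef <- .rat_mul(coef, .rat(3 - 2 * (k - 1), 2 * k))
    tk <- .rs_mul(tk, t)
    out <- .rs_add(out, .rs_scale(tk, coef))
  }
  out
}

#' Correction-factor series coefficients from the exact solution
#'
#' Derives, independently of any tabulated values, the coefficients `c_k`
#' of the expansion `F_exact / F_parabolic = 1 + sum_k c_k (delta/R)^k` by
#' series inversion of the exact parametric spherical-indenter solution.
#'
#' With `u = a/R` and `s = u^2`, the parametric solution gives
#' `delta/R = s * A(s)` with `A(s) = sum_k s^k/(2k+1)` (the `artanh` series)
#' and `F_exact/F_parabolic = B(s) / ((4/3) A(s)^{3/2})` with
#' `B(s) = sum_{k>=1} s^{k-1} (1/(2k+1) + 1/(2k-1))`. Reverting
#' `x = s A(s)` to obtain `s(x)` and composing yields the expansion in
#' `x = delta/R`. In `"rational"` mode every step is carried out in exact
#' reduced-fraction arithmetic; in `"numeric"` mode the coefficients are
#' estimated independently by a least-squares polynomial fit to the
#' numerically evaluated ratio [sneddon_exact] / [force_parabolic] at small
#' `delta/R` (accurate to roughly 1e-6 relative — a cross-check, not a
#' reference).
#'
#' @param order highest power of `delta/R` to compute (>= 1; rational mode
#'   is exact for any order within double-integer range, order <= 8 is
#'   guaranteed).
#' @param mode `"rational"` (exact fractions) or `"numeric"` (polynomial
#'   fit to the exact force ratio).
#' @return A data frame with columns `order`, `numerator`, `denominator`
#'   (reduced fraction, `NA` in numeric mode), and `value`.
#' @export
series_coefficients <- function(order = 4L, mode = c("rational", "numeric")) {
  mode <- match.arg(mode)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (mode == "numeric") return(.series_coefficients_numeric(order))

  n <- order
  A <- .rs_new(n)
  B <- .rs_new(n)
  for (k in 0:n) {
    A <- .rs_set(A, k, .rat(1, 2 * k + 1))
    B <- .rs_set(B, k, .rat_add(.rat(1, 2 * k + 3), .rat(1, 2 * k + 1)))
  }
  # G(s) = B(s) / ((4/3) A(s)^(3/2))
  G <- .rs_mul(B, .rs_inv(.rs_scale(.rs_pow_3_2(A), c(4, 3))))
  # revert x = s A(s): fixed-point iteration s <- x / A(s) in series form
  x <- .rs_new(n); x <- .rs_set(x, 1, c(1, 1))
  s <- x
  for (i in seq_len(n + 2)) s <- .rs_mul(x, .rs_inv(.rs_compose(A, s)))
  C <- .rs_compose(G, s)
  ks <- seq_len(order)
  data.frame(order = ks,
             numerator = C$num[ks + 1],
             denominator = C$den[ks + 1],
             value = C$num[ks + 1] / C$den[ks + 1])
}

.series_coefficients_numeric <- function(order) {
  p <- contact_params(E = 1, nu = 0.5, R = 1)
  # sample the exact/parabolic ratio on a short range of delta/R; extra
  # nuisance orders absorb the truncation tail
  deg <- order + 4L
  x <- seq(0.002, 0.2, length.out = 40 * deg)
  ratio <- sneddon_exact(x, p, tol = 1e-15) / force_parabolic(x, p)
  X <- outer(x, seq_len(deg), `^`)
  coefs <- stats::lm.fit(X, ratio - 1)$coefficients
  data.frame(order = seq_len(order),
             numerator = NA_real_,
             denominator = NA_real_,
             value = unname(coefs[seq_len(order)]))
}
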