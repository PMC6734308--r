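# Synthetic FD-curve generator: forward-simulated spherical-indentation
# curves with controlled artifact injection (contact-point offset,
# indentation spikes, baseline tilt, Gaussian noise), procedural
# ground-truth ratings, and 2-D FD maps emulating tissue regions.

#' Artifact specification for synthetic curves
#'
#' Magnitudes of the three artifact classes observed in tissue
#' indentation — a force step (offset) at the contact point from partial
#' tip-sample contact, sudden spikes in the indentation part from slippage,
#' and a tilt of the approach baseline from contingent contact with poorly
#' attached sample — plus Gaussian measurement noise.
#'
#' @param spike_count number of injected spikes (integer >= 0).
#' @param spike_amplitude spike amplitude as a fraction of the maximum
#'   clean force.
#' @param spike_width spike width in points.
#' @param tilt baseline slope \[N/m\] along the tip-position axis.
#' @param contact_offset force step at the contact point as a fraction of
#'   the maximum clean force.
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   maximum clean force.
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(spike_count = 0L, spike_amplitude = 0,
                          spike_width = 10L, tilt = 0, contact_offset = 0,
                          noise_sd = 0) {
  stopifnot(spike_count >= 0, spike_amplitude >= 0, spike_width >= 1,
            contact_offset >= 0, noise_sd >= 0)
  structure(list(spike_count = as.integer(spike_count),
                 spike_amplitude = spike_amplitude,
                 spike_width = as.integer(spike_width),
                 tilt = tilt, contact_offset = contact_offset,
                 noise_sd = noise_sd),
            class = "artifact_spec")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic FD curve
#'
#' Forward-simulates an approach curve: the tip position ramps linearly
#' from `z_approach` above the contact point to `z_indent` below it; the
#' force is zero before contact and follows the series-corrected
#' spherical-indenter law after contact. The piezo height is reconstructed
#' as `tip_position + force / spring_constant`, so [compute_tip_position]
#' recovers the simulated tip position exactly. Artifacts and noise are
#' then added to the force.
#'
#' @param E_true true apparent Young's modulus \[Pa\].
#' @param delta_c_true true contact-point tip position \[m\].
#' @param params a [contact_params] carrying `nu` and `R`.
#' @param n_points number of approach points (>= 2).
#' @param artifact an [artifact_spec].
#' @param seed integer seed; the same seed reproduces the curve
#'   bit-identically.
#' @param spring_constant cantilever spring constant \[N/m\].
#' @param z_approach pre-contact travel \[m\] (default 6 um).
#' @param z_indent post-contact travel \[m\] (default 2 um, about 10% of
#'   the standard indenter radius).
#' @param retract_points number of retract points appended (same force law
#'   traversed backwards; 0 for an approach-only curve).
#' @return An `fd_curve`; the simulation ground truth is stored in `meta`
#'   (`E_true`, `delta_c_true`, the artifact magnitudes, and the
#'   procedural `rating`).
#' @export
generate_curve <- function(E_true, delta_c_true = 0,
                           params = contact_params(), n_points = 1000L,
                           artifact = artifact_spec(), seed = 1L,
                           spring_constant = 0.5,
                           z_approach = 6e-6, z_indent = 2e-6,
                           retract_points = 0L) {
  stopifnot(n_points >= 2L, E_true >= 0, inherits(artifact, "artifact_spec"))
  p <- contact_params(E = E_true, nu = params$nu, R = params$R,
                      delta_c = delta_c_true)
  .with_seed(seed, {
    dt <- seq(delta_c_true + z_approach, delta_c_true - z_indent,
              length.out = n_points)
    d <- pmax(delta_c_true - dt, 0)
    force <- force_spherical_approx(d, p)
    f_ref <- max(force)
    if (f_ref == 0) f_ref <- 1e-9  # zero-modulus curve: scale artifacts to 1 nN
    # baseline tilt along the approach travel
    force <- force + artifact$tilt * (dt[1] - dt)
    # force step at the contact point
    force[d > 0] <- force[d > 0] + artifact$contact_offset * f_ref
    # spikes at stratified random indentation positions (one per equal
    # bin, placed in the central 80%), so requested spikes stay distinct
    idt_idx <- which(d > 0)
    if (artifact$spike_count > 0L && length(idt_idx) > 0L) {
      bins <- seq(0, length(idt_idx), length.out = artifact$spike_count + 1L)
      pos <- vapply(seq_len(artifact$spike_count), function(j) {
        lo <- bins[j] + 0.1 * (bins[j + 1L] - bins[j])
        hi <- bins[j + 1L] - 0.1 * (bins[j + 1L] - bins[j])
        max(1L, ceiling(stats::runif(1, lo, hi)))
      }, numeric(1))
      starts <- idt_idx[pmin(pos, length(idt_idx))]
      signs <- sample(c(-1, 1), artifact$spike_count, replace = TRUE)
      for (j in seq_len(artifact$spike_count)) {
        span <- starts[j]:min(starts[j] + artifact$spike_width - 1L, n_points)
        force[span] <- force[span] + signs[j] * artifact$spike_amplitude * f_ref
      }
    }
    if (artifact$noise_sd > 0)
      force <- force + stats::rnorm(n_points, 0, artifact$noise_sd * f_ref)
    height <- dt + force / spring_constant
    segment <- rep("approach", n_points)
    if (retract_points > 0L) {
      dt_r <- seq(delta_c_true - z_indent, delta_c_true + z_approach,
                  length.out = retract_points)
      f_r <- force_spherical_approx(pmax(delta_c_true - dt_r, 0), p)
      if (artifact$noise_sd > 0)
        f_r <- f_r + stats::rnorm(retract_points, 0, artifact$noise_sd * f_ref)
      height <- c(height, dt_r + f_r / spring_constant)
      force <- c(force, f_r)
      segment <- c(segment, rep("retract", retract_points))
    }
    fd_curve(height, force, segment, spring_constant,
             meta = list(E_true = E_true, delta_c_true = delta_c_true,
                         spike_count = artifact$spike_count,
                         spike_amplitude = artifact$spike_amplitude,
                         tilt = artifact$tilt,
                         contact_offset = artifact$contact_offset,
                         noise_sd = artifact$noise_sd,
                         rating = ground_truth_rating(artifact)))
  })
}

#' Procedural ground-truth rating of an artifact specification
#'
#' Stands in for the manual 0 (poor) to 10 (good) rating of real curves:
#' each artifact contributes a penalty proportional to its magnitude,
#' `penalty = a1 * spike_count * spike_amplitude + a2 * |tilt| / tilt0 +
#' a3 * contact_offset + a4 * noise_sd / noise0`, and the rating is
#' `round(10 - penalty)` clipped to \[0, 10\]. The default constants
#' anchor a single moderate artifact (e.g. 10% noise, or a 20% contact
#' step) at the "just usable" rating of 5, and the rating is monotone
#' non-increasing in every artifact magnitude.
#'
#' @param artifact an [artifact_spec].
#' @param config a configuration list from [fd_config] (uses the
#'   `penalty` entries).
#' @return Integer rating in 0..10.
#' @export
ground_truth_rating <- function(artifact, config = fd_config()) {
  stopifnot(inherits(artifact, "artifact_spec"))
  pc <- config$penalty
  penalty <- pc$a_spike * artifact$spike_count * artifact$spike_amplitude +
    pc$a_tilt * abs(artifact$tilt) / pc$tilt0 +
    pc$a_offset * artifact$contact_offset +
    pc$a_noise * artifact$noise_sd / pc$noise0
  as.integer(max(0, min(10, round_half_away(10 - penalty))))
}

#' Round to the nearest integer, halves away from zero
#' @param x numeric vector.
#' @return Rounded values (0.5 -> 1, -0.5 -> -1, unlike [round]).
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# draw one artifact spec from the default heterogeneity model: each
# artifact class enters with probability p_include, with a penalty-scale
# severity drawn log-uniformly, mapped back to a physical magnitude via
# the rating constants; a small noise floor is always present
.draw_artifact <- function(config) {
  pc <- config$penalty
  gen <- config$generator
  sev <- function() {
    if (stats::runif(1) > gen$p_include) return(0)
    exp(stats::runif(1, log(gen$severity_min), log(gen$severity_max)))
  }
  s_spike <- sev(); s_tilt <- sev(); s_offset <- sev(); s_noise <- sev()
  count <- if (s_spike > 0) sample(1:5, 1) else 0L
  artifact_spec(
    spike_count = count,
    spike_amplitude = if (count > 0) s_spike / (pc$a_spike * count) else 0,
    spike_width = sample(5:12, 1),
    tilt = sample(c(-1, 1), 1) * s_tilt / pc$a_tilt * pc$tilt0,
    contact_offset = s_offset / pc$a_offset,
    noise_sd = max(gen$noise_floor, s_noise / pc$a_noise * pc$noise0))
}

#' Generate a heterogeneous synthetic training population
#'
#' Draws `n` curves whose artifact magnitudes follow the default
#' heterogeneity model (Bernoulli inclusion per artifact class,
#' log-uniform severities), emulating the broad quality range of a
#' manually rated training set. For `n >= 500` every rating class 0..10
#' is populated.
#'
#' @param n number of curves.
#' @param seed integer seed; curve `i` uses `seed + i`.
#' @param config configuration list from [fd_config].
#' @param n_points points per curve.
#' @return A list with `curves` (list of `fd_curve`), `ratings` (integer
#'   vector), and `specs` (list of `artifact_spec`).
#' @export
generate_training_set <- function(n, seed = 1L, config = fd_config(),
                                  n_points = 1000L) {
  stopifnot(n >= 1L)
  gen <- config$generator
  specs <- vector("list", n)
  curves <- vector("list", n)
  ratings <- integer(n)
  for (i in seq_len(n)) {
    specs[[i]] <- .with_seed(seed + i, .draw_artifact(config))
    E_i <- .with_seed(seed + i,
                      exp(stats::runif(2, log(gen$E_min), log(gen$E_max)))[2])
    dc_i <- .with_seed(seed + i, stats::runif(3, -5e-7, 5e-7)[3])
    curves[[i]] <- generate_curve(E_i, dc_i, artifact = specs[[i]],
                                  seed = seed + i, n_points = n_points)
    ratings[i] <- curves[[i]]$meta$rating
  }
  list(curves = curves, ratings = ratings, specs = specs)
}

#' Generate a synthetic 2-D FD map
#'
#' One curve per pixel; per-pixel stiffness from `E_layout` and per-pixel
#' artifact load from `severity_layout` (penalty units, split equally
#' between a contact-point offset and added noise), emulating tissue
#' regions of different stiffness and data quality.
#'
#' @param E_layout numeric matrix (rows x cols) of true moduli \[Pa\].
#' @param severity_layout numeric matrix of artifact severities (same
#'   shape; 0 = clean). Default all clean.
#' @param seed integer seed; pixel `(r, c)` derives its own sub-seed.
#' @param pixel_size pixel edge length \[m\].
#' @param n_points points per curve.
#' @param config configuration list from [fd_config].
#' @return An `fd_map` whose pixel curves carry `row`/`col` and the ground
#'   truth in their `meta`.
#' @export
generate_map <- function(E_layout, severity_layout = NULL, seed = 1L,
                         pixel_size = 10e-6, n_points = 1000L,
                         config = fd_config()) {
  stopifnot(is.matrix(E_layout), all(E_layout >= 0))
  if (is.null(severity_layout))
    severity_layout <- matrix(0, nrow(E_layout), ncol(E_layout))
  if (!all(dim(severity_layout) == dim(E_layout)))
    stop("severity_layout must match the shape of E_layout")
  pc <- config$penalty
  gen <- config$generator
  map <- fd_map(dim(E_layout), pixel_size)
  for (row in seq_len(nrow(E_layout)))
    for (col in seq_len(ncol(E_layout))) {
      s <- severity_layout[row, col]
      art <- artifact_spec(
        contact_offset = (s / 2) / pc$a_offset,
        noise_sd = max(gen$noise_floor, (s / 2) / pc$a_noise * pc$noise0))
      px_seed <- seed + (row - 1L) * ncol(E_layout) + col
      cur <- generate_curve(E_layout[row, col], artifact = art,
                            seed = px_seed, n_points = n_points)
      cur$meta$row <- row
      cur$meta$col <- col
      map <- map_set_pixel(map, row, col, cur)
    }
  map
}
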