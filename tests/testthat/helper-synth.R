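# Shared fixtures, generated in code: small synthetic curves keep the
# suite fast; n_points >= 600 only where the size filter matters.

clean_curve <- function(E = 1000, delta_c = 0, n_points = 400L, seed = 1L,
                        noise = 0, ...) {
  generate_curve(E, delta_c, n_points = n_points, seed = seed,
                 artifact = artifact_spec(noise_sd = noise), ...)
}

fitted_clean <- function(E = 1000, n_points = 400L, seed = 1L, noise = 0,
                         ...) {
  curve_sample(clean_curve(E, n_points = n_points, seed = seed,
                           noise = noise, ...))$fit
}

# a minimal hand-built fd_fit for feature tests with fully controlled
# residuals: tip position runs from +z_apr to -z_idt, contact at 0, the
# "model" is zero so residuals == force
manual_fit <- function(force, tip_position, delta_c = 0, R = 18.64e-6,
                       max_force = NULL) {
  idt <- tip_position < delta_c
  structure(list(params = contact_params(E = 1000, R = R, delta_c = delta_c),
                 residuals = force, weights = rep(1, length(force)),
                 delta = tip_position, force = force,
                 model_name = "manual", converged = TRUE,
                 max_force = if (is.null(max_force)) max(force[idt]) else max_force,
                 max_indentation = max(delta_c - tip_position[idt]),
                 sse = NA_real_),
            class = "fd_fit")
}

small_config <- fd_config()
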