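#' Migration model parameters
#'
#' Bundles the cell-intrinsic parameters of the force-based biased
#' persistent-random-walk migration model. Each timestep a cell generates a
#' force of magnitude `alpha` (up to multiplicative jitter) whose radial
#' component points pial-ward with probability `rho` and ventricle-ward
#' otherwise; the angular deviation from the radial axis is uniform on
#' `[0, theta_max]` degrees with a fair lateral sign. A cell that cannot
#' overcome the local tissue resistance stores a fraction `k_spring` of the
#' undissipated force as a spring-like force for the next step.
#'
#' @param rho Probability of pial-ward radial orientation per generated
#'   force, in `[0, 1]`. `rho = 0.5` is an unbiased (pure) random walk.
#' @param alpha Force-scaling coefficient (arbitrary force units, > 0).
#'   Controls generated-force magnitude and hence velocity magnitudes.
#' @param k_spring Retained fraction of undissipated force per stalled
#'   step, in `[0, 1]`. 1 = full force conservation.
#' @param dt Timestep in minutes (> 0). Default matches the 15-min
#'   imaging frame interval.
#' @param step_force_jitter Half-width of the uniform multiplicative noise
#'   on the generated-force magnitude (dimensionless, in `[0, 1)`).
#' @param theta_max Maximal angular deviation of the generated force from
#'   the radial axis, in degrees (`(0, 90]`).
#' @param v_ref Unit-calibration speed constant (um/min) entering the stall
#'   threshold `|F| <= R * v_ref`.
#' @param seed Optional integer RNG seed recorded with the parameters.
#'
#' @return An object of class `model_params`.
#' @seealso [control_params()], [ko_params()], [effective_parameters()]
#' @export
model_params <- function(rho, alpha, k_spring = 1, dt = 15,
                         step_force_jitter = 0.2, theta_max = 60,
                         v_ref = 1, seed = NULL) {
  stopifnot(is.numeric(rho), length(rho) == 1L)
  if (is.na(rho) || rho < 0 || rho > 1)
    stop("'rho' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (!is.numeric(k_spring) || k_spring < 0 || k_spring > 1)
    stop("'k_spring' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("'dt' must be positive", call. = FALSE)
  if (!is.numeric(step_force_jitter) || step_force_jitter < 0 ||
      step_force_jitter >= 1)
    stop("'step_force_jitter' must be in [0, 1)", call. = FALSE)
  if (!is.numeric(theta_max) || theta_max < 0 || theta_max > 90)
    stop("'theta_max' must be in [0, 90] degrees", call. = FALSE)
  if (!is.numeric(v_ref) || v_ref <= 0)
    stop("'v_ref' must be positive", call. = FALSE)
  structure(
    list(rho = as.numeric(rho), alpha = as.numeric(alpha),
         k_spring = as.numeric(k_spring), dt = as.numeric(dt),
         step_force_jitter = as.numeric(step_force_jitter),
         theta_max = as.numeric(theta_max), v_ref = as.numeric(v_ref),
         seed = if (!is.null(seed)) as.integer(seed) else NULL),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  rho = %g, alpha = %g, k_spring = %g\n",
              x$rho, x$alpha, x$k_spring))
  cat(sprintf("  dt = %g min, jitter = %g, theta_max = %g deg, v_ref = %g\n",
              x$dt, x$step_force_jitter, x$theta_max, x$v_ref))
  invisible(x)
}

#' Tissue resistance field
#'
#' A piecewise-constant resistance profile along the radial axis
#' (y = 0 at the ventricular surface, y = `height` at the pia). Resistance
#' is drag per unit velocity: viscosity and cell-shape drag coefficients
#' are merged into a single locally constant parameter per compartment.
#'
#' @param height Tissue height in micrometers (> 0).
#' @param boundaries Strictly increasing radial fractions in (0, 1)
#'   delimiting compartments; length must be `length(magnitudes) - 1`.
#' @param magnitudes Positive resistance per compartment, ordered from the
#'   ventricular side (force per unit velocity, arbitrary units).
#'
#' @return An object of class `resistance_field`.
#' @seealso [control_field()], [ko_field()]
#' @export
resistance_field <- function(height, boundaries = numeric(0), magnitudes) {
  if (!is.numeric(height) || length(height) != 1L || height <= 0)
    stop("'height' must be a single positive number", call. = FALSE)
  boundaries <- as.numeric(boundaries)
  magnitudes <- as.numeric(magnitudes)
  if (length(magnitudes) < 1L || any(magnitudes <= 0))
    stop("'magnitudes' must all be > 0", call. = FALSE)
  if (length(boundaries) != length(magnitudes) - 1L)
    stop("need exactly length(magnitudes) - 1 boundaries", call. = FALSE)
  if (length(boundaries) &&
      (any(boundaries <= 0) || any(boundaries >= 1) ||
       any(diff(boundaries) <= 0)))
    stop("'boundaries' must be strictly increasing within (0, 1)",
         call. = FALSE)
  structure(list(height = height, boundaries = boundaries,
                 magnitudes = magnitudes),
            class = "resistance_field")
}

#' @export
print.resistance_field <- function(x, ...) {
  cat(sprintf("<resistance_field> height = %g um, %d compartment(s)\n",
              x$height, length(x$magnitudes)))
  lo <- c(0, x$boundaries)
  hi <- c(x$boundaries, 1)
  for (i in seq_along(x$magnitudes))
    cat(sprintf("  [%0.2f, %0.2f) R = %g\n", lo[i], hi[i], x$magnitudes[i]))
  invisible(x)
}

#' Local resistance lookup
#'
#' @param field A [resistance_field()].
#' @param y Radial positions in micrometers (vectorised).
#' @return Resistance magnitudes at `y`.
#' @export
resistance_at <- function(field, y) {
  stopifnot(inherits(field, "resistance_field"))
  if (any(!is.finite(y)) || any(y < 0) || any(y > field$height))
    stop("position outside the resistance field (0 <= y <= height)",
         call. = FALSE)
  idx <- findInterval(y / field$height, field$boundaries) + 1L
  field$magnitudes[idx]
}

# ---- shipped presets -------------------------------------------------------
# Calibrated stand-ins: the directionality biases (65% control, 51% KO) come
# from tracked-neuron measurements; force/resistance magnitudes were calibrated once so
# that (i) the control environment yields the fast-lower-half / sharp-drop
# velocity signature, (ii) the uniform KO environment yields a flat profile,
# and (iii) the mixed model's mosaic-like -> KO-like flip lands between 5%
# and 6% mutant abundance. See the methods vignette for the procedure.

#' Control-model parameter preset
#'
#' Directionality bias 65% pial-ward with calibrated force generation and
#' spring retention (see the methods vignette for the calibration).
#'
#' @param ... Overrides passed to [model_params()].
#' @return A `model_params` object.
#' @export
control_params <- function(...) {
  defaults <- list(rho = 0.65, alpha = 2.251, k_spring = 0.65,
                   step_force_jitter = 0.05, theta_max = 60,
                   dt = 15, v_ref = 1)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

#' Knockout-model parameter preset
#'
#' Directionality bias 51% pial-ward (close to a pure random walk) with
#' reduced force generation.
#'
#' @param ... Overrides passed to [model_params()].
#' @return A `model_params` object.
#' @export
ko_params <- function(...) {
  defaults <- list(rho = 0.51, alpha = 0.50, k_spring = 0.65,
                   step_force_jitter = 0.05, theta_max = 60,
                   dt = 15, v_ref = 1)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

#' Control tissue resistance preset
#'
#' Three compartments with a high-resistance band at radial fractions
#' 0.45-0.55 of the tissue height, roughly corresponding to the border
#' between the intermediate zone and the cortical plate.
#'
#' @param height Tissue height in micrometers.
#' @param r_low Resistance of the lower and upper compartments.
#' @param r_band Resistance of the middle band (`> r_low`).
#' @param band Radial fractions delimiting the band.
#' @return A `resistance_field` with 3 compartments.
#' @export
control_field <- function(height = 300, r_low = 1, r_band = 4,
                          band = c(0.40, 0.60)) {
  resistance_field(height, boundaries = band,
                   magnitudes = c(r_low, r_band, r_low))
}

#' Uniform knockout tissue resistance preset
#'
#' A single compartment with low resistance on the order of the control
#' field's outer compartments: the layered structure is virtually absent
#' in the global-knockout tissue.
#'
#' @param height Tissue height in micrometers.
#' @param r Uniform resistance magnitude.
#' @return A `resistance_field` with 1 compartment.
#' @export
ko_field <- function(height = 300, r = 1) {
  resistance_field(height, magnitudes = r)
}

#' Linear parameter coupling with the control-cell fraction
#'
#' Mixed-population (non-cell-autonomous) coupling: a mutant cell's
#' directionality and force generation interpolate linearly between the
#' pure-knockout values at `beta = 0` (no control cells) and the control
#' values at `beta = 1` (vanishing mutant fraction). All other fields are
#' taken from the knockout parameter set.
#'
#' @param beta Fraction of control cells, `N_ctrl / (N_ctrl + N_mut)`,
#'   in `[0, 1]`.
#' @param params_ctrl,params_ko `model_params` for the two anchors.
#' @return A `model_params` object with interpolated `rho` and `alpha`.
#' @export
effective_parameters <- function(beta, params_ctrl, params_ko) {
  stopifnot(inherits(params_ctrl, "model_params"),
            inherits(params_ko, "model_params"))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1)
    stop("'beta' must be a single number in [0, 1]", call. = FALSE)
  out <- params_ko
  out$rho <- params_ko$rho + beta * (params_ctrl$rho - params_ko$rho)
  out$alpha <- params_ko$alpha + beta * (params_ctrl$alpha - params_ko$alpha)
  out
}

#' Mixed-population simulation specification
#'
#' @param n_control,n_mutant Cell counts (sum must be >= 1).
#' @param params_control `model_params` used by control cells.
#' @param params_mutant_pure_ko `model_params` of the pure-knockout anchor
#'   used for mutant cells (directly, or as the `beta = 0` anchor under
#'   coupling).
#' @param field `resistance_field` the population migrates in.
#' @param coupling `"global_linear"` (mutant parameters interpolated via
#'   [effective_parameters()] with `beta = n_control / (n_control +
#'   n_mutant)`) or `"none"` (mutants use the pure-knockout parameters).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_control, n_mutant, params_control,
                            params_mutant_pure_ko, field,
                            coupling = c("global_linear", "none")) {
  coupling <- match.arg(coupling)
  n_control <- as.integer(n_control)
  n_mutant <- as.integer(n_mutant)
  if (is.na(n_control) || is.na(n_mutant) || n_control < 0 || n_mutant < 0 ||
      n_control + n_mutant < 1L)
    stop("need n_control + n_mutant >= 1 with non-negative counts",
         call. = FALSE)
  stopifnot(inherits(params_control, "model_params"),
            inherits(params_mutant_pure_ko, "model_params"),
            inherits(field, "resistance_field"))
  structure(list(n_control = n_control, n_mutant = n_mutant,
                 params_control = params_control,
                 params_mutant_pure_ko = params_mutant_pure_ko,
                 field = field, coupling = coupling),
            class = "population_spec")
}
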