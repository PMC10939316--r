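#' Sample generated forces
#'
#' Draws the per-step generated force of the biased random walk: magnitude
#' `alpha * u` with `u ~ Uniform(1 - jitter, 1 + jitter)`, radial component
#' pial-ward (positive y) with probability `rho`, angular deviation from
#' the radial axis uniform on `[0, theta_max]` degrees, lateral sign fair.
#'
#' @param params A [model_params()] object.
#' @param n Number of force vectors to draw.
#' @return An `n x 2` matrix with columns `fx` (lateral) and `fy` (radial).
#' @export
sample_generated_force <- function(params, n = 1L) {
  stopifnot(inherits(params, "model_params"), n >= 1)
  n <- as.integer(n)
  pial <- ifelse(stats::runif(n) < params$rho, 1, -1)
  theta <- stats::runif(n, 0, params$theta_max) * pi / 180
  lat <- ifelse(stats::runif(n) < 0.5, 1, -1)
  j <- params$step_force_jitter
  mag <- params$alpha * stats::runif(n, 1 - j, 1 + j)
  cbind(fx = mag * sin(theta) * lat,
        fy = mag * cos(theta) * pial)
}

#' Empirical pial-ward force fraction
#'
#' Fraction of generated forces whose radial component points pial-ward;
#' converges to `rho` over many draws.
#'
#' @param params A [model_params()] object.
#' @param n Number of draws.
#' @param seed Optional seed for reproducibility.
#' @return The empirical fraction (a single number).
#' @export
pial_ward_fraction <- function(params, n = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- sample_generated_force(params, n)
  mean(f[, 2] > 0)
}

#' Single-cell state
#'
#' @param position Length-2 numeric `(x, y)` in micrometers; `y = 0` is the
#'   ventricular surface.
#' @param spring_force Length-2 stored force vector (zero after any step in
#'   which the cell moved).
#' @param cell_class `"control"` or `"mutant"`.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(position, spring_force = c(0, 0),
                       cell_class = c("control", "mutant")) {
  cell_class <- match.arg(cell_class)
  stopifnot(is.numeric(position), length(position) == 2L,
            all(is.finite(position)),
            is.numeric(spring_force), length(spring_force) == 2L)
  structure(list(position = as.numeric(position),
                 spring_force = as.numeric(spring_force),
                 cell_class = cell_class),
            class = "cell_state")
}

# Vectorised population stepper. pos and spring are n x 2 matrices; forces
# is the n x 2 matrix of generated forces for this step. Returns updated
# pos/spring. Reflecting boundaries at y = 0 and y = height.
.step_population <- function(pos, spring, forces, params, field) {
  ftot <- forces + spring
  fmag <- sqrt(ftot[, 1]^2 + ftot[, 2]^2)
  R <- resistance_at(field, pos[, 2])
  thr <- R * params$v_ref
  move <- fmag > thr
  if (any(move)) {
    v <- (fmag[move] - thr[move]) / R[move]            # um/min, overdamped
    scale <- v * params$dt / fmag[move]
    pos[move, 1] <- pos[move, 1] + ftot[move, 1] * scale
    pos[move, 2] <- pos[move, 2] + ftot[move, 2] * scale
    spring[move, ] <- 0
  }
  if (any(!move)) {
    spring[!move, 1] <- params$k_spring * ftot[!move, 1]
    spring[!move, 2] <- params$k_spring * ftot[!move, 2]
  }
  # reflect radial coordinate into [0, height] (folded reflection handles
  # displacements larger than the tissue height)
  h <- field$height
  y <- pos[, 2]
  if (any(y < 0 | y > h)) {
    y <- abs(y) %% (2 * h)
    y <- ifelse(y > h, 2 * h - y, y)
    pos[, 2] <- y
  }
  list(pos = pos, spring = spring)
}

#' Advance a single cell one timestep
#'
#' Computes the total force `F = F_gen + F_spring`. If `|F|` does not exceed
#' the local stall threshold `R * v_ref` the cell does not move and stores
#' `k_spring * F` as spring force; otherwise it moves with overdamped
#' velocity `(|F| - R * v_ref) / R` along `F` for one timestep and the
#' spring resets. Position is reflected at the tissue boundaries.
#'
#' @param state A [cell_state()].
#' @param params A [model_params()].
#' @param field A [resistance_field()]; must cover the cell's position.
#' @param force Optional length-2 generated force; drawn from
#'   [sample_generated_force()] when missing.
#' @return The updated `cell_state`.
#' @export
step_cell <- function(state, params, field, force = NULL) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "model_params"),
            inherits(field, "resistance_field"))
  if (is.null(force)) force <- sample_generated_force(params, 1L)
  force <- matrix(as.numeric(force), 1L, 2L)
  st <- .step_population(matrix(state$position, 1L, 2L),
                         matrix(state$spring_force, 1L, 2L),
                         force, params, field)
  cell_state(st$pos[1L, ], st$spring[1L, ], state$cell_class)
}

#' Simulate a mixed migration population
#'
#' Initialises `n_control + n_mutant` cells uniformly in the lowest
#' compartment of the resistance field (cells are born at the ventricular
#' side) and advances them `n_steps` timesteps. Control cells always use
#' `params_control`; under `coupling = "global_linear"` mutant cells use
#' [effective_parameters()] with `beta = n_control / (n_control + n_mutant)`.
#' Identical `(spec, n_steps, seed)` give bit-identical output.
#'
#' @param spec A [population_spec()].
#' @param n_steps Number of timesteps (> 0).
#' @param seed Integer RNG seed.
#' @param lateral_span Lateral extent (um) over which starting x positions
#'   are drawn.
#' @param seed_fraction Radial fraction of the tissue height over which
#'   starting y positions are drawn when the field has a single
#'   compartment; multi-compartment fields seed in their lowest
#'   compartment.
#' @return An object of class `simulation_result` with elements
#'   `trajectories` (data.frame: `cell_id`, `cell_class`, `t_min`, `x_um`,
#'   `y_um`), `spec`, `n_steps`, `seed`.
#' @export
simulate_population <- function(spec, n_steps, seed,
                                lateral_span = 100, seed_fraction = 0.45) {
  stopifnot(inherits(spec, "population_spec"))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps <= 0L)
    stop("'n_steps' must be a positive integer", call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)

  field <- spec$field
  n <- spec$n_control + spec$n_mutant
  cls <- rep(c("control", "mutant"), c(spec$n_control, spec$n_mutant))
  p_ctrl <- spec$params_control
  p_mut <- if (spec$coupling == "global_linear") {
    effective_parameters(spec$n_control / n, spec$params_control,
                         spec$params_mutant_pure_ko)
  } else {
    spec$params_mutant_pure_ko
  }
  if (p_ctrl$dt != p_mut$dt)
    stop("control and mutant parameter sets must share 'dt'", call. = FALSE)
  dt <- p_ctrl$dt

  y_top <- if (length(field$boundaries)) {
    field$boundaries[1] * field$height
  } else {
    seed_fraction * field$height
  }
  pos <- cbind(stats::runif(n, 0, lateral_span), stats::runif(n, 0, y_top))
  spring <- matrix(0, n, 2L)
  is_ctrl <- cls == "control"

  xs <- matrix(NA_real_, n, n_steps + 1L)
  ys <- matrix(NA_real_, n, n_steps + 1L)
  xs[, 1L] <- pos[, 1]
  ys[, 1L] <- pos[, 2]

  for (s in seq_len(n_steps)) {
    forces <- matrix(0, n, 2L)
    if (any(is_ctrl))
      forces[is_ctrl, ] <- sample_generated_force(p_ctrl, sum(is_ctrl))
    if (any(!is_ctrl))
      forces[!is_ctrl, ] <- sample_generated_force(p_mut, sum(!is_ctrl))
    if (any(is_ctrl)) {
      st <- .step_population(pos[is_ctrl, , drop = FALSE],
                             spring[is_ctrl, , drop = FALSE],
                             forces[is_ctrl, , drop = FALSE], p_ctrl, field)
      pos[is_ctrl, ] <- st$pos
      spring[is_ctrl, ] <- st$spring
    }
    if (any(!is_ctrl)) {
      st <- .step_population(pos[!is_ctrl, , drop = FALSE],
                             spring[!is_ctrl, , drop = FALSE],
                             forces[!is_ctrl, , drop = FALSE], p_mut, field)
      pos[!is_ctrl, ] <- st$pos
      spring[!is_ctrl, ] <- st$spring
    }
    xs[, s + 1L] <- pos[, 1]
    ys[, s + 1L] <- pos[, 2]
  }

  t_min <- (0:n_steps) * dt
  traj <- data.frame(
    cell_id = rep(seq_len(n), each = n_steps + 1L),
    cell_class = rep(cls, each = n_steps + 1L),
    t_min = rep(t_min, times = n),
    x_um = as.vector(t(xs)),
    y_um = as.vector(t(ys)),
    stringsAsFactors = FALSE)

  structure(list(trajectories = traj, spec = spec, n_steps = n_steps,
                 seed = seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- x$spec$n_control + x$spec$n_mutant
  cat(sprintf(
    "<simulation_result> %d cells (%d control, %d mutant), %d steps, seed %d\n",
    n, x$spec$n_control, x$spec$n_mutant, x$n_steps, x$seed))
  invisible(x)
}
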