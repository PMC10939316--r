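#' Velocity profile along the radial axis
#'
#' Computes, from trajectories, the mean step speed as a function of
#' normalized radial position (0 = ventricular surface, 1 = pia). Each
#' step's speed (um/min) is assigned to the equal-width bin containing the
#' normalized y of its midpoint; per-bin means are divided by the maximum
#' bin mean so that the best-populated velocity band is 1. Bins never
#' visited are reported as `NA`, not zero. Applies identically to
#' simulated and experimental tracks.
#'
#' @param trajectories A [simulate_population()] result, or a data.frame
#'   with columns `cell_id`, `t_min`, `y_um` and `x_um` (a `cell_class`
#'   column is honoured by `cell_class` filtering).
#' @param n_bins Number of radial bins.
#' @param field_height Tissue height (um); taken from the simulation spec
#'   when `trajectories` is a `simulation_result`.
#' @param cell_class Optional filter (`"control"` or `"mutant"`).
#' @param normalize Divide bin means by the maximum bin mean.
#' @return An object of class `velocity_profile`: list with `bin_centers`,
#'   `values` (normalized mean speed, `NA` for empty bins), `counts`,
#'   `n_bins`, `max_speed` (the normalizing mean speed in um/min).
#' @export
velocity_profile <- function(trajectories, n_bins = 20, field_height = NULL,
                             cell_class = NULL, normalize = TRUE) {
  if (inherits(trajectories, "simulation_result")) {
    if (is.null(field_height)) field_height <- trajectories$spec$field$height
    trajectories <- trajectories$trajectories
  }
  if (is.null(field_height))
    stop("'field_height' is required for plain trajectory tables",
         call. = FALSE)
  stopifnot(is.data.frame(trajectories),
            all(c("cell_id", "t_min", "x_um", "y_um") %in%
                  names(trajectories)))
  if (!is.null(cell_class)) {
    if (!"cell_class" %in% names(trajectories))
      stop("no 'cell_class' column to filter on", call. = FALSE)
    trajectories <- trajectories[trajectories$cell_class %in% cell_class, ,
                                 drop = FALSE]
  }
  if (!nrow(trajectories))
    stop("no trajectories to profile", call. = FALSE)

  o <- order(trajectories$cell_id, trajectories$t_min)
  tr <- trajectories[o, , drop = FALSE]
  same <- tr$cell_id[-1L] == tr$cell_id[-nrow(tr)]
  if (!any(same))
    stop("need at least one trajectory with >= 2 timepoints", call. = FALSE)
  i1 <- which(same)            # step start rows
  i2 <- i1 + 1L
  dtm <- tr$t_min[i2] - tr$t_min[i1]
  if (any(dtm <= 0))
    stop("times must be strictly increasing within a trajectory",
         call. = FALSE)
  speed <- sqrt((tr$x_um[i2] - tr$x_um[i1])^2 +
                (tr$y_um[i2] - tr$y_um[i1])^2) / dtm
  ymid <- (tr$y_um[i1] + tr$y_um[i2]) / 2 / field_height
  if (any(ymid < 0 | ymid > 1))
    stop("positions outside [0, field_height]", call. = FALSE)

  bin <- pmin(pmax(floor(ymid * n_bins) + 1L, 1L), as.integer(n_bins))
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(speed[bin == b]), 0)
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  if (all(counts == 0) || all(means[counts > 0] == 0))
    stop("no movement at all: velocity profile undefined", call. = FALSE)
  max_speed <- max(means, na.rm = TRUE)
  values <- if (normalize) means / max_speed else means
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
                 values = values, counts = counts,
                 n_bins = as.integer(n_bins), max_speed = max_speed),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> %d bins, max mean speed %.4g um/min\n",
              x$n_bins, x$max_speed))
  print(round(stats::setNames(x$values, sprintf("%.3f", x$bin_centers)), 3))
  invisible(x)
}

# L1 distance between two profiles on the same bin grid; unvisited bins
# carry zero velocity signal (absence of moving cells is informative).
.profile_l1 <- function(a, b) {
  va <- ifelse(is.na(a$values), 0, a$values)
  vb <- ifelse(is.na(b$values), 0, b$values)
  sum(abs(va - vb))
}

#' Classify a velocity profile against two references
#'
#' Labels a profile `mosaic_like` or `ko_like` by the nearest reference
#' under L1 distance on the common bin grid; unvisited (`NA`) bins count
#' as zero. Ties go to `ko_like`. Also reports the lower-minus-upper-half
#' contrast of the profile.
#'
#' @param profile,ref_control_like,ref_ko_like `velocity_profile` objects
#'   on identical bins.
#' @return A list with `label`, `contrast`, `d_control`, `d_ko`.
#' @export
classify_profile <- function(profile, ref_control_like, ref_ko_like) {
  stopifnot(inherits(profile, "velocity_profile"),
            inherits(ref_control_like, "velocity_profile"),
            inherits(ref_ko_like, "velocity_profile"))
  if (profile$n_bins != ref_control_like$n_bins ||
      profile$n_bins != ref_ko_like$n_bins)
    stop("profile and references must be on identical bins", call. = FALSE)
  v <- ifelse(is.na(profile$values), 0, profile$values)
  half <- profile$n_bins %/% 2
  contrast <- mean(v[seq_len(half)]) - mean(v[(half + 1L):profile$n_bins])
  d_control <- .profile_l1(profile, ref_control_like)
  d_ko <- .profile_l1(profile, ref_ko_like)
  label <- if (d_control < d_ko) "mosaic_like" else "ko_like"
  list(label = label, contrast = contrast,
       d_control = d_control, d_ko = d_ko)
}

#' Locate the mosaic-like to KO-like transition in mutant abundance
#'
#' Sweeps the mutant abundance of the mixed model: for each fraction the
#' mixed population is simulated `reps` times and the mutant-subpopulation
#' velocity profile is classified against a mosaic-like reference (the
#' full population under control parameters in the given field) and a
#' KO-like reference (an all-mutant population under pure-knockout
#' parameters in a uniform low-resistance field), by majority vote across
#' replicates. Returns the interval between the largest fraction voted
#' `mosaic_like` before the first `ko_like` vote and that first `ko_like`
#' fraction. Monotone classification is not assumed: the first flip is
#' reported and a warning is raised on non-monotone vote sequences.
#'
#' @param spec_template A [population_spec()] carrying the parameter sets
#'   and the (control) field; its cell counts define the population size.
#' @param fractions Sorted ascending mutant abundances in (0, 1].
#' @param reps Replicate simulations per fraction (>= 1).
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @param n_steps Steps per simulation.
#' @param n_bins Profile bins.
#' @param ko_reference_field Field for the KO-like reference; defaults to a
#'   uniform field of the template field's first compartment magnitude.
#' @return An object of class `transition_sweep`: list with `fractions`,
#'   `votes` (fraction of replicates voting `ko_like`), `labels`, `f_low`,
#'   `f_high`, `transition` (logical), `monotone` (logical), plus the two
#'   reference profiles.
#' @export
find_transition <- function(spec_template, fractions, reps = 20, seed = 1,
                            n_steps = 500, n_bins = 20,
                            ko_reference_field = NULL) {
  stopifnot(inherits(spec_template, "population_spec"), reps >= 1)
  fractions <- as.numeric(fractions)
  if (is.unsorted(fractions, strictly = TRUE))
    stop("'fractions' must be sorted strictly ascending", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("'fractions' must lie in (0, 1]", call. = FALSE)
  n_total <- spec_template$n_control + spec_template$n_mutant
  field <- spec_template$field
  if (is.null(ko_reference_field))
    ko_reference_field <- resistance_field(field$height,
                                           magnitudes = field$magnitudes[1])

  # reference profiles from the same seed family, averaged across reps
  avg_profile <- function(make_spec, seeds) {
    vals <- NULL
    counts <- NULL
    for (s in seeds) {
      p <- velocity_profile(simulate_population(make_spec, n_steps, s),
                            n_bins = n_bins, normalize = FALSE)
      v <- ifelse(is.na(p$values), 0, p$values)
      vals <- if (is.null(vals)) v else vals + v
      counts <- if (is.null(counts)) p$counts else counts + p$counts
    }
    m <- vals / length(seeds)
    m[counts == 0] <- NA_real_
    mx <- max(m, na.rm = TRUE)
    structure(list(bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
                   values = m / mx, counts = counts,
                   n_bins = as.integer(n_bins), max_speed = mx),
              class = "velocity_profile")
  }
  seed <- as.integer(seed)
  ref_seeds <- seed + seq_len(min(reps, 8L)) * 1000L
  ref_ctrl <- avg_profile(
    population_spec(n_total, 0, spec_template$params_control,
                    spec_template$params_mutant_pure_ko, field,
                    coupling = spec_template$coupling),
    ref_seeds)
  ref_ko <- avg_profile(
    population_spec(0, n_total, spec_template$params_control,
                    spec_template$params_mutant_pure_ko,
                    ko_reference_field, coupling = "none"),
    ref_seeds + 1L)

  votes <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    n_mut <- max(1L, as.integer(round(f * n_total)))
    sp <- population_spec(n_total - n_mut, n_mut,
                          spec_template$params_control,
                          spec_template$params_mutant_pure_ko, field,
                          coupling = spec_template$coupling)
    ko_votes <- 0L
    for (r in seq_len(reps)) {
      sim <- simulate_population(sp, n_steps, seed + i * 101L + r)
      prof <- velocity_profile(sim, n_bins = n_bins, cell_class = "mutant")
      cl <- classify_profile(prof, ref_ctrl, ref_ko)
      if (cl$label == "ko_like") ko_votes <- ko_votes + 1L
    }
    votes[i] <- ko_votes / reps
  }
  labels <- ifelse(votes > 0.5, "ko_like", "mosaic_like")

  first_ko <- match("ko_like", labels)
  transition <- !is.na(first_ko)
  if (transition) {
    prior_mosaic <- which(labels[seq_len(first_ko - 1L)] == "mosaic_like")
    f_low <- if (length(prior_mosaic)) fractions[max(prior_mosaic)] else NA_real_
    f_high <- fractions[first_ko]
  } else {
    f_low <- f_high <- NA_real_
  }
  monotone <- !is.unsorted(labels == "ko_like")
  if (transition && !monotone)
    warning("non-monotone classification across the sweep; ",
            "reporting the first flip", call. = FALSE)

  structure(list(fractions = fractions, votes = votes, labels = labels,
                 f_low = f_low, f_high = f_high, transition = transition,
                 monotone = monotone, ref_control = ref_ctrl,
                 ref_ko = ref_ko, reps = as.integer(reps), seed = seed),
            class = "transition_sweep")
}

#' @export
print.transition_sweep <- function(x, ...) {
  cat("<transition_sweep>\n")
  print(data.frame(fraction = x$fractions, ko_vote = x$votes,
                   label = x$labels))
  if (x$transition) {
    cat(sprintf("flip interval: (%g, %g]\n", x$f_low, x$f_high))
  } else {
    cat("no transition within the sweep range\n")
  }
  invisible(x)
}
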