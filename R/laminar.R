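#' Tissue boundary polyline
#'
#' An ordered 2D polyline marking a tissue boundary (the ventricular
#' surface or the pia) as drawn on a section image.
#'
#' @param x_um,y_um Vertex coordinates (um), at least 2 vertices.
#' @param role `"ventricular"` or `"pial"`.
#' @return An object of class `boundary_polyline`.
#' @export
boundary_polyline <- function(x_um, y_um, role = c("ventricular", "pial")) {
  role <- match.arg(role)
  stopifnot(length(x_um) == length(y_um))
  if (length(x_um) < 2L)
    stop("a boundary polyline needs at least 2 vertices", call. = FALSE)
  if (any(!is.finite(c(x_um, y_um))))
    stop("polyline vertices must be finite", call. = FALSE)
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 role = role),
            class = "boundary_polyline")
}

#' Shortest distance from a point to a polyline
#'
#' Minimum over segments of the point-to-segment Euclidean distance (the
#' perpendicular foot when it falls inside the segment, else the nearest
#' endpoint). Segment geometry, not vertex-only: boundaries are drawn as
#' segmented lines.
#'
#' @param point Length-2 numeric `(x, y)` in um.
#' @param polyline A [boundary_polyline()].
#' @return Distance in um.
#' @export
shortest_distance_to_polyline <- function(point, polyline) {
  stopifnot(inherits(polyline, "boundary_polyline"),
            is.numeric(point), length(point) == 2L, all(is.finite(point)))
  px <- polyline$x_um; py <- polyline$y_um
  n <- length(px)
  ax <- px[-n]; ay <- py[-n]
  bx <- px[-1L]; by <- py[-1L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  if (all(len2 == 0))
    stop("degenerate polyline: all segments have zero length", call. = FALSE)
  t <- ifelse(len2 > 0,
              pmin(pmax(((point[1L] - ax) * dx + (point[2L] - ay) * dy) /
                          pmax(len2, .Machine$double.xmin), 0), 1),
              0)
  qx <- ax + t * dx
  qy <- ay + t * dy
  min(sqrt((point[1L] - qx)^2 + (point[2L] - qy)^2))
}

#' Relative radial position between two boundaries
#'
#' The normalized depth `d1 / (d1 + d2)` of a point, where `d1` is its
#' shortest distance to the ventricular boundary and `d2` to the pial
#' boundary: 0 on the ventricular surface, 1 at the pia.
#'
#' @param point Length-2 numeric `(x, y)` in um.
#' @param ventricular,pial [boundary_polyline()] objects (roles are
#'   checked).
#' @return Relative distance in `[0, 1]`.
#' @export
relative_distance <- function(point, ventricular, pial) {
  stopifnot(inherits(ventricular, "boundary_polyline"),
            inherits(pial, "boundary_polyline"))
  if (ventricular$role != "ventricular" || pial$role != "pial")
    stop("boundary roles do not match the argument order", call. = FALSE)
  d1 <- shortest_distance_to_polyline(point, ventricular)
  d2 <- shortest_distance_to_polyline(point, pial)
  if (d1 + d2 <= 0)
    stop("point is at zero distance to both boundaries", call. = FALSE)
  d1 / (d1 + d2)
}

#' Bin relative distances into equal-depth zones
#'
#' Equal-width half-open bins `[k/n, (k+1)/n)` with the last bin closed at
#' 1. Zone indices are emitted in both numbering conventions: 1 =
#' ventricular-most and 1 = pial-most (distribution figures are drawn with
#' the marginal zone on top), with the convention recorded in the result.
#'
#' @param rel Relative distances in `[0, 1]`.
#' @param n_zones Number of zones (default 10).
#' @return An object of class `zone_distribution`: list with `counts`
#'   (ventricular-first), `fractions`, `zone_ventricular_first`,
#'   `zone_pial_first` (per-input indices), `n_zones`, `convention`.
#' @export
bin_into_zones <- function(rel, n_zones = 10) {
  rel <- as.numeric(rel)
  if (any(!is.finite(rel)) || any(rel < 0) || any(rel > 1))
    stop("relative distances must lie in [0, 1]", call. = FALSE)
  n_zones <- as.integer(n_zones)
  zv <- pmin(floor(rel * n_zones) + 1L, n_zones)
  counts <- tabulate(zv, nbins = n_zones)
  structure(list(counts = counts,
                 fractions = if (length(rel)) counts / length(rel)
                             else rep(NA_real_, n_zones),
                 zone_ventricular_first = zv,
                 zone_pial_first = n_zones + 1L - zv,
                 n_zones = n_zones,
                 convention = "counts/fractions indexed 1 = ventricular-most; pial-first indices provided per mark"),
            class = "zone_distribution")
}

#' @export
print.zone_distribution <- function(x, ...) {
  cat(sprintf("<zone_distribution> %d zones (%s)\n", x$n_zones,
              x$convention))
  print(stats::setNames(x$counts, paste0("z", seq_len(x$n_zones))))
  invisible(x)
}

#' Arcsine square-root transform of proportions
#'
#' Variance-stabilising transform `asin(sqrt(p))` applied before the
#' zone-distribution ANOVA.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Compare zone distributions between genotypes
#'
#' Applies the arcsine square-root transform to per-replicate zone
#' fractions, fits a two-way ANOVA (`zone * genotype`) and runs Tukey HSD
#' post hoc contrasts; within-zone genotype contrasts are extracted from
#' the interaction term. Per-zone one-way ANOVAs are also emitted since
#' distribution figures annotate zones individually.
#'
#' @param fractions Data.frame with columns `zone` (integer), `genotype`,
#'   `replicate`, `fraction` (per-replicate fractions summing to 1 across
#'   zones). Must be balanced: every genotype needs the same zones and >= 2
#'   replicates.
#' @param alpha_levels Significance levels mapped to `*`, `**`, `***`.
#' @return A list with `anova_table` (two-way ANOVA), `contrasts`
#'   (within-zone Tukey genotype contrasts with adjusted p-values and
#'   significance stars) and `per_zone` (per-zone one-way ANOVA p-values).
#' @export
compare_distributions <- function(fractions,
                                  alpha_levels = c(0.05, 0.01, 0.001)) {
  req <- c("zone", "genotype", "replicate", "fraction")
  if (!all(req %in% names(fractions)))
    stop("'fractions' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- data.frame(zone = factor(fractions$zone),
                   genotype = factor(fractions$genotype),
                   replicate = factor(fractions$replicate),
                   y = arcsine_transform(fractions$fraction))
  tab <- table(df$zone, df$genotype)
  if (any(tab < 2L) || length(unique(as.vector(tab))) != 1L)
    stop("unbalanced design: every zone x genotype cell needs the same ",
         "number (>= 2) of replicates", call. = FALSE)

  fit <- stats::aov(y ~ zone * genotype, data = df)
  anova_table <- as.data.frame(summary(fit)[[1L]])
  rownames(anova_table) <- trimws(rownames(anova_table))
  tuk <- stats::TukeyHSD(fit, "zone:genotype")[["zone:genotype"]]

  # keep contrasts comparing genotypes within the same zone
  parts <- strsplit(rownames(tuk), "-", fixed = TRUE)
  keep <- vapply(parts, function(p) {
    a <- strsplit(p[1L], ":", fixed = TRUE)[[1L]]
    b <- strsplit(p[2L], ":", fixed = TRUE)[[1L]]
    a[1L] == b[1L] && a[2L] != b[2L]
  }, TRUE)
  tw <- tuk[keep, , drop = FALSE]
  zone_of <- vapply(parts[keep], function(p)
    strsplit(p[1L], ":", fixed = TRUE)[[1L]][1L], "")
  stars <- function(p) {
    ifelse(p < alpha_levels[3L], "***",
           ifelse(p < alpha_levels[2L], "**",
                  ifelse(p < alpha_levels[1L], "*", "ns")))
  }
  contrasts <- data.frame(zone = zone_of,
                          contrast = rownames(tw),
                          diff = tw[, "diff"],
                          p_adj = tw[, "p adj"],
                          significance = stars(tw[, "p adj"]),
                          row.names = NULL, stringsAsFactors = FALSE)
  contrasts <- contrasts[order(as.integer(contrasts$zone)), ]

  per_zone <- do.call(rbind, lapply(split(df, df$zone), function(d) {
    p <- if (nlevels(droplevels(d$genotype)) > 1L)
      summary(stats::aov(y ~ genotype, data = d))[[1L]][1L, "Pr(>F)"]
    else NA_real_
    data.frame(zone = d$zone[1L], p_value = p,
               significance = stars(p), stringsAsFactors = FALSE)
  }))
  rownames(per_zone) <- NULL
  list(anova_table = anova_table, contrasts = contrasts, per_zone = per_zone)
}
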