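test_that("point-to-polyline distance covers foot, endpoint and identity", {
  seg <- boundary_polyline(c(-1, 1), c(0, 0), "ventricular")
  expect_equal(shortest_distance_to_polyline(c(0, 1), seg), 1)
  # nearest-endpoint case: foot of the perpendicular falls outside the
  # segment, so the distance is to the endpoint (1, 0)
  short <- boundary_polyline(c(0, 1), c(0, 0), "ventricular")
  expect_equal(shortest_distance_to_polyline(c(3, 4), short), sqrt(20))
  expect_equal(shortest_distance_to_polyline(c(3, 2), short), sqrt(8))
  poly <- boundary_polyline(c(0, 2, 4), c(0, 1, 0), "ventricular")
  expect_equal(shortest_distance_to_polyline(c(2, 1), poly), 0)
  degen <- boundary_polyline(c(1, 1), c(2, 2), "pial")
  expect_error(shortest_distance_to_polyline(c(0, 0), degen), "degenerate")
})

test_that("relative distance is the d1/(d1+d2) depth with exact anchors", {
  vent <- boundary_polyline(c(-100, 100), c(0, 0), "ventricular")
  pia <- boundary_polyline(c(-100, 100), c(8, 8), "pial")
  expect_equal(relative_distance(c(0, 4), vent, pia), 0.5)
  expect_equal(relative_distance(c(5, 0), vent, pia), 0)
  expect_equal(relative_distance(c(0, 2), vent, pia), 0.25)   # d1=2, d2=6
  expect_error(relative_distance(c(0, 4), pia, vent), "roles")
})

test_that("relative distance is invariant under rigid motion and flips with roles", {
  set.seed(5)
  vx <- seq(0, 100, length.out = 11)
  vent <- boundary_polyline(vx, 5 * sin(vx / 20), "ventricular")
  pia <- boundary_polyline(vx, 120 + 6 * cos(vx / 15), "pial")
  pts <- cbind(runif(20, 10, 90), runif(20, 10, 110))
  rot <- function(x, y, th, dx, dy)
    cbind(cos(th) * x - sin(th) * y + dx, sin(th) * x + cos(th) * y + dy)
  th <- 0.6; dx <- 31; dy <- -17
  rv <- rot(vent$x_um, vent$y_um, th, dx, dy)
  rp <- rot(pia$x_um, pia$y_um, th, dx, dy)
  vent_r <- boundary_polyline(rv[, 1], rv[, 2], "ventricular")
  pia_r <- boundary_polyline(rp[, 1], rp[, 2], "pial")
  for (i in seq_len(nrow(pts))) {
    r0 <- relative_distance(pts[i, ], vent, pia)
    expect_true(r0 >= 0 && r0 <= 1)
    pr <- rot(pts[i, 1], pts[i, 2], th, dx, dy)
    expect_equal(relative_distance(c(pr), vent_r, pia_r), r0,
                 tolerance = 1e-10)
    # flipping the boundary roles maps r -> 1 - r
    vent_f <- boundary_polyline(pia$x_um, pia$y_um, "ventricular")
    pia_f <- boundary_polyline(vent$x_um, vent$y_um, "pial")
    expect_equal(relative_distance(pts[i, ], vent_f, pia_f), 1 - r0,
                 tolerance = 1e-10)
  }
})

test_that("zone binning uses half-open bins, conserves counts, both conventions", {
  zd <- bin_into_zones(c(0.05, 1.0, 0.999, 0.1, 0.1999999), n_zones = 10)
  expect_equal(zd$zone_ventricular_first, c(1L, 10L, 10L, 2L, 2L))
  expect_equal(zd$zone_pial_first, 11L - zd$zone_ventricular_first)
  expect_equal(sum(zd$counts), 5L)
  expect_error(bin_into_zones(c(-0.1)), "\\[0, 1\\]")

  # uniform sampling oracle: chi-squared not rejected at alpha = 0.01
  set.seed(9)
  u <- runif(1000)
  cz <- bin_into_zones(u, 10)$counts
  expect_equal(sum(cz), 1000L)
  expect_gt(stats::chisq.test(cz)$p.value, 0.01)
})

test_that("arcsine transform has the contract endpoints and monotonicity", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
})

test_that("identical genotype tables yield no significant contrasts", {
  set.seed(3)
  rows <- list()
  for (g in c("a", "b")) for (r in 1:4) {
    counts <- stats::rmultinom(1, 300, rep(0.2, 5))[, 1]
    rows[[length(rows) + 1L]] <-
      data.frame(zone = 1:5, genotype = g, replicate = paste0(g, r),
                 fraction = counts / 300)
  }
  res <- compare_distributions(do.call(rbind, rows))
  expect_true(all(res$contrasts$p_adj > 0.05))
  expect_true(all(res$contrasts$significance == "ns"))
})

test_that("a shifted zone is detected and the ANOVA matches a by-hand oracle", {
  tab <- shifted_fraction_table()
  res <- compare_distributions(tab)
  z2 <- res$contrasts[res$contrasts$zone == "2", ]
  expect_true(all(z2$p_adj < 0.05))
  expect_true(all(res$per_zone$p_value[res$per_zone$zone == "2"] < 0.05))

  # independent oracle: two-way ANOVA sums of squares computed directly
  y <- arcsine_transform(tab$fraction)
  zf <- factor(tab$zone); gf <- factor(tab$genotype)
  gm <- mean(y)
  ss_zone <- sum(tapply(y, zf, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, list(zf, gf), mean)
  zone_means <- rowMeans(cell_means)
  geno_means <- colMeans(cell_means)
  n_per_cell <- sum(zf == levels(zf)[1] & gf == levels(gf)[1])
  ss_geno <- sum(length(levels(zf)) * n_per_cell *
                   (geno_means - gm)^2)
  inter <- sweep(sweep(cell_means, 1, zone_means), 2, geno_means) + gm
  ss_int <- n_per_cell * sum(inter^2)
  at <- res$anova_table
  expect_equal(at["zone", "Sum Sq"], ss_zone, tolerance = 1e-8)
  expect_equal(at["genotype", "Sum Sq"], ss_geno, tolerance = 1e-8)
  expect_equal(at["zone:genotype", "Sum Sq"], ss_int, tolerance = 1e-8)
})

test_that("unbalanced designs are rejected", {
  tab <- shifted_fraction_table()
  expect_error(compare_distributions(tab[-1, ]), "unbalanced")
})
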