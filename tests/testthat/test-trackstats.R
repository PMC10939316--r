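test_that("distances, speed and directionality match hand computations", {
  tr <- l_track()                       # (0,0) -> (3,0) -> (3,4)
  d <- track_distances(tr)
  expect_equal(d$d_tot, 7)
  expect_equal(d$d_net, 5)
  expect_equal(d$t_net, 70)
  expect_equal(mean_straight_line_speed(tr), 5 / 70)
  expect_equal(directionality_index(tr), 5 / 7)

  loop <- track("loop", c(0, 30, 60), c(0, 1, 0), c(0, 1, 0))
  dl <- track_distances(loop)
  expect_equal(dl$d_net, 0)
  expect_equal(dl$d_tot, 2 * sqrt(2))
  expect_equal(directionality_index(loop), 0)

  seg <- track("seg", c(0, 5), c(0, 0), c(0, 10))
  ds <- track_distances(seg)
  expect_equal(ds$d_tot, 10)
  expect_equal(ds$d_net, 10)
  expect_equal(mean_straight_line_speed(seg), 2)
  expect_equal(directionality_index(seg), 1)

  still <- track("still", c(0, 15), c(1, 1), c(2, 2))
  expect_error(directionality_index(still), "stationary")
  expect_error(track_distances(track("one", 0, 0, 0)), "2 samples")
})

test_that("statistics match a naive reference on random tracks to 1e-9", {
  for (i in 1:100) {
    tr <- random_track(paste0("r", i), seed = 1000 + i)
    ref <- naive_track_stats(tr)
    d <- track_distances(tr)
    expect_equal(d$d_tot, ref$d_tot, tolerance = 1e-9)
    expect_equal(d$d_net, ref$d_net, tolerance = 1e-9)
    expect_equal(mean_straight_line_speed(tr), ref$speed, tolerance = 1e-9)
    expect_equal(directionality_index(tr), ref$directionality,
                 tolerance = 1e-9)
    # invariants
    expect_lte(d$d_net, d$d_tot + 1e-12)
    expect_true(ref$directionality >= 0 && ref$directionality <= 1)
  }
})

test_that("statistics are invariant under rigid translation and time shift", {
  tr <- random_track("t", seed = 7)
  shifted <- track(tr$track_id, tr$t_min + 120, tr$x_um + 50, tr$y_um - 30,
                   tr$channel)
  expect_equal(track_distances(tr), track_distances(shifted))
  expect_equal(mean_straight_line_speed(tr),
               mean_straight_line_speed(shifted))
})

test_that("zone grouping follows the any-frame rule with a strict boundary", {
  geom <- zone_geometry(100)
  below <- track("b", c(0, 15, 30), c(0, 0, 0), c(10, 50, 99))
  once_above <- track("a", c(0, 15, 30), c(0, 0, 0), c(10, 101, 50))
  on_line <- track("m", c(0, 15), c(0, 0), c(100, 100))
  g <- assign_zone_groups(list(below, once_above, on_line), geom)
  expect_equal(vapply(g$upper, `[[`, "", "track_id"), "a")
  expect_setequal(vapply(g$lower, `[[`, "", "track_id"), c("b", "m"))
  # exhaustive and exclusive
  expect_equal(length(g$upper) + length(g$lower), 3L)
})

test_that("crossing splits conserve path length and count crossings", {
  mono <- track("m", (0:4) * 15, rep(0, 5), c(10, 40, 90, 120, 150))
  s1 <- split_crossing_tracks(mono, 100)
  expect_equal(length(s1$subtracks), 2L)
  expect_true(s1$crossing)

  never <- track("n", (0:3) * 15, rep(0, 4), c(10, 20, 30, 40))
  s2 <- split_crossing_tracks(never, 100)
  expect_equal(length(s2$subtracks), 1L)
  expect_false(s2$crossing)
  expect_identical(s2$subtracks[[1L]], never)

  zig <- track("z", (0:5) * 15, rep(0, 6), c(50, 120, 130, 80, 60, 70))
  s3 <- split_crossing_tracks(zig, 100)
  expect_equal(length(s3$subtracks), 3L)
  # sub-track path lengths sum to the parent's
  expect_equal(sum(vapply(s3$subtracks,
                          function(t) track_distances(t)$d_tot, 0)),
               track_distances(zig)$d_tot)
})

test_that("top-n ranking is by net distance with stable id tie-break", {
  t1 <- track("a2", c(0, 15), c(0, 0), c(0, 5))
  t2 <- track("a1", c(0, 15), c(0, 0), c(0, 5))
  t3 <- track("b", c(0, 15), c(0, 0), c(0, 20))
  t4 <- track("c", c(0, 15), c(0, 0), c(0, 10))
  top <- top_n_by_net_distance(list(t1, t2, t3, t4), n = 15)
  expect_equal(vapply(top, `[[`, "", "track_id"), c("b", "c", "a1", "a2"))
  top2 <- top_n_by_net_distance(list(t1, t2, t3, t4), n = 2)
  expect_equal(length(top2), 2L)
  expect_equal(top2[[1L]]$track_id, "b")
})

test_that("start/end occupancy counts zones and excludes yellow tracks", {
  geom <- zone_geometry(100)
  mk <- function(id, y0, ch = "green")
    track(id, c(0, 360, 725), c(0, 0, 0), c(y0, y0, y0), channel = ch)
  tracks <- c(lapply(1:5, function(i) mk(paste0("lo", i), 50)),
              lapply(1:5, function(i) mk(paste0("hi", i), 150)))
  occ <- start_end_distribution(tracks, geom)
  expect_equal(occ$fraction[occ$timepoint == 0 & occ$zone == "lower"], 0.5)
  expect_equal(occ$fraction[occ$timepoint == 725 & occ$zone == "upper"], 0.5)

  yellow_only <- lapply(1:3, function(i) mk(paste0("y", i), 50, "yellow"))
  expect_warning(
    expect_warning(occ2 <- start_end_distribution(yellow_only, geom),
                   "yellow"),
    "no red/green")
  expect_equal(nrow(occ2), 0L)
})

test_that("synthetic control population starts near 50/50 occupancy", {
  trs <- make_tracks(200, seed = 21, occupancy_upper = 0.5, y_mid = 150)
  occ <- start_end_distribution(trs, zone_geometry(150))
  lower0 <- occ$fraction[occ$timepoint == 0 & occ$zone == "lower"]
  expect_true(abs(lower0 - 0.5) <= 3 * sqrt(0.25 / 200))
})
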