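test_that("static movies yield (near) zero flow", {
  mv <- make_movie(n_frames = 3, size = 64, drift = "none", n_cells = 0,
                   noise_sd = 0, seed = 2)
  flows <- estimate_pairwise_flow(mv$movie)
  expect_length(flows, 2L)
  for (fl in flows)
    expect_lt(max(abs(c(fl$dy, fl$dx))), 0.1)
  expect_error(estimate_pairwise_flow(
    movie(array(0, c(1, 8, 8)))), "2 frames")
})

test_that("a known translation is recovered within half a pixel", {
  mv <- make_movie(n_frames = 2, size = 96, drift = "constant",
                   drift_px = c(3, 0), n_cells = 0, noise_sd = 0, seed = 6)
  fl <- estimate_pairwise_flow(mv$movie)[[1L]]
  interior <- 20:77
  expect_equal(median(fl$dy[interior, interior]), 3, tolerance = 0.5)
  expect_equal(median(fl$dx[interior, interior]), 0, tolerance = 0.5)
})

test_that("channels are averaged before flow estimation", {
  mv <- make_movie(n_frames = 3, size = 48, drift = "constant",
                   drift_px = c(1, 1), n_cells = 0, noise_sd = 0, seed = 3)
  arr <- mv$movie$channels[[1L]]
  two_ch <- movie(list(2 * arr, 0 * arr))        # average equals arr
  f1 <- estimate_pairwise_flow(mv$movie)
  f2 <- estimate_pairwise_flow(two_ch)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("flow smoothing preserves constants and suppresses cell-scale blobs", {
  H <- 80
  const <- list(list(dy = matrix(1.3, H, H), dx = matrix(-0.4, H, H)))
  sm <- smooth_flow(const, sigma_t = 1, sigma_xy = 25.6)
  expect_equal(sm[[1L]]$dy, const[[1L]]$dy, tolerance = 1e-9)
  expect_equal(sm[[1L]]$dx, const[[1L]]$dx, tolerance = 1e-9)

  blob <- matrix(0, H, H)
  yy <- rep(1:H, H); xx <- rep(1:H, each = H)
  blob[] <- exp(-((yy - 40)^2 + (xx - 40)^2) / (2 * 3^2))  # ~10 px blob
  sm2 <- smooth_flow(list(list(dy = blob, dx = blob * 0)), sigma_xy = 25.6)
  expect_gt(max(blob) / max(sm2[[1L]]$dy), 10)

  # degenerate kernel is the identity
  sm3 <- smooth_flow(list(list(dy = blob, dx = blob)), sigma_t = 0,
                     sigma_xy = 0)
  expect_identical(sm3[[1L]]$dy, blob)
})

test_that("temporal integration composes displacements", {
  H <- 32
  zero <- list(dy = matrix(0, H, H), dx = matrix(0, H, H))
  cum0 <- integrate_flow(list(zero, zero))
  expect_equal(cum0[[3L]]$dy, zero$dy)

  d <- list(dy = matrix(1.5, H, H), dx = matrix(-0.5, H, H))
  cum <- integrate_flow(list(d, d, d))
  for (k in 1:4) {
    inner <- 8:24   # away from the clamped border
    expect_equal(mean(cum[[k]]$dy[inner, inner]), (k - 1) * 1.5,
                 tolerance = 1e-6)
    expect_equal(mean(cum[[k]]$dx[inner, inner]), -(k - 1) * 0.5,
                 tolerance = 1e-6)
  }
  # single pair: cumulative equals that pair
  cum1 <- integrate_flow(list(d))
  expect_equal(cum1[[2L]]$dy, d$dy, tolerance = 1e-9)
})

test_that("unwarp honours identity, reference frame and shape checks", {
  mv <- make_movie(n_frames = 3, size = 32, drift = "constant",
                   drift_px = c(2, 1), n_cells = 2, noise_sd = 0, seed = 8)
  zero <- list(dy = matrix(0, 32, 32), dx = matrix(0, 32, 32))
  res <- unwarp(mv$movie, list(zero, zero, zero))
  expect_equal(res$movie$channels[[1L]], mv$movie$channels[[1L]],
               tolerance = 1e-9)
  expect_true(all(res$valid))

  res2 <- unwarp(mv$movie, mv$truth)
  expect_identical(res2$movie$channels[[1L]][1, , ],
                   mv$movie$channels[[1L]][1, , ])
  expect_error(unwarp(mv$movie, mv$truth[1:2]), "per frame")
  bad <- lapply(1:3, function(i) list(dy = matrix(0, 8, 8),
                                      dx = matrix(0, 8, 8)))
  expect_error(unwarp(mv$movie, bad), "shape")
})

test_that("the pipeline recovers a smooth drift at desk scale", {
  # constant drift: the short sequence leaves the temporal smoother's
  # passband untouched (sinusoids need periods well above sigma_t, which
  # the full-scale acceptance test covers)
  mv <- make_movie(n_frames = 6, size = 96, drift = "constant",
                   drift_px = c(1.2, 0.5), n_cells = 2, cell_speed_px = 1,
                   noise_sd = 0.005, seed = 10)
  res <- undrift_movie(mv$movie)
  idx <- 11:86
  rmse <- sqrt(mean(unlist(lapply(2:6, function(t)
    (res$cumulative[[t]]$dy[idx, idx] - mv$truth[[t]]$dy[idx, idx])^2 +
    (res$cumulative[[t]]$dx[idx, idx] - mv$truth[[t]]$dx[idx, idx])^2))))
  expect_lt(rmse, 1)
  # corrected frames resemble the reference frame better than uncorrected
  orig <- mv$movie$channels[[1L]]
  corr <- res$movie$channels[[1L]]
  mad0 <- mean(abs(orig[6, idx, idx] - orig[1, idx, idx]))
  mad1 <- mean(abs(corr[6, idx, idx] - orig[1, idx, idx]))
  expect_lt(mad1, mad0)
})

test_that("independently moving spots survive drift correction", {
  mv <- make_movie(n_frames = 6, size = 96, drift = "constant",
                   drift_px = c(1.5, 0.5), n_cells = 2, cell_speed_px = 1.5,
                   noise_sd = 0, cell_intensity = 1.5, seed = 14)
  res <- undrift_movie(mv$movie)
  corr <- res$movie$channels[[1L]]
  # after correction each spot should sit at its drift-free scene
  # position to within ~1 px
  for (t in c(3L, 6L)) {
    fr <- corr[t, , ]
    for (cl in 1:2) {
      truth <- mv$cells[mv$cells$cell == cl & mv$cells$frame == t, ]
      ry <- max(1, round(truth$y) - 4):min(96, round(truth$y) + 4)
      rx <- max(1, round(truth$x) - 4):min(96, round(truth$x) + 4)
      peak <- which(fr[ry, rx] == max(fr[ry, rx]), arr.ind = TRUE)[1L, ]
      expect_lte(abs(ry[peak[1L]] - truth$y), 1.6)
      expect_lte(abs(rx[peak[2L]] - truth$x), 1.6)
    }
  }
})

test_that("pre-shifting a movie shifts the recovered flow identically", {
  # translation equivariance on an integer pre-shift, modulo borders
  mv <- make_movie(n_frames = 2, size = 64, drift = "constant",
                   drift_px = c(1.5, 0.5), n_cells = 0, noise_sd = 0,
                   seed = 12)
  arr <- mv$movie$channels[[1L]]
  sh <- 5L
  shifted <- array(0, dim(arr))
  shifted[, , 1:(64 - sh)] <- arr[, , (sh + 1):64]
  f0 <- estimate_pairwise_flow(mv$movie)[[1L]]
  f1 <- estimate_pairwise_flow(movie(shifted))[[1L]]
  inner <- 16:44
  expect_equal(f0$dy[inner, inner + sh], f1$dy[inner, inner],
               tolerance = 0.2)
})
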