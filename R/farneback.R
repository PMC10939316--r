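# Dense optical flow via quadratic polynomial expansion (Farneback-style).
#
# Each neighbourhood of an image is approximated by a quadratic polynomial
#   f(x) ~ x' A x + b' x + c
# fitted by Gaussian-weighted least squares over a (2r+1)^2 window. For a
# pure translation d between two images the expansions satisfy
#   A d = -0.5 * (b2 - b1)
# which is solved per pixel after averaging A and the right-hand side over
# an averaging window, iterated and embedded in a coarse-to-fine pyramid.

# Polynomial expansion: returns coefficient matrices (c, bx, by, axx, ayy,
# axy) for every pixel. poly_n is the window size (odd), sigma the Gaussian
# applicability.
.poly_expansion <- function(img, poly_n = 5, sigma = 0.4) {
  r <- (poly_n - 1L) / 2L
  x <- -r:r
  a <- exp(-x^2 / (2 * sigma^2))
  # separable basis correlations: weighted moments of the image
  m00 <- .sep_filter(img, a, a)
  m10 <- .sep_filter(img, a * x, a)      # y moment (rows)
  m01 <- .sep_filter(img, a, a * x)      # x moment (cols)
  m20 <- .sep_filter(img, a * x^2, a)
  m02 <- .sep_filter(img, a, a * x^2)
  m11 <- .sep_filter(img, a * x, a * x)
  # normal-equation matrix G for basis {1, y, x, y^2, x^2, xy} is constant
  s0 <- sum(a); s2 <- sum(a * x^2); s4 <- sum(a * x^4)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[1, 4] <- G[4, 1] <- s2 * s0
  G[1, 5] <- G[5, 1] <- s0 * s2
  G[2, 2] <- s2 * s0
  G[3, 3] <- s0 * s2
  G[4, 4] <- s4 * s0
  G[5, 5] <- s0 * s4
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Ginv <- solve(G)
  # coefficients = Ginv %*% moments, basis order {1, y, x, y^2, x^2, xy}
  co <- function(row) {
    Ginv[row, 1] * m00 + Ginv[row, 2] * m10 + Ginv[row, 3] * m01 +
      Ginv[row, 4] * m20 + Ginv[row, 5] * m02 + Ginv[row, 6] * m11
  }
  list(c = co(1), by = co(2), bx = co(3), ayy = co(4), axx = co(5),
       axy = co(6))
}

# One pyramid level of displacement estimation. d0y/d0x is the initial
# flow (same size as img1). winsize is the averaging window (clipped to
# the image), iterations the number of refinement passes.
.flow_level <- function(img1, img2, d0y, d0x, poly_n, poly_sigma,
                        winsize, iterations) {
  H <- nrow(img1); W <- ncol(img1)
  p1 <- .poly_expansion(img1, poly_n, poly_sigma)
  p2 <- .poly_expansion(img2, poly_n, poly_sigma)
  win <- min(winsize, 2L * min(H, W) - 1L)
  wsig <- win / 4          # Gaussian averaging over the window
  gy <- rep(seq_len(H), W)
  gx <- rep(seq_len(W), each = H)
  dy <- d0y; dx <- d0x
  for (it in seq_len(iterations)) {
    yy <- gy + as.vector(dy)
    xx <- gx + as.vector(dx)
    a_yy <- matrix(.sample_bilinear(p2$ayy, yy, xx), H, W)
    a_xx <- matrix(.sample_bilinear(p2$axx, yy, xx), H, W)
    a_xy <- matrix(.sample_bilinear(p2$axy, yy, xx), H, W)
    b_y2 <- matrix(.sample_bilinear(p2$by, yy, xx), H, W)
    b_x2 <- matrix(.sample_bilinear(p2$bx, yy, xx), H, W)
    # averaged quadratic-form matrix: A = (A1 + A2) / 2 with
    # A(img) = [[ayy, axy/2], [axy/2, axx]]
    A11 <- (p1$ayy + a_yy) / 2
    A22 <- (p1$axx + a_xx) / 2
    A12 <- (p1$axy + a_xy) / 4
    # db = -(b2(x+d) - b1)/2 + A d0  (solve for total displacement)
    hy <- -(b_y2 - p1$by) / 2 + A11 * dy + A12 * dx
    hx <- -(b_x2 - p1$bx) / 2 + A12 * dy + A22 * dx
    # accumulate normal equations over the averaging window
    k <- .gauss_kernel(wsig)
    G11 <- .sep_filter(A11 * A11 + A12 * A12, k)
    G12 <- .sep_filter(A11 * A12 + A12 * A22, k)
    G22 <- .sep_filter(A12 * A12 + A22 * A22, k)
    h1 <- .sep_filter(A11 * hy + A12 * hx, k)
    h2 <- .sep_filter(A12 * hy + A22 * hx, k)
    det <- G11 * G22 - G12 * G12
    det[abs(det) < 1e-12] <- 1e-12
    dy <- (G22 * h1 - G12 * h2) / det
    dx <- (G11 * h2 - G12 * h1) / det
  }
  list(dy = dy, dx = dx)
}

# Full coarse-to-fine Farneback-style flow between two frames.
# Returns displacement fields (dy, dx) in pixels such that
# img2(x + d(x)) ~ img1(x).
.farneback_flow <- function(img1, img2, pyr_levels = 3, winsize = 512,
                            poly_n = 5, poly_sigma = 0.4, iterations = 3) {
  stopifnot(all(dim(img1) == dim(img2)))
  pyr1 <- list(img1); pyr2 <- list(img2)
  for (l in seq_len(pyr_levels - 1L)) {
    if (min(dim(pyr1[[l]])) < 16L) break
    pyr1[[l + 1L]] <- .pyr_down(pyr1[[l]])
    pyr2[[l + 1L]] <- .pyr_down(pyr2[[l]])
  }
  nl <- length(pyr1)
  dy <- matrix(0, nrow(pyr1[[nl]]), ncol(pyr1[[nl]]))
  dx <- dy
  for (l in rev(seq_len(nl))) {
    i1 <- pyr1[[l]]; i2 <- pyr2[[l]]
    if (any(dim(dy) != dim(i1))) {
      dy <- .resize(dy, nrow(i1), ncol(i1)) * 2
      dx <- .resize(dx, nrow(i1), ncol(i1)) * 2
    }
    # window scales with the pyramid level so the full-resolution value
    # matches the requested size
    lvl_win <- max(9L, as.integer(winsize / 2^(l - 1L)))
    fl <- .flow_level(i1, i2, dy, dx, poly_n, poly_sigma, lvl_win,
                      iterations)
    dy <- fl$dy; dx <- fl$dx
  }
  list(dy = dy, dx = dx)
}
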