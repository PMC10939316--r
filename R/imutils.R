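# Low-level image helpers shared by the optical-flow and unwarp code.
# Images are numeric matrices indexed [row = y, col = x].

# 1D Gaussian kernel, truncated at 4 sigma (matching common image-filter
# practice); sigma = 0 gives the identity kernel.
.gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# reflect (mirror without repeating the edge sample, "symmetric") index
# vector for padding length n by r on both sides
.reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  if (n == 1L) return(rep(1L, n + 2L * r))
  idx <- c(rev(seq_len(min(r, n - 1L)) + 1L), seq_len(n),
           n - seq_len(min(r, n - 1L)))
  # for r > n - 1 extend periodically on the reflected sequence
  while (length(idx) < n + 2L * r) {
    idx <- c(idx[1L], idx, idx[length(idx)])
  }
  idx
}

# separable correlation of matrix m with 1D kernels along rows (y) and
# columns (x), reflect padding
.sep_filter <- function(m, ky, kx = ky) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  if (ry > 0) {
    mp <- m[.reflect_idx(nrow(m), ry), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(ky))
      out <- out + ky[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    m <- out
  }
  if (rx > 0) {
    mp <- m[, .reflect_idx(ncol(m), rx), drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(kx))
      out <- out + kx[i] * mp[, i:(i + ncol(m) - 1L), drop = FALSE]
    m <- out
  }
  m
}

# Gaussian blur with reflect borders (constants are preserved)
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .sep_filter(m, .gauss_kernel(sigma))
}

# Bilinear sampling of matrix img at fractional coordinates (yy, xx),
# 1-based; coordinates outside are clamped to the border.
.sample_bilinear <- function(img, yy, xx) {
  H <- nrow(img); W <- ncol(img)
  yy <- pmin(pmax(yy, 1), H)
  xx <- pmin(pmax(xx, 1), W)
  y0 <- pmin(floor(yy), H - 1L); x0 <- pmin(floor(xx), W - 1L)
  fy <- yy - y0; fx <- xx - x0
  i00 <- (x0 - 1) * H + y0
  v00 <- img[i00];     v10 <- img[i00 + 1]
  v01 <- img[i00 + H]; v11 <- img[i00 + H + 1]
  (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
    (1 - fy) * fx * v01 + fy * fx * v11
}

# Catmull-Rom cubic interpolation weights for fractional offset t in [0,1]
.cubic_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
        1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
        0.5 * t3 - 0.5 * t2)
}

# Bicubic (Catmull-Rom) sampling with border clamping. Separable: sample
# 4 rows cubically in x, then combine in y.
.sample_bicubic <- function(img, yy, xx) {
  H <- nrow(img); W <- ncol(img)
  yy <- pmin(pmax(yy, 1), H)
  xx <- pmin(pmax(xx, 1), W)
  y0 <- floor(yy); x0 <- floor(xx)
  y0 <- pmin(y0, H - 1L); x0 <- pmin(x0, W - 1L)
  fy <- yy - y0; fx <- xx - x0
  wy <- .cubic_w(fy); wx <- .cubic_w(fx)
  out <- numeric(length(yy))
  for (iy in -1:2) {
    ry <- pmin(pmax(y0 + iy, 1), H)
    rowv <- numeric(length(yy))
    for (ix in -1:2) {
      cx <- pmin(pmax(x0 + ix, 1), W)
      rowv <- rowv + wx[, ix + 2L] * img[(cx - 1) * H + ry]
    }
    out <- out + wy[, iy + 2L] * rowv
  }
  out
}

# Downscale by 2 with Gaussian pre-smoothing (pyramid construction)
.pyr_down <- function(m) {
  sm <- .gauss_blur(m, 1)
  sm[seq(1L, nrow(m), by = 2L), seq(1L, ncol(m), by = 2L), drop = FALSE]
}

# Resize matrix to (H, W) by bilinear sampling (used to upsample flow)
.resize <- function(m, H, W) {
  yy <- (seq_len(H) - 0.5) * nrow(m) / H + 0.5
  xx <- (seq_len(W) - 0.5) * ncol(m) / W + 0.5
  g <- expand.grid(y = yy, x = xx)
  matrix(.sample_bilinear(m, g$y, g$x), H, W)
}
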