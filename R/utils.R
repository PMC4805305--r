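# Internal numeric helpers shared by the image modules.

# Reflect-pad a matrix by `k` pixels on every side (indices clamped when k
# exceeds the image extent).
pad_reflect <- function(m, k) {
  if (k == 0) return(m)
  take <- function(n) {
    pre <- rev(pmin(seq_len(k) + 1L, n))
    post <- pmax(n - seq_len(k), 1L)
    c(pre, seq_len(n), post)
  }
  m[take(nrow(m)), take(ncol(m)), drop = FALSE]
}

# Separable Gaussian convolution with reflective boundary handling.
gaussian_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  p <- pad_reflect(m, r)
  # convolve along rows (y axis)
  out <- matrix(0, nrow(p), ncol(p))
  for (i in seq_along(kern)) {
    sh <- i - r - 1L
    idx <- seq_len(nrow(p)) + sh
    idx <- pmin(pmax(idx, 1L), nrow(p))
    out <- out + kern[i] * p[idx, , drop = FALSE]
  }
  p <- out
  out <- matrix(0, nrow(p), ncol(p))
  for (i in seq_along(kern)) {
    sh <- i - r - 1L
    idx <- seq_len(ncol(p)) + sh
    idx <- pmin(pmax(idx, 1L), ncol(p))
    out <- out + kern[i] * p[, idx, drop = FALSE]
  }
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

# Bilinear sample of matrix `m` at fractional positions (row = yq, col = xq),
# 1-based coordinates; positions outside the domain return `fill`.
bilinear_sample <- function(m, yq, xq, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  y0 <- floor(yq); x0 <- floor(xq)
  fy <- yq - y0; fx <- xq - x0
  inside <- yq >= 1 & xq >= 1 & yq <= nr & xq <= nc
  y0c <- pmin(pmax(y0, 1L), nr); x0c <- pmin(pmax(x0, 1L), nc)
  y1c <- pmin(y0c + 1L, nr); x1c <- pmin(x0c + 1L, nc)
  idx <- function(yy, xx) (xx - 1L) * nr + yy
  v <- (1 - fy) * (1 - fx) * m[idx(y0c, x0c)] +
    (1 - fy) * fx * m[idx(y0c, x1c)] +
    fy * (1 - fx) * m[idx(y1c, x0c)] +
    fy * fx * m[idx(y1c, x1c)]
  v[!inside] <- fill
  v
}

# Whole-image bilinear shift: value at (i, j) is m(i + dy, j + dx).
shift_bilinear <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  yq <- rep(seq_len(nr), times = nc) + dy
  xq <- rep(seq_len(nc), each = nr) + dx
  matrix(bilinear_sample(m, yq, xq, fill = fill), nr, nc)
}

# Integral image; S[i+1, j+1] = sum of m[1:i, 1:j].
integral_image <- function(m) {
  s <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  cs <- apply(m, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  s[-1, -1] <- t(apply(cs, 1, cumsum))
  s
}

# Window sums over [y0, y1] x [x0, x1] (inclusive, vectorised) from an
# integral image.
window_sum <- function(S, y0, y1, x0, x1) {
  S[cbind(y1 + 1L, x1 + 1L)] - S[cbind(y0, x1 + 1L)] -
    S[cbind(y1 + 1L, x0)] + S[cbind(y0, x0)]
}

# Minimal union-find used for branch-point clustering.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

# Coerce raster_image | matrix to matrix.
as_intensity <- function(img) {
  if (inherits(img, "raster_image")) img$intensities
  else if (is.matrix(img)) img
  else stop("expected a raster_image or matrix", call. = FALSE)
}

px_size <- function(img, default = 0.0775) {
  if (inherits(img, "raster_image")) img$pixel_size_um else default
}
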