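# Internal helpers shared across modules.
# Image convention: a micrograph is a numeric matrix, rows = y (top row is
# y = 0), cols = x.  All public coordinates are 0-based, top-left origin,
# half-open boxes [x, x+w) x [y, y+h).  Pixel (x, y) lives at m[y+1, x+1].

clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

round_half_up <- function(x) floor(x + 0.5)

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(m, r) {
  if (r < 1) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Box (moving-average) filter with window (2r+1)^2 and replicate borders,
# via integral images: exact, no FFT wrap-around.
box_mean <- function(m, r) {
  if (r < 1) return(m)
  p <- pad_replicate(m, r)
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  h <- nrow(m); w <- ncol(m); k <- 2L * r + 1L
  colsum <- cs[(k + 1):(k + h), , drop = FALSE] - cs[1:h, , drop = FALSE]
  cs2 <- t(apply(colsum, 1, cumsum))
  if (h == 1L) cs2 <- matrix(cumsum(colsum[1, ]), nrow = 1)
  cs2 <- cbind(0, cs2)
  out <- cs2[, (k + 1):(k + w), drop = FALSE] - cs2[, 1:w, drop = FALSE]
  out / (k * k)
}

# Direct 2-D convolution with a small kernel and replicate borders.
conv2_replicate <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  r <- max(rh, rw)
  p <- pad_replicate(m, r)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out <- out + kernel[i, j] *
        p[(r - rh + i):(r - rh + i + h - 1L),
          (r - rw + j):(r - rw + j + w - 1L), drop = FALSE]
    }
  }
  out
}

gaussian_kernel <- function(size, sd) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  d <- outer((-r):r, (-r):r, function(i, j) i^2 + j^2)
  k <- exp(-d / (2 * max(sd, 1e-6)^2))
  k / sum(k)
}

# Minimal union-find used by component labeling and score-map cleaning.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

# Crop a half-open box out of a matrix; caller guarantees it fits.
crop_box <- function(m, x, y, w, h) {
  m[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
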