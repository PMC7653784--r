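#' Preprocessing parameters
#'
#' Bundles the tunable parameters of the seven-step enhancement chain.
#' The chain order is: intensity normalization, percentile contrast
#' stretch, global histogram equalization, adaptive Wiener restoration,
#' contrast-limited adaptive histogram equalization, guided filtering and
#' grayscale morphological smoothing.  Every step maps `[0, 1]` images back
#' into `[0, 1]`.
#'
#' @param p_low,p_high Percentiles for the contrast stretch (defaults 1, 99).
#' @param wiener_window Side of the local Wiener neighborhood, pixels.
#' @param clahe_clip CLAHE clip limit as a fraction of the tile histogram.
#' @param clahe_tiles CLAHE tile grid count per axis.
#' @param guided_radius,guided_eps Guided-filter window radius (pixels) and
#'   ridge regularization.
#' @param morph_radius Disc structuring-element radius for the final
#'   opening + closing; around a tenth of the particle size works well.
#' @param augment_sd_range Range the augmentation SD is drawn from.
#' @param augment_mask_sizes Candidate Gaussian mask sizes for augmentation.
#' @return A named list of class `cryo_preprocess_params`.
#' @export
preprocess_params <- function(p_low = 1, p_high = 99, wiener_window = 5,
                              clahe_clip = 0.01, clahe_tiles = 8,
                              guided_radius = 4, guided_eps = 1e-3,
                              morph_radius = 2, augment_sd_range = c(0, 1),
                              augment_mask_sizes = c(3, 5)) {
  stopifnot(wiener_window >= 1, clahe_tiles >= 2, guided_radius >= 1,
            morph_radius >= 1, all(augment_sd_range >= 0),
            all(augment_sd_range <= 1))
  structure(list(p_low = p_low, p_high = p_high,
                 wiener_window = wiener_window, clahe_clip = clahe_clip,
                 clahe_tiles = clahe_tiles, guided_radius = guided_radius,
                 guided_eps = guided_eps, morph_radius = morph_radius,
                 augment_sd_range = augment_sd_range,
                 augment_mask_sizes = augment_mask_sizes),
            class = "cryo_preprocess_params")
}

#' Min-max intensity normalization
#'
#' Linear rescale to `[0, 1]`; a constant image maps to all zeros.
#'
#' @param m Micrograph matrix.
#' @return Matrix in `[0, 1]`.
#' @export
normalize_micrograph <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Percentile contrast stretch
#'
#' Clips intensities at the `p_low` / `p_high` percentiles and rescales the
#' clipped range to `[0, 1]`, suppressing extreme outliers (hot pixels,
#' dense ice) before equalization.
#'
#' @param m Micrograph matrix.
#' @param p_low,p_high Percentiles in `[0, 100]`.
#' @return Matrix in `[0, 1]`.
#' @export
contrast_stretch <- function(m, p_low = 1, p_high = 99) {
  q <- stats::quantile(m, c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) return(normalize_micrograph(m))
  clamp01((pmin(pmax(m, q[1]), q[2]) - q[1]) / (q[2] - q[1]))
}

#' Global histogram equalization
#'
#' Classic 256-bin cumulative-histogram mapping; output spans `[0, 1]`.
#' A constant image is returned unchanged.
#'
#' @param m Micrograph matrix with values in `[0, 1]`.
#' @param bins Number of histogram bins.
#' @return Equalized matrix in `[0, 1]`.
#' @export
hist_equalize <- function(m, bins = 256) {
  idx <- pmin(pmax(floor(m * bins) + 1L, 1L), bins)
  h <- tabulate(idx, bins)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  if (length(m) == cdf_min) return(m)  # constant image
  map <- (cdf - cdf_min) / (length(m) - cdf_min)
  matrix(map[idx], nrow = nrow(m))
}

#' Locally adaptive Wiener restoration
#'
#' Pixel-wise Wiener filter over a `window x window` neighborhood with the
#' noise power estimated as the mean of the local variances, shrinking each
#' pixel toward its local mean where the local variance is low.
#'
#' @param m Micrograph matrix.
#' @param window Odd neighborhood side, pixels; must fit inside the image.
#' @return Restored matrix, clipped to `[0, 1]`.
#' @export
wiener_restore <- function(m, window = 5) {
  if (window > min(dim(m)))
    stop("wiener window (", window, ") larger than image", call. = FALSE)
  r <- max(1L, (as.integer(window) - 1L) %/% 2L)
  mu <- box_mean(m, r)
  sig2 <- pmax(box_mean(m^2, r) - mu^2, 0)
  nu2 <- mean(sig2)
  gain <- ifelse(sig2 > 0, pmax(sig2 - nu2, 0) / sig2, 0)
  clamp01(mu + gain * (m - mu))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based equalization with bilinear interpolation between tile
#' mappings, delegated to \code{EBImage::clahe}.
#'
#' @param m Micrograph matrix in `[0, 1]`.
#' @param clip Clip limit as a fraction of each tile's histogram mass.
#' @param tiles Tile grid count per axis (at least 2).
#' @return Matrix in `[0, 1]`.
#' @export
clahe_enhance <- function(m, clip = 0.01, tiles = 8) {
  if (tiles < 2) stop("clahe needs a tile grid of at least 2 x 2",
                      call. = FALSE)
  if (diff(range(m)) == 0) return(m)
  # EBImage needs dimensions divisible by the tile grid: replicate-pad
  # to the next multiple and crop back.
  h <- nrow(m); w <- ncol(m)
  hp <- ceiling(h / tiles) * tiles
  wp <- ceiling(w / tiles) * tiles
  mp <- m[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)),
          drop = FALSE]
  out <- EBImage::clahe(mp, nx = tiles, ny = tiles, bins = 256,
                        limit = max(1, clip * 256))
  clamp01(matrix(as.numeric(out), nrow = hp)[seq_len(h), seq_len(w),
                                             drop = FALSE])
}

#' Edge-preserving guided filter
#'
#' Smooths `p` under the guidance image `I` by fitting, in every
#' `(2 radius + 1)` square window, the ridge-regularized linear model
#' `q = a I + b` and averaging the per-window coefficients.  With `I = p`
#' this is the standard edge-preserving self-guided smoother: `eps`
#' controls how strong an edge must be to survive.
#'
#' @param p Input micrograph.
#' @param I Guidance image (defaults to `p`).
#' @param radius Window radius, pixels; must be below half the image size.
#' @param eps Regularization (relative intensity units squared).
#' @return Filtered matrix.
#' @export
guided_filter <- function(p, I = p, radius = 4, eps = 1e-3) {
  stopifnot(all(dim(p) == dim(I)))
  if (radius >= min(dim(p)) / 2)
    stop("guided filter radius (", radius, ") must be below half the ",
         "smallest image dimension", call. = FALSE)
  mean_I <- box_mean(I, radius)
  mean_p <- box_mean(p, radius)
  corr_Ip <- box_mean(I * p, radius)
  var_I <- pmax(box_mean(I * I, radius) - mean_I^2, 0)
  a <- (corr_Ip - mean_I * mean_p) / (var_I + eps)
  b <- mean_p - a * mean_I
  box_mean(a, radius) * I + box_mean(b, radius)
}

#' Morphological shape enhancement
#'
#' Grayscale opening followed by closing with a disc structuring element,
#' removing specks smaller than the disc and filling comparable gaps while
#' preserving particle-scale structure.
#'
#' @param m Micrograph matrix.
#' @param radius Disc radius, pixels.
#' @return Filtered matrix.
#' @export
morph_enhance <- function(m, radius = 2) {
  size <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  out <- EBImage::closing(EBImage::opening(m, brush), brush)
  matrix(as.numeric(out), nrow = nrow(m))
}

#' The seven-step micrograph enhancement chain
#'
#' Applies, in order: [normalize_micrograph()], [contrast_stretch()],
#' [hist_equalize()], [wiener_restore()], [clahe_enhance()],
#' [guided_filter()] (self-guided) and [morph_enhance()], re-clipping to
#' `[0, 1]` after every stage.  The chain is deterministic and is the same
#' enhancement used before clustering, before training crops and at test
#' time.
#'
#' @param m Micrograph matrix.
#' @param params A [preprocess_params()] object.
#' @return Enhanced matrix in `[0, 1]`.
#' @export
preprocess_chain <- function(m, params = preprocess_params()) {
  m <- normalize_micrograph(m)
  m <- clamp01(contrast_stretch(m, params$p_low, params$p_high))
  m <- clamp01(hist_equalize(m))
  m <- clamp01(wiener_restore(m, params$wiener_window))
  m <- clamp01(clahe_enhance(m, params$clahe_clip, params$clahe_tiles))
  m <- clamp01(guided_filter(m, m, params$guided_radius, params$guided_eps))
  m <- clamp01(morph_enhance(m, params$morph_radius))
  m
}

#' Randomized smoothing augmentation for training patches
#'
#' Draws a Gaussian SD from `augment_sd_range` and a mask size from
#' `augment_mask_sizes` (3 or 5) using the seeded RNG, convolves the patch
#' with that Gaussian mask, and then applies the self-guided filter.  With
#' SD near 0 the convolution kernel approaches the identity.
#'
#' @param patch 2-D patch matrix.
#' @param params A [preprocess_params()] object.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Augmented patch of the same shape.
#' @export
augment_patch <- function(patch, params = preprocess_params(), seed = 1) {
  set.seed(seed)
  sd <- stats::runif(1, params$augment_sd_range[1], params$augment_sd_range[2])
  size <- sample(params$augment_mask_sizes, 1)
  k <- gaussian_kernel(size, sd)
  out <- conv2_replicate(patch, k)
  radius <- min(params$guided_radius,
                max(1L, floor((min(dim(patch)) - 1) / 2) - 1L))
  clamp01(guided_filter(out, out, radius, params$guided_eps))
}
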