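#' Simulate a cryo-EM micrograph with known particle coordinates
#'
#' Renders `n_particles` bright particle projections of a chosen shape on a
#' flat background, optionally adds bright ice-like blobs and additive
#' Gaussian noise, and returns the image together with a tidy ground-truth
#' table of tight bounding boxes.  Identical arguments (including `seed`)
#' produce bit-identical output, so every downstream stage of the picking
#' pipeline can be tested without external data.
#'
#' Particle shapes emulate the three projection classes seen in single
#' particle cryo-EM: `"disc"` (top view), `"square"` (side view) and
#' `"irregular"` (a union of 3--6 overlapping random ellipses, standing in
#' for ribosome-like projections).  Particles are light-on-dark by default
#' so that segmentation can take the highest-intensity cluster as the
#' particle mask.
#'
#' @param width,height Image dimensions in pixels.
#' @param shape One of `"disc"`, `"square"`, `"irregular"`.
#' @param n_particles Number of particles to place (centers at least
#'   `min_separation` apart, fully inside the image).
#' @param particle_size Disc diameter / square side / blob bounding size,
#'   pixels.
#' @param particle_intensity,background_level Intensities in relative units.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#'   Ignored when `snr` is given.
#' @param snr If non-`NULL`, the noise sigma is derived from the rendered
#'   clean image so that `var(clean - mean(clean)) / noise_sigma^2 == snr`.
#' @param n_ice_blobs Number of bright soft-edged artifacts to add.
#' @param min_separation Minimum pairwise center distance, pixels. Default
#'   `1.4 * particle_size`.
#' @param n_clipped Number of additional particles deliberately placed so
#'   that they are clipped by the image border (their ground-truth boxes are
#'   clipped to the image and labelled in the `clipped` column).  Useful for
#'   exercising the good/bad training-sample selection.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return An object of class `cryo_simulation`: a list with `pixels` (noisy
#'   image matrix), `clean` (pre-noise image), `truth` (tibble with columns
#'   `x`, `y`, `w`, `h`, `cx`, `cy`, `label`, `clipped`), `noise_sigma` and
#'   the generating parameters.
#' @export
simulate_micrograph <- function(width = 256, height = 256,
                                shape = c("disc", "square", "irregular"),
                                n_particles = 20, particle_size = 24,
                                particle_intensity = 1, background_level = 0.1,
                                noise_sigma = 0, snr = NULL, n_ice_blobs = 0,
                                min_separation = NULL, n_clipped = 0,
                                seed = 1) {
  shape <- match.arg(shape)
  stopifnot(n_particles >= 0, n_clipped >= 0,
            particle_size < min(width, height))
  min_separation <- min_separation %||% (1.4 * particle_size)
  set.seed(seed)

  clean <- matrix(background_level, nrow = height, ncol = width)
  centers <- place_centers(width, height, n_particles, n_clipped,
                           particle_size, min_separation)

  boxes <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    sten <- render_particle(shape, particle_size)
    res <- stamp(clean, sten, centers$cx[i], centers$cy[i],
                 particle_intensity, background_level)
    clean <- res$image
    boxes[[i]] <- res$box
  }
  truth <- if (length(boxes)) dplyr::bind_rows(boxes) else
    tibble::tibble(x = integer(), y = integer(), w = integer(),
                   h = integer(), cx = double(), cy = double())
  truth$label <- rep(shape_label(shape), nrow(truth))
  truth$clipped <- centers$clipped[seq_len(nrow(truth))]

  for (b in seq_len(n_ice_blobs)) {
    cx <- stats::runif(1, 0, width - 1)
    cy <- stats::runif(1, 0, height - 1)
    r <- particle_size * stats::runif(1, 0.8, 1.6)
    yy <- matrix(0:(height - 1), height, width)
    xx <- matrix(0:(width - 1), height, width, byrow = TRUE)
    d2 <- (xx - cx)^2 + (yy - cy)^2
    blob <- 1.3 * particle_intensity * exp(-d2 / (2 * (r / 2)^2))
    clean <- pmax(clean, background_level + blob * (d2 <= r^2))
  }

  if (!is.null(snr)) {
    s2 <- stats::var(as.vector(clean))
    noise_sigma <- if (s2 > 0) sqrt(s2 / snr) else 0
  }
  pixels <- clean
  if (noise_sigma > 0)
    pixels <- clean + matrix(stats::rnorm(length(clean), 0, noise_sigma),
                             nrow = height)

  structure(list(pixels = pixels, clean = clean, truth = truth,
                 shape = shape, particle_size = particle_size,
                 noise_sigma = noise_sigma, background_level = background_level,
                 particle_intensity = particle_intensity, seed = seed),
            class = "cryo_simulation")
}

shape_label <- function(shape) {
  switch(shape, disc = "top_view", square = "side_view",
         irregular = "irregular")
}

# Rejection-sample particle centers; clipped ones straddle the border.
place_centers <- function(width, height, n_inside, n_clipped, size, min_sep,
                          max_attempts = 10000) {
  half <- size / 2
  cx <- cy <- numeric(0)
  clipped <- logical(0)
  want <- n_inside + n_clipped
  attempts <- 0
  while (length(cx) < want) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("cannot place particles: ", length(cx), " of ", want,
           " placed after ", max_attempts, " attempts at min_separation ",
           min_sep, call. = FALSE)
    clip_this <- length(cx) >= n_inside
    if (clip_this) {
      # Center sits half a radius outside one border edge.
      edge <- sample(4, 1)
      off <- half / 2
      x <- switch(edge, -off, width - 1 + off,
                  stats::runif(1, half, width - 1 - half),
                  stats::runif(1, half, width - 1 - half))
      y <- switch(edge, stats::runif(1, half, height - 1 - half),
                  stats::runif(1, half, height - 1 - half),
                  -off, height - 1 + off)
    } else {
      x <- stats::runif(1, half, width - 1 - half)
      y <- stats::runif(1, half, height - 1 - half)
    }
    if (length(cx) == 0 || all((cx - x)^2 + (cy - y)^2 >= min_sep^2)) {
      cx <- c(cx, x); cy <- c(cy, y); clipped <- c(clipped, clip_this)
    }
  }
  tibble::tibble(cx = cx, cy = cy, clipped = clipped)
}

# A particle stencil: logical matrix plus its nominal size.
render_particle <- function(shape, size) {
  n <- as.integer(ceiling(size)) + 2L
  cc <- (n - 1) / 2
  yy <- matrix(0:(n - 1), n, n)
  xx <- t(yy)
  switch(shape,
    disc = (xx - cc)^2 + (yy - cc)^2 <= (size / 2)^2,
    square = abs(xx - cc) <= size / 2 - 0.5 & abs(yy - cc) <= size / 2 - 0.5,
    irregular = {
      k <- sample(3:6, 1)
      m <- matrix(FALSE, n, n)
      for (i in seq_len(k)) {
        ecx <- cc + stats::runif(1, -size / 5, size / 5)
        ecy <- cc + stats::runif(1, -size / 5, size / 5)
        a <- stats::runif(1, size / 6, size / 3.2)
        b <- stats::runif(1, size / 6, size / 3.2)
        th <- stats::runif(1, 0, pi)
        xr <- (xx - ecx) * cos(th) + (yy - ecy) * sin(th)
        yr <- -(xx - ecx) * sin(th) + (yy - ecy) * cos(th)
        m <- m | (xr / a)^2 + (yr / b)^2 <= 1
      }
      m
    })
}

# Paste a stencil at a (possibly border-clipped) center; returns updated
# image and the tight, image-clipped bounding box of the stamped pixels.
stamp <- function(image, sten, cx, cy, intensity, background) {
  h <- nrow(image); w <- ncol(image)
  n <- nrow(sten)
  x0 <- round_half_up(cx - (n - 1) / 2)
  y0 <- round_half_up(cy - (n - 1) / 2)
  sx <- max(0, -x0); sy <- max(0, -y0)
  ex <- min(n - 1, w - 1 - x0); ey <- min(n - 1, h - 1 - y0)
  if (sx > ex || sy > ey)
    return(list(image = image, box = NULL))
  sub <- sten[(sy + 1):(ey + 1), (sx + 1):(ex + 1), drop = FALSE]
  ri <- (y0 + sy + 1):(y0 + ey + 1)
  ci <- (x0 + sx + 1):(x0 + ex + 1)
  patch <- image[ri, ci, drop = FALSE]
  patch[sub] <- background + intensity
  image[ri, ci] <- patch
  on <- which(sub, arr.ind = TRUE)
  bx <- x0 + sx + min(on[, 2]) - 1L
  by <- y0 + sy + min(on[, 1]) - 1L
  bw <- diff(range(on[, 2])) + 1L
  bh <- diff(range(on[, 1])) + 1L
  list(image = image,
       box = tibble::tibble(x = bx, y = by, w = bw, h = bh,
                            cx = bx + bw / 2, cy = by + bh / 2))
}

#' Estimate the signal-to-noise ratio of a noisy micrograph
#'
#' SNR is defined as the variance of the centered clean signal divided by
#' the variance of the residual `noisy - clean`.  A zero-variance residual
#' (no noise) returns `Inf`.
#'
#' @param clean,noisy Micrograph matrices of identical dimensions.
#' @return A single number; `Inf` when the images are identical.
#' @export
estimate_snr <- function(clean, noisy) {
  stopifnot(all(dim(clean) == dim(noisy)))
  num <- stats::var(as.vector(clean) - mean(clean))
  den <- stats::var(as.vector(noisy) - as.vector(clean))
  if (!is.finite(den) || den == 0) return(Inf)
  num / den
}

#' Build a labeled synthetic training set
#'
#' Simulates micrographs of each requested particle shape, runs the
#' preprocessing chain, crops fixed-size patches at the known particle
#' centers and harvests non-overlapping background crops, yielding a
#' tidy sample table ready for [balance_and_split()] and [train_cnn()].
#'
#' @param n_per_class Raw samples wanted per class (before augmentation
#'   or balancing).
#' @param patch_size Patch side, pixels.
#' @param shapes Particle classes to include.
#' @param include_background Add a `"background"` class of particle-free
#'   crops.
#' @param snr Signal-to-noise ratio of the simulated micrographs.
#' @param particle_size,width,height,n_particles Simulator geometry.
#' @param params Preprocessing parameters.
#' @param seed Integer seed.
#' @return Tibble with `patch` (list-column), `label`, `source`.
#' @export
build_synthetic_dataset <- function(n_per_class = 200, patch_size = 32,
                                    shapes = c("disc", "square", "irregular"),
                                    include_background = TRUE, snr = 0.3,
                                    particle_size = 24, width = 256,
                                    height = 256, n_particles = 20,
                                    params = preprocess_params(),
                                    seed = 1) {
  out <- list()
  sub_seed <- seed * 1000L
  # Unify particle sizes to the window scale: the same scaling rule used
  # at test time is applied to the training micrographs, so crops show
  # particles at the size the sliding window will see.
  decision <- select_scaling(particle_size, patch_size)
  for (shape in shapes) {
    got <- 0L
    while (got < n_per_class) {
      sub_seed <- sub_seed + 1L
      sim <- simulate_micrograph(width = width, height = height,
                                 shape = shape, n_particles = n_particles,
                                 particle_size = particle_size, snr = snr,
                                 seed = sub_seed)
      scaled <- rescale_and_pad(sim$pixels, decision)
      pre <- preprocess_chain(scaled, params)
      # Jitter crop centers by up to a twelfth of the patch so the
      # classifier tolerates the off-center windows the sliding scan
      # produces (test windows land up to stride/2 from a particle).
      set.seed(sub_seed + 500000L)
      jit <- patch_size / 12
      truth_sc <- dplyr::mutate(sim$truth,
                                cx = .data$cx * decision$factor +
                                  stats::runif(dplyr::n(), -jit, jit),
                                cy = .data$cy * decision$factor +
                                  stats::runif(dplyr::n(), -jit, jit))
      crops <- extract_particles(pre, truth_sc, patch_size)
      if (!nrow(crops)) next
      take <- min(nrow(crops), n_per_class - got)
      crops <- crops[seq_len(take), , drop = FALSE]
      out[[length(out) + 1]] <- tibble::tibble(
        patch = crops$patch, label = shape_label(shape),
        source = sprintf("%s_sim%d", shape, sub_seed))
      got <- got + take
    }
  }
  if (include_background) {
    got <- 0L
    crowded <- TRUE
    # Noise level a particle-free field would carry at this SNR.
    sigma_ref <- simulate_micrograph(width = width, height = height,
                                     n_particles = n_particles,
                                     particle_size = particle_size,
                                     snr = snr, seed = sub_seed)$noise_sigma
    while (got < n_per_class) {
      sub_seed <- sub_seed + 1L
      # Alternate between particle-bearing and particle-free micrographs
      # so the background class covers both kinds of field.
      crowded <- !crowded
      sim <- simulate_micrograph(width = width, height = height,
                                 n_particles = if (crowded) n_particles else 0,
                                 particle_size = particle_size,
                                 snr = if (crowded) snr else NULL,
                                 noise_sigma = if (crowded) 0 else sigma_ref,
                                 seed = sub_seed)
      scaled <- rescale_and_pad(sim$pixels, decision)
      pre <- preprocess_chain(scaled, params)
      truth_sc <- dplyr::mutate(sim$truth,
                                x = .data$x * decision$factor,
                                y = .data$y * decision$factor,
                                w = .data$w * decision$factor,
                                h = .data$h * decision$factor)
      bg <- harvest_negatives(pre, truth_sc,
                              n = min(n_per_class - got,
                                      ceiling(n_per_class / 6)),
                              patch_size = patch_size, seed = sub_seed)
      bg <- bg[bg$label == "background", , drop = FALSE]
      if (!nrow(bg)) next
      out[[length(out) + 1]] <- tibble::tibble(
        patch = bg$patch, label = "background",
        source = sprintf("background_sim%d", sub_seed))
      got <- got + nrow(bg)
    }
  }
  dplyr::bind_rows(out)
}
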