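#' Intensity-based clustering segmentation
#'
#' Partitions the pixels of a preprocessed micrograph into `k` intensity
#' clusters by one-dimensional k-means with deterministic quantile
#' initialization, and returns the binary particle mask as the cluster with
#' the highest mean intensity.  Because the clustering depends only on
#' intensity, permuting pixel positions cannot change any assignment.
#'
#' @param m Preprocessed micrograph in `[0, 1]`.
#' @param k Number of intensity clusters (at least 2).
#' @return List with `labels` (integer matrix of cluster ids, ordered by
#'   ascending cluster mean) and `mask` (logical matrix, highest-mean
#'   cluster).
#' @export
ibc_cluster <- function(m, k = 2) {
  stopifnot(k >= 2)
  x <- as.vector(m)
  ux <- unique(x)
  if (length(ux) < k)
    stop("fewer than k = ", k, " distinct intensities (", length(ux), ")",
         call. = FALSE)
  centers <- kmeans_1d(x, k)
  lab <- assign_nearest(x, centers)
  labels <- matrix(lab, nrow = nrow(m))
  list(labels = labels, mask = labels == k, centers = centers)
}

# Deterministic 1-D k-means (Lloyd) on value-weighted unique intensities,
# initialized at the (2i-1)/(2k) quantiles.
kmeans_1d <- function(x, k, max_iter = 100) {
  tab <- table(x)
  v <- as.numeric(names(tab))
  w <- as.numeric(tab)
  centers <- stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  # Nudge coincident initial centers apart deterministically.
  for (i in 2:k) if (centers[i] <= centers[i - 1])
    centers[i] <- centers[i - 1] + 1e-9
  for (iter in seq_len(max_iter)) {
    lab <- assign_nearest(v, centers)
    new_centers <- vapply(seq_len(k), function(j) {
      sel <- lab == j
      if (any(sel)) sum(v[sel] * w[sel]) / sum(w[sel]) else centers[j]
    }, numeric(1))
    new_centers <- sort(new_centers)
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  centers
}

assign_nearest <- function(x, centers) {
  d <- abs(outer(x, centers, "-"))
  max.col(-d, ties.method = "first")
}

#' Superpixel k-means segmentation
#'
#' Over-segments the micrograph into roughly `n_superpixels` compact
#' regions by iterative local clustering on (x, y, intensity), then runs
#' 1-D k-means on the per-superpixel mean intensities; the particle mask is
#' the union of superpixels in the highest-mean cluster.  This is the
#' coarse-to-fine alternative to [ibc_cluster()] used for irregular and
#' complex particle shapes.
#'
#' @param m Preprocessed micrograph in `[0, 1]`.
#' @param n_superpixels Target number of superpixels (must be >= `k`).
#' @param k Number of intensity clusters for the second stage.
#' @param compactness Weight of spatial distance against intensity
#'   distance; higher values give more regular superpixels.
#' @param iterations Local clustering sweeps.
#' @return List with `mask` (logical matrix), `superpixels` (integer label
#'   matrix) and `centers` (intensity cluster centers).
#' @export
superpixel_cluster <- function(m, n_superpixels = 200, k = 2,
                               compactness = 0.05, iterations = 5) {
  if (n_superpixels < k)
    stop("n_superpixels (", n_superpixels, ") must be at least k = ", k,
         call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  S <- max(2, round(sqrt(h * w / n_superpixels)))
  cy <- seq(S %/% 2, h - 1, by = S)
  cx <- seq(S %/% 2, w - 1, by = S)
  cen <- expand.grid(y = cy, x = cx)
  cen$int <- m[cbind(cen$y + 1, cen$x + 1)]
  n_cen <- nrow(cen)
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  lab <- matrix(0L, h, w)
  dist <- matrix(Inf, h, w)
  sw <- (compactness / S)^2
  for (it in seq_len(iterations)) {
    lab[] <- 0L; dist[] <- Inf
    for (ci in seq_len(n_cen)) {
      r0 <- max(1, round(cen$y[ci]) - 2 * S + 1)
      r1 <- min(h, round(cen$y[ci]) + 2 * S + 1)
      c0 <- max(1, round(cen$x[ci]) - 2 * S + 1)
      c1 <- min(w, round(cen$x[ci]) + 2 * S + 1)
      d <- (m[r0:r1, c0:c1] - cen$int[ci])^2 +
        sw * ((yy[r0:r1, c0:c1] - cen$y[ci])^2 +
              (xx[r0:r1, c0:c1] - cen$x[ci])^2)
      upd <- d < dist[r0:r1, c0:c1]
      if (any(upd)) {
        sub_lab <- lab[r0:r1, c0:c1]; sub_lab[upd] <- ci
        lab[r0:r1, c0:c1] <- sub_lab
        sub_d <- dist[r0:r1, c0:c1]; sub_d[upd] <- d[upd]
        dist[r0:r1, c0:c1] <- sub_d
      }
    }
    # Recompute centers from their members.
    idx <- lab > 0
    agg_n <- tabulate(lab[idx], n_cen)
    keep <- agg_n > 0
    cen$y[keep] <- (rowsum(as.numeric(yy[idx]), lab[idx])[, 1] / agg_n[keep])
    cen$x[keep] <- (rowsum(as.numeric(xx[idx]), lab[idx])[, 1] / agg_n[keep])
    cen$int[keep] <- (rowsum(as.numeric(m[idx]), lab[idx])[, 1] / agg_n[keep])
  }
  sp_mean <- cen$int
  if (length(unique(sp_mean)) < k)
    stop("fewer than k = ", k, " distinct superpixel intensities",
         call. = FALSE)
  centers <- kmeans_1d(sp_mean, k)
  sp_lab <- assign_nearest(sp_mean, centers)
  mask <- matrix(sp_lab[lab] == k, h, w)
  list(mask = mask, superpixels = lab, centers = centers)
}

#' Remove small and border-touching objects from a binary mask
#'
#' Drops 8-connected components with fewer than `min_area` pixels and
#' components having any pixel within `border_margin` pixels of the image
#' border.  With `min_area = 0` and `border_margin = 0` the mask is
#' returned unchanged.  Cleaning can only remove components, never add.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area, pixels.
#' @param border_margin Width of the border exclusion zone, pixels.
#' @return Cleaned logical matrix.
#' @export
clean_mask <- function(mask, min_area = 20, border_margin = 1) {
  if (min_area <= 0 && border_margin <= 0) return(mask)
  lab <- label_matrix_8(mask)
  n <- max(lab)
  if (n == 0) return(mask)
  areas <- tabulate(lab[lab > 0], n)
  drop <- areas < min_area
  if (border_margin > 0) {
    bm <- border_margin
    h <- nrow(mask); w <- ncol(mask)
    border_labels <- unique(c(lab[seq_len(min(bm, h)), ],
                              lab[(h - min(bm, h) + 1):h, ],
                              lab[, seq_len(min(bm, w))],
                              lab[, (w - min(bm, w) + 1):w]))
    drop[border_labels[border_labels > 0]] <- TRUE
  }
  mask & !matrix(drop[pmax(lab, 1)] & lab > 0, nrow(mask))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so diagonal
# neighbors of distinct labels are merged with a union-find pass.
label_matrix_8 <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]     # down-left diagonal
  pairs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1],
                       b1[a1 > 0 & b1 > 0 & a1 != b1]),
                 cbind(a2[a2 > 0 & b2 > 0 & a2 != b2],
                       b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs)) {
    parent <- uf_new(n)
    for (i in seq_len(nrow(pairs)))
      parent <- uf_union(parent, pairs[i, 1], pairs[i, 2])
    root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    root <- match(root, sort(unique(root)))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

#' Label the connected components of a binary mask
#'
#' 8-connectivity labeling.  Each component carries its cropped mask, its
#' offset in the micrograph frame, area (pixel count), perimeter (number of
#' steps along the closed 8-connected outer contour), sub-pixel centroid
#' and pixel index list.
#'
#' @param mask Logical matrix.
#' @return A list of `cryo_component` objects (empty list for an empty
#'   mask); see [components_tbl()] for a tabular summary.
#' @export
label_components <- function(mask) {
  lab <- label_matrix_8(mask)
  n <- max(lab)
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) {
    px <- which(lab == i, arr.ind = TRUE)  # row = y+1, col = x+1
    x <- px[, 2] - 1L; y <- px[, 1] - 1L
    x0 <- min(x); y0 <- min(y)
    sub <- matrix(FALSE, max(y) - y0 + 1L, max(x) - x0 + 1L)
    sub[cbind(y - y0 + 1L, x - x0 + 1L)] <- TRUE
    structure(list(mask = sub, offset = c(x = x0, y = y0),
                   area = nrow(px),
                   perimeter = contour_steps(sub),
                   centroid = c(x = mean(x), y = mean(y)),
                   pixels = cbind(x = x, y = y)),
              class = "cryo_component")
  })
}

#' Summarize components as a tibble
#'
#' @param components List of components from [label_components()].
#' @return Tibble with one row per component: offsets, area, perimeter,
#'   centroid, bounding box and the component object in a list-column.
#' @export
components_tbl <- function(components) {
  if (!length(components))
    return(tibble::tibble(id = integer(), area = integer(),
                          perimeter = double(), cx = double(), cy = double(),
                          x = integer(), y = integer(), w = integer(),
                          h = integer(), component = list()))
  tibble::tibble(
    id = seq_along(components),
    area = vapply(components, function(c) c$area, numeric(1)),
    perimeter = vapply(components, function(c) c$perimeter, numeric(1)),
    cx = vapply(components, function(c) c$centroid[["x"]], numeric(1)),
    cy = vapply(components, function(c) c$centroid[["y"]], numeric(1)),
    x = vapply(components, function(c) c$offset[["x"]], numeric(1)),
    y = vapply(components, function(c) c$offset[["y"]], numeric(1)),
    w = vapply(components, function(c) ncol(c$mask), numeric(1)),
    h = vapply(components, function(c) nrow(c$mask), numeric(1)),
    component = components)
}

# Chain-code length of the closed outer contour, by Moore-neighbor
# tracing with Jacob's stopping criterion: axis steps count 1, diagonal
# steps sqrt(2), so a rasterized disc measures close to its true
# perimeter (a raw step count would rate discs less round than squares).
# A single pixel counts as perimeter 1.
contour_steps <- function(sub) {
  if (sum(sub) == 1) return(1)
  p <- matrix(FALSE, nrow(sub) + 2, ncol(sub) + 2)
  p[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)] <- sub
  # Moore neighborhood in clockwise order starting west (dy, dx).
  nb <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
               ncol = 2, byrow = TRUE)
  start <- which(p, arr.ind = TRUE)
  start <- start[order(start[, 2], start[, 1]), , drop = FALSE][1, ]
  step_len <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  cur <- start
  enter <- 1L  # came from the west
  nsteps <- 0L
  len <- 0
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    # Scan clockwise starting just after the backtrack direction.
    for (i in seq_len(8)) {
      d <- ((enter - 1L + i - 1L) %% 8L) + 1L
      ny <- cur[1] + nb[d, 1]; nx <- cur[2] + nb[d, 2]
      if (p[ny, nx]) {
        if (nsteps == 0L) first_dir <- d
        else if (cur[1] == start[1] && cur[2] == start[2] && d == first_dir)
          return(len)
        cur <- c(ny, nx)
        # New backtrack: the neighbor we came from, i.e. opposite step,
        # advanced by one clockwise position.
        enter <- ((d + 4L - 1L + 1L) %% 8L) + 1L
        nsteps <- nsteps + 1L
        len <- len + step_len[d]
        found <- TRUE
        break
      }
    }
    if (!found) return(max(len, 1))           # isolated pixel cluster
    if (nsteps > 8L * length(p)) return(len)  # safety, never expected
  }
}

#' Detect circles in a binary mask by the circular Hough transform
#'
#' Edge pixels of the mask vote for circle centers at every radius in
#' `[r_min, r_max]`; local accumulator maxima above `vote_frac` of the
#' full-circle vote count are returned, deduplicated so that kept centers
#' are more than `r_min` apart.
#'
#' @param mask Logical matrix.
#' @param r_min,r_max Radius search range, pixels (`0 < r_min < r_max`).
#' @param vote_frac Minimum fraction of the full perimeter vote.
#' @return Tibble with columns `cx`, `cy`, `r`, `score` (vote fraction),
#'   possibly empty.
#' @export
detect_circles <- function(mask, r_min, r_max, vote_frac = 0.5) {
  stopifnot(r_min > 0, r_max > r_min)
  h <- nrow(mask); w <- ncol(mask)
  edge <- mask & !erode4(mask)
  ep <- which(edge, arr.ind = TRUE)
  if (!nrow(ep))
    return(tibble::tibble(cx = double(), cy = double(), r = double(),
                          score = double()))
  ey <- ep[, 1]; ex <- ep[, 2]
  out <- list()
  for (r in seq(ceiling(r_min), floor(r_max))) {
    # Vote for every lattice center within 1 px of distance r from the
    # edge pixel; normalize by the width-1 annulus count (the number of
    # edge pixels an ideal circle of radius r contributes), so a full
    # circle scores ~1.
    span <- (-(r + 1)):(r + 1)
    d <- sqrt(outer(span^2, span^2, "+"))
    sel <- which(abs(d - r) <= 1, arr.ind = TRUE)
    off <- cbind(span[sel[, 2]], span[sel[, 1]])
    n_full <- sum(abs(d - r) <= 0.5)
    acc <- matrix(0L, h, w)
    for (i in seq_len(nrow(off))) {
      cyv <- ey + off[i, 2]; cxv <- ex + off[i, 1]
      ok <- cyv >= 1 & cyv <= h & cxv >= 1 & cxv <= w
      idx <- cyv[ok] + (cxv[ok] - 1L) * h
      t <- tabulate(idx, h * w)
      acc <- acc + t
    }
    score <- acc / n_full
    hits <- which(score >= vote_frac, arr.ind = TRUE)
    if (nrow(hits))
      out[[length(out) + 1]] <- tibble::tibble(
        cx = hits[, 2] - 1, cy = hits[, 1] - 1, r = r,
        score = score[hits])
  }
  if (!length(out))
    return(tibble::tibble(cx = double(), cy = double(), r = double(),
                          score = double()))
  cand <- dplyr::arrange(dplyr::bind_rows(out),
                         dplyr::desc(.data$score), .data$cx, .data$cy)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep) ||
        all((cand$cx[keep] - cand$cx[i])^2 +
            (cand$cy[keep] - cand$cy[i])^2 > r_min^2))
      keep <- c(keep, i)
  }
  cand[keep, ]
}

erode4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(FALSE, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- mask
  p[2:(h + 1), 2:(w + 1)] & p[1:h, 2:(w + 1)] & p[3:(h + 2), 2:(w + 1)] &
    p[2:(h + 1), 1:w] & p[2:(h + 1), 3:(w + 2)]
}

#' Feret (caliper) diameters of a component
#'
#' Projects the corners of the component's boundary pixels onto directions
#' in 1-degree steps and reports the maximum and minimum caliper extents
#' and the direction of the maximum.  Pixel corners (not centers) are
#' used, so an axis-aligned `n x n` square measures exactly `n` and
#' `n * sqrt(2)`.
#'
#' @param component A `cryo_component` from [label_components()].
#' @param angle_step Direction step in degrees.
#' @return Tibble with `max_diameter`, `min_diameter`, `max_angle`
#'   (degrees).
#' @export
feret_diameters <- function(component, angle_step = 1) {
  px <- component$pixels
  if (nrow(px) == 1)
    return(tibble::tibble(max_diameter = 1, min_diameter = 1, max_angle = 0))
  # The four corners of each pixel's unit square.
  cx <- c(px[, "x"], px[, "x"] + 1, px[, "x"], px[, "x"] + 1)
  cy <- c(px[, "y"], px[, "y"], px[, "y"] + 1, px[, "y"] + 1)
  hull <- grDevices::chull(cx, cy)
  hx <- cx[hull]; hy <- cy[hull]
  ang <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  ext <- vapply(ang, function(a) {
    pr <- hx * cos(a) + hy * sin(a)
    max(pr) - min(pr)
  }, numeric(1))
  tibble::tibble(max_diameter = max(ext), min_diameter = min(ext),
                 max_angle = (which.max(ext) - 1) * angle_step)
}

#' Crop fixed-size particle patches around detection centers
#'
#' Each detection is re-boxed to a fixed `patch_size` square centered on
#' its center; detections whose fixed box falls outside the image are
#' dropped.
#'
#' @param m Micrograph matrix.
#' @param detections Tibble with columns `cx`, `cy` (0-based centers);
#'   other columns are carried through.
#' @param patch_size Patch side, pixels; must fit in the image.
#' @return Tibble with `x`, `y`, `w`, `h`, the carried columns and a
#'   `patch` list-column of cropped matrices.
#' @export
extract_particles <- function(m, detections, patch_size) {
  if (patch_size > min(dim(m)))
    stop("patch_size (", patch_size, ") exceeds image dimensions",
         call. = FALSE)
  if (!nrow(detections))
    return(dplyr::mutate(detections, x = integer(), y = integer(),
                         w = integer(), h = integer(), patch = list()))
  x <- round_half_up(detections$cx - patch_size / 2)
  y <- round_half_up(detections$cy - patch_size / 2)
  ok <- x >= 0 & y >= 0 & x + patch_size <= ncol(m) &
    y + patch_size <= nrow(m)
  det <- detections[ok, , drop = FALSE]
  det$x <- x[ok]; det$y <- y[ok]
  det$w <- patch_size; det$h <- patch_size
  det$patch <- purrr::map2(det$x, det$y,
                           function(xi, yi) crop_box(m, xi, yi,
                                                     patch_size, patch_size))
  det
}

#' Unsupervised Stage-1 particle localization
#'
#' Runs the full first-stage pipeline on a raw micrograph: preprocessing
#' chain, intensity (or superpixel) clustering into a binary particle
#' mask, mask cleaning, component labeling and shape-specific detection
#' (circular Hough transform for discs, Feret-based boxes otherwise).
#'
#' @param m Raw micrograph matrix.
#' @param particle_size Expected particle size, pixels (drives the Hough
#'   radius range, minimum area and morphology radius).
#' @param shape `"disc"`, `"square"` or `"irregular"`.
#' @param method `"ibc"` (intensity k-means) or `"superpixel"`.
#' @param params Preprocessing parameters; by default `morph_radius` is
#'   set to a tenth of `particle_size`.
#' @param k Number of intensity clusters.
#' @param keep_clipped Keep components touching the border (default FALSE).
#' @return List with `detections` (tibble: `cx`, `cy`, `r` or Feret
#'   columns, `score`), `components`, `mask` and the preprocessed image.
#' @export
stage1_pick <- function(m, particle_size, shape = c("disc", "square",
                                                    "irregular"),
                        method = c("ibc", "superpixel"),
                        params = NULL, k = 2, keep_clipped = FALSE) {
  shape <- match.arg(shape)
  method <- match.arg(method)
  params <- params %||%
    preprocess_params(morph_radius = max(1, round(particle_size / 10)))
  pre <- preprocess_chain(m, params)
  mask <- if (method == "ibc") ibc_cluster(pre, k)$mask else
    superpixel_cluster(pre, n_superpixels =
                         max(k, round(length(m) / particle_size^2)), k = k)$mask
  # Binary object smoothing: closing fills boundary pits, opening strips
  # noise arms thinner than about a quarter of the particle off the
  # masks, before any geometry is measured.
  br <- max(1, round(particle_size / 8))
  brush <- EBImage::makeBrush(2L * br + 1L, shape = "disc")
  mask <- EBImage::opening(EBImage::closing(mask * 1, brush), brush) > 0.5
  min_area <- round(0.15 * (particle_size / 2)^2 * pi)
  mask <- clean_mask(mask, min_area = min_area,
                     border_margin = if (keep_clipped) 0 else 1)
  comps <- label_components(mask)
  ctbl <- components_tbl(comps)
  detections <- if (shape == "disc") {
    circ <- detect_circles(mask, r_min = 0.6 * particle_size / 2,
                           r_max = 1.4 * particle_size / 2)
    circ
  } else {
    ctbl[, c("cx", "cy", "area")]
  }
  list(detections = detections, components = comps, mask = mask,
       preprocessed = pre)
}
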