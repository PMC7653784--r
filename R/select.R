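#' Circularity of a shape
#'
#' `perimeter^2 / (4 * pi * area)`: exactly 1 for an ideal circle,
#' `4 / pi` for an ideal square, larger for less round shapes.
#'
#' @param perimeter Perimeter (pixels, or continuous units).
#' @param area Area (pixels squared); must be positive.
#' @return Dimensionless circularity.
#' @export
circularity <- function(perimeter, area) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  perimeter^2 / (4 * pi * area)
}

#' @rdname circularity
#' @param component A `cryo_component`; its stored perimeter and area are
#'   used.
#' @export
circularity_component <- function(component) {
  circularity(component$perimeter, component$area)
}

#' Rasterize a filled circle mask
#'
#' Pixel (x, y) is set when its center lies within `r` of the given
#' center.  A radius of 1 therefore gives the 5-pixel plus shape.
#'
#' @param cx,cy Circle center, 0-based pixels.
#' @param r Radius, pixels.
#' @param dim Output `c(height, width)`.
#' @return Logical matrix.
#' @export
perfect_circle_mask <- function(cx, cy, r, dim) {
  if (cx < 0 || cy < 0 || cx > dim[2] - 1 || cy > dim[1] - 1)
    stop("circle center outside the patch", call. = FALSE)
  yy <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  xx <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

jaccard_masks <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

# Render a component's mask and a circle into a common frame and compare.
component_circle_jaccard <- function(component, cx, cy, r) {
  off <- component$offset
  x0 <- min(off[["x"]], floor(cx - r)); y0 <- min(off[["y"]], floor(cy - r))
  x1 <- max(off[["x"]] + ncol(component$mask) - 1, ceiling(cx + r))
  y1 <- max(off[["y"]] + nrow(component$mask) - 1, ceiling(cy + r))
  w <- x1 - x0 + 1; h <- y1 - y0 + 1
  cm <- matrix(FALSE, h, w)
  cm[cbind(component$pixels[, "y"] - y0 + 1,
           component$pixels[, "x"] - x0 + 1)] <- TRUE
  circ <- perfect_circle_mask(cx - x0, cy - y0, r, c(h, w))
  jaccard_masks(cm, circ)
}

#' Good/bad selection of top-view (circular) particles
#'
#' Implements the automated roundness screen for circular projections.
#' Each component is paired with the closest detected Hough circle (circle
#' center inside or nearest to the component); a component is *good* iff
#' (a) it has a circle, (b) its circularity deviates from 1 no more than
#' the batch mean circularity does ("achieves the average roundness"), and
#' (c) its Jaccard overlap with the perfect rasterized circle built from
#' the Hough center and radius is at least `jaccard_min`.  Everything else
#' - border-clipped half discs, fused or speckled masks, circle-less
#' blobs - is *bad*.
#'
#' @param components List of `cryo_component` objects.
#' @param circles Tibble from [detect_circles()] (`cx`, `cy`, `r`).
#' @param jaccard_min Minimum overlap with the perfect circle.
#' @return Tibble with one row per component: `id`, `circularity`,
#'   `jaccard`, `has_circle`, `good`, and the component in a list-column.
#'   The good and bad subsets partition the input.
#' @export
select_good_topview <- function(components, circles, jaccard_min = 0.8) {
  tbl <- components_tbl(components)
  if (!nrow(tbl)) {
    tbl$circularity <- double(); tbl$jaccard <- double()
    tbl$has_circle <- logical(); tbl$good <- logical()
    return(tbl)
  }
  tbl$circularity <- vapply(components, circularity_component, numeric(1))
  mean_dev <- abs(mean(tbl$circularity) - 1)
  match_idx <- rep(NA_integer_, nrow(tbl))
  if (nrow(circles)) {
    for (i in seq_len(nrow(tbl))) {
      d2 <- (circles$cx - tbl$cx[i])^2 + (circles$cy - tbl$cy[i])^2
      j <- which.min(d2)
      if (d2[j] <= circles$r[j]^2) match_idx[i] <- j
    }
  }
  tbl$has_circle <- !is.na(match_idx)
  tbl$jaccard <- vapply(seq_len(nrow(tbl)), function(i) {
    if (is.na(match_idx[i])) return(0)
    ci <- circles[match_idx[i], ]
    component_circle_jaccard(components[[i]], ci$cx, ci$cy, ci$r)
  }, numeric(1))
  tbl$good <- tbl$has_circle &
    abs(tbl$circularity - 1) <= mean_dev + 1e-9 &
    tbl$jaccard >= jaccard_min
  tbl
}

#' Good/bad selection of side-view (square) particles
#'
#' Removes circular and otherwise non-square components (Feret min/max
#' ratio outside `ratio_band`; a filled square measures about
#' `1/sqrt(2) = 0.707`, a disc about 1), then removes overlapped (fused)
#' components whose maximum Feret diameter exceeds `overlap_factor` times
#' the batch median.  Each survivor is replaced by the perfect square mask
#' built from its Feret dimensions (side = minimum Feret, rotated so its
#' diagonal lies along the maximum-Feret direction).
#'
#' @param components List of `cryo_component` objects.
#' @param ratio_band Acceptable `min/max` Feret ratio interval.
#' @param overlap_factor Multiple of the batch median max-Feret beyond
#'   which a component counts as overlapped.
#' @return Tibble with Feret measures, rejection reasons, `good` flag, the
#'   original components and, for good rows, the replacement square mask
#'   (list-column `square_mask`, in the component's local frame).
#' @export
select_good_sideview <- function(components, ratio_band = c(0.6, 0.8),
                                 overlap_factor = 1.5) {
  tbl <- components_tbl(components)
  if (!nrow(tbl)) {
    tbl$max_diameter <- double(); tbl$min_diameter <- double()
    tbl$ratio <- double(); tbl$good <- logical()
    tbl$square_mask <- list()
    return(tbl)
  }
  fer <- dplyr::bind_rows(lapply(components, feret_diameters))
  tbl$max_diameter <- fer$max_diameter
  tbl$min_diameter <- fer$min_diameter
  tbl$max_angle <- fer$max_angle
  tbl$ratio <- tbl$min_diameter / tbl$max_diameter
  square_shape <- tbl$ratio >= ratio_band[1] & tbl$ratio <= ratio_band[2] &
    tbl$area >= 0.8 * tbl$min_diameter^2
  med <- stats::median(tbl$max_diameter[square_shape])
  overlapped <- tbl$max_diameter > overlap_factor *
    (if (is.na(med)) Inf else med)
  tbl$good <- square_shape & !overlapped
  tbl$square_mask <- lapply(seq_len(nrow(tbl)), function(i) {
    if (!tbl$good[i]) return(NULL)
    side <- tbl$min_diameter[i]
    theta <- (tbl$max_angle[i] - 45) * pi / 180
    h <- nrow(components[[i]]$mask); w <- ncol(components[[i]]$mask)
    ccx <- tbl$cx[i] - tbl$x[i]; ccy <- tbl$cy[i] - tbl$y[i]
    yy <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
    xr <- (xx - ccx) * cos(theta) + (yy - ccy) * sin(theta)
    yr <- -(xx - ccx) * sin(theta) + (yy - ccy) * cos(theta)
    abs(xr) <= side / 2 & abs(yr) <= side / 2
  })
  tbl
}

#' Good/bad selection of irregular (complex) particles
#'
#' Computes the batch mean component area and keeps a component iff its
#' area is at least `area_frac` of the mean (rejecting fragments) and, when
#' patch geometry is supplied, its centroid falls within the central half
#' of its patch.
#'
#' @param components List of `cryo_component` objects.
#' @param patch_centers Optional tibble with `cx`, `cy` (one row per
#'   component): the centers of the training patches the components will
#'   be cropped into.
#' @param patch_size Patch side, pixels (needed with `patch_centers`).
#' @param area_frac Minimum fraction of the mean area.
#' @return Tibble with `area`, `mean_area`, `centered`, `good` and the
#'   components.
#' @export
select_good_irregular <- function(components, patch_centers = NULL,
                                  patch_size = NULL, area_frac = 0.7) {
  tbl <- components_tbl(components)
  if (!nrow(tbl)) {
    tbl$mean_area <- double(); tbl$centered <- logical()
    tbl$good <- logical()
    return(tbl)
  }
  tbl$mean_area <- mean(tbl$area)
  tbl$centered <- TRUE
  if (!is.null(patch_centers)) {
    stopifnot(!is.null(patch_size), nrow(patch_centers) == nrow(tbl))
    tbl$centered <- abs(tbl$cx - patch_centers$cx) <= patch_size / 4 &
      abs(tbl$cy - patch_centers$cy) <= patch_size / 4
  }
  tbl$good <- tbl$area >= area_frac * tbl$mean_area & tbl$centered
  tbl
}

#' Harvest background and negative training samples
#'
#' Background samples are random fixed-size crops whose boxes intersect no
#' particle box; negative samples are crops centered on the provided bad
#' components.  When fewer than `n` disjoint background crops can be
#' found, the shorter result carries a `warning` attribute.
#'
#' @param m Micrograph matrix.
#' @param particle_boxes Tibble with `x`, `y`, `w`, `h` of known particles
#'   (may be empty).
#' @param n Number of background crops wanted.
#' @param patch_size Crop side, pixels.
#' @param seed Integer seed.
#' @param bad_components Optional list of components whose centroids seed
#'   `"negative"` crops.
#' @return Tibble with `x`, `y`, `w`, `h`, `label` and a `patch`
#'   list-column.
#' @export
harvest_negatives <- function(m, particle_boxes, n, patch_size, seed = 1,
                              bad_components = NULL) {
  set.seed(seed)
  h <- nrow(m); w <- ncol(m)
  stopifnot(patch_size <= min(h, w))
  got <- list()
  attempts <- 0
  while (length(got) < n && attempts < 200 * max(n, 1)) {
    attempts <- attempts + 1
    x <- sample.int(w - patch_size + 1, 1) - 1L
    y <- sample.int(h - patch_size + 1, 1) - 1L
    if (nrow(particle_boxes)) {
      overlap <- particle_boxes$x < x + patch_size &
        particle_boxes$x + particle_boxes$w > x &
        particle_boxes$y < y + patch_size &
        particle_boxes$y + particle_boxes$h > y
      if (any(overlap)) next
    }
    got[[length(got) + 1]] <- tibble::tibble(x = x, y = y, w = patch_size,
                                             h = patch_size,
                                             label = "background")
  }
  bg <- if (length(got)) dplyr::bind_rows(got) else
    tibble::tibble(x = integer(), y = integer(), w = integer(),
                   h = integer(), label = character())
  neg <- NULL
  if (length(bad_components)) {
    ctbl <- components_tbl(bad_components)
    crops <- extract_particles(m, ctbl[, c("cx", "cy")], patch_size)
    if (nrow(crops))
      neg <- tibble::tibble(x = crops$x, y = crops$y, w = patch_size,
                            h = patch_size, label = "negative")
  }
  out <- dplyr::bind_rows(bg, neg)
  out$patch <- purrr::map2(out$x, out$y,
                           function(xi, yi) crop_box(m, xi, yi,
                                                     patch_size, patch_size))
  if (nrow(bg) < n)
    attr(out, "warning") <- sprintf(
      "only %d of %d background crops found", nrow(bg), n)
  out
}

#' Expand a sample by right-angle rotations
#'
#' Returns the original patch plus its 90, 180 and 270 degree rotations
#' (three additional samples), labels preserved.
#'
#' @param patch Square patch matrix.
#' @param label Class label carried through.
#' @return Tibble with 4 rows: `patch` list-column, `label`, `rotation`.
#' @export
augment_rotations <- function(patch, label = NA_character_) {
  if (nrow(patch) != ncol(patch))
    stop("rotation augmentation requires square patches", call. = FALSE)
  r90 <- rotate90(patch)
  r180 <- rotate90(r90)
  r270 <- rotate90(r180)
  tibble::tibble(patch = list(patch, r90, r180, r270),
                 label = label, rotation = c(0, 90, 180, 270))
}

# Counterclockwise quarter-turn.
rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Balance classes and split into train / validation / test
#'
#' Each class is brought to exactly `per_class_target` samples: classes
#' above the target are randomly subsampled; classes below are expanded by
#' right-angle rotations first and subsampled after (an error names any
#' class that still falls short).  Each class is then split 80/20 into
#' (train+validation)/test and the first part 80/20 again into
#' train/validation, flooring the 80% side so that a target of 1500 yields
#' exactly 960 / 240 / 300.
#'
#' @param samples Tibble with at least `patch` (list-column) and `label`;
#'   a `rotation` column is added if absent.
#' @param per_class_target Samples per class after balancing.
#' @param seed Integer seed for subsampling and the split.
#' @return A `cryo_dataset_split`: the balanced tibble with a `split`
#'   column in `{"train", "val", "test"}`.
#' @export
balance_and_split <- function(samples, per_class_target, seed = 1) {
  set.seed(seed)
  if (!"rotation" %in% names(samples)) samples$rotation <- 0
  out <- list()
  for (cls in sort(unique(samples$label))) {
    sub <- samples[samples$label == cls, , drop = FALSE]
    if (nrow(sub) < per_class_target) {
      aug <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
        a <- augment_rotations(sub$patch[[i]], cls)
        a$source <- i
        a
      }))
      sub <- aug
    }
    if (nrow(sub) < per_class_target)
      stop("class '", cls, "' has only ", nrow(sub),
           " samples after rotation augmentation; target ",
           per_class_target, call. = FALSE)
    sub <- sub[sample.int(nrow(sub), per_class_target), , drop = FALSE]
    n <- per_class_target
    n_trainval <- floor(0.8 * n)
    n_train <- floor(0.8 * n_trainval)
    idx <- sample.int(n)
    split <- character(n)
    split[idx[seq_len(n_train)]] <- "train"
    split[idx[(n_train + 1):n_trainval]] <- "val"
    split[idx[(n_trainval + 1):n]] <- "test"
    sub$split <- split
    out[[cls]] <- sub
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("cryo_dataset_split", class(res))
  attr(res, "per_class_target") <- per_class_target
  attr(res, "seed") <- seed
  res
}
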