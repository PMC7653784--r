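#' Choose the micrograph scaling operation and factor
#'
#' Candidate factors are multiples of `step` (> 1 for up-scaling when the
#' average particle is smaller than the sliding window, < 1 for
#' down-scaling when it is larger).  The chosen factor maximizes the
#' rescaled particle size subject to it not exceeding the window
#' ("slightly smaller than the sliding window"); sizes are rounded half
#' up.  When no candidate satisfies the bound - e.g. an average particle
#' of 221 px against a 227 px window, where even the smallest up factor
#' 1.125 overshoots to 249 - no scaling is performed.
#'
#' @param avg_particle Average detected particle size, pixels.
#' @param window Sliding-window (network input) size, pixels.
#' @param step Scaling-factor step.
#' @return A tibble with `operation` (`"up"`, `"down"` or `"none"`),
#'   `factor` and `scaled_particle`.
#' @export
select_scaling <- function(avg_particle, window = 227, step = 0.125) {
  stopifnot(avg_particle > 0, window > 0, step > 0)
  none <- tibble::tibble(operation = "none", factor = 1,
                         scaled_particle = avg_particle)
  if (avg_particle == window) return(none)
  if (avg_particle < window) {
    n_max <- ceiling(window / avg_particle / step) + 1
    f <- seq(1 + step, n_max * step + 1, by = step)
    op <- "up"
  } else {
    f <- seq(step, 1 - step, by = step)
    op <- "down"
  }
  scaled <- round_half_up(avg_particle * f)
  ok <- scaled <= window
  if (!any(ok)) return(none)
  best <- which(ok)[which.max(scaled[ok])]
  tibble::tibble(operation = op, factor = f[best],
                 scaled_particle = scaled[best])
}

#' Rescale a micrograph and pad to even dimensions
#'
#' Bilinear rescale by the decision's factor, then zero-padding on the
#' right/bottom so both dimensions are even.
#'
#' @param m Micrograph matrix.
#' @param decision A [select_scaling()] row, or a bare numeric factor.
#' @return Rescaled matrix with attribute `scale_factor`.
#' @export
rescale_and_pad <- function(m, decision) {
  factor <- if (is.numeric(decision)) decision else decision$factor
  out <- m
  if (factor != 1) {
    nh <- round_half_up(nrow(m) * factor)
    nw <- round_half_up(ncol(m) * factor)
    out <- EBImage::resize(m, w = nh, h = nw, filter = "bilinear")
    out <- matrix(as.numeric(out), nh, nw)
  }
  if (nrow(out) %% 2 == 1) out <- rbind(out, 0)
  if (ncol(out) %% 2 == 1) out <- cbind(out, 0)
  attr(out, "scale_factor") <- factor
  out
}

#' Score every sliding-window position with the classifier
#'
#' Scans the micrograph from the top-left to the bottom-right corner with
#' a constant step, scoring each window by [predict_patch()].
#'
#' @param m Preprocessed micrograph matrix.
#' @param fit A `cryo_cnn_fit` (or bare `cryo_cnn`).
#' @param window Window size; defaults to the network input size.
#' @param stride Step between window positions (default `window / 4`).
#' @return A `cryo_score_map`: list with `scores` array
#'   `(ny, nx, n_classes)`, the 0-based window origins `x0`, `y0`,
#'   `window`, `stride` and `class_names`.
#' @export
sliding_window_scores <- function(m, fit, window = NULL, stride = NULL) {
  net <- if (inherits(fit, "cryo_cnn_fit")) fit$net else fit
  window <- window %||% net$input_size
  stride <- stride %||% max(1, round(window / 4))
  if (window > min(dim(m)))
    stop("window (", window, ") exceeds micrograph dimensions", call. = FALSE)
  x0 <- seq(0, ncol(m) - window, by = stride)
  y0 <- seq(0, nrow(m) - window, by = stride)
  nc <- length(net$class_names)
  scores <- array(NA_real_, c(length(y0), length(x0), nc))
  for (j in seq_along(x0)) {
    for (i in seq_along(y0)) {
      patch <- crop_box(m, x0[j], y0[i], window, window)
      scores[i, j, ] <- predict_patch(net, patch)
    }
  }
  structure(list(scores = scores, x0 = x0, y0 = y0, window = window,
                 stride = stride, class_names = net$class_names),
            class = "cryo_score_map")
}

#' Clean a score map into particle candidates
#'
#' Thresholds the score grid of one particle class, 8-connects
#' above-threshold positions whose scores differ by at most
#' `closeness_tol`, drops connected regions larger than `max_region_area`
#' grid cells (smeared responses over ice or carbon are the usual cause),
#' and emits one candidate per surviving region at its maximum-score
#' position.
#'
#' @param sm A `cryo_score_map`.
#' @param particle_class Class name to extract candidates for.
#' @param score_threshold Minimum class probability.
#' @param closeness_tol Maximum score difference for two neighboring
#'   positions to be connected.
#' @param max_region_area Region-size cutoff in grid cells; defaults to
#'   `2 * (window / stride)^2`.
#' @return Tibble of candidates: `x`, `y`, `w`, `h`, `cx`, `cy`, `score`,
#'   `label`.
#' @export
clean_score_map <- function(sm, particle_class, score_threshold = 0.5,
                            closeness_tol = 0.2, max_region_area = NULL) {
  max_region_area <- max_region_area %||%
    (2 * (sm$window / sm$stride)^2)
  ci <- match(particle_class, sm$class_names)
  if (is.na(ci)) stop("unknown class '", particle_class, "'", call. = FALSE)
  g <- sm$scores[, , ci, drop = TRUE]
  if (is.null(dim(g))) g <- matrix(g, length(sm$y0), length(sm$x0))
  above <- g >= score_threshold
  empty <- tibble::tibble(x = double(), y = double(), w = double(),
                          h = double(), cx = double(), cy = double(),
                          score = double(), label = character())
  if (!any(above)) return(empty)
  cells <- which(above)
  n <- length(cells)
  pos <- arrayInd(cells, dim(g))
  cell_id <- matrix(0L, nrow(g), ncol(g))
  cell_id[cells] <- seq_len(n)
  parent <- uf_new(n)
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  for (s in seq_len(nrow(shifts))) {
    ni <- pos[, 1] + shifts[s, 1]
    nj <- pos[, 2] + shifts[s, 2]
    ok <- ni >= 1 & ni <= nrow(g) & nj >= 1 & nj <= ncol(g)
    ok[ok] <- above[cbind(ni[ok], nj[ok])] &
      abs(g[pos[ok, , drop = FALSE]] -
          g[cbind(ni[ok], nj[ok])]) <= closeness_tol
    for (i in which(ok))
      parent <- uf_union(parent, i, cell_id[ni[i], nj[i]])
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  out <- list()
  for (r in unique(root)) {
    members <- which(root == r)
    if (length(members) > max_region_area) next
    scores_m <- g[cells[members]]
    top <- members[which.max(scores_m)]
    out[[length(out) + 1]] <- tibble::tibble(
      x = sm$x0[pos[top, 2]], y = sm$y0[pos[top, 1]],
      w = sm$window, h = sm$window,
      cx = sm$x0[pos[top, 2]] + sm$window / 2,
      cy = sm$y0[pos[top, 1]] + sm$window / 2,
      score = max(scores_m), label = particle_class)
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Intersection over union of bounding boxes
#'
#' Boxes use the half-open `[x, x + w) x [y, y + h)` convention, so areas
#' are `w * h` exactly.  Vectorized over the first box set against a
#' single second box, or elementwise when both have equal length.
#'
#' @param ax,ay,aw,ah First box (vectors allowed).
#' @param bx,by,bw,bh Second box.
#' @return Numeric IoU in `[0, 1]`.
#' @export
box_iou <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  ix <- pmax(0, pmin(ax + aw, bx + bw) - pmax(ax, bx))
  iy <- pmax(0, pmin(ay + ah, by + bh) - pmax(ay, by))
  inter <- ix * iy
  uni <- aw * ah + bw * bh - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Greedy non-maximum suppression
#'
#' Per class: sort candidates by score (descending; ties broken by
#' ascending `x`, then `y`), keep the best, discard every remaining box
#' whose IoU with it reaches `iou_threshold`, repeat until no candidates
#' remain.
#'
#' @param candidates Tibble with `x`, `y`, `w`, `h`, `score`, `label`.
#' @param iou_threshold Overlap at or above which a box is suppressed.
#' @return The surviving subset, in keep order.
#' @export
nms <- function(candidates, iou_threshold = 0.3) {
  if (!nrow(candidates)) return(candidates)
  out <- list()
  for (cls in unique(candidates$label)) {
    cand <- candidates[candidates$label == cls, , drop = FALSE]
    cand <- cand[order(-cand$score, cand$x, cand$y), , drop = FALSE]
    keep <- logical(nrow(cand))
    alive <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (i < nrow(cand)) {
        rest <- which(alive & seq_len(nrow(cand)) > i)
        if (length(rest)) {
          ious <- box_iou(cand$x[rest], cand$y[rest], cand$w[rest],
                          cand$h[rest], cand$x[i], cand$y[i], cand$w[i],
                          cand$h[i])
          alive[rest[ious >= iou_threshold]] <- FALSE
        }
      }
    }
    out[[cls]] <- cand[keep, , drop = FALSE]
  }
  dplyr::bind_rows(out)
}

#' Fully automated particle picking in one micrograph
#'
#' Composes the testing pipeline: scaling decision from the average
#' particle size, bilinear rescale and even-dimension padding,
#' preprocessing chain, sliding-window scoring by the trained classifier,
#' score-map cleaning, per-class non-maximum suppression, and mapping of
#' the kept boxes back to original-micrograph coordinates (division by
#' the scale factor).
#'
#' @param m Raw micrograph matrix.
#' @param fit A `cryo_cnn_fit`.
#' @param avg_particle Average particle size from the Stage-1 detections,
#'   pixels.
#' @param particle_classes Class names treated as particles (default: all
#'   classes except `"background"` and `"negative"`).
#' @param window,stride Sliding-window size (default: network input) and
#'   step (default `window / 4`).
#' @param score_threshold,closeness_tol,max_region_area Passed to
#'   [clean_score_map()].
#' @param iou_threshold Passed to [nms()].
#' @param params Preprocessing parameters.
#' @param scale_step Scaling-factor step.
#' @param micrograph_id Identifier recorded in the output.
#' @return Tibble of picks in original coordinates: `micrograph_id`, `x`,
#'   `y`, `w`, `h`, `cx`, `cy`, `score`, `label`.
#' @export
pick_particles <- function(m, fit, avg_particle,
                           particle_classes = NULL, window = NULL,
                           stride = NULL, score_threshold = 0.5,
                           closeness_tol = 0.2, max_region_area = NULL,
                           iou_threshold = 0.3,
                           params = preprocess_params(),
                           scale_step = 0.125, micrograph_id = "micrograph") {
  net <- if (inherits(fit, "cryo_cnn_fit")) fit$net else fit
  window <- window %||% net$input_size
  particle_classes <- particle_classes %||%
    setdiff(net$class_names, c("background", "negative"))
  decision <- select_scaling(avg_particle, window, scale_step)
  scaled <- rescale_and_pad(m, decision)
  pre <- preprocess_chain(scaled, params)
  sm <- sliding_window_scores(pre, net, window, stride)
  cands <- dplyr::bind_rows(lapply(particle_classes, function(cls)
    clean_score_map(sm, cls, score_threshold, closeness_tol,
                    max_region_area)))
  kept <- nms(cands, iou_threshold)
  if (!nrow(kept))
    return(tibble::tibble(micrograph_id = character(), x = double(),
                          y = double(), w = double(), h = double(),
                          cx = double(), cy = double(), score = double(),
                          label = character()))
  f <- decision$factor
  tibble::tibble(micrograph_id = micrograph_id,
                 x = kept$x / f, y = kept$y / f,
                 w = kept$w / f, h = kept$h / f,
                 cx = kept$cx / f, cy = kept$cy / f,
                 score = kept$score, label = kept$label)
}
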