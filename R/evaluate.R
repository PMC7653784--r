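#' Match picks to ground truth by center distance
#'
#' Greedy one-to-one matching over all pick/truth pairs in ascending
#' center distance: a pick matched within `match_radius` is a true
#' positive, an unmatched pick a false positive, an unmatched truth
#' particle a false negative.  True negatives are undefined for detection
#' and reported as `NA`.
#'
#' @param picks Tibble with centers `cx`, `cy` (e.g. from
#'   [pick_particles()]).
#' @param truth Tibble with centers `cx`, `cy`.
#' @param match_radius Maximum center distance for a match, pixels.
#' @return Tibble with one row: `TP`, `FP`, `FN`, `TN` (`NA`).
#' @export
match_picks <- function(picks, truth, match_radius) {
  np <- nrow(picks); nt <- nrow(truth)
  if (np == 0 || nt == 0)
    return(tibble::tibble(TP = 0L, FP = np, FN = nt, TN = NA_integer_))
  d <- outer(picks$cx, truth$cx, "-")^2 + outer(picks$cy, truth$cy, "-")^2
  ok <- which(d <= match_radius^2, arr.ind = TRUE)
  tp <- 0L
  if (nrow(ok)) {
    ord <- order(d[ok])
    used_p <- logical(np); used_t <- logical(nt)
    for (i in ord) {
      p <- ok[i, 1]; t <- ok[i, 2]
      if (!used_p[p] && !used_t[t]) {
        used_p[p] <- TRUE; used_t[t] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  tibble::tibble(TP = tp, FP = np - tp, FN = nt - tp, TN = NA_integer_)
}

#' Detection metrics from matched counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1.
#' Two accuracies are reported: `accuracy_tp_only = TP/(TP+FP+TN+FN)`
#' (a TP-only numerator, kept because some picking evaluations print
#' accuracy this way) and the standard
#' `accuracy_std = (TP+TN)/(TP+FP+TN+FN)`; both treat a missing TN as 0
#' and are mainly meaningful for patch classification, not detection.
#' Any division by zero yields 0 and sets `zero_division`.
#'
#' @param counts Tibble/list with `TP`, `FP`, `FN` and optionally `TN`.
#' @return One-row tibble: `precision`, `recall`, `f1`, `accuracy_tp_only`,
#'   `accuracy_std`, `zero_division`.
#' @export
detection_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  tn <- counts$TN %||% NA_integer_
  tn0 <- ifelse(is.na(tn), 0L, tn)
  zd <- FALSE
  div <- function(a, b) {
    if (b == 0) { zd <<- TRUE; return(0) }
    a / b
  }
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else { zd <- TRUE; 0 }
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 accuracy_tp_only = div(tp, tp + fp + tn0 + fn),
                 accuracy_std = div(tp + tn0, tp + fp + tn0 + fn),
                 zero_division = zd)
}

#' Precision-recall curve over score thresholds
#'
#' Sweeps the decision threshold over every distinct pick score, matching
#' at each threshold by [match_picks()]; as the threshold rises, recall is
#' non-increasing.  The area is the trapezoid over recall, anchored at
#' recall 0 with the precision of the strictest threshold; duplicate
#' recalls keep their best precision.
#'
#' @param picks Tibble with `cx`, `cy`, `score`.
#' @param truth Tibble with `cx`, `cy`; must be non-empty.
#' @param match_radius Matching radius, pixels.
#' @return A `cryo_pr_curve`: tibble of `threshold`, `precision`,
#'   `recall` with attribute `area`.
#' @export
pr_curve <- function(picks, truth, match_radius) {
  if (!nrow(truth))
    stop("empty ground truth: recall is undefined", call. = FALSE)
  thr <- sort(unique(picks$score))
  rows <- lapply(thr, function(t) {
    cnt <- match_picks(picks[picks$score >= t, , drop = FALSE], truth,
                       match_radius)
    met <- detection_metrics(cnt)
    tibble::tibble(threshold = t, precision = met$precision,
                   recall = met$recall)
  })
  out <- dplyr::bind_rows(rows)
  pts <- rbind(
    data.frame(recall = 0, precision = out$precision[nrow(out)]),
    data.frame(recall = out$recall, precision = out$precision))
  pts <- stats::aggregate(precision ~ recall, pts, max)
  pts <- pts[order(pts$recall), ]
  area <- if (nrow(pts) > 1)
    sum(diff(pts$recall) *
        (utils::head(pts$precision, -1) + utils::tail(pts$precision, -1)) / 2)
  else 0
  structure(out, area = area, class = c("cryo_pr_curve", class(out)))
}

#' KLH benchmark bookkeeping
#'
#' Published composition of the keyhole limpet hemocyanin (KLH) benchmark
#' commonly used to compare particle pickers: 80 micrographs split 80/20
#' into training and testing, with per-view particle counts.  Useful for
#' sizing evaluations against this standard dataset.
#'
#' @return Tibble with columns `view`, `split`, `n_particles`,
#'   `n_micrographs`.
#' @export
klh_benchmark <- function() {
  tibble::tibble(
    view = rep(c("top_view", "side_view"), each = 2),
    split = rep(c("training", "testing"), 2),
    n_particles = c(853, 293, 725, 252),
    n_micrographs = rep(c(60, 20), 2))
}
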