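# Shared fixtures and independent reference implementations ("oracles").
# Everything is generated in code; the trained toy classifier is built
# once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

toy_fit <- function() {
  if (is.null(.fixtures$fit)) {
    ds <- build_synthetic_dataset(n_per_class = 200, seed = 1)
    split <- balance_and_split(ds, 200, seed = 1)
    .fixtures$split <- split
    .fixtures$fit <- train_cnn(split, epochs = 20, batch_size = 8,
                               learning_rate = 0.3, lr_decay = 0.3,
                               seed = 1)
  }
  .fixtures$fit
}

toy_split <- function() {
  toy_fit()
  .fixtures$split
}

# Naive triple-loop convolution with sigmoid, the reference for
# conv_forward.
naive_conv <- function(x, W, b, k, stride, pad, channels, filters) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  oh <- floor((d[1] + 2 * pad - k) / stride) + 1
  ow <- floor((d[2] + 2 * pad - k) / stride) + 1
  out <- array(0, c(oh, ow, filters))
  for (f in seq_len(filters)) {
    Wa <- array(W[, f], c(k, k, channels))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      s <- 0
      for (dy in seq_len(k)) for (dx in seq_len(k)) for (c in seq_len(channels))
        s <- s + xp[(i - 1) * stride + dy, (j - 1) * stride + dx, c] *
          Wa[dy, dx, c]
      out[i, j, f] <- 1 / (1 + exp(-(s + b[f])))
    }
  }
  out
}

# Brute-force window scan, the reference for maxpool_forward.
naive_pool <- function(x, k, stride) {
  d <- dim(x)
  oh <- floor((d[1] - k) / stride) + 1
  ow <- floor((d[2] - k) / stride) + 1
  out <- array(0, c(oh, ow, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(oh)) for (j in seq_len(ow))
    out[i, j, c] <- max(x[(i - 1) * stride + seq_len(k),
                          (j - 1) * stride + seq_len(k), c])
  out
}

# Quadratic reference NMS with the same tie rule (score desc, x asc,
# y asc).
naive_nms <- function(cand, thr) {
  out <- list()
  for (cls in unique(cand$label)) {
    cc <- cand[cand$label == cls, , drop = FALSE]
    cc <- cc[order(-cc$score, cc$x, cc$y), , drop = FALSE]
    kept <- cc[0, ]
    while (nrow(cc)) {
      top <- cc[1, , drop = FALSE]
      kept <- rbind(kept, top)
      if (nrow(cc) == 1) break
      rest <- cc[-1, , drop = FALSE]
      io <- vapply(seq_len(nrow(rest)), function(i)
        box_iou(rest$x[i], rest$y[i], rest$w[i], rest$h[i],
                top$x, top$y, top$w, top$h), numeric(1))
      cc <- rest[io < thr, , drop = FALSE]
    }
    out[[cls]] <- kept
  }
  dplyr::bind_rows(out)
}

# Full-grid circular Hough accumulator: for every center and radius,
# count edge pixels whose distance is within the voting annulus.
brute_cht <- function(mask, r_min, r_max, vote_frac = 0.5) {
  edge <- mask & !(mask &
    rbind(FALSE, mask[-nrow(mask), ]) & rbind(mask[-1, ], FALSE) &
    cbind(FALSE, mask[, -ncol(mask)]) & cbind(mask[, -1], FALSE))
  ep <- which(edge, arr.ind = TRUE)
  best <- NULL
  for (r in seq(ceiling(r_min), floor(r_max))) {
    span <- (-(r + 1)):(r + 1)
    dk <- sqrt(outer(span^2, span^2, "+"))
    n_full <- sum(abs(dk - r) <= 0.5)
    for (cy in seq_len(nrow(mask))) for (cx in seq_len(ncol(mask))) {
      d <- sqrt((ep[, 1] - cy)^2 + (ep[, 2] - cx)^2)
      votes <- sum(abs(d - r) <= 1)
      score <- votes / n_full
      if (score >= vote_frac &&
          (is.null(best) || score > best$score))
        best <- list(cx = cx - 1, cy = cy - 1, r = r, score = score)
    }
  }
  best
}

# Independent Feret reference: max over all pairwise corner distances,
# min over fine-angle projections of every corner (no hull).
naive_feret <- function(component) {
  px <- component$pixels
  cx <- c(px[, "x"], px[, "x"] + 1, px[, "x"], px[, "x"] + 1)
  cy <- c(px[, "y"], px[, "y"], px[, "y"] + 1, px[, "y"] + 1)
  dmax <- max(stats::dist(cbind(cx, cy)))
  ang <- seq(0, 179, by = 1) * pi / 180
  dmin <- min(vapply(ang, function(a) {
    pr <- cx * cos(a) + cy * sin(a)
    max(pr) - min(pr)
  }, numeric(1)))
  list(max_diameter = dmax, min_diameter = dmin)
}

# Independent contour length via EBImage's own contour tracer.
ocontour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(mask * 1)[[1]]
  if (nrow(oc) == 1) return(1)
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  sum(sqrt(rowSums(d^2)))
}

random_boxes <- function(n, side = 200, wmax = 40, labels = "p") {
  tibble::tibble(x = runif(n, 0, side), y = runif(n, 0, side),
                 w = runif(n, 5, wmax), h = runif(n, 5, wmax),
                 score = runif(n), label = sample(labels, n, replace = TRUE))
}
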