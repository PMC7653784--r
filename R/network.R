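#' Layer chains for the particle classification network
#'
#' `"full"` is the 13-layer architecture used for 227 x 227 x 3 crops:
#' five convolutional layers (96@11 stride 4, 256@5 pad 2, 384@3 pad 1,
#' 384@3 pad 1, 256@3 pad 1), three 3x3 stride-2 max-pooling layers, two
#' 4096-unit fully connected layers and a softmax output.  Its spatial
#' dimension chain from 227 is 55, 27, 27, 13, 13, 13, 13, 6.
#' `"toy"` is a reduced two-block network for 32 x 32 grayscale patches,
#' suitable for desk-scale experiments and tests.
#'
#' @param preset `"full"` or `"toy"`.
#' @param class_count Number of output classes.
#' @return A list of layer specifications plus input geometry, suitable
#'   for [build_network()].
#' @export
network_preset <- function(preset = c("full", "toy"), class_count = 4) {
  preset <- match.arg(preset)
  if (preset == "full") {
    list(input_size = 227, channels = 3, layers = list(
      list(type = "conv", filters = 96, k = 11, stride = 4, pad = 0),
      list(type = "pool", k = 3, stride = 2),
      list(type = "conv", filters = 256, k = 5, stride = 1, pad = 2),
      list(type = "pool", k = 3, stride = 2),
      list(type = "conv", filters = 384, k = 3, stride = 1, pad = 1),
      list(type = "conv", filters = 384, k = 3, stride = 1, pad = 1),
      list(type = "conv", filters = 256, k = 3, stride = 1, pad = 1),
      list(type = "pool", k = 3, stride = 2),
      list(type = "fc", units = 4096),
      list(type = "fc", units = 4096),
      list(type = "fc", units = class_count, activation = "softmax")))
  } else {
    list(input_size = 32, channels = 1, layers = list(
      list(type = "conv", filters = 8, k = 5, stride = 1, pad = 0),
      list(type = "pool", k = 2, stride = 2),
      list(type = "conv", filters = 16, k = 3, stride = 1, pad = 0),
      list(type = "pool", k = 2, stride = 2),
      list(type = "fc", units = 64),
      list(type = "fc", units = class_count, activation = "softmax")))
  }
}

#' Build a classification network with seeded initial parameters
#'
#' Walks the layer chain, checks the dimension arithmetic (`floor((n + 2
#' pad - k) / stride) + 1` per conv/pool), precomputes the patch-index
#' tables used by the convolution, and initializes weights.  The default
#' initialization is symmetric fan-scaled uniform
#' (`U(-s, s), s = sqrt(6 / (fan_in + fan_out))`); `init = "uniform01"`
#' reproduces plain `U(0, 1)` weights, which saturate the sigmoid
#' activations and are kept only for comparison.
#'
#' @param arch A [network_preset()] result (or a list with the same
#'   structure).
#' @param class_names Character vector of class labels; its length must
#'   match the output layer.
#' @param seed Integer seed for the initialization.
#' @param init `"fan"` or `"uniform01"`.
#' @param activation Hidden activation, `"sigmoid"` (default) only.
#' @return An object of class `cryo_cnn`.
#' @export
build_network <- function(arch, class_names, seed = 1, init = c("fan",
                                                                "uniform01"),
                          activation = "sigmoid") {
  init <- match.arg(init)
  set.seed(seed)
  h <- w <- arch$input_size
  c_in <- arch$channels
  layers <- list()
  flat <- NULL
  for (li in seq_along(arch$layers)) {
    sp <- arch$layers[[li]]
    if (sp$type == "conv") {
      if (is.null(flat)) {
        oh <- floor((h + 2 * sp$pad - sp$k) / sp$stride) + 1
        ow <- floor((w + 2 * sp$pad - sp$k) / sp$stride) + 1
        if (oh < 1 || ow < 1)
          stop("layer ", li, " (conv): output size ", oh, " x ", ow,
               " invalid for input ", h, " x ", w, call. = FALSE)
        kkc <- sp$k^2 * c_in
        s <- sqrt(6 / (kkc + sp$filters))
        W <- if (init == "fan")
          matrix(stats::runif(kkc * sp$filters, -s, s), kkc, sp$filters)
        else matrix(stats::runif(kkc * sp$filters), kkc, sp$filters)
        lay <- list(type = "conv", k = sp$k, stride = sp$stride,
                    pad = sp$pad, filters = sp$filters,
                    activation = activation,
                    in_h = h, in_w = w, in_c = c_in, out_h = oh, out_w = ow,
                    W = W, b = numeric(sp$filters),
                    idx = im2col_idx(h, w, c_in, sp$k, sp$stride, sp$pad))
        h <- oh; w <- ow; c_in <- sp$filters
        layers[[length(layers) + 1]] <- lay
      } else stop("conv layer after flatten is not supported", call. = FALSE)
    } else if (sp$type == "pool") {
      oh <- floor((h - sp$k) / sp$stride) + 1
      ow <- floor((w - sp$k) / sp$stride) + 1
      if (oh < 1 || ow < 1)
        stop("layer ", li, " (pool): kernel ", sp$k,
             " does not fit input ", h, " x ", w, call. = FALSE)
      layers[[length(layers) + 1]] <-
        list(type = "pool", k = sp$k, stride = sp$stride,
             mode = sp$mode %||% "max",
             in_h = h, in_w = w, in_c = c_in, out_h = oh, out_w = ow)
      h <- oh; w <- ow
    } else if (sp$type == "fc") {
      if (is.null(flat)) flat <- h * w * c_in
      act <- sp$activation %||% activation
      s <- sqrt(6 / (flat + sp$units))
      W <- if (init == "fan")
        matrix(stats::runif(flat * sp$units, -s, s), flat, sp$units)
      else matrix(stats::runif(flat * sp$units), flat, sp$units)
      layers[[length(layers) + 1]] <-
        list(type = "fc", units = sp$units, activation = act,
             in_units = flat, W = W, b = numeric(sp$units))
      flat <- sp$units
    } else stop("unknown layer type '", sp$type, "'", call. = FALSE)
  }
  last <- layers[[length(layers)]]
  if (last$type != "fc" || last$activation != "softmax")
    stop("the final layer must be a softmax fc layer", call. = FALSE)
  if (last$units != length(class_names))
    stop("output layer has ", last$units, " units but ",
         length(class_names), " class names were given", call. = FALSE)
  structure(list(layers = layers, input_size = arch$input_size,
                 channels = arch$channels, class_names = class_names,
                 seed = seed),
            class = "cryo_cnn")
}

# im2col index table: idx[patch, column] is the linear index into the
# zero-padded (hp, wp, c) input array; columns are ordered (dy, dx,
# channel) to match the flattened kernel layout.
im2col_idx <- function(h, w, c, k, stride, pad) {
  hp <- h + 2 * pad; wp <- w + 2 * pad
  oh <- floor((hp - k) / stride) + 1
  ow <- floor((wp - k) / stride) + 1
  py <- seq(0, oh - 1) * stride + 1
  px <- seq(0, ow - 1) * stride + 1
  grid <- expand.grid(py = py, px = px)  # py fastest = column-major output
  lin0 <- (grid$px - 1) * hp + grid$py
  offs <- as.vector(vapply(seq_len(c) - 1, function(ci)
    vapply(seq_len(k) - 1, function(dx)
      ci * hp * wp + dx * hp + seq_len(k) - 1, numeric(k)),
    matrix(numeric(1), k, k)))
  idx <- outer(lin0, offs, "+")
  storage.mode(idx) <- "integer"
  attr(idx, "dims") <- c(oh = oh, ow = ow, hp = hp, wp = wp)
  idx
}

#' Sigmoid activation
#'
#' `1 / (1 + exp(-x))`, elementwise, saturating without overflow for
#' large-magnitude inputs.
#'
#' @param x Numeric vector, matrix or array.
#' @return Same shape as `x`, values in `(0, 1)`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  out
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

#' Convolutional layer forward pass
#'
#' Cross-correlates the input feature maps with the layer's shared
#' weights, adds the bias and applies the activation.  Exposed mainly for
#' testing against naive-loop references; [predict_patch()] composes it.
#'
#' @param x Input array `(h, w, channels)`.
#' @param layer A conv layer from a built `cryo_cnn`.
#' @param pre_activation Return the linear response without activation.
#' @return Array `(out_h, out_w, filters)`.
#' @export
conv_forward <- function(x, layer, pre_activation = FALSE) {
  if (!all(dim(x) == c(layer$in_h, layer$in_w, layer$in_c)))
    stop("conv input shape (", paste(dim(x), collapse = " x "),
         ") does not match layer (", layer$in_h, " x ", layer$in_w, " x ",
         layer$in_c, ")", call. = FALSE)
  xp <- pad_array(x, layer$pad)
  X2 <- matrix(xp[layer$idx], nrow(layer$idx), ncol(layer$idx))
  Z <- X2 %*% layer$W
  Z <- Z + matrix(layer$b, nrow(Z), ncol(Z), byrow = TRUE)
  A <- if (pre_activation || layer$activation == "identity") Z else sigmoid(Z)
  array(A, c(layer$out_h, layer$out_w, layer$filters))
}

#' Max-pooling forward pass
#'
#' @param x Input array `(h, w, channels)`.
#' @param kernel,stride Pooling window and step, pixels.
#' @param mode `"max"` (default) or `"mean"`.
#' @return Array `(floor((h - kernel)/stride) + 1, ..., channels)`.
#' @export
maxpool_forward <- function(x, kernel, stride, mode = "max") {
  d <- dim(x)
  if (kernel > d[1] || kernel > d[2])
    stop("pooling kernel (", kernel, ") larger than input (",
         d[1], " x ", d[2], ")", call. = FALSE)
  oh <- floor((d[1] - kernel) / stride) + 1
  ow <- floor((d[2] - kernel) / stride) + 1
  oy <- seq(0, oh - 1) * stride
  ox <- seq(0, ow - 1) * stride
  if (mode == "mean") {
    out <- array(0, c(oh, ow, d[3]))
    for (dy in seq_len(kernel) - 1)
      for (dx in seq_len(kernel) - 1)
        out <- out + x[oy + dy + 1, ox + dx + 1, , drop = FALSE]
    return(out / kernel^2)
  }
  best <- array(-Inf, c(oh, ow, d[3]))
  arg <- array(0L, c(oh, ow, d[3]))
  id <- 0L
  for (dx in seq_len(kernel) - 1) {
    for (dy in seq_len(kernel) - 1) {
      id <- id + 1L
      sl <- x[oy + dy + 1, ox + dx + 1, , drop = FALSE]
      upd <- sl > best
      best[upd] <- sl[upd]
      arg[upd] <- id
    }
  }
  attr(best, "argmax") <- arg
  best
}

# Forward pass through the whole network, optionally caching activations.
forward_net <- function(net, x, keep = FALSE) {
  cache <- if (keep) vector("list", length(net$layers)) else NULL
  flat_done <- FALSE
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    if (lay$type == "conv") {
      xp <- pad_array(x, lay$pad)
      X2 <- matrix(xp[lay$idx], nrow(lay$idx), ncol(lay$idx))
      Z <- X2 %*% lay$W
      Z <- Z + matrix(lay$b, nrow(Z), ncol(Z), byrow = TRUE)
      A <- sigmoid(Z)
      if (keep) cache[[li]] <- list(X2 = X2, A = A)
      x <- array(A, c(lay$out_h, lay$out_w, lay$filters))
    } else if (lay$type == "pool") {
      x <- maxpool_forward(x, lay$k, lay$stride, lay$mode)
      if (keep) cache[[li]] <- list(argmax = attr(x, "argmax"))
      attr(x, "argmax") <- NULL
    } else {
      if (!flat_done) { x <- as.vector(x); flat_done <- TRUE }
      z <- drop(x %*% lay$W) + lay$b
      a <- switch(lay$activation,
                  softmax = { e <- exp(z - max(z)); e / sum(e) },
                  identity = z,
                  sigmoid(z))
      if (keep) cache[[li]] <- list(v_in = x, a = a)
      x <- a
    }
  }
  list(prob = x, cache = cache)
}

# Backward pass; returns per-layer gradients for one sample.
# `dout` is dLoss/dProb-layer-z for softmax (prob - y).
backward_net <- function(net, cache, y_onehot) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dz <- NULL
  dx <- NULL
  for (li in rev(seq_len(L))) {
    lay <- net$layers[[li]]
    if (lay$type == "fc") {
      a <- cache[[li]]$a
      v <- cache[[li]]$v_in
      dz <- if (lay$activation == "softmax") a - y_onehot
      else if (lay$activation == "identity") dx
      else dx * a * (1 - a)
      grads[[li]] <- list(W = outer(v, dz), b = dz)
      dx <- drop(lay$W %*% dz)
    } else if (lay$type == "pool") {
      d_in <- array(0, c(lay$in_h, lay$in_w, lay$in_c))
      dout_arr <- array(dx, c(lay$out_h, lay$out_w, lay$in_c))
      arg <- cache[[li]]$argmax
      oy <- seq(0, lay$out_h - 1) * lay$stride
      ox <- seq(0, lay$out_w - 1) * lay$stride
      id <- 0L
      for (dxo in seq_len(lay$k) - 1) {
        for (dyo in seq_len(lay$k) - 1) {
          id <- id + 1L
          sel <- which(arg == id, arr.ind = TRUE)
          if (nrow(sel)) {
            tgt <- cbind(oy[sel[, 1]] + dyo + 1, ox[sel[, 2]] + dxo + 1,
                         sel[, 3])
            d_in[tgt] <- d_in[tgt] + dout_arr[sel]
          }
        }
      }
      dx <- d_in
    } else { # conv
      A <- cache[[li]]$A
      dA <- matrix(dx, nrow(A), ncol(A))
      dZ <- dA * A * (1 - A)
      grads[[li]] <- list(W = crossprod(cache[[li]]$X2, dZ),
                          b = colSums(dZ))
      dX2 <- dZ %*% t(lay$W)
      hp <- lay$in_h + 2 * lay$pad; wp <- lay$in_w + 2 * lay$pad
      dpad <- numeric(hp * wp * lay$in_c)
      for (j in seq_len(ncol(lay$idx)))
        dpad[lay$idx[, j]] <- dpad[lay$idx[, j]] + dX2[, j]
      dpad <- array(dpad, c(hp, wp, lay$in_c))
      dx <- if (lay$pad > 0)
        dpad[lay$pad + seq_len(lay$in_h), lay$pad + seq_len(lay$in_w), ,
             drop = FALSE]
      else dpad
    }
  }
  grads
}

#' Summed cross-entropy loss with L2 penalty
#'
#' `sum_i sum_c -y_ic log f_c(x_i) + l2_coeff * ||W||_2^2`, with predicted
#' probabilities floored at 1e-12 before the log.
#'
#' @param prob Matrix of predicted probabilities, one row per sample.
#' @param labels One-hot matrix of the same shape.
#' @param net Optional `cryo_cnn` whose weights enter the L2 term.
#' @param l2_coeff Weight of the squared L2 norm of all weights.
#' @return A single number.
#' @export
cross_entropy_loss <- function(prob, labels, net = NULL, l2_coeff = 0) {
  stopifnot(all(dim(prob) == dim(labels)))
  ce <- -sum(labels * log(pmax(prob, 1e-12)))
  if (l2_coeff > 0 && !is.null(net))
    ce <- ce + l2_coeff * sum(vapply(net$layers, function(l)
      if (!is.null(l$W)) sum(l$W^2) else 0, numeric(1)))
  ce
}

#' One stochastic-gradient-descent parameter update
#'
#' Applies `w <- w - (learning_rate / n) * accumulated_gradient` to every
#' weight and bias, the accumulated gradients being sums over the `n`
#' samples of a batch.
#'
#' @param net A `cryo_cnn`.
#' @param grads Accumulated per-layer gradients (as produced internally by
#'   [train_cnn()]).
#' @param learning_rate Step size.
#' @param n Number of samples the gradients were summed over.
#' @param l2_coeff L2 penalty coefficient (adds `2 l2 W` to each weight
#'   gradient).
#' @return The updated network.
#' @export
sgd_step <- function(net, grads, learning_rate, n, l2_coeff = 0) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    if (any(!is.finite(g$W)) || any(!is.finite(g$b)))
      stop("non-finite gradient in layer ", li, call. = FALSE)
    gW <- g$W / n
    if (l2_coeff > 0) gW <- gW + 2 * l2_coeff * net$layers[[li]]$W
    net$layers[[li]]$W <- net$layers[[li]]$W - learning_rate * gW
    net$layers[[li]]$b <- net$layers[[li]]$b - learning_rate * g$b / n
  }
  net
}

patch_to_input <- function(net, patch) {
  if (is.matrix(patch)) patch <- array(patch, c(dim(patch), 1))
  if (dim(patch)[1] != net$input_size || dim(patch)[2] != net$input_size)
    stop("patch is ", dim(patch)[1], " x ", dim(patch)[2],
         " but the network expects ", net$input_size, " x ",
         net$input_size, call. = FALSE)
  if (dim(patch)[3] == 1 && net$channels > 1)
    patch <- array(rep(patch, net$channels),
                   c(dim(patch)[1:2], net$channels))
  patch
}

#' Class probabilities for a single patch
#'
#' Runs the forward pass; grayscale patches are replicated across the
#' network's input channels.  Probabilities are normalized by the softmax
#' output and sum to 1.
#'
#' @param net A `cryo_cnn` or `cryo_cnn_fit`.
#' @param patch Square matrix (or `(h, w, c)` array) matching the input
#'   size.
#' @return Named probability vector over the class names.
#' @export
predict_patch <- function(net, patch) {
  if (inherits(net, "cryo_cnn_fit")) net <- net$net
  x <- patch_to_input(net, patch)
  p <- forward_net(net, x)$prob
  names(p) <- net$class_names
  p
}

one_hot <- function(labels, class_names) {
  m <- matrix(0, length(labels), length(class_names))
  m[cbind(seq_along(labels), match(labels, class_names))] <- 1
  m
}

#' Train the classification network by mini-batch SGD
#'
#' Minimizes the summed cross-entropy objective (with optional L2 weight
#' penalty) by backpropagation and the `w - (eta / n) * sum(grad)` update,
#' with seeded shuffling.  Per-epoch loss and train/validation accuracy
#' are recorded in the returned history.
#'
#' @param split A `cryo_dataset_split` from [balance_and_split()], or any
#'   tibble with `patch`, `label` and `split` columns.
#' @param arch A [network_preset()] architecture; default is the reduced
#'   `"toy"` preset.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial step size eta (the full-scale network is
#'   described with 1e-4; the reduced preset trains comfortably around
#'   0.2-0.5).
#' @param lr_decay Learning-rate decay: epoch e uses
#'   `learning_rate / (1 + lr_decay * (e - 1))`.  0 keeps eta constant.
#' @param l2_coeff L2 penalty coefficient.
#' @param seed Integer seed (initialization and shuffling).
#' @param class_names Optional explicit class ordering.
#' @return A `cryo_cnn_fit`: list with the trained `net`, a `history`
#'   tibble (`epoch`, `loss`, `train_acc`, `val_acc`) and the
#'   configuration.
#' @export
train_cnn <- function(split, arch = NULL, epochs = 20, batch_size = 16,
                      learning_rate = 0.5, lr_decay = 0, l2_coeff = 0,
                      seed = 1, class_names = NULL) {
  stopifnot(epochs >= 1, learning_rate > 0)
  tr <- split[split$split == "train", , drop = FALSE]
  va <- split[split$split == "val", , drop = FALSE]
  if (!nrow(tr)) stop("empty training split", call. = FALSE)
  class_names <- class_names %||% sort(unique(split$label))
  arch <- arch %||% network_preset("toy", length(class_names))
  net <- build_network(arch, class_names, seed = seed)
  xs <- lapply(tr$patch, function(p) patch_to_input(net, p))
  ys <- one_hot(tr$label, class_names)
  vx <- lapply(va$patch, function(p) patch_to_input(net, p))
  vy <- match(va$label, class_names)
  ty <- match(tr$label, class_names)
  n <- length(xs)
  set.seed(seed + 1)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- learning_rate / (1 + lr_decay * (ep - 1))
    ord <- sample.int(n)
    for (b0 in seq(1, n, by = batch_size)) {
      bidx <- ord[b0:min(b0 + batch_size - 1, n)]
      acc_grads <- NULL
      for (i in bidx) {
        fw <- forward_net(net, xs[[i]], keep = TRUE)
        g <- backward_net(net, fw$cache, ys[i, ])
        if (is.null(acc_grads)) acc_grads <- g
        else for (li in seq_along(g)) if (!is.null(g[[li]])) {
          acc_grads[[li]]$W <- acc_grads[[li]]$W + g[[li]]$W
          acc_grads[[li]]$b <- acc_grads[[li]]$b + g[[li]]$b
        }
      }
      net <- sgd_step(net, acc_grads, lr_ep, length(bidx), l2_coeff)
    }
    # Report the loss of the end-of-epoch weights over the training set
    # (the running loss mixes parameter states and wiggles during the
    # plateau-escape phase).
    probs_tr <- lapply(xs, function(x) forward_net(net, x)$prob)
    ep_loss <- -sum(vapply(seq_len(n), function(i)
      sum(ys[i, ] * log(pmax(probs_tr[[i]], 1e-12))), numeric(1)))
    if (l2_coeff > 0)
      ep_loss <- ep_loss + l2_coeff * sum(vapply(net$layers, function(l)
        if (!is.null(l$W)) sum(l$W^2) else 0, numeric(1)))
    pred_tr <- vapply(probs_tr, which.max, integer(1))
    val_acc <- if (length(vx))
      mean(vapply(vx, function(x) which.max(forward_net(net, x)$prob),
                  integer(1)) == vy) else NA_real_
    history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss,
                                    train_acc = mean(pred_tr == ty),
                                    val_acc = val_acc)
  }
  structure(list(net = net, history = dplyr::bind_rows(history),
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate,
                               lr_decay = lr_decay,
                               l2_coeff = l2_coeff, seed = seed)),
            class = "cryo_cnn_fit")
}

#' Spatial dimension chain of a network
#'
#' @param net A `cryo_cnn` (or `cryo_cnn_fit`).
#' @return Integer vector of the spatial output size after each conv and
#'   pool layer; the full preset gives `55 27 27 13 13 13 13 6` from 227.
#' @export
network_dims <- function(net) {
  if (inherits(net, "cryo_cnn_fit")) net <- net$net
  dims <- integer(0)
  for (lay in net$layers)
    if (lay$type %in% c("conv", "pool")) dims <- c(dims, lay$out_h)
  dims
}
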