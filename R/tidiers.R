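#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted network
#'
#' @param x A `cryo_cnn_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `train_acc`,
#'   `val_acc`.
#' @export
tidy.cryo_cnn_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted network
#'
#' @param x A `cryo_cnn_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `final_loss`, `train_acc`, `val_acc`,
#'   `n_parameters`, `learning_rate`.
#' @export
glance.cryo_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    final_loss = last$loss,
    train_acc = last$train_acc,
    val_acc = last$val_acc,
    n_parameters = sum(vapply(x$net$layers, function(l)
      if (!is.null(l$W)) length(l$W) + length(l$b) else 0, numeric(1))),
    learning_rate = x$config$learning_rate)
}

#' @export
print.cryo_cnn_fit <- function(x, ...) {
  cat("<cryo_cnn_fit> classes:", paste(x$net$class_names, collapse = ", "),
      "\n  input", x$net$input_size, "x", x$net$input_size, "x",
      x$net$channels, "| epochs", nrow(x$history), "| final val acc",
      format(x$history$val_acc[nrow(x$history)], digits = 3), "\n")
  invisible(x)
}

#' @export
print.cryo_simulation <- function(x, ...) {
  cat("<cryo_simulation>", nrow(x$pixels), "x", ncol(x$pixels),
      "px,", nrow(x$truth), x$shape, "particles, noise sd",
      format(x$noise_sigma, digits = 3), "\n")
  invisible(x)
}

#' Plot a micrograph with optional box overlays
#'
#' @param m Micrograph matrix (or a `cryo_simulation`).
#' @param boxes Optional tibble with `x`, `y`, `w`, `h` (and optionally
#'   `label`) to overlay.
#' @return A ggplot object.
#' @export
plot_micrograph <- function(m, boxes = NULL) {
  if (inherits(m, "cryo_simulation")) {
    boxes <- boxes %||% m$truth
    m <- m$pixels
  }
  df <- data.frame(x = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
                   y = rep(seq_len(nrow(m)) - 1, ncol(m)),
                   value = as.vector(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes)) {
    aes_col <- if ("label" %in% names(boxes))
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h,
                   colour = .data$label)
    else ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                      ymin = .data$y, ymax = .data$y + .data$h)
    p <- p + ggplot2::geom_rect(data = boxes, mapping = aes_col,
                                inherit.aes = FALSE, fill = NA,
                                linewidth = 0.4)
  }
  p
}

#' @export
autoplot.cryo_simulation <- function(object, ...) {
  plot_micrograph(object)
}

#' Plot training curves of a fitted network
#'
#' @param object A `cryo_cnn_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracies over epochs.
#' @export
autoplot.cryo_cnn_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, value = h$loss / max(h$loss),
                         series = "loss (scaled)"),
              data.frame(epoch = h$epoch, value = h$train_acc,
                         series = "train accuracy"),
              data.frame(epoch = h$epoch, value = h$val_acc,
                         series = "validation accuracy"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `cryo_pr_curve` from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot; the subtitle reports the area under the curve.
#' @export
autoplot.cryo_pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(subtitle = sprintf("area = %.3f", attr(object, "area"))) +
    ggplot2::theme_minimal()
}

#' Plot a score map as a heat map
#'
#' @param sm A `cryo_score_map`.
#' @param class_name Class whose probability grid to show (default:
#'   first).
#' @return A ggplot object.
#' @export
plot_score_map <- function(sm, class_name = sm$class_names[1]) {
  ci <- match(class_name, sm$class_names)
  g <- sm$scores[, , ci]
  df <- expand.grid(y = sm$y0, x = sm$x0)
  df$score <- as.vector(g)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = class_name) +
    ggplot2::theme_void()
}
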