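#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained detector
#'
#' One row per training epoch with the joint loss, its binary cross-entropy
#' and correction components, and the learning rate.
#'
#' @param x a `wt_detector`.
#' @param ... unused.
#' @return A tibble `epoch, loss, bce, l2, lr`.
#' @export
tidy.wt_detector <- function(x, ...) x$history

#' @rdname tidy.wt_detector
#' @export
glance.wt_detector <- function(x, ...) {
  tibble(n_train = x$n_train, n_pos = x$n_pos,
         n_params = sum(vapply(x$params, length, integer(1))),
         epochs = nrow(x$history),
         final_loss = tail(x$history$loss, 1),
         anchor_sizes = paste(x$anchor_sizes, collapse = ","))
}

#' Tidy a trained recognizer
#'
#' One row per training epoch with the margin-softmax loss and (when a
#' validation set was supplied) the held-out top-1 accuracy.
#'
#' @param x a `wt_recognizer`.
#' @param ... unused.
#' @return A tibble `epoch, loss, val_top1`.
#' @export
tidy.wt_recognizer <- function(x, ...) x$history

#' @rdname tidy.wt_recognizer
#' @export
glance.wt_recognizer <- function(x, ...) {
  vt <- x$history$val_top1
  tibble(n_train = x$n_train, n_classes = length(x$class_ids),
         d = x$d, s = x$s, m1 = x$m1, m2 = x$m2, m3 = x$m3,
         final_loss = tail(x$history$loss, 1),
         val_top1 = if (any(!is.na(vt))) tail(vt[!is.na(vt)], 1) else NA_real_)
}

#' Plot detected regions over a frame or projection
#'
#' @param img `H x W` matrix (a frame or a MIP).
#' @param regions region tibble (`x, y, w, h`; optionally `z` to facet).
#' @param gt optional ground-truth region tibble, drawn dashed.
#' @return A ggplot object.
#' @export
plot_detections <- function(img, regions, gt = NULL) {
  df <- tidyr::expand_grid(py = seq_len(nrow(img)) - 1L,
                           px = seq_len(ncol(img)) - 1L)
  df$value <- as.vector(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_rect(data = regions,
                       ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                                    ymin = .data$y, ymax = .data$y + .data$h),
                       inherit.aes = FALSE, colour = "deepskyblue",
                       fill = NA, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(gt))
    p <- p + ggplot2::geom_rect(data = gt,
                                ggplot2::aes(xmin = .data$x,
                                             xmax = .data$x + .data$w,
                                             ymin = .data$y,
                                             ymax = .data$y + .data$h),
                                inherit.aes = FALSE, colour = "orange",
                                fill = NA, linetype = "dashed",
                                linewidth = 0.3)
  p
}

#' Plot activity traces
#'
#' Ratiometric activity against volume index, one line per digital ID.
#'
#' @param object a `wt_traces` tibble with `volume` and `assigned_id`
#'   columns (e.g. from [run_pipeline()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wt_traces <- function(object, ...) {
  df <- filter(object, !is.na(.data$R), !is.na(.data$assigned_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$volume, .data$R,
                                   group = .data$assigned_id,
                                   colour = factor(.data$assigned_id))) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = "volume", y = "R = F_GCaMP / F_RFP")
}

#' Plot a recognition learning curve
#'
#' @param curve tibble with `n_train` and `top1` columns.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$n_train, .data$top1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training volumes", y = "top-1 tracking accuracy") +
    ggplot2::ylim(0, 1)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
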