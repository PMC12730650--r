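# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' @param x A `vib_report` from [evaluate_rf()] / [run_protocol()].
#' @param ... Unused.
#' @return Per-class metrics tibble (`class`, `precision`, `class_accuracy`,
#'   `recall`, `f1`, `specificity`, `support`).
#' @method tidy vib_report
#' @export
tidy.vib_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation report
#'
#' @param x A `vib_report`.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `auc`, `cv_mean`, `cv_sd`,
#'   `overfitting_gap`, `n_train`, `n_test`.
#' @method glance vib_report
#' @export
glance.vib_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$overall_accuracy,
    auc = x$auc,
    cv_mean = if (!is.null(x$cv)) x$cv$mean else NA_real_,
    cv_sd = if (!is.null(x$cv)) x$cv$sd else NA_real_,
    overfitting_gap = x$overfitting_gap,
    n_train = if (!is.null(x$n_train)) x$n_train else NA_integer_,
    n_test = x$n_test
  )
}

#' Tidy a cross-validation summary
#'
#' @param x A `vib_cv` from [crossval()].
#' @param ... Unused.
#' @return Tibble with one row per fold (`fold`, `accuracy`).
#' @method tidy vib_cv
#' @export
tidy.vib_cv <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$k), accuracy = x$fold_accuracy)
}

#' @rdname tidy.vib_cv
#' @method glance vib_cv
#' @export
glance.vib_cv <- function(x, ...) {
  tibble::tibble(k = x$k, mean = x$mean, sd = x$sd,
                 ci95_normal_low = x$ci95_normal[1],
                 ci95_normal_high = x$ci95_normal[2],
                 ci95_sd_low = x$ci95_sd[1], ci95_sd_high = x$ci95_sd[2])
}

#' ROC curve plot of an evaluation report
#'
#' @param object A `vib_report` with a ROC curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vib_report
#' @export
autoplot.vib_report <- function(object, ...) {
  if (is.null(object$roc)) stop("report carries no ROC curve", call. = FALSE)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC, AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Laser-spot trajectory plot
#'
#' @param object A `spot_trajectory` from [simulate_spot_trajectory()].
#' @param every Plot every `every`-th sample (thinning).
#' @param ... Unused.
#' @return A ggplot of the spot path on the screen.
#' @method autoplot spot_trajectory
#' @export
autoplot.spot_trajectory <- function(object, every = 10L, ...) {
  geom <- attr(object, "geometry")
  d <- object[seq(1, nrow(object), by = every), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$t)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_fixed(xlim = c(-1, 1) * geom$screen_width / 2,
                         ylim = c(-1, 1) * geom$screen_height / 2) +
    ggplot2::labs(x = "screen x (m)", y = "screen y (m)", colour = "t (s)") +
    ggplot2::theme_minimal()
}

#' Centroid-trajectory plot
#'
#' @param object A `trajectory_metrics` object.
#' @param ... Unused.
#' @return A ggplot of the centroid path in the XY pixel plane.
#' @method autoplot trajectory_metrics
#' @export
autoplot.trajectory_metrics <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$time_s)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "centroid x (px)", y = "centroid y (px, image rows)",
                  colour = "t (s)") +
    ggplot2::theme_minimal()
}

#' Plot a single frame
#'
#' @param frame Grayscale matrix, a `masked_frame`, or a [frame_sequence()]
#'   (then `index` selects the frame).
#' @param index Frame index when `frame` is a sequence.
#' @return A ggplot raster of the frame.
#' @export
plot_frame <- function(frame, index = 1L) {
  m <- if (inherits(frame, "frame_sequence")) {
    frame$frames[[index]]
  } else if (inherits(frame, "masked_frame")) {
    frame$pixels
  } else as.matrix(frame)
  d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$value <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom rlang .data
NULL
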