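#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training trace of a model
#'
#' @param x an `ms2_model`.
#' @param ... unused.
#' @return the per-step trace as a tibble.
#' @export
tidy.ms2_model <- function(x, ...) {
  x$trace %||% tibble(step = integer(0), loss = numeric(0))
}

#' One-row model summary
#'
#' @param x an `ms2_model`.
#' @param ... unused.
#' @return tibble with the task, architecture scale and final losses.
#' @export
glance.ms2_model <- function(x, ...) {
  tr <- x$trace
  tibble(
    task = x$task %||% "pretrain",
    d = x$model_cfg$d,
    layers = x$model_cfg$layers,
    n_params = param_count(x$params),
    steps = if (is.null(tr)) 0L else max(tr$step),
    final_loss = if (!is.null(tr) && "loss" %in% names(tr)) {
      tr$loss[nrow(tr)]
    } else {
      NA_real_
    },
    val_metric = x$val_metric %||% NA_real_
  )
}

#' Plot the training trace
#'
#' @param object an `ms2_model`.
#' @param ... unused.
#' @return a ggplot of the loss components over steps.
#' @export
autoplot.ms2_model <- function(object, ...) {
  tr <- tidy(object)
  long <- tidyr::pivot_longer(tr, dplyr::any_of(c("loss_mass", "loss_order",
                                                  "loss", "val_metric")),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "optimization step", y = NULL,
                  title = "training trace") +
    ggplot2::theme_minimal()
}

#' Plot a spectrum
#'
#' @param object a spectra tibble.
#' @param rows which spectra to draw.
#' @param ... unused.
#' @return a ggplot stick plot faceted by scan.
#' @export
autoplot.ms_spectra <- function(object, rows = 1, ...) {
  sub <- object[rows, , drop = FALSE]
  long <- tidyr::unnest(
    dplyr::mutate(sub, .scan = paste0(.data$source_id, "#", .data$scan)),
    cols = c("mz", "intensity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                     y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::facet_wrap(~.scan, scales = "free") +
    ggplot2::labs(x = "m/z (Da)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
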