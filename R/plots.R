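#' Chromaticity-diagram plot of model results
#'
#' Draws stimulus loci in the (two-dimensional) chromaticity diagram,
#' with the receptor vectors as labelled segments from the origin.
#' One-dimensional (dichromat) spaces are drawn along a line; spaces
#' with more than two dimensions cannot be drawn flat — plot the
#' distance profile instead (see [plot_delta_s()]).
#'
#' @param object A `vision_model` from [run_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vision_model <- function(object, ...) {
  n <- attr(object$basis, "n")
  if (n > 2) {
    stop("chromaticity diagrams can be drawn for 1- or 2-dimensional spaces only", call. = FALSE)
  }
  V <- unclass(object$basis)
  r <- object$results
  if (n == 1) {
    r$X2 <- 0
    Vt <- tibble::tibble(X1 = V[1, ], X2 = 0, receptor = colnames(V))
  } else {
    Vt <- tibble::tibble(X1 = V[1, ], X2 = V[2, ], receptor = colnames(V))
  }
  ggplot2::ggplot(r, ggplot2::aes(.data$X1, .data$X2)) +
    ggplot2::geom_segment(data = Vt, ggplot2::aes(x = 0, y = 0, xend = .data$X1, yend = .data$X2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey50") +
    ggplot2::geom_text(data = Vt, ggplot2::aes(label = .data$receptor),
                       nudge_y = 0.05, colour = "grey30", size = 3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$delta_s)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "X1", y = if (n == 1) NULL else "X2", colour = expression(Delta * S),
                  title = sprintf("%s chromaticity diagram", object$config$kind)) +
    ggplot2::theme_minimal()
}

#' Distance profile of a sweep
#'
#' Chromatic distance to the background as a function of the swept
#' parameter (logistic midpoint or achromatic reflectance level), with
#' spurious (near-singular) points marked.
#'
#' @param sweep A `sweep_result`.
#' @return A ggplot object.
#' @export
plot_delta_s <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  r <- sweep$results
  ggplot2::ggplot(r, ggplot2::aes(.data[[sweep$parameter]], .data$delta_s)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$near_singular)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4), guide = "none") +
    ggplot2::labs(x = sweep$parameter, y = expression(Delta * S),
                  title = sprintf("%s model: distance to background", sweep$config$kind)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_delta_s
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @export
autoplot.sweep_result <- function(object, ...) plot_delta_s(object)

#' Screening summary plot
#'
#' Distribution of mean chromatic distances over all receptor
#' combinations at each set size, with the best combination per size
#' highlighted.
#'
#' @param object A `receptor_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.receptor_screen <- function(object, ...) {
  r <- object$results
  best <- glance(object)
  ggplot2::ggplot(r, ggplot2::aes(factor(.data$size), .data$mean_delta_s)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_point(data = best, ggplot2::aes(y = .data$best_mean_delta_s),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "number of receptor types", y = expression(paste("mean ", Delta * S)),
                  title = sprintf("Receptor-set screening (%s)", object$kind)) +
    ggplot2::theme_minimal()
}
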