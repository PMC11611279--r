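#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an absorption result
#'
#' @param x An `absorption_result`.
#' @param ... Unused.
#' @return A plain tibble with `index` and `A`.
#' @export
tidy.absorption_result <- function(x, ...) {
  tibble::tibble(index = x$index, A = x$A)
}

#' One-row summary of an absorption result
#'
#' @inheritParams tidy.absorption_result
#' @return A tibble with the reflection count, back-end, sampling settings
#'   and the range of computed factors.
#' @export
glance.absorption_result <- function(x, ...) {
  s <- attr(x, "sampling")
  tibble::tibble(
    n_reflections = nrow(x),
    method = attr(x, "method"),
    sampling_method = s$method,
    ratio = s$ratio,
    n_voxels = s$n_selected,
    A_min = if (nrow(x)) min(x$A) else NA_real_,
    A_mean = if (nrow(x)) mean(x$A) else NA_real_,
    A_max = if (nrow(x)) max(x$A) else NA_real_
  )
}

#' Histogram of absorption factors
#'
#' @param object An `absorption_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.absorption_result <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$A)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey30") +
    ggplot2::labs(
      x = expression(A[h]),
      y = "reflections",
      title = sprintf("Absorption factors (%s back-end)", attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
}

#' Sampling-fidelity plot
#'
#' KS statistic against full sampling as a function of sampling ratio, one
#' point per seed with the per-ratio mean overlaid.
#'
#' @param object A `sample_report` from [sample_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_report <- function(object, ...) {
  means <- object |>
    dplyr::group_by(.data$ratio) |>
    dplyr::summarise(statistic = mean(.data$statistic), .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.35, colour = "grey40") +
    ggplot2::geom_line(data = means, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(data = means, colour = "firebrick", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sampling ratio", y = "KS statistic vs full sampling",
                  title = "Sampling fidelity") +
    ggplot2::theme_minimal()
}
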