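#' Plot axial slices of an accuracy (or p) map
#'
#' @param map 3D numeric array.
#' @param slices Z indices to show; default: every slice.
#' @param label Fill legend label.
#' @return A ggplot object.
#' @export
plot_accuracy_map <- function(map, slices = NULL, label = "accuracy") {
  dims <- dim(map)
  slices <- slices %||% seq_len(dims[3])
  d <- tidyr::expand_grid(z = slices, y = seq_len(dims[2]),
                          x = seq_len(dims[1]))
  d$value <- map[cbind(d$x, d$y, d$z)]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = label) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_searchlight <- function(object, what = c("accuracy", "p"),
                                       ...) {
  what <- match.arg(what)
  map <- if (what == "accuracy") object$group_map else object$p_map
  plot_accuracy_map(map, label = if (what == "accuracy")
    "group accuracy" else "empirical p")
}

#' Histogram of a bootstrap null distribution against an observed statistic
#'
#' @param null Numeric vector of null draws.
#' @param observed Observed statistic (vertical line).
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null, observed) {
  d <- tibble::tibble(null = null)
  ggplot2::ggplot(d, ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = observed, color = "firebrick") +
    ggplot2::labs(x = "group-level chance accuracy", y = "draws") +
    ggplot2::theme_minimal()
}
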