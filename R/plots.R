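# ggplot2 views of clustering results.

#' Plot an OTU clustering result
#'
#' Without `points`, draws the OTU size distribution (size against rank on
#' log-scaled axes). With `points` — a coordinate tibble whose ids match
#' the fit, as from [sim_gaussian_points()] — draws the first two
#' coordinates colored by OTU.
#'
#' @param object An `mpick_fit`.
#' @param points Optional point tibble (`id` plus at least two numeric
#'   columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpick_fit <- function(object, points = NULL, ...) {
  otus <- object$otus
  if (is.null(points)) {
    sizes <- dplyr::count(otus, .data$otu_id, name = "size")
    sizes <- dplyr::arrange(sizes, dplyr::desc(.data$size))
    sizes$rank <- seq_len(nrow(sizes))
    ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$size)) +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "OTU rank", y = "OTU size",
                    title = sprintf("%d OTUs from %d items", object$n_otus,
                                    object$n_items))
  } else {
    stopifnot(is.data.frame(points), "id" %in% names(points))
    num <- names(points)[vapply(points, is.numeric, TRUE)]
    if (length(num) < 2L) {
      abort("`points` needs at least two numeric coordinate columns.",
            class = "mpick_error_usage")
    }
    df <- dplyr::inner_join(points, otus, by = c(id = "member_id"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[num[1L]]],
                                     y = .data[[num[2L]]],
                                     color = .data$otu_id)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::guides(color = "none") +
      ggplot2::labs(title = sprintf("%d OTUs (epsilon = %g, delta = %g)",
                                    object$n_otus, object$params$epsilon,
                                    object$params$delta))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' OTU size distribution plot
#'
#' @param fit An `mpick_fit`.
#' @return A ggplot object.
#' @export
plot_otu_sizes <- function(fit) {
  autoplot.mpick_fit(fit)
}
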