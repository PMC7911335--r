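#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a HomoDist trace
#'
#' Quick diagnostic plot of the trace: one panel per metric (by default
#' CI, HI and SHI, plus the distance columns `disCen` and `MaxD`), with
#' the addition step on the x axis and one line per tree method. Distances
#' are shown on the percentage scale.
#'
#' @param object A `homodist_trace`.
#' @param metrics Character vector of metric names to show, from
#'   `c("CI", "RI", "HI", "RCI", "SHI", "disCen", "MaxD")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot homodist_trace
#' @export
autoplot.homodist_trace <- function(object,
                                    metrics = c("CI", "HI", "SHI",
                                                "disCen", "MaxD"), ...) {
  steps <- object$steps
  long <- tidyr::pivot_longer(
    steps,
    cols = -c("step", "added_taxon", "n_taxa"),
    names_to = "column", values_to = "value"
  )
  long <- dplyr::mutate(long,
    method = dplyr::case_when(
      grepl("^nj_", .data$column) ~ "NJ",
      grepl("^upgma_", .data$column) ~ "UPGMA",
      TRUE ~ "distance"
    ),
    metric = sub("^(nj|upgma)_", "", .data$column)
  )
  long <- dplyr::filter(long, .data$metric %in% metrics)
  long <- dplyr::mutate(long, value = ifelse(
    .data$metric %in% c("disCen", "MaxD"), .data$value * 100, .data$value))
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "addition step", y = NULL, colour = NULL,
                  title = paste0("HomoDist trace (center: ", object$center,
                                 ")"),
                  subtitle = "distances in %, indices on [0, 1]") +
    ggplot2::theme_minimal()
}

#' Plot taxon HI groups along the series
#'
#' Bar plot of the HI carried by each taxon in series order, coloured by
#' HI group, mirroring the way HI plateaus mark candidate species blocks.
#'
#' @param partition An `hi_partition` from [delimit_hi_groups()].
#' @return A ggplot object.
#' @export
plot_hi_groups <- function(partition) {
  df <- dplyr::mutate(tibble::as_tibble(partition),
                      taxon = factor(.data$taxon, levels = .data$taxon),
                      group = factor(.data$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$HI,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "HI", fill = "HI group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
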