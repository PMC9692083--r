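# ggplot2 views of the two result types: the stacked component scores of a
# prioritization run and the per-extract ion map.

#' Plot the component scores of a prioritization run
#'
#' Stacked bars of the four components per extract, ordered by rank, so the
#' make-up of each Priority Score is visible at a glance. Negative Literature
#' Components (heavily studied taxa) plot below zero.
#'
#' @param object an `npscout_priority` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot npscout_priority
#' @export
autoplot.npscout_priority <- function(object, ...) {
  long <- object$results |>
    select("filename", "rank", "FC", "LC", "CC", "SC") |>
    mutate(SC = as.numeric(.data$SC)) |>
    tidyr::pivot_longer(c("FC", "LC", "CC", "SC"),
                        names_to = "component", values_to = "score") |>
    mutate(component = factor(.data$component, levels = c("SC", "CC", "LC", "FC")))
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$filename, -.data$rank),
    y = .data$score, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Priority Score contribution",
                  fill = "Component") +
    ggplot2::theme_minimal()
}

#' Plot an ion map
#'
#' Retention time against m/z for every feature detected in the extract,
#' point size proportional to the original peak area and colour encoding the
#' feature status: specific unannotated features (the isolation candidates),
#' specific annotated, and non-specific.
#'
#' @param object an ion-map tibble from [export_ion_map()] or [ion_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot npscout_ion_map
#' @export
autoplot.npscout_ion_map <- function(object, ...) {
  palette <- c(specific_unannotated = "#2166ac",
               specific_annotated = "#1b7837",
               nonspecific = "#e6c300")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$rt, y = .data$mz, size = .data$area, colour = .data$category
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = palette) +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::labs(
      title = paste0("Ion map: ", attr(object, "extract") %||% ""),
      x = "Retention time (min)", y = "m/z", colour = "Feature status"
    ) +
    ggplot2::theme_minimal()
}
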