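# ggplot2 views of analysis results.

#' Plot scaled diversity against scaled overlap
#'
#' Scatter of scaled PD versus scaled overlap for the generated groups,
#' faceted by group size, with a linear trend; observed communities, when
#' present, are overlaid as filled points.
#'
#' @param object A `myco_report`.
#' @param alpha Point transparency for generated groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.myco_report <- function(object, alpha = 0.15, ...) {
  gen <- object$groups[object$groups$provenance == "generated", ]
  obs <- object$groups[object$groups$provenance == "observed", ]
  p <- ggplot2::ggplot(gen, ggplot2::aes(x = .data$scaled_overlap, y = .data$scaled_pd)) +
    ggplot2::geom_point(alpha = alpha, size = 0.6, colour = "grey30") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "#2166ac") +
    ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "scaled overlap", y = "scaled PD",
                  title = "Fungal-host diversity vs. host overlap in plant groups") +
    ggplot2::theme_minimal()
  if (nrow(obs) > 0) {
    p <- p + ggplot2::geom_point(data = obs, colour = "#b2182b", size = 2)
  }
  p
}

#' Compare scaled metrics between same- and mixed-location groups
#'
#' @param report A `myco_report`.
#' @param metric `"scaled_overlap"` or `"scaled_pd"`.
#' @return A ggplot object.
#' @export
plot_location_comparison <- function(report, metric = c("scaled_overlap", "scaled_pd")) {
  metric <- match.arg(metric)
  gen <- report$groups[report$groups$provenance == "generated", ]
  gen$location <- ifelse(gen$same_location, "same location", "different locations")
  ggplot2::ggplot(gen, ggplot2::aes(x = factor(.data$n), y = .data[[metric]],
                                    fill = .data$location)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_fill_manual(values = c("same location" = "#66c2a5",
                                          "different locations" = "#fc8d62")) +
    ggplot2::labs(x = "group size", y = gsub("_", " ", metric), fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-plant scaled phylogenetic diversity
#'
#' Bar chart of each plant's scaled PD with a reference line at 0.5, the
#' midpoint of the attainable range at its host count.
#'
#' @param report A `myco_report`.
#' @return A ggplot object.
#' @export
plot_per_plant <- function(report) {
  pp <- report$per_plant
  ggplot2::ggplot(pp, ggplot2::aes(x = stats::reorder(.data$plant_id, .data$scaled_pd),
                                   y = .data$scaled_pd)) +
    ggplot2::geom_col(fill = "#5e81ac") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "scaled PD of fungal host set") +
    ggplot2::theme_minimal()
}
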