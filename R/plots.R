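#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_point
#'   geom_hline facet_wrap labs theme_minimal coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot a nutrient adequacy report
#'
#' Per-nutrient bars of supply as a percentage of the demographically
#' weighted target (100% line marked), with whiskers at the lower/upper
#' safe bounds where available, each on the same percent-of-target scale.
#'
#' @param object A `delta_nutrient_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_nutrient_report
#' @export
autoplot.delta_nutrient_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(lower_pct = 100 * .data$lower_safe / .data$target,
           upper_pct = 100 * .data$upper_safe / .data$target)
  ggplot(df, aes(x = .data$nutrient_id, y = .data$pct_of_target)) +
    geom_col(aes(fill = .data$material)) +
    geom_errorbar(aes(ymin = .data$lower_pct, ymax = .data$upper_pct),
                  width = 0.3, colour = "grey40", na.rm = TRUE) +
    geom_hline(yintercept = 100, linetype = 2) +
    coord_flip() +
    labs(x = NULL, y = "supply, % of weighted target",
         fill = "material gap") +
    theme_minimal()
}

#' Plot a nutrient waste report
#'
#' Per-nutrient waste and loss as a percentage of the target daily
#' intake, split into plant- and animal-origin contributions.
#'
#' @param object A `delta_waste_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_waste_report
#' @export
autoplot.delta_waste_report <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("plant_share_pct", "animal_share_pct"),
                        names_to = "origin", values_to = "share_pct") |>
    mutate(origin = sub("_share_pct", "", .data$origin),
           part_pct = .data$pct_of_target * .data$share_pct / 100)
  ggplot(df, aes(x = .data$nutrient_id, y = .data$part_pct,
                 fill = .data$origin)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "wasted or lost, % of target daily intake",
         fill = "origin") +
    theme_minimal()
}

#' Plot a scenario comparison
#'
#' Dot plot of the change in percent-of-target per nutrient between the
#' two runs (B minus A).
#'
#' @param object A `delta_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_comparison
#' @export
autoplot.delta_comparison <- function(object, ...) {
  ggplot(object$nutrients,
         aes(x = .data$nutrient_id, y = .data$delta_pct_of_target)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    coord_flip() +
    labs(x = NULL,
         y = sprintf("change in %% of target (%s minus %s)",
                     object$name_b, object$name_a)) +
    theme_minimal()
}
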