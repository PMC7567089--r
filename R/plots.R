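# ggplot2 views of the main result types.

class_palette <- c(bacteria_specific = "#c0392b",
  sponge_specific = "#2980b9", unspecific = "grey60")

#' Bar plot of tracer processing rates by species
#'
#' Mean and SD of assimilation, respiration and nitrogen assimilation rates
#' per species, faceted by food source.
#'
#' @param rates Output of [bulk_rates()].
#' @return A ggplot.
#' @export
plot_rates <- function(rates) {
  df <- rates |>
    tidyr::pivot_longer(c("assimilation_rate", "respiration_rate"),
      names_to = "process", values_to = "rate") |>
    filter(!(.data$element == "N" & .data$process == "respiration_rate"),
      !is.na(.data$rate)) |>
    mutate(quantity = dplyr::case_when(
      .data$element == "C" & .data$process == "assimilation_rate" ~ "C assimilation",
      .data$element == "C" ~ "C respiration",
      TRUE ~ "N assimilation")) |>
    group_by(.data$species, .data$food_source, .data$quantity) |>
    summarise(mean = mean(.data$rate), sd = sd(.data$rate), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$mean,
    fill = .data$quantity)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
      ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_wrap(~food_source) +
    ggplot2::scale_fill_manual(values = c("C assimilation" = "#922b21",
      "C respiration" = "#e6b0aa", "N assimilation" = "#2471a3")) +
    ggplot2::labs(x = NULL, fill = NULL,
      y = expression(mu * "mol tracer " * mmol^-1 * " " * d^-1))
}

#' Stacked relative assimilation vs respiration
#'
#' Mean assimilated and respired percentages of total carbon processing per
#' species, stacking to 100.
#'
#' @param rates Output of [bulk_rates()].
#' @return A ggplot.
#' @export
plot_relative_processing <- function(rates) {
  df <- relative_processing(rates) |>
    tidyr::pivot_longer(c("assimilated_pct", "respired_pct"),
      names_to = "fate", values_to = "pct") |>
    group_by(.data$species, .data$food_source, .data$fate) |>
    summarise(pct = mean(.data$pct), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$pct,
    fill = .data$fate)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::facet_wrap(~food_source) +
    ggplot2::scale_fill_manual(values = c(assimilated_pct = "#922b21",
      respired_pct = "#e6b0aa"),
      labels = c("assimilated", "respired")) +
    ggplot2::labs(x = NULL, y = "% of total processing", fill = NULL)
}

#' PLFA profile bar plot with biomarker classes
#'
#' Mean (SD) relative abundance of each fatty acid across samples, coloured
#' by biomarker class.
#'
#' @param profile Output of [plfa_profile()].
#' @return A ggplot.
#' @export
plot_plfa_profile <- function(profile) {
  df <- profile |>
    group_by(.data$fatty_acid, .data$class) |>
    summarise(mean = mean(.data$pct), sd = sd(.data$pct), .groups = "drop") |>
    arrange(.data$class, dplyr::desc(.data$mean))
  df$fatty_acid <- factor(df$fatty_acid, levels = df$fatty_acid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fatty_acid, y = .data$mean,
    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
      ymax = .data$mean + .data$sd), width = 0.3) +
    ggplot2::scale_fill_manual(values = class_palette) +
    ggplot2::labs(x = NULL, y = "% of total PLFA carbon", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Per-PLFA tracer incorporation plot
#'
#' Mean percentage of total tracer incorporation per fatty acid, coloured
#' by biomarker class, faceted by species and food source.
#'
#' @param incorporation Output of [plfa_incorporation()].
#' @return A ggplot.
#' @export
plot_incorporation <- function(incorporation) {
  df <- incorporation |>
    group_by(.data$species, .data$food_source, .data$fatty_acid, .data$class) |>
    summarise(pct = mean(.data$pct_of_total), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fatty_acid, y = .data$pct,
    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(species ~ food_source) +
    ggplot2::scale_fill_manual(values = class_palette) +
    ggplot2::labs(x = NULL, y = "% of total tracer incorporation",
      fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
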