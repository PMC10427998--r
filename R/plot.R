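#' Status palette used by the plotting helpers
#'
#' Conventional blue-green-yellow-orange-red scheme of the five-class
#' ecological status scale, plus grey for unclassifiable stations.
#' @return Named character vector of colors.
#' @export
status_palette <- function() {
  c(high = "#2c7bb6", good = "#abd9e9", moderate = "#ffffbf",
    poor = "#fdae61", bad = "#d7191c", unclassifiable = "grey70")
}

#' Plot the index and status of each station
#'
#' Bars of the index value per station, filled by ecological status class,
#' with horizontal lines at the class boundaries. Unclassifiable stations
#' (no assigned reads) are shown as zero-height bars in grey.
#'
#' @param object A `microgambi_assessment` from [assess_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microgambi_assessment <- function(object, ...) {
  cfg <- assessment_config(object)
  df <- tidy(object)
  df$station <- factor(df$station, levels = df$station)
  df$index_plot <- ifelse(is.na(df$index_value), 0, df$index_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$station, y = .data$index_plot,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cfg$class_boundaries,
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_fill_manual(values = status_palette(), drop = FALSE) +
    ggplot2::labs(x = "station", y = "index value", fill = "status") +
    ggplot2::theme_minimal()
}

#' Plot per-station ecological-group composition
#'
#' Stacked percentage bars of reads in EGI, EGIII, not assigned and not in
#' list for each station.
#'
#' @param assessment A `microgambi_assessment`.
#' @return A ggplot object.
#' @export
plot_eg_composition <- function(assessment) {
  stopifnot(inherits(assessment, "microgambi_assessment"))
  df <- tidy(assessment)
  long <- tidyr::pivot_longer(
    df[, c("station", "pct_egi", "pct_egiii", "pct_not_assigned", "pct_not_in_list")],
    -"station", names_to = "group", values_to = "pct"
  )
  long$group <- factor(long$group,
                       levels = c("pct_egi", "pct_egiii", "pct_not_assigned",
                                  "pct_not_in_list"),
                       labels = c("EGI", "EGIII", "not assigned", "not in list"))
  long$station <- factor(long$station, levels = df$station)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$station, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      "EGI" = "#2c7bb6", "EGIII" = "#d7191c",
      "not assigned" = "grey60", "not in list" = "grey85"
    )) +
    ggplot2::labs(x = "station", y = "% of reads", fill = "group") +
    ggplot2::theme_minimal()
}
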