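#' Plot ranked state-specific contact frequency differences
#'
#' Bar chart of inactive-minus-active frequency differences, one bar per
#' residue pair, coloured by inactivating/activating label, faceted by
#' class when several are present.
#'
#' @param records output of [filter_state_specific()] (optionally after
#'   [conservation_filter()]).
#' @param top_n show at most this many pairs per class.
#' @return a ggplot object.
#' @export
plot_pair_frequencies <- function(records, top_n = 25) {
  dat <- records |>
    dplyr::group_by(.data$gpcr_class) |>
    dplyr::slice_max(abs(.data$diff), n = top_n, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(pair = paste0(.data$pos_a, "-", .data$pos_b))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$pair, abs(.data$diff)),
    y = .data$diff, fill = .data$label
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gpcr_class), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(inactivating = "#3b6fb6",
                                          activating = "#c03a3a")) +
    ggplot2::labs(x = NULL, y = "Frequency difference (inactive - active, %)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.helix_movement_report <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$region <- factor(dat$region, levels = c("ec_end", "mid", "ic_end"),
                       labels = c("Extracellular end", "Membrane mid",
                                  "Intracellular end"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tm, y = .data$region,
                                    fill = .data$translation)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$translation), "n.m.",
                     sprintf("%.1f", .data$translation))
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c03a3a",
                                 na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Movement (Å)",
                  title = unique(dat$receptor)) +
    ggplot2::theme_minimal()
}

#' Plot mutant potency/efficacy shifts by group
#'
#' Box-and-jitter plot of per-mutant shifts relative to wild type for each
#' G protein, mirroring the two-group mutant comparison.
#'
#' @param deltas output of [delta_from_wt()].
#' @param measure `"potency"` (delta log EC50) or `"efficacy"` (delta
#'   Emax).
#' @return a ggplot object.
#' @export
plot_mutation_shifts <- function(deltas, measure = c("potency", "efficacy")) {
  measure <- match.arg(measure)
  ycol <- if (measure == "potency") "delta_log_ec50" else "delta_emax"
  ylab <- if (measure == "potency") {
    expression(Delta * log(EC[50]) ~ "from wild type")
  } else {
    expression(Delta * E[max] ~ "from wild type")
  }
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$group, y = .data[[ycol]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2,
                         ggplot2::aes(color = .data$group)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$g_protein)) +
    ggplot2::scale_color_manual(values = c(state_changing = "#d97818",
                                           nonstate_changing = "grey40")) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}
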