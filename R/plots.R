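#' @import ggplot2
NULL

#' Volcano plot of a contrast result
#'
#' @param object A `contrast_result`.
#' @param alpha FDR threshold colouring significant genes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot contrast_result
#' @export
autoplot.contrast_result <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$p)) |>
    mutate(status = dplyr::case_when(
      !is.na(.data$fdr) & .data$fdr < alpha & .data$lfc > 0 ~ "up",
      !is.na(.data$fdr) & .data$fdr < alpha & .data$lfc < 0 ~ "down",
      TRUE ~ "ns"))
  ggplot(df, aes(x = .data$lfc, y = -log10(.data$p), colour = .data$status)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_colour_manual(values = c(up = "#c23b22", down = "#2b6ca3",
                                   ns = "grey60")) +
    labs(x = "log2 fold change", y = "-log10 p",
         title = attr(object, "contrast"), colour = NULL) +
    theme_minimal()
}

#' Transition flows between two contrasts
#'
#' Tile view of the regulation-call transition table; tile labels give
#' gene counts per (from, to) cell.
#'
#' @param tt Tibble from [transition_table()].
#' @return A ggplot.
#' @export
plot_transitions <- function(tt) {
  lv <- c("up", "ns", "down", "increased", "decreased")
  lv <- lv[lv %in% unique(c(tt$from, tt$to))]
  df <- mutate(tt, from = factor(.data$from, levels = lv),
               to = factor(.data$to, levels = lv))
  ggplot(df, aes(x = .data$to, y = .data$from, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), colour = "white") +
    scale_fill_viridis_c() +
    labs(x = "call at second contrast", y = "call at first contrast",
         fill = "genes") +
    theme_minimal()
}

#' Observed versus expected regional DEG counts
#'
#' Bars of observed up/down counts per region with the uniform-placement
#' expectation overlaid, mirroring the chromosome-distribution figures.
#'
#' @param tally Output of [expected_counts()] / [fisher_region_tests()].
#' @return A ggplot.
#' @export
plot_region_tally <- function(tally) {
  long <- tally |>
    select("region", up = "n_up", down = "n_down") |>
    tidyr::pivot_longer(c("up", "down"), names_to = "direction",
                        values_to = "n")
  ggplot(long, aes(x = .data$region, y = .data$n, fill = .data$direction)) +
    geom_col(position = "stack") +
    geom_point(data = tally, aes(x = .data$region, y = .data$expected_deg),
               inherit.aes = FALSE, shape = 95, size = 6) +
    scale_fill_manual(values = c(up = "#c23b22", down = "#2b6ca3")) +
    labs(x = NULL, y = "regulated genes",
         caption = "dash = expected DEGs under uniform placement") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' PCCR class overview
#'
#' @param object A `pccr_result`.
#' @param ... Unused.
#' @return A ggplot: distribution of PCCR deltas coloured by class.
#' @method autoplot pccr_result
#' @export
autoplot.pccr_result <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- filter(as_tibble(object), .data$class != "undefined")
  ggplot(df, aes(x = .data$delta, fill = .data$class)) +
    geom_histogram(bins = 60) +
    geom_vline(xintercept = c(-thr, thr), linetype = 2) +
    scale_fill_manual(values = c(increased = "#c23b22", constant = "grey60",
                                 decreased = "#2b6ca3")) +
    labs(x = "PCCR change (comparison - reference)", y = "genes",
         fill = NULL) +
    theme_minimal()
}
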