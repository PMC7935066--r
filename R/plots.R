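# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sequence-logo-style plot of a position frequency matrix
#'
#' Per-position letter contributions scaled by information content, the
#' quantity a sequence logo displays (a U bias at position 1 shows as a tall
#' U bar there).
#'
#' @param object A `mirna_pfm` from [position_bias()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_pfm <- function(object, ...) {
  df <- tidy(object)
  df$contribution <- df$freq * df$information
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$contribution,
                                   fill = .data$letter)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#33A02C", C = "#1F78B4",
                                          G = "#FF7F00", U = "#E31A1C")) +
    ggplot2::labs(x = "miRNA position", y = "information (bits)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Criterion heatmap of a curation audit
#'
#' One tile per candidate and criterion, coloured by pass/fail, with the
#' final bona fide call as an extra column.
#'
#' @param object A `mirna_audit` from [curate_mirnas()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_audit <- function(object, ...) {
  crit <- grep("^pass_", names(object), value = TRUE)
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), dplyr::all_of(c("id", crit,
                                                             "bona_fide"))),
    cols = dplyr::all_of(c(crit, "bona_fide")),
    names_to = "criterion", values_to = "pass")
  df$criterion <- factor(sub("^pass_", "", df$criterion),
                         levels = c(sub("^pass_", "", crit), "bona_fide"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$id,
                                   fill = .data$pass)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2C7FB8",
                                          `FALSE` = "#DE2D26"),
                               na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "pass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Gains and shared-family counts on the species tree
#'
#' Bar chart of Dollo gains, losses and shared-family counts per tree node
#' (tips and internal nodes).
#'
#' @param object A `dollo_recon` from [dollo_reconstruct()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dollo_recon <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, cols = c("n_gains", "n_losses",
                                           "n_present"),
                              names_to = "measure", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node_label, y = .data$count,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "miRNA families", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
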