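#' Volcano plot of a consensus DE result
#'
#' @param object A `de_consensus` tibble from [run_de()] /
#'   [consensus_de()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_consensus <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$log2fc, y = -log10(pmax(.data$p_wald, 1e-300)),
      colour = .data$consensus_call
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * thr$min_abs_log2fc, linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = -log10(thr$p_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = "consensus DE"
    ) +
    ggplot2::labs(
      x = "log2 fold change (Wald)", y = "-log10 p (Wald)",
      title = attr(object, "contrast")
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise expression correlations by pair class
#'
#' @param pairs Tibble from [correlate_pairs()] with `r` and `class`.
#' @return A ggplot.
#' @export
plot_correlation_classes <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$r, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0, colour = "white") +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "Pearson r", y = "gene pairs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Feature view of coding-potential results
#'
#' @param codpot Tibble from [codpot_classify()].
#' @return A ggplot of ORF coverage vs logistic probability, coloured by
#'   the consensus gate.
#' @export
plot_coding_potential <- function(codpot) {
  ggplot2::ggplot(
    codpot,
    ggplot2::aes(
      x = .data$orf_coverage, y = .data$logistic_prob,
      colour = .data$consensus_noncoding
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "firebrick"),
      name = "noncoding consensus"
    ) +
    ggplot2::labs(x = "ORF coverage", y = "logistic coding probability") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a ceRNA network
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cerna_network <- function(object, ...) {
  s <- network_summary(object)
  if (nrow(s$degree) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
        ggplot2::theme_void()
    )
  }
  ggplot2::ggplot(
    s$degree,
    ggplot2::aes(x = stats::reorder(.data$node, -.data$degree), y = .data$degree, fill = .data$side)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "degree") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
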