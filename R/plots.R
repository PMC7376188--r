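#' Plot allele coverage ratios per locus
#'
#' One point per heterozygous call, loci ordered by mean ACR, with the 0.5
#' imbalance guide line; loci whose heterozygotes all fall below it are
#' the candidates for discarding.
#'
#' @param calls Output of [call_genotypes()].
#' @return A ggplot object.
#' @export
plot_acr <- function(calls) {
  hets <- calls[!is.na(calls$acr), , drop = FALSE]
  ord <- hets |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(m = mean(.data$acr), .groups = "drop") |>
    dplyr::arrange(.data$m)
  hets$locus <- factor(hets$locus, levels = ord$locus)
  ggplot2::ggplot(hets, ggplot2::aes(x = .data$locus, y = .data$acr)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          shape = 18, size = 2.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Allele coverage ratio (min/max reads)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot sequence-based allele gains over length-based alleles
#'
#' Stacked bars per locus: the length-based allele count plus the gained
#' sequence-based alleles split by variant class.
#'
#' @param gain Output of [summarize_allele_gain()] (the `TOTAL` row is
#'   dropped).
#' @return A ggplot object.
#' @export
plot_allele_gain <- function(gain) {
  gain <- gain[gain$locus != "TOTAL", , drop = FALSE]
  long <- gain |>
    dplyr::select("locus", `length-based` = "lb_count",
                  `repeat region` = "gain_rrvo",
                  `flanking region` = "gain_frvo",
                  `repeat + flanking` = "gain_rrfr") |>
    tidyr::pivot_longer(-"locus", names_to = "component",
                        values_to = "n") |>
    dplyr::mutate(component = factor(
      .data$component,
      levels = c("repeat + flanking", "flanking region", "repeat region",
                 "length-based")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$n,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_grey(start = 0.2, end = 0.95) +
    ggplot2::labs(x = NULL, y = "Alleles", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a per-locus allele frequency spectrum
#'
#' @param freqs A `freq_table` from [allele_frequencies()].
#' @param loci Optional subset of loci to facet.
#' @return A ggplot object.
#' @export
plot_frequencies <- function(freqs, loci = NULL) {
  if (!is.null(loci)) freqs <- freqs[freqs$locus %in% loci, , drop = FALSE]
  ggplot2::ggplot(freqs, ggplot2::aes(x = stats::reorder(.data$allele,
                                                         -.data$frequency),
                                      y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~locus, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Relative frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
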