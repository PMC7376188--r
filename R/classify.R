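#' Classify an allele against its locus reference
#'
#' Alleles are partitioned into four classes relative to the configured
#' reference: `REFERENCE` (repeat pattern matches the reference template,
#' no flanking variants), `RRVO` (repeat-region variants only), `FRVO`
#' (flanking-region variants only) and `RRFR` (both). "Repeat pattern
#' matches" means the allele differs from the template only in the counts
#' of its variable motif runs; interruptions absent from the template,
#' truncated or missing template interruptions, altered gap lengths and
#' non-canonical tail units all count as repeat-region variation. Flanking
#' variants that physically lie inside the repeat region (the printed
#' tables mark these "Not counted") are treated as repeat-region variation,
#' not as flanking variants.
#'
#' @param allele A [sequence_allele()].
#' @param config The matching [locus_config()].
#' @return One of `"REFERENCE"`, `"RRVO"`, `"FRVO"`, `"RRFR"`.
#' @export
classify_variant <- function(allele, config) {
  if (allele$locus != config$name) {
    stopf("allele locus '%s' does not match config '%s'", allele$locus,
          config$name)
  }
  dev <- attr(allele$structure, "pattern_deviation")
  if (is.null(dev)) {
    # structures from parsed names carry no alignment provenance;
    # re-encoding the expanded sequence recovers it deterministically
    reenc <- bracket_encode(expand_structure(allele$structure), config)
    dev <- attr(reenc, "pattern_deviation")
  }
  fl <- allele$flanks
  rr_variant <- nrow(fl) > 0 && any(fl$region == "repeat_region")
  dev <- isTRUE(dev) || rr_variant
  has_flank <- nrow(fl) > 0 && any(fl$region != "repeat_region")
  if (dev && has_flank) "RRFR"
  else if (dev) "RRVO"
  else if (has_flank) "FRVO"
  else "REFERENCE"
}

#' Known-allele catalogs
#'
#' A catalog is a set of canonical allele names per locus, standing in for
#' a local snapshot of a sequence-allele registry. Lookups are exact on the
#' canonical string; enlarging a catalog can only remove novelty flags.
#'
#' @param path TSV file with columns `locus` and `isfg_name`.
#' @param source_tag Free-text provenance label stored on the catalog.
#' @return A tibble of class `allele_catalog`.
#' @export
read_allele_catalog <- function(path, source_tag = basename(path)) {
  cat_df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!all(c("locus", "isfg_name") %in% names(cat_df))) {
    stopf("catalog needs 'locus' and 'isfg_name' columns",
          class = "forenseqr_input_error")
  }
  allele_catalog(cat_df, source_tag = source_tag)
}

#' @param entries Data frame with columns `locus`, `isfg_name`.
#' @rdname read_allele_catalog
#' @export
allele_catalog <- function(entries, source_tag = "local") {
  out <- dplyr::distinct(as_tibble(entries), .data$locus, .data$isfg_name)
  attr(out, "source_tag") <- source_tag
  class(out) <- unique(c("allele_catalog", class(out)))
  out
}

#' Flag alleles absent from a catalog
#'
#' @param alleles Data frame with columns `locus` and `isfg_name` (e.g. the
#'   output of [name_alleles()]).
#' @param catalog An [allele_catalog()].
#' @return Logical vector: `TRUE` for alleles not present in the catalog.
#' @export
flag_novel <- function(alleles, catalog) {
  !(paste(alleles$locus, alleles$isfg_name, sep = "\r") %in%
      paste(catalog$locus, catalog$isfg_name, sep = "\r"))
}

#' Decompose sequence-based allele gains over length-based alleles
#'
#' For each locus, counts the distinct length-based (CE) alleles, the
#' distinct sequence-based alleles, and decomposes the gain by the variant
#' class of the gained alleles. Within each CE group one allele is the
#' baseline a ladder would report and the rest are gains; the baseline is
#' chosen as the allele closest to the reference pattern (`REFERENCE`
#' first, then `FRVO`, `RRVO`, `RRFR`).
#'
#' @param alleles Data frame of distinct alleles with columns `locus`,
#'   `ce`, `isfg_name`, `variant_class` (e.g. distinct rows of
#'   [name_alleles()] output).
#' @param totals Append a `TOTAL` row?
#' @return A tibble with one row per locus: `lb_count`, `sb_count`, `gain`,
#'   `gain_rrvo`, `gain_frvo`, `gain_rrfr`.
#' @export
summarize_allele_gain <- function(alleles, totals = TRUE) {
  alleles <- dplyr::distinct(as_tibble(alleles), .data$locus, .data$ce,
                             .data$isfg_name, .data$variant_class)
  baseline_rank <- c(REFERENCE = 1, FRVO = 2, RRVO = 3, RRFR = 4)
  gains <- alleles |>
    dplyr::group_by(.data$locus, .data$ce) |>
    dplyr::arrange(baseline_rank[.data$variant_class], .data$isfg_name,
                   .by_group = TRUE) |>
    dplyr::slice(-1) |>
    dplyr::ungroup()
  out <- alleles |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      lb_count = dplyr::n_distinct(.data$ce),
      sb_count = dplyr::n_distinct(.data$isfg_name),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      gains |>
        dplyr::group_by(.data$locus) |>
        dplyr::summarise(
          gain_rrvo = sum(.data$variant_class == "RRVO"),
          gain_frvo = sum(.data$variant_class == "FRVO"),
          gain_rrfr = sum(.data$variant_class == "RRFR"),
          .groups = "drop"
        ),
      by = "locus"
    ) |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("gain_"), ~ tidyr::replace_na(.x, 0L)),
      gain = .data$sb_count - .data$lb_count,
      .after = "sb_count"
    )
  if (totals && nrow(out) > 0) {
    tot <- out |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum)) |>
      dplyr::mutate(locus = "TOTAL")
    out <- dplyr::bind_rows(out, tot)
  }
  out
}
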