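#' CE designations
#'
#' A CE designation is the allele number a capillary-electrophoresis ladder
#' would assign: an integer repeat count plus, for microvariants, the number
#' of leftover nucleotides (`10.1` = one extra nucleotide relative to allele
#' 10). Designations here are *length-anchored*, never unit-count-anchored:
#' each locus configuration carries a reference allele with a known CE
#' anchor, and an observed allele's designation is obtained from its length
#' offset relative to that reference. This reproduces the behaviour of CE
#' ladders for alleles whose repeat-unit count and fragment length disagree
#' (flanking insertions/deletions, interrupted repeats, locus-specific
#' ladder offsets).
#'
#' @name ce_designation
NULL

parse_ce <- function(x) {
  if (is.list(x) && !is.null(x$whole)) {
    return(list(whole = as.integer(x$whole), partial = as.integer(x$partial)))
  }
  x <- as.character(x)
  parts <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (!length(parts) %in% 1:2 || !grepl("^[0-9]+(\\.[0-9]+)?$", x)) {
    stopf("malformed CE designation '%s'", x, class = "forenseqr_parse_error")
  }
  list(whole = as.integer(parts[1]),
       partial = if (length(parts) == 2) as.integer(parts[2]) else 0L)
}

format_ce <- function(ce) {
  if (ce$partial > 0) paste0(ce$whole, ".", ce$partial) else as.character(ce$whole)
}

ce_numeric <- function(ce) ce$whole + ce$partial / 10

# net length contribution of flanking variants: insertions add, deletions
# subtract; variants lying inside the repeat region are already part of the
# repeat-region sequence and must not be double counted.
flank_length_delta <- function(flanks) {
  if (is.null(flanks) || nrow(flanks) == 0) return(0L)
  keep <- is.na(flanks$region) | flanks$region != "repeat_region"
  ins <- sum(nchar(flanks$alt[keep & flanks$kind == "insertion"]))
  del <- sum((flanks$end - flanks$pos + 1L)[keep & flanks$kind == "deletion"])
  as.integer(ins - del)
}

#' Length-anchored CE designation of an allele
#'
#' Computes the CE designation from the analysed-fragment length offset
#' between the allele and the locus reference: with `dL` the length
#' difference (flanking insertions and deletions included),
#' `whole = anchor_whole + floor((dL + anchor_partial) / motif_len)` and
#' `partial = (dL + anchor_partial) mod motif_len`.
#'
#' @param structure The allele's repeat-region [repeat_structure()].
#' @param config The [locus_config()] supplying the reference structure and
#'   CE anchor.
#' @param flanks Flanking-variant tibble (see [parse_flank_annotations()]);
#'   `NULL` for none.
#' @return A list with integer fields `whole` and `partial`.
#' @export
#' @examples
#' cfgs <- read_locus_config(forenseqr_example("forenseq_strs.json"))
#' s <- repeat_structure("TATC", 10L)
#' ins <- flank_variant(kind = "insertion", pos = 84160204L, sub = 1L,
#'                      alt = "A", region = "upstream")
#' format_ce(ce_designation(s, cfgs$D7S820, ins))  # "10.1"
ce_designation <- function(structure, config, flanks = NULL) {
  dL <- structure_length(structure) - reference_length(config) +
    flank_length_delta(flanks)
  anchor <- config$reference_ce
  total <- dL + anchor$partial
  whole <- anchor$whole + floor(total / config$motif_len)
  partial <- total %% config$motif_len
  if (whole < 0) {
    stopf("locus %s: allele %d nt shorter than representable from anchor CE %s",
          config$name, -dL, format_ce(anchor), class = "forenseqr_error")
  }
  list(whole = as.integer(whole), partial = as.integer(partial))
}
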