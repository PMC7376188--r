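#' Sequence-based allele objects
#'
#' A `sequence_allele` bundles everything known about one observed allele:
#' the locus, the bracketed repeat structure, the flanking variants, the
#' length-anchored CE designation and the canonical name. The canonical
#' name regenerates byte-identically from the structure, the flanking
#' variants and the locus configuration.
#'
#' @param config A [locus_config()].
#' @param structure A [repeat_structure()] (typically from
#'   [bracket_encode()]).
#' @param flanks A [flank_variant()] tibble or a printed annotation string.
#' @return A `sequence_allele` object.
#' @export
sequence_allele <- function(config, structure, flanks = NULL) {
  if (is.character(flanks)) {
    flanks <- parse_flank_annotations(flanks, config)
  }
  flanks <- validate_flanks(flanks %||% empty_flanks(), config)
  ce <- ce_designation(structure, config, flanks)
  al <- structure(
    list(locus = config$name, structure = structure, flanks = flanks, ce = ce),
    class = "sequence_allele"
  )
  al$isfg_name <- format_isfg(al, config)
  al
}

#' Format a sequence allele as its canonical bracketed name
#'
#' Layout:
#' `<Locus> [CE<x>]-Chr<label>-GRCh38 <start>–<end> <segments> <flanks>`
#' with thousands separators and an en dash in the coordinate interval,
#' `[UNIT]n` for counted runs of two or more, bare uppercase units for
#' counted singletons, lowercase for uncounted interruptions, `N<len>` for
#' gaps, and `"; "`-separated flank annotations.
#'
#' @param allele A [sequence_allele()].
#' @param config The matching [locus_config()].
#' @return A single string.
#' @export
format_isfg <- function(allele, config) {
  if (allele$locus != config$name) {
    stopf("allele locus '%s' does not match config '%s'", allele$locus,
          config$name)
  }
  head <- sprintf("%s [CE%s]-Chr%s-GRCh38 %s%s%s",
                  config$name, format_ce(allele$ce), config$chrom_label,
                  fmt_coord(config$repeat_start), EN_DASH,
                  fmt_coord(config$repeat_end))
  segs <- format_segments(allele$structure)
  fl <- format_flank_annotations(allele$flanks)
  paste0(head, " ", segs, if (nzchar(fl)) paste0(" ", fl) else "")
}

#' Parse a canonical bracketed allele name
#'
#' Inverse of [format_isfg()]: recovers the repeat structure, the flanking
#' variants and the CE designation, so that formatting the result
#' reproduces the input byte-identically. Tolerant mode (default) accepts
#' an ASCII hyphen in place of the en dash.
#'
#' @param name Canonical allele name string.
#' @param config The [locus_config()] for the named locus.
#' @param strict Require canonical en-dash characters?
#' @return A [sequence_allele()].
#' @export
parse_isfg <- function(name, config, strict = FALSE) {
  m <- regmatches(name, regexec(
    paste0("^(.+?) \\[CE([0-9.]+)\\]-Chr([^-]+)-GRCh38 ",
           "([0-9,]+)(", EN_DASH, "|-)([0-9,]+) (.*)$"),
    name))[[1]]
  if (length(m) != 8) {
    stopf("malformed allele name near offset %d: '%s'",
          attr(regexpr(" ", name), "match.length") %||% 1L, name,
          class = "forenseqr_parse_error")
  }
  if (strict && m[6] != EN_DASH) {
    stopf("coordinate interval must use an en dash in strict mode",
          class = "forenseqr_parse_error")
  }
  locus <- m[2]
  if (locus != config$name) {
    stopf("name is for locus '%s' but config is '%s'", locus, config$name,
          class = "forenseqr_parse_error")
  }
  tokens <- strsplit(m[8], " ", fixed = TRUE)[[1]]
  is_seg <- grepl("^(\\[[ACGTacgt]+\\][0-9]+|[ACGTacgt]+|N[0-9]+)$", tokens)
  first_flank <- match(FALSE, is_seg)
  if (is.na(first_flank)) {
    seg_tokens <- tokens
    flank_str <- ""
  } else {
    if (first_flank == 1L) {
      stopf("allele name has no structure segments: '%s'", name,
            class = "forenseqr_parse_error")
    }
    seg_tokens <- tokens[seq_len(first_flank - 1L)]
    flank_str <- paste(tokens[first_flank:length(tokens)], collapse = " ")
  }
  structure <- parse_segments(seg_tokens)
  flanks <- parse_flank_annotations(flank_str, config, strict = strict)
  al <- sequence_allele(config, structure, flanks)
  parsed_ce <- parse_ce(m[3])
  if (!identical(parsed_ce, al$ce)) {
    warn(sprintf(
      "locus %s: printed CE %s disagrees with the length-anchored CE %s",
      locus, m[3], format_ce(al$ce)))
  }
  al
}

#' @export
print.sequence_allele <- function(x, ...) {
  cat("<sequence_allele>", x$isfg_name, "\n")
  invisible(x)
}

#' Name alleles in an observation table
#'
#' The workhorse of the naming stage: takes a tibble with at least `locus`
#' and `sequence` columns (repeat-region nucleotides) and an optional
#' `flanks` column of printed annotations, and appends the canonical
#' bracketed name, the CE designation, the counted repeat units and the
#' variant classification for each distinct allele.
#'
#' @param observations A data frame with columns `locus`, `sequence` and
#'   optionally `flanks`.
#' @param configs Named list of [locus_config()] objects.
#' @param catalog Optional known-allele catalog (see
#'   [read_allele_catalog()]); adds a `novel` flag.
#' @return The input tibble with columns `isfg_name`, `ce`, `ce_numeric`,
#'   `repeat_units` and `variant_class` (and `novel` when a catalog is
#'   given) appended.
#' @export
#' @examples
#' cfgs <- read_locus_config(forenseqr_example("forenseq_strs.json"))
#' obs <- tibble::tibble(locus = "D7S820",
#'                       sequence = strrep("TATC", 10),
#'                       flanks = "84,160,204-A; 84,160,204.1A")
#' name_alleles(obs, cfgs)
name_alleles <- function(observations, configs, catalog = NULL) {
  observations <- as_tibble(observations)
  if (!all(c("locus", "sequence") %in% names(observations))) {
    stopf("observations need 'locus' and 'sequence' columns",
          class = "forenseqr_input_error")
  }
  if (!"flanks" %in% names(observations)) observations$flanks <- ""
  observations$flanks[is.na(observations$flanks)] <- ""
  key <- dplyr::distinct(observations, .data$locus, .data$sequence,
                         .data$flanks)
  named <- purrr::pmap(key, function(locus, sequence, flanks) {
    cfg <- get_config(configs, locus)
    st <- bracket_encode(sequence, cfg)
    fl <- parse_flank_annotations(flanks, cfg)
    al <- sequence_allele(cfg, st, fl)
    tibble(
      locus = locus, sequence = sequence, flanks = flanks,
      isfg_name = al$isfg_name,
      ce = format_ce(al$ce),
      ce_numeric = ce_numeric(al$ce),
      repeat_units = repeat_unit_count(st),
      variant_class = classify_variant(al, cfg)
    )
  })
  named <- dplyr::bind_rows(named)
  if (!is.null(catalog)) {
    named$novel <- flag_novel(named, catalog)
  }
  dplyr::left_join(observations, named,
                   by = c("locus", "sequence", "flanks"))
}
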