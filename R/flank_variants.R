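#' Flanking-region variants
#'
#' Variants observed in the analysed flanking ranges of an STR fragment,
#' stored one row per variant with columns `kind` (`"substitution"`,
#' `"insertion"`, `"deletion"`), `pos` (GRCh38 coordinate; for insertions
#' the anchor base), `sub` (insertion sub-index: `204.1` means inserted
#' after base 204; 0 otherwise), `alt` (substituted/inserted bases, empty
#' for deletions), `end` (deletion end coordinate, `NA` otherwise) and
#' `region` (`"upstream"`, `"downstream"` or `"repeat_region"`).
#'
#' Rendering follows the printed conventions: substitutions `"pos-ALT"`,
#' insertions `"pos.1ALT"`, deletions `"start–end DEL"`; multiple
#' variants are joined with `"; "` in position order. Insertions with an
#' ambiguous placement are left-aligned to their 5'-most equivalent anchor
#' so that naming is deterministic.
#'
#' @param kind,pos,sub,alt,end,region Field vectors, recycled to a common
#'   length.
#' @return A tibble of flanking variants.
#' @export
flank_variant <- function(kind = character(), pos = integer(), sub = 0L,
                          alt = "", end = NA_integer_, region = NA_character_) {
  n <- max(length(kind), length(pos))
  tibble(
    kind = rep_len(as.character(kind), n),
    pos = rep_len(as.integer(pos), n),
    sub = rep_len(as.integer(sub), n),
    alt = rep_len(toupper(as.character(alt)), n),
    end = rep_len(as.integer(end), n),
    region = rep_len(as.character(region), n)
  )
}

empty_flanks <- function() flank_variant()

# classify a coordinate relative to the configured locus intervals
flank_region_of <- function(pos, config) {
  if (pos >= config$repeat_start && pos <= config$repeat_end) {
    return("repeat_region")
  }
  if (pos < config$repeat_start) "upstream" else "downstream"
}

validate_flanks <- function(flanks, config) {
  if (nrow(flanks) == 0) return(flanks)
  flanks$region <- vapply(flanks$pos, flank_region_of, character(1),
                          config = config)
  in_range <- function(p, fr) !is.null(fr) && p >= fr[1] && p <= fr[2]
  ok <- vapply(seq_len(nrow(flanks)), function(i) {
    p <- flanks$pos[i]
    flanks$region[i] == "repeat_region" ||
      in_range(p, config$flank_upstream) || in_range(p, config$flank_downstream)
  }, logical(1))
  if (!all(ok)) {
    warn(sprintf("locus %s: %d flank variant(s) outside the analysed ranges",
                 config$name, sum(!ok)))
  }
  flanks[order(flanks$pos, flanks$sub), , drop = FALSE]
}

#' Render flanking variants as printed annotations
#'
#' @param flanks A [flank_variant()] tibble.
#' @return A single string (`""` when there are no variants).
#' @export
format_flank_annotations <- function(flanks) {
  if (is.null(flanks) || nrow(flanks) == 0) return("")
  flanks <- flanks[order(flanks$pos, flanks$sub), , drop = FALSE]
  out <- vapply(seq_len(nrow(flanks)), function(i) {
    switch(flanks$kind[i],
      substitution = paste0(fmt_coord(flanks$pos[i]), "-", flanks$alt[i]),
      insertion = paste0(fmt_coord(flanks$pos[i]), ".", flanks$sub[i],
                         flanks$alt[i]),
      deletion = paste0(fmt_coord(flanks$pos[i]), EN_DASH,
                        fmt_coord(flanks$end[i]), " DEL"),
      stopf("unknown flank variant kind '%s'", flanks$kind[i])
    )
  }, character(1))
  paste(out, collapse = "; ")
}

#' Parse printed flanking-variant annotations
#'
#' Inverse of [format_flank_annotations()]. In tolerant mode (the default)
#' an ASCII hyphen is accepted wherever the canonical form prints an en
#' dash; strict mode requires the canonical characters.
#'
#' @param x Annotation string such as
#'   `"84,160,204-A; 84,160,204.1A"` or `""`.
#' @param config Optional [locus_config()] used to label each variant's
#'   region; without it `region` is `NA`.
#' @param strict Require canonical dash characters?
#' @return A [flank_variant()] tibble.
#' @export
parse_flank_annotations <- function(x, config = NULL, strict = FALSE) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(empty_flanks())
  parts <- strsplit(trimws(x), ";\\s*")[[1]]
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl(paste0("^[0-9,]+(", EN_DASH, "|-)[0-9,]+ DEL$"), p)) {
      if (strict && !grepl(EN_DASH, p, fixed = TRUE)) {
        stopf("deletion '%s' must use an en dash in strict mode", p,
              class = "forenseqr_parse_error")
      }
      cc <- strsplit(sub(" DEL$", "", p), paste0("(", EN_DASH, "|-)"))[[1]]
      return(flank_variant("deletion", parse_coord(cc[1]), 0L, "",
                           parse_coord(cc[2])))
    }
    m <- regmatches(p, regexec("^([0-9,]+)\\.([0-9]+)([ACGT]+)$", p))[[1]]
    if (length(m) == 4) {
      return(flank_variant("insertion", parse_coord(m[2]), as.integer(m[3]),
                           m[4]))
    }
    m <- regmatches(p, regexec("^([0-9,]+)-([ACGT]+)$", p))[[1]]
    if (length(m) == 3) {
      return(flank_variant("substitution", parse_coord(m[2]), 0L, m[3]))
    }
    stopf("malformed flank annotation '%s'", p, class = "forenseqr_parse_error")
  })
  flanks <- dplyr::bind_rows(rows)
  if (!is.null(config)) flanks <- validate_flanks(flanks, config)
  flanks[order(flanks$pos, flanks$sub), , drop = FALSE]
}
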