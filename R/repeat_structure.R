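#' Repeat-region structures
#'
#' A repeat structure is the bracketed decomposition of an STR repeat region:
#' an ordered set of segments, each either a repeated motif block
#' (`[TCTA]5`), a singleton unit (`TCTA`), an uncounted interruption rendered
#' lowercase (`tca`), or an uncalled gap of known length rendered `N42`.
#' Structures are stored as tibbles with one row per segment and columns
#' `unit` (uppercase motif, `NA` for gaps), `count`, `counted` (uncounted
#' segments print lowercase and contribute nothing to the repeat-unit count),
#' `role` (how the segment arose: `"variable"`, `"fixed"`, `"tail"`,
#' `"novel_run"`, `"novel_word"`, `"truncated"`, or `"gap"`) and `gap_len`.
#'
#' @param unit Character vector of uppercase motif units (`NA` for gaps).
#' @param count Integer repeat counts (`NA` for gaps).
#' @param counted Logical; does the segment contribute to the repeat-unit
#'   count (and print uppercase)?
#' @param role Character segment provenance; defaults to `"variable"`.
#' @param gap_len Integer gap lengths (`NA` for sequence segments).
#' @return A `repeat_structure` tibble.
#' @export
#' @examples
#' rs <- repeat_structure(unit = c("TATC", "TGTC", "TATC"),
#'                        count = c(9L, 1L, 1L))
#' format_segments(rs)
#' expand_structure(rs)
repeat_structure <- function(unit = character(), count = integer(),
                             counted = TRUE, role = "variable",
                             gap_len = NA_integer_) {
  n <- max(length(unit), length(count))
  out <- tibble(
    unit    = toupper(as.character(rep_len(unit %||% NA_character_, n))),
    count   = as.integer(rep_len(count, n)),
    counted = rep_len(as.logical(counted), n),
    role    = rep_len(as.character(role), n),
    gap_len = as.integer(rep_len(gap_len, n))
  )
  new_repeat_structure(out)
}

new_repeat_structure <- function(x) {
  class(x) <- unique(c("repeat_structure", class(x)))
  x
}

rs_gap <- function(len) {
  repeat_structure(unit = NA_character_, count = NA_integer_, counted = FALSE,
                   role = "gap", gap_len = as.integer(len))
}

rs_bind <- function(...) {
  segs <- list(...)
  segs <- segs[vapply(segs, function(s) !is.null(s) && nrow(s) > 0, logical(1))]
  if (!length(segs)) return(empty_structure())
  new_repeat_structure(dplyr::bind_rows(segs))
}

empty_structure <- function() {
  repeat_structure(unit = character(), count = integer())
}

is_gap_seg <- function(structure) !is.na(structure$gap_len)

#' Expand a repeat structure to its nucleotide sequence
#'
#' Gap blocks expand to runs of `N`; output is uppercase regardless of the
#' counted flags, so expansion followed by re-encoding against the same locus
#' configuration reproduces the structure.
#'
#' @param structure A [repeat_structure()].
#' @return A single nucleotide string.
#' @export
expand_structure <- function(structure) {
  if (nrow(structure) == 0) return("")
  pieces <- ifelse(
    is_gap_seg(structure),
    strrep("N", structure$gap_len),
    strrep(structure$unit, structure$count)
  )
  paste(pieces, collapse = "")
}

#' @rdname expand_structure
#' @export
structure_length <- function(structure) {
  nchar(expand_structure(structure))
}

#' Count repeat units in a structure
#'
#' Sums the repeat counts of counted segments only: lowercase interruptions
#' and gap blocks contribute zero, while uppercase singleton interruptions
#' count as one unit each (so the Fibrinogen-alpha structure
#' `[GGAA]2 GGAG [AAAG]16 AGAG AAAG AGAA AAAA [GAAA]3` counts 26).
#'
#' @inheritParams expand_structure
#' @return Integer number of counted repeat units.
#' @export
repeat_unit_count <- function(structure) {
  if (nrow(structure) == 0) return(0L)
  sum(structure$count[structure$counted & !is_gap_seg(structure)], na.rm = TRUE)
}

#' Render structure segments as bracketed tokens
#'
#' Counted runs with two or more copies render as `[UNIT]n`, counted
#' singletons as the bare uppercase unit, uncounted segments lowercase, and
#' gaps as `N<len>`.
#'
#' @inheritParams expand_structure
#' @return A single space-separated string.
#' @export
format_segments <- function(structure) {
  if (nrow(structure) == 0) return("")
  tok <- character(nrow(structure))
  for (i in seq_len(nrow(structure))) {
    if (!is.na(structure$gap_len[i])) {
      tok[i] <- paste0("N", structure$gap_len[i])
    } else if (!structure$counted[i]) {
      u <- tolower(structure$unit[i])
      tok[i] <- if (structure$count[i] >= 2) {
        paste0("[", u, "]", structure$count[i])
      } else u
    } else if (structure$count[i] >= 2) {
      tok[i] <- paste0("[", structure$unit[i], "]", structure$count[i])
    } else {
      tok[i] <- structure$unit[i]
    }
  }
  paste(tok, collapse = " ")
}

#' Parse bracketed segment tokens into a repeat structure
#'
#' Inverse of [format_segments()]. Casing determines the counted flag;
#' segment provenance is unknown after parsing and is set to `NA`.
#'
#' @param tokens Character vector of tokens such as `"[TCTA]5"`, `"tca"`,
#'   `"N42"`.
#' @return A [repeat_structure()].
#' @export
parse_segments <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(empty_structure())
  segs <- lapply(seq_along(tokens), function(i) {
    tk <- tokens[i]
    if (grepl("^N[0-9]+$", tk)) {
      return(rs_gap(as.integer(sub("^N", "", tk))))
    }
    m <- regmatches(tk, regexec("^\\[([ACGTacgt]+)\\]([0-9]+)$", tk))[[1]]
    if (length(m) == 3) {
      unit <- m[2]; count <- as.integer(m[3])
    } else if (grepl("^[ACGTacgt]+$", tk)) {
      unit <- tk; count <- 1L
    } else {
      stopf("malformed segment token '%s' (token %d)", tk, i,
            class = "forenseqr_parse_error")
    }
    counted <- unit == toupper(unit)
    repeat_structure(unit = toupper(unit), count = count, counted = counted,
                     role = NA_character_)
  })
  do.call(rs_bind, segs)
}

#' Compare two structures for rendering equality
#'
#' Two structures are the same allele when their units, counts, counted flags
#' and gap lengths agree segment by segment; provenance roles are ignored.
#'
#' @param a,b [repeat_structure()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_structure <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0) return(TRUE)
  all(
    (a$unit == b$unit | (is.na(a$unit) & is.na(b$unit))),
    a$count == b$count | (is.na(a$count) & is.na(b$count)),
    a$counted == b$counted,
    a$gap_len == b$gap_len | (is.na(a$gap_len) & is.na(b$gap_len)),
    na.rm = TRUE
  ) &&
    identical(is.na(a$unit), is.na(b$unit)) &&
    identical(is.na(a$gap_len), is.na(b$gap_len))
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat("<repeat_structure> ", format_segments(x), "\n", sep = "")
  invisible(x)
}
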