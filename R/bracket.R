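#' Bracketed encoding of repeat-region sequences
#'
#' Converts the repeat-region portion of an analysed fragment into its
#' bracketed structure, guided by the locus reference template. The encoder
#' works in two passes:
#'
#' 1. *Tokenization*: maximal runs (two or more copies) of the template's
#'    variable motifs are located greedily left to right; when runs of
#'    different motifs overlap in shifted reading frames, the run whose
#'    start preserves the current motif frame is preferred. Runs, `N` gap
#'    blocks and the unmatched stretches between them become tokens.
#' 2. *Template alignment*: tokens are aligned to the reference segments by
#'    a small dynamic program that prefers, in order, exact template
#'    matches (including folding reference singletons such as `cctt CCTT`
#'    out of a longer physical run), truncated lowercase interruptions,
#'    novel motif runs, and finally novel interruption words chopped at
#'    motif length. Novel segments are rendered uppercase and counted;
#'    lowercase casing is inherited from the template only.
#'
#' The expansion of the result always equals the input sequence (gaps as
#' `N` runs). Deviations from the reference pattern (novel runs or words,
#' truncated interruptions, altered gap lengths, skipped template segments,
#' non-canonical tail units) are recorded in the `"pattern_deviation"`
#' attribute, which downstream variant classification consumes.
#'
#' @param sequence Repeat-region nucleotide string (A/C/G/T/N; flanks
#'   already split off).
#' @param config The [locus_config()] whose reference template guides the
#'   encoding.
#' @return A [repeat_structure()] with attributes `pattern_deviation`
#'   (logical) and `template_skips` (integer).
#' @export
#' @examples
#' cfgs <- read_locus_config(forenseqr_example("forenseq_strs.json"))
#' s <- bracket_encode(paste0(strrep("TATC", 9), "TGTC", "TATC"), cfgs$D7S820)
#' format_segments(s)  # "[TATC]9 TGTC TATC"
bracket_encode <- function(sequence, config) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stopf("locus %s: sequence contains non-nucleotide characters",
          config$name, class = "forenseqr_input_error")
  }
  if (nchar(sequence) < config$motif_len) {
    stopf("locus %s: sequence shorter than one motif (%d nt)",
          config$name, config$motif_len, class = "forenseqr_input_error")
  }
  tpl <- config$reference_structure
  has_tail <- tpl$kind[nrow(tpl)] == "tail"
  tail_seg <- NULL
  tail_dev <- FALSE
  if (has_tail && nchar(sequence) > config$motif_len) {
    m <- config$motif_len
    tail_unit <- substr(sequence, nchar(sequence) - m + 1, nchar(sequence))
    if (!grepl("N", tail_unit, fixed = TRUE)) {
      tail_dev <- tail_unit != tpl$unit[nrow(tpl)]
      tail_seg <- repeat_structure(unit = tail_unit, count = 1L,
                                   counted = tpl$counted[nrow(tpl)],
                                   role = "tail")
      sequence_body <- substr(sequence, 1, nchar(sequence) - m)
    } else {
      sequence_body <- sequence
    }
  } else {
    sequence_body <- sequence
  }
  tpl_body <- tpl[tpl$kind != "tail", , drop = FALSE]
  units <- unique(tpl_body$unit[tpl_body$kind == "variable"])
  tokens <- tokenize_repeat_seq(sequence_body, units, config$motif_len)
  aligned <- align_tokens(tokens, tpl_body, units, config$motif_len)
  out <- rs_bind(aligned$structure, tail_seg)
  attr(out, "pattern_deviation") <- aligned$deviation || tail_dev
  attr(out, "template_skips") <- aligned$skips
  stopifnot(expand_structure(out) == sequence)
  out
}

# ---- tokenization ---------------------------------------------------------

run_length_at <- function(seq, pos, unit) {
  m <- nchar(unit)
  k <- 0L
  n <- nchar(seq)
  while (pos + (k + 1L) * m - 1L <= n &&
         substr(seq, pos + k * m, pos + (k + 1L) * m - 1L) == unit) {
    k <- k + 1L
  }
  k
}

first_run2 <- function(seq, from, unit) {
  m <- nchar(unit)
  n <- nchar(seq)
  pos <- from
  while (pos + 2L * m - 1L <= n) {
    if (substr(seq, pos, pos + m - 1L) == unit &&
        substr(seq, pos + m, pos + 2L * m - 1L) == unit) {
      return(pos)
    }
    pos <- pos + 1L
  }
  NA_integer_
}

tok_run <- function(u, k) list(type = "run", u = u, k = as.integer(k))
tok_stretch <- function(s) list(type = "stretch", s = s)
tok_gap <- function(len) list(type = "gap", len = as.integer(len))

tokenize_chunk <- function(chunk, units, motif_len) {
  tokens <- list()
  i <- 1L
  n <- nchar(chunk)
  while (i <= n) {
    cand_pos <- vapply(units, function(u) first_run2(chunk, i, u), integer(1))
    if (!length(cand_pos) || all(is.na(cand_pos))) {
      tokens[[length(tokens) + 1L]] <- tok_stretch(substr(chunk, i, n))
      break
    }
    # penalize runs that break the current motif reading frame, so a
    # frame-shifted alias (e.g. GAAA inside G|AAAG|AAAG...) does not steal
    # the anchor from the in-frame motif
    adj <- cand_pos + ifelse((cand_pos - i) %% motif_len == 0L, 0L, motif_len)
    u <- units[which.min(adj)]
    p <- cand_pos[which.min(adj)]
    if (p > i) {
      tokens[[length(tokens) + 1L]] <- tok_stretch(substr(chunk, i, p - 1L))
    }
    k <- run_length_at(chunk, p, u)
    tokens[[length(tokens) + 1L]] <- tok_run(u, k)
    i <- p + k * nchar(u)
  }
  tokens
}

tokenize_repeat_seq <- function(seq, units, motif_len) {
  tokens <- list()
  gaps <- gregexpr("N+", seq)[[1]]
  bounds <- if (gaps[1] == -1) integer() else as.integer(gaps)
  lens <- if (gaps[1] == -1) integer() else attr(gaps, "match.length")
  i <- 1L
  gi <- 1L
  n <- nchar(seq)
  while (i <= n) {
    if (gi <= length(bounds) && bounds[gi] == i) {
      tokens[[length(tokens) + 1L]] <- tok_gap(lens[gi])
      i <- i + lens[gi]
      gi <- gi + 1L
    } else {
      chunk_end <- if (gi <= length(bounds)) bounds[gi] - 1L else n
      tokens <- c(tokens, tokenize_chunk(substr(seq, i, chunk_end), units,
                                         motif_len))
      i <- chunk_end + 1L
    }
  }
  tokens
}

# ---- template alignment ---------------------------------------------------

COST_SKIP <- 1
COST_TRUNC <- 1
COST_NOVEL_RUN <- 2
COST_GAP_MISMATCH <- 1
COST_NOVEL_GAP <- 2
cost_word <- function(len, motif_len) 2.5 + 0.1 * (motif_len - len) / motif_len

seg_emit <- function(unit, count, counted, role, gap_len = NA_integer_,
                     dev = FALSE) {
  list(unit = unit, count = as.integer(count), counted = counted, role = role,
       gap_len = as.integer(gap_len), dev = dev)
}

align_tokens <- function(tokens, tpl, units, motif_len) {
  ntok <- length(tokens)
  ntpl <- nrow(tpl)
  memo <- new.env(parent = emptyenv())
  lit_of <- function(j) strrep(tpl$unit[j], tpl$count[j])

  rec <- function(t, off, j) {
    key <- paste(t, off, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (t > ntok) {
      res <- list(cost = COST_SKIP * (ntpl - j + 1L), segs = list(),
                  skips = ntpl - j + 1L)
      memo[[key]] <- res
      return(res)
    }
    tok <- tokens[[t]]
    if (tok$type == "stretch" && off >= nchar(tok$s)) {
      res <- rec(t + 1L, 0L, j)
      memo[[key]] <- res
      return(res)
    }
    best <- NULL
    consider <- function(cost_add, emits, nt, noff, nj, skip_add = 0L) {
      sub <- rec(nt, noff, nj)
      total <- cost_add + sub$cost
      if (is.null(best) || total < best$cost - 1e-9) {
        best <<- list(cost = total, segs = c(emits, sub$segs),
                      skips = skip_add + sub$skips)
      }
    }

    if (j <= ntpl) {
      consider(COST_SKIP, list(), t, off, j + 1L, skip_add = 1L)
    }

    if (tok$type == "run") {
      u <- tok$u; k <- tok$k
      if (j <= ntpl && tpl$kind[j] == "variable" && tpl$unit[j] == u) {
        Fmax <- 0L
        while (j + 1L + Fmax <= ntpl && tpl$kind[j + 1L + Fmax] == "fixed" &&
               tpl$unit[j + 1L + Fmax] == u) {
          Fmax <- Fmax + 1L
        }
        for (f in 0:Fmax) {
          idx <- if (f > 0) (j + 1L):(j + f) else integer()
          ftot <- sum(tpl$count[idx])
          fixed_emits <- lapply(idx, function(jj) {
            seg_emit(tpl$unit[jj], tpl$count[jj], tpl$counted[jj], "fixed")
          })
          if (k - ftot >= 1L) {
            emits <- c(list(seg_emit(u, k - ftot, tpl$counted[j], "variable")),
                       fixed_emits)
            consider(0, emits, t + 1L, 0L, j + 1L + f)
          } else if (k == ftot && f > 0L) {
            consider(COST_SKIP, fixed_emits, t + 1L, 0L, j + 1L + f,
                     skip_add = 1L)
          }
        }
      }
      if (j <= ntpl && tpl$kind[j] == "fixed" && tpl$unit[j] == u) {
        g <- 0L; tot <- 0L
        while (j + g <= ntpl && tpl$kind[j + g] == "fixed" &&
               tpl$unit[j + g] == u) {
          tot <- tot + tpl$count[j + g]
          g <- g + 1L
          if (tot == k) {
            idx <- j:(j + g - 1L)
            emits <- lapply(idx, function(jj) {
              seg_emit(tpl$unit[jj], tpl$count[jj], tpl$counted[jj], "fixed")
            })
            consider(0, emits, t + 1L, 0L, j + g)
            break
          }
          if (tot > k) break
        }
      }
      consider(COST_NOVEL_RUN,
               list(seg_emit(u, k, TRUE, "novel_run", dev = TRUE)),
               t + 1L, 0L, j)
    } else if (tok$type == "gap") {
      if (j <= ntpl && tpl$kind[j] == "gap") {
        mismatch <- tok$len != tpl$gap_len[j]
        consider(if (mismatch) COST_GAP_MISMATCH else 0,
                 list(seg_emit(NA_character_, NA_integer_, FALSE, "gap",
                               gap_len = tok$len, dev = mismatch)),
                 t + 1L, 0L, j + 1L)
      }
      consider(COST_NOVEL_GAP,
               list(seg_emit(NA_character_, NA_integer_, FALSE, "gap",
                             gap_len = tok$len, dev = TRUE)),
               t + 1L, 0L, j)
    } else { # stretch
      rem <- substr(tok$s, off + 1L, nchar(tok$s))
      if (j <= ntpl && tpl$kind[j] == "fixed") {
        lit <- lit_of(j)
        if (startsWith(rem, lit)) {
          consider(0,
                   list(seg_emit(tpl$unit[j], tpl$count[j], tpl$counted[j],
                                 "fixed")),
                   t, off + nchar(lit), j + 1L)
        }
        if (!tpl$counted[j] && nchar(lit) >= 2L) {
          for (l in seq_len(nchar(lit) - 1L)) {
            pieces <- unique(c(substr(lit, 1L, l),
                               substr(lit, nchar(lit) - l + 1L, nchar(lit))))
            for (piece in pieces) {
              if (startsWith(rem, piece)) {
                consider(COST_TRUNC,
                         list(seg_emit(piece, 1L, FALSE, "truncated",
                                       dev = TRUE)),
                         t, off + l, j + 1L)
              }
            }
          }
        }
      }
      for (u in units) {
        r <- run_length_at(rem, 1L, u)
        if (r >= 1L) {
          consider(COST_NOVEL_RUN,
                   list(seg_emit(u, r, TRUE, "novel_run", dev = TRUE)),
                   t, off + r * nchar(u), j)
        }
      }
      for (l in seq_len(min(motif_len, nchar(rem)))) {
        consider(cost_word(l, motif_len),
                 list(seg_emit(substr(rem, 1L, l), 1L, TRUE, "novel_word",
                               dev = TRUE)),
                 t, off + l, j)
      }
    }
    memo[[key]] <- best
    best
  }

  res <- rec(1L, 0L, 1L)
  segs <- res$segs
  structure_rows <- if (length(segs)) {
    new_repeat_structure(dplyr::bind_rows(lapply(segs, function(s) {
      tibble(unit = s$unit, count = s$count, counted = s$counted,
             role = s$role, gap_len = s$gap_len)
    })))
  } else {
    empty_structure()
  }
  deviation <- res$skips > 0L ||
    any(vapply(segs, function(s) isTRUE(s$dev), logical(1)))
  list(structure = structure_rows, deviation = deviation, skips = res$skips)
}
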