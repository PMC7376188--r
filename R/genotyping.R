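#' Read per-sample allele observation tables
#'
#' Observation tables emulate the per-allele output of an MPS STR typing
#' tool: one row per (sample, locus, allele sequence) with a read count.
#' Required columns: `sample`, `sex` (`"female"`/`"male"`), `locus`,
#' `sequence` (repeat-region nucleotides), `reads`; optional `flanks`
#' (printed flanking-variant annotations).
#'
#' @param path Path to a TSV file.
#' @return A tibble of observations.
#' @export
read_observations <- function(path) {
  obs <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    sex = readr::col_character(),
    locus = readr::col_character(),
    sequence = readr::col_character(),
    reads = readr::col_integer(),
    .default = readr::col_character()
  ))
  need <- c("sample", "sex", "locus", "sequence", "reads")
  if (!all(need %in% names(obs))) {
    stopf("observations need columns %s", paste(need, collapse = ", "),
          class = "forenseqr_input_error")
  }
  if (!"flanks" %in% names(obs)) obs$flanks <- ""
  obs$flanks[is.na(obs$flanks)] <- ""
  if (any(obs$reads < 0, na.rm = TRUE)) {
    stopf("negative read counts", class = "forenseqr_input_error")
  }
  obs
}

#' Threshold-based genotype calling from read counts
#'
#' Calls genotypes per sample and locus from per-allele read counts using
#' analytical (AT) and interpretation (IT) thresholds and an intralocus
#' balance cutoff:
#'
#' * alleles with reads below `AT x total` are discarded as noise;
#' * alleles between AT and IT are flagged `below_interpretation` and are
#'   not callable;
#' * among callable alleles, a second allele is retained as a heterozygote
#'   partner only when `reads(second)/reads(first) >= balance_threshold`;
#' * Y loci and male X loci are hemizygous (a balanced second callable
#'   allele raises `surplus_alleles`); diploid loci with a third balanced
#'   callable allele raise `mixture_suspect`.
#'
#' The allele coverage ratio (ACR) of a heterozygote is the lower read
#' count divided by the higher; calls with ACR below 0.5 are flagged
#' `imbalance_suspect` (the behaviour seen at severely imbalanced loci,
#' where heterozygotes are at risk of being miscalled as homozygotes).
#'
#' Two threshold profiles are available: `"relative"` interprets AT/IT as
#' fractions of the total reads at the sample and locus (instrument
#' software convention; the package default of AT 1.5%, IT 4.5% comes from
#' the locus configuration), and `"absolute"` uses a fixed read count
#' (default 2 reads) with a 0.40 balance threshold, the convention of
#' string-matching callers.
#'
#' @param observations Observation tibble (see [read_observations()]).
#' @param configs Named list of [locus_config()] objects.
#' @param profile `"relative"` (AT/IT fractions from the config) or
#'   `"absolute"` (fixed read count).
#' @param at_reads Analytical threshold in reads for the absolute profile.
#' @param absolute_balance Balance threshold for the absolute profile.
#' @return A tibble with one row per (sample, locus): called allele
#'   sequences and flank strings, read counts, `acr` and `flags`
#'   (`;`-separated, empty when clean).
#' @export
call_genotypes <- function(observations, configs,
                           profile = c("relative", "absolute"),
                           at_reads = 2L, absolute_balance = 0.40) {
  profile <- match.arg(profile)
  observations <- as_tibble(observations)
  if (!"flanks" %in% names(observations)) observations$flanks <- ""
  observations$flanks[is.na(observations$flanks)] <- ""
  observations |>
    dplyr::group_by(.data$sample, .data$sex, .data$locus) |>
    dplyr::group_modify(function(df, key) {
      cfg <- get_config(configs, key$locus)
      call_one_locus(df, cfg, key$sex, profile, at_reads, absolute_balance)
    }) |>
    dplyr::ungroup()
}

call_one_locus <- function(df, cfg, sex, profile, at_reads, absolute_balance) {
  no_call <- function(flags) {
    tibble(allele_1 = NA_character_, allele_2 = NA_character_,
           flanks_1 = NA_character_, flanks_2 = NA_character_,
           reads_1 = NA_integer_, reads_2 = NA_integer_,
           acr = NA_real_, flags = paste(flags, collapse = ";"))
  }
  total <- sum(df$reads)
  if (total == 0) return(no_call("no_call"))
  if (profile == "relative") {
    at <- cfg$analytical_threshold_pct * total
    it <- cfg$interpretation_threshold_pct * total
    balance <- cfg$balance_threshold
  } else {
    at <- at_reads
    it <- at_reads
    balance <- absolute_balance
  }
  df <- df[df$reads >= at, , drop = FALSE]
  flags <- character()
  callable <- df[df$reads >= it, , drop = FALSE]
  if (nrow(df) > nrow(callable)) flags <- c(flags, "below_interpretation")
  if (nrow(callable) == 0) return(no_call(c(flags, "no_call")))
  callable <- callable[order(-callable$reads, callable$sequence,
                             callable$flanks), , drop = FALSE]
  ploidy <- if (cfg$chrom_class == "Y" ||
                (cfg$chrom_class == "X" && identical(sex, "male"))) 1L else 2L
  top <- callable[1, ]
  second <- NULL
  if (nrow(callable) >= 2) {
    ratios <- callable$reads[-1] / top$reads
    balanced <- which(ratios >= balance)
    if (ploidy == 1L) {
      if (length(balanced)) flags <- c(flags, "surplus_alleles")
    } else {
      if (length(balanced) >= 1) second <- callable[1 + balanced[1], ]
      if (length(balanced) >= 2) flags <- c(flags, "mixture_suspect")
    }
  }
  if (!is.null(second)) {
    acr <- second$reads / top$reads
    if (acr < 0.5) flags <- c(flags, "imbalance_suspect")
    tibble(allele_1 = top$sequence, allele_2 = second$sequence,
           flanks_1 = top$flanks, flanks_2 = second$flanks,
           reads_1 = top$reads, reads_2 = second$reads,
           acr = acr, flags = paste(flags, collapse = ";"))
  } else {
    tibble(allele_1 = top$sequence, allele_2 = NA_character_,
           flanks_1 = top$flanks, flanks_2 = NA_character_,
           reads_1 = top$reads, reads_2 = NA_integer_,
           acr = NA_real_, flags = paste(flags, collapse = ";"))
  }
}

#' Summarise allele coverage ratios per locus
#'
#' Heterozygous calls only. A locus whose heterozygote ACRs never reach
#' 0.5 is marked `discard_recommended`: its heterozygotes sit in the range
#' where they risk being miscalled as homozygotes, and downstream
#' statistics should drop the locus.
#'
#' @param calls Output of [call_genotypes()].
#' @return A tibble with per-locus `n_het`, `mean_acr`, `min_acr`,
#'   `max_acr` and `discard_recommended`; loci without heterozygotes are
#'   omitted with a message.
#' @export
acr_summary <- function(calls) {
  hets <- calls[!is.na(calls$acr), , drop = FALSE]
  missing <- setdiff(unique(calls$locus), unique(hets$locus))
  if (length(missing)) {
    message("no heterozygous calls at: ", paste(missing, collapse = ", "))
  }
  hets |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_het = dplyr::n(),
      mean_acr = mean(.data$acr),
      min_acr = min(.data$acr),
      max_acr = max(.data$acr),
      .groups = "drop"
    ) |>
    dplyr::mutate(discard_recommended = .data$max_acr < 0.5)
}

#' Project sequence-based calls onto length-based genotypes
#'
#' Maps each called allele to its CE designation; distinct sequence alleles
#' with equal CE merge, so a sequence-based heterozygote whose two alleles
#' share a CE designation becomes a length-based homozygote.
#'
#' @param calls Output of [call_genotypes()].
#' @param configs Named list of [locus_config()] objects.
#' @return `calls` with `ce_1`, `ce_2` (sorted, `ce_2` `NA` for
#'   single-allele or merged calls) and `lb_merged` appended.
#' @export
lb_projection <- function(calls, configs) {
  key <- dplyr::bind_rows(
    dplyr::select(calls, locus = "locus", sequence = "allele_1",
                  flanks = "flanks_1"),
    dplyr::select(calls, locus = "locus", sequence = "allele_2",
                  flanks = "flanks_2")
  ) |>
    dplyr::filter(!is.na(.data$sequence)) |>
    dplyr::distinct()
  named <- name_alleles(key, configs)
  lookup <- setNames(named$ce_numeric,
                     paste(named$locus, named$sequence, named$flanks,
                           sep = "\r"))
  ce1 <- unname(lookup[paste(calls$locus, calls$allele_1, calls$flanks_1,
                             sep = "\r")])
  ce2 <- unname(lookup[paste(calls$locus, calls$allele_2, calls$flanks_2,
                             sep = "\r")])
  lo <- pmin(ce1, ce2, na.rm = FALSE)
  hi <- pmax(ce1, ce2, na.rm = FALSE)
  merged <- !is.na(ce2) & ce1 == ce2
  out <- calls
  out$ce_1 <- ifelse(is.na(ce2), ce1, lo)
  out$ce_2 <- ifelse(is.na(ce2) | merged, NA_real_, hi)
  out$lb_merged <- merged
  out
}

#' Concordance between two length-based genotype tables
#'
#' Compares two call sets on their length-based (CE) projections over the
#' shared loci: per-locus counts of concordant and discordant sample
#' calls, itemized discordances, and samples present in only one set
#' (listed separately, not counted).
#'
#' @param set_a,set_b Tables with columns `sample`, `locus`, `ce_1`, `ce_2`
#'   (e.g. from [lb_projection()]).
#' @param shared_loci Loci to compare; default, the intersection.
#' @return A `concordance_report`: list with `per_locus`, `discordances`
#'   and `unmatched_samples`. [generics::tidy()] returns the per-locus
#'   table, [generics::glance()] the overall rate.
#' @export
concordance_report <- function(set_a, set_b, shared_loci = NULL) {
  shared_loci <- shared_loci %||% intersect(unique(set_a$locus),
                                            unique(set_b$locus))
  a <- dplyr::filter(set_a, .data$locus %in% shared_loci)
  b <- dplyr::filter(set_b, .data$locus %in% shared_loci)
  gt_label <- function(ce_1, ce_2) {
    ifelse(is.na(ce_2), paste0(ce_1, "/", ce_1), paste0(ce_1, "/", ce_2))
  }
  a$gt_a <- gt_label(a$ce_1, a$ce_2)
  b$gt_b <- gt_label(b$ce_1, b$ce_2)
  j <- dplyr::inner_join(
    dplyr::select(a, "sample", "locus", "gt_a"),
    dplyr::select(b, "sample", "locus", "gt_b"),
    by = c("sample", "locus")
  )
  unmatched <- dplyr::bind_rows(
    dplyr::anti_join(dplyr::select(a, "sample", "locus"),
                     dplyr::select(b, "sample", "locus"),
                     by = c("sample", "locus")) |>
      dplyr::mutate(only_in = "a"),
    dplyr::anti_join(dplyr::select(b, "sample", "locus"),
                     dplyr::select(a, "sample", "locus"),
                     by = c("sample", "locus")) |>
      dplyr::mutate(only_in = "b")
  )
  j$concordant <- j$gt_a == j$gt_b
  per_locus <- j |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n = dplyr::n(),
      discordant = sum(!.data$concordant),
      concordant = sum(.data$concordant),
      .groups = "drop"
    ) |>
    dplyr::relocate("concordant", .before = "discordant") |>
    dplyr::mutate(concordance = .data$concordant / .data$n)
  out <- list(per_locus = per_locus,
              discordances = j[!j$concordant, , drop = FALSE],
              unmatched_samples = unmatched)
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  total <- sum(x$per_locus$n)
  disc <- sum(x$per_locus$discordant)
  cat(sprintf("<concordance_report> %d comparisons, %d discordant (%.2f%% concordance)\n",
              total, disc, if (total) 100 * (1 - disc / total) else NA_real_))
  if (disc > 0) print(x$discordances)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.concordance_report <- function(x, ...) x$per_locus

#' @importFrom generics glance
#' @export
glance.concordance_report <- function(x, ...) {
  tibble(
    n = sum(x$per_locus$n),
    n_loci = nrow(x$per_locus),
    discordant = sum(x$per_locus$discordant),
    concordance = if (sum(x$per_locus$n) > 0) {
      1 - sum(x$per_locus$discordant) / sum(x$per_locus$n)
    } else NA_real_
  )
}
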