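#' Counting-method allele frequencies with ploidy-aware denominators
#'
#' Relative allele frequencies obtained by direct counting. Each autosomal
#' (and female X) call contributes two chromosomes — homozygotes count
#' their allele twice — while male X and Y calls contribute one. The
#' denominator is therefore `2N` for autosomal loci, `2F + M` for X loci
#' and `M` for Y loci. Samples with a missing sex at a sex-linked locus
#' are excluded with a warning.
#'
#' @param calls Genotype calls (one row per sample and locus) with allele
#'   identity columns; see `freq_on`.
#' @param configs Named list of [locus_config()] objects.
#' @param freq_on Length-2 character vector naming the two allele identity
#'   columns, default `c("allele_1", "allele_2")`; use e.g.
#'   `c("ce_1", "ce_2")` for length-based frequencies after
#'   [lb_projection()].
#' @return A `freq_table` tibble: `locus`, `allele`, `count`,
#'   `denominator`, `frequency` (exact rational `count/denominator`).
#' @export
allele_frequencies <- function(calls, configs,
                               freq_on = c("allele_1", "allele_2")) {
  calls <- as_tibble(calls)
  a1 <- as.character(calls[[freq_on[1]]])
  a2 <- as.character(calls[[freq_on[2]]])
  out <- lapply(split(seq_len(nrow(calls)), calls$locus), function(idx) {
    locus <- calls$locus[idx[1]]
    cfg <- get_config(configs, locus)
    sex <- calls$sex[idx]
    if (cfg$chrom_class != "autosomal") {
      bad <- is.na(sex) | !sex %in% c("female", "male")
      if (any(bad)) {
        warn(sprintf("locus %s: %d sample(s) with missing sex excluded",
                     locus, sum(bad)))
        idx <- idx[!bad]
        sex <- sex[!bad]
      }
      if (cfg$chrom_class == "Y") {
        idx <- idx[sex == "male"]
        sex <- rep("male", length(idx))
      }
    }
    called <- !is.na(a1[idx])
    idx <- idx[called]
    sex <- sex[called]
    if (!length(idx)) return(NULL)
    # one chromosome for Y and male X, two otherwise; a single called
    # allele on a diploid chromosome is a homozygote and counts twice
    diploid <- !(cfg$chrom_class == "Y" |
                   (cfg$chrom_class == "X" & sex == "male"))
    alleles <- c(
      a1[idx][!diploid],
      a1[idx][diploid],
      ifelse(is.na(a2[idx][diploid]), a1[idx][diploid], a2[idx][diploid])
    )
    denom <- sum(ifelse(diploid, 2L, 1L))
    counts <- table(alleles)
    tibble(
      locus = locus,
      allele = names(counts),
      count = as.integer(counts),
      denominator = denom,
      frequency = as.integer(counts) / denom
    )
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$locus, dplyr::desc(.data$count), .data$allele)
  class(out) <- unique(c("freq_table", class(out)))
  out
}

#' Flanking-variant frequencies over chromosome denominators
#'
#' Counts each distinct flanking variant over the locus's chromosome
#' denominator, with the same ploidy weighting as [allele_frequencies()].
#' Variants physically inside the repeat region are reported but not
#' assigned a frequency (`counted = FALSE`), mirroring the "Not counted"
#' convention of printed flanking-variant tables.
#'
#' @inheritParams allele_frequencies
#' @return A tibble: `locus`, `annotation`, `kind`, `region`, `count`,
#'   `denominator`, `frequency`, `counted`.
#' @export
flank_variant_frequencies <- function(calls, configs) {
  calls <- as_tibble(calls)
  out <- lapply(split(seq_len(nrow(calls)), calls$locus), function(idx) {
    locus <- calls$locus[idx[1]]
    cfg <- get_config(configs, locus)
    sex <- calls$sex[idx]
    if (cfg$chrom_class == "Y") {
      idx <- idx[sex == "male"]
      sex <- rep("male", length(idx))
    }
    called <- !is.na(calls$allele_1[idx])
    idx <- idx[called]
    sex <- sex[called]
    if (!length(idx)) return(NULL)
    diploid <- !(cfg$chrom_class == "Y" |
                   (cfg$chrom_class == "X" & sex == "male"))
    f1 <- calls$flanks_1[idx]
    f2 <- ifelse(is.na(calls$allele_2[idx]), calls$flanks_1[idx],
                 calls$flanks_2[idx])
    strings <- c(f1[!diploid], f1[diploid], f2[diploid])
    strings[is.na(strings)] <- ""
    denom <- sum(ifelse(diploid, 2L, 1L))
    per_chrom <- lapply(strings, function(s) {
      fl <- parse_flank_annotations(s, cfg)
      if (nrow(fl) == 0) return(NULL)
      fl$annotation <- vapply(seq_len(nrow(fl)), function(i) {
        format_flank_annotations(fl[i, , drop = FALSE])
      }, character(1))
      fl
    })
    all_fl <- dplyr::bind_rows(per_chrom)
    if (is.null(all_fl) || nrow(all_fl) == 0) return(NULL)
    all_fl |>
      dplyr::group_by(.data$annotation, .data$kind, .data$region) |>
      dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        locus = locus,
        denominator = denom,
        counted = .data$region != "repeat_region",
        frequency = ifelse(.data$counted, .data$count / denom, NA_real_)
      ) |>
      dplyr::select("locus", "annotation", "kind", "region", "count",
                    "denominator", "frequency", "counted")
  })
  dplyr::bind_rows(out)
}

#' Gene (genetic) diversity
#'
#' Unbiased heterozygosity-style estimator
#' `GD = n (1 - sum p_i^2) / (n - 1)` where `n` is the number of sampled
#' chromosomes and `p_i` the allele frequencies.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @param n Number of sampled chromosomes (>= 2).
#' @return GD in `[0, 1]`.
#' @export
genetic_diversity <- function(p, n) {
  check_freqs(p)
  if (!is_scalar_number(n) || n < 2) {
    stopf("genetic diversity is undefined for n < 2",
          class = "forenseqr_input_error")
  }
  n * (1 - sum(p^2)) / (n - 1)
}

#' Haplotype diversity
#'
#' `HD = N (1 - sum p_j^2) / (N - 1)` over haplotype frequencies `p_j`
#' from `N` sampled haplotypes; equals 1 exactly when every haplotype is a
#' singleton.
#'
#' @param counts Integer vector of haplotype counts, or frequencies when
#'   `N` is given.
#' @param N Number of sampled haplotypes; inferred as `sum(counts)` when
#'   `counts` are counts.
#' @return HD in `[0, 1]`.
#' @export
#' @examples
#' haplotype_diversity(c(rep(1, 48), 2, 3))  # 0.9971 at 4 dp
haplotype_diversity <- function(counts, N = NULL) {
  if (is.null(N)) {
    N <- sum(counts)
    p <- counts / N
  } else {
    p <- counts
  }
  check_freqs(p)
  if (N < 2) {
    stopf("haplotype diversity is undefined for N < 2",
          class = "forenseqr_input_error")
  }
  N * (1 - sum(p^2)) / (N - 1)
}

#' Effective number of alleles
#'
#' Reciprocal of the expected homozygosity, `Ae = 1 / sum p_i^2`; the
#' screening index used for selecting microhaplotype loci for mixture
#' interpretation (useful loci show `Ae > 2`, strong ones `Ae > 3`).
#'
#' @inheritParams genetic_diversity
#' @return Ae in `[1, k]` for `k` alleles.
#' @export
effective_alleles <- function(p) {
  check_freqs(p)
  1 / sum(p^2)
}

check_freqs <- function(p) {
  if (!length(p) || any(p < 0)) {
    stopf("frequencies must be non-negative and non-empty",
          class = "forenseqr_input_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stopf("frequencies must sum to 1 (got %.12f)", sum(p),
          class = "forenseqr_input_error")
  }
  invisible(p)
}

#' Per-locus identity and kinship statistics from allele frequencies
#'
#' Closed forms under Hardy-Weinberg equilibrium:
#' * `pic(p)`: polymorphism information content
#'   `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`;
#' * `rmp(p)`: random match probability, the sum of squared expected
#'   genotype frequencies; discrimination power is `1 - rmp(p)`;
#' * `pe_duo(p)`: probability that a random unrelated man is excluded
#'   given only the child's genotype (he shares no allele with the child);
#' * `pe_trio(p)`: the same given mother and child, where the mother
#'   restricts the set of possible paternal alleles;
#' * `mec_duo_x(p)`, `mec_trio_x(p)`: the X-chromosomal analogues for
#'   father/daughter duos and father/mother/daughter trios — the alleged
#'   father is hemizygous, so exclusion requires only that his single X
#'   allele is impossible.
#'
#' All four exclusion forms are analytic sums over one or two allele
#' indices derived from exhaustive case analysis of the
#' mother/child/random-man genotype space; the test suite checks them
#' against brute-force enumeration oracles to 1e-12.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @name forensic_formulas
NULL

#' @rdname forensic_formulas
#' @export
pic <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' @rdname forensic_formulas
#' @param observed Optional table of observed genotype frequencies (named
#'   numeric, names `"i/j"` with allele indices); when supplied, RMP is
#'   the sum of their squares instead of the HWE expectation.
#' @export
rmp <- function(p, observed = NULL) {
  if (!is.null(observed)) return(sum(observed^2))
  check_freqs(p)
  hom <- sum(p^4)
  op <- outer(p, p)
  het <- sum((2 * op[upper.tri(op)])^2)
  hom + het
}

#' @rdname forensic_formulas
#' @export
pe_duo <- function(p) {
  check_freqs(p)
  hom <- sum(p^2 * (1 - p)^2)
  op <- outer(p, p)
  sum_p <- outer(p, p, `+`)
  ut <- upper.tri(op)
  het <- sum(2 * op[ut] * (1 - sum_p[ut])^2)
  hom + het
}

#' @rdname forensic_formulas
#' @export
pe_trio <- function(p) {
  check_freqs(p)
  hom <- sum(p^2 * (1 - p)^2)
  k <- length(p)
  het <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (b <= a) next
      pa <- p[a]; pb <- p[b]
      het <- het +
        pa * pb * (pa + pb) * (1 - pa - pb)^2 +  # mother carries both
        pa * pb * ((1 - pa)^3 + (1 - pb)^3)      # single obligate allele
    }
  }
  hom + het
}

#' @rdname forensic_formulas
#' @export
mec_duo_x <- function(p) {
  check_freqs(p)
  hom <- sum(p^2 * (1 - p))
  op <- outer(p, p)
  sum_p <- outer(p, p, `+`)
  ut <- upper.tri(op)
  hom + sum(2 * op[ut] * (1 - sum_p[ut]))
}

#' @rdname forensic_formulas
#' @export
mec_trio_x <- function(p) {
  check_freqs(p)
  hom <- sum(p^2 * (1 - p))
  k <- length(p)
  het <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (b <= a) next
      pa <- p[a]; pb <- p[b]
      het <- het +
        pa * pb * (pa + pb) * (1 - pa - pb) +
        pa * pb * ((1 - pa)^2 + (1 - pb)^2)
    }
  }
  hom + het
}

#' Per-locus forensic parameter table
#'
#' Computes, for every locus in a call set, the observed and expected
#' heterozygosity, PIC, RMP, discrimination power, paternity exclusion
#' powers (duo and trio) and — for X loci — the mean exclusion chance for
#' father/daughter duos and father/mother/daughter trios. Expected
#' heterozygosity uses the unbiased `n/(n-1)` correction with `n` the
#' chromosome count, i.e. the same estimator as [genetic_diversity()];
#' Y loci report gene diversity and effective allele number only.
#'
#' @inheritParams allele_frequencies
#' @param freqs Optional precomputed [allele_frequencies()] table; computed
#'   from `calls` when omitted.
#' @return A tibble with one row per locus and columns `n_typed`,
#'   `n_chromosomes`, `k_alleles`, `gd`, `ae`, `hobs`, `hexp`, `pic`,
#'   `rmp`, `dp`, `pe_duo`, `pe_trio`, `mec_duo`, `mec_trio` (the
#'   diploid-only columns are `NA` for Y loci, the MEC columns non-`NA`
#'   only for X loci).
#' @export
locus_parameters <- function(calls, configs, freqs = NULL,
                             freq_on = c("allele_1", "allele_2")) {
  freqs <- freqs %||% allele_frequencies(calls, configs, freq_on = freq_on)
  out <- lapply(split(freqs, freqs$locus), function(ft) {
    locus <- ft$locus[1]
    cfg <- get_config(configs, locus)
    p <- ft$frequency
    n_chrom <- ft$denominator[1]
    lc <- calls[calls$locus == locus & !is.na(calls[[freq_on[1]]]), ,
                drop = FALSE]
    diploid <- cfg$chrom_class == "autosomal" |
      (cfg$chrom_class == "X" & lc$sex == "female")
    hets <- !is.na(lc[[freq_on[2]]]) &
      lc[[freq_on[1]]] != lc[[freq_on[2]]]
    n_dip <- sum(diploid)
    row <- tibble(
      locus = locus,
      chrom_class = cfg$chrom_class,
      n_typed = nrow(lc),
      n_chromosomes = n_chrom,
      k_alleles = length(p),
      gd = if (n_chrom >= 2) genetic_diversity(p, n_chrom) else NA_real_,
      ae = effective_alleles(p),
      hobs = if (n_dip > 0) sum(hets & diploid) / n_dip else NA_real_,
      hexp = if (n_chrom >= 2) genetic_diversity(p, n_chrom) else NA_real_,
      pic = pic(p),
      rmp = rmp(p),
      pe_duo = pe_duo(p),
      pe_trio = pe_trio(p),
      mec_duo = if (cfg$chrom_class == "X") mec_duo_x(p) else NA_real_,
      mec_trio = if (cfg$chrom_class == "X") mec_trio_x(p) else NA_real_
    )
    row$dp <- 1 - row$rmp
    if (cfg$chrom_class == "Y") {
      row[c("hobs", "hexp", "pic", "rmp", "dp", "pe_duo", "pe_trio")] <-
        NA_real_
    }
    dplyr::relocate(row, "dp", .after = "rmp")
  })
  dplyr::bind_rows(out)
}
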