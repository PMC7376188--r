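#' Combine per-locus parameters into panel-level statistics
#'
#' For a set of independent loci, the cumulative match probability is the
#' product of the per-locus random match probabilities, the total
#' discrimination power its complement, and the combined powers of
#' exclusion `1 - prod(1 - PE)`. Products are accumulated in log space so
#' that panels reaching the 1e-70 scale neither underflow nor lose their
#' exponents; `log10` columns carry the exact magnitudes alongside the
#' (possibly denormalised) numeric values.
#'
#' X-STR loci are excluded unless `include_x = TRUE`, since combined
#' identity panels conventionally mix autosomal STRs and identity SNPs
#' only; when X loci are included their MEC columns are used for the
#' exclusion products.
#'
#' @param params Per-locus parameter table from [locus_parameters()] (needs
#'   `locus`, `chrom_class`, `rmp`, `pe_duo`, `pe_trio`, and MEC columns
#'   for X loci).
#' @param subset Optional character vector of loci to combine; default all
#'   eligible rows.
#' @param include_x Include X loci (using MEC for the exclusion products)?
#' @return A one-row `panel_summary` tibble: `n_loci`, `cmp`, `log10_cmp`,
#'   `tdp`, `cpe_duo`, `cpe_trio`, `log10_comp_cpe_*` (the complements'
#'   magnitudes) and display strings `cmp_label`, `tdp_label` following
#'   the `1-(x)` convention for values indistinguishable from 1.
#' @export
#' @examples
#' params <- tibble::tibble(locus = c("L1", "L2"), chrom_class = "autosomal",
#'                          rmp = c(0.1, 0.1), pe_duo = c(0.9, 0.9),
#'                          pe_trio = c(0.95, 0.95))
#' combine_panels(params)
combine_panels <- function(params, subset = NULL, include_x = FALSE) {
  params <- as_tibble(params)
  if (!is.null(subset)) {
    missing <- setdiff(subset, params$locus)
    if (length(missing)) {
      stopf("no parameters for locus '%s'", missing[1],
            class = "forenseqr_input_error")
    }
    params <- params[params$locus %in% subset, , drop = FALSE]
  }
  if ("chrom_class" %in% names(params)) {
    if (any(params$chrom_class == "Y")) {
      stopf("Y loci have no match/exclusion parameters to combine",
            class = "forenseqr_input_error")
    }
    if (!include_x) params <- params[params$chrom_class != "X", , drop = FALSE]
  }
  if (nrow(params) == 0) {
    stopf("no loci left to combine", class = "forenseqr_input_error")
  }
  pe_d <- params$pe_duo
  pe_t <- params$pe_trio
  if (include_x && "chrom_class" %in% names(params)) {
    x <- params$chrom_class == "X"
    pe_d[x] <- params$mec_duo[x]
    pe_t[x] <- params$mec_trio[x]
  }
  need <- cbind(params$rmp, pe_d, pe_t)
  if (anyNA(need)) {
    stopf("missing RMP/PE parameter at locus '%s'",
          params$locus[which(rowSums(is.na(need)) > 0)[1]],
          class = "forenseqr_input_error")
  }
  log10_cmp <- sum(log10(params$rmp))
  log10_comp_duo <- sum(log10(1 - pe_d))
  log10_comp_trio <- sum(log10(1 - pe_t))
  cmp <- 10^log10_cmp
  out <- tibble(
    n_loci = nrow(params),
    cmp = cmp,
    log10_cmp = log10_cmp,
    tdp = 1 - cmp,
    cpe_duo = 1 - 10^log10_comp_duo,
    cpe_trio = 1 - 10^log10_comp_trio,
    log10_comp_cpe_duo = log10_comp_duo,
    log10_comp_cpe_trio = log10_comp_trio,
    cmp_label = format_log10_scientific(log10_cmp),
    tdp_label = format_one_minus(log10_cmp),
    cpe_duo_label = format_complement(log10_comp_duo),
    cpe_trio_label = format_complement(log10_comp_trio)
  )
  attr(out, "loci") <- params$locus
  class(out) <- unique(c("panel_summary", class(out)))
  out
}

# "3.218E-34" from a log10 magnitude, 4 significant digits
format_log10_scientific <- function(log10_x) {
  e <- floor(log10_x)
  mant <- 10^(log10_x - e)
  if (round(mant, 3) >= 10) {
    mant <- mant / 10
    e <- e + 1
  }
  sprintf("%.3fE%+03d", mant, e)
}

# printed convention for probabilities indistinguishable from 1: "1-(x)"
format_one_minus <- function(log10_complement) {
  paste0("1-(", format_log10_scientific(log10_complement), ")")
}

format_complement <- function(log10_comp) {
  x <- 1 - 10^log10_comp
  if (x < 1 - 1e-12) {
    format(signif(x, 13), scientific = FALSE)
  } else {
    format_one_minus(log10_comp)
  }
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> %d loci  CMP %s  TDP %s  CPEduo %s  CPEtrio %s\n",
              x$n_loci, x$cmp_label, x$tdp_label, x$cpe_duo_label,
              x$cpe_trio_label))
  invisible(x)
}

#' @export
glance.panel_summary <- function(x, ...) {
  dplyr::select(as_tibble(x), "n_loci", "cmp", "log10_cmp", "tdp",
                "cpe_duo", "cpe_trio")
}
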