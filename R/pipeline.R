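#' Run the full analysis pipeline
#'
#' Convenience orchestrator chaining the stages: genotype calling from
#' observations, allele naming and classification, ACR QC, length-based
#' projection, allele and flanking-variant frequencies, per-locus forensic
#' parameters and panel combination. Each stage's output is returned (and
#' optionally written to an output directory together with a reproducible
#' run manifest).
#'
#' Loci whose ACR summary recommends discarding (all heterozygote ACRs
#' below 0.5) are excluded from the frequency and parameter stages, and
#' the exclusion is recorded in the manifest.
#'
#' @param observations Observation tibble or path to a TSV (see
#'   [read_observations()]).
#' @param configs Named list of [locus_config()] objects or path to a JSON
#'   configuration.
#' @param catalog Optional [allele_catalog()] or TSV path for novelty
#'   flagging.
#' @param outdir Optional output directory; stage outputs are written as
#'   TSV/CSV plus a `manifest.json`.
#' @param combine_subsets Optional named list of locus subsets to combine
#'   into panel summaries.
#' @return A list with elements `calls`, `alleles`, `acr`, `lb`, `freqs`,
#'   `flank_freqs`, `params`, `panels`, `manifest`.
#' @export
run_pipeline <- function(observations, configs, catalog = NULL,
                         outdir = NULL, combine_subsets = NULL) {
  t0 <- Sys.time()
  if (is.character(observations)) {
    observations <- read_observations(observations)
  }
  if (is.character(configs)) configs <- read_locus_config(configs)
  if (is.character(catalog)) catalog <- read_allele_catalog(catalog)

  calls <- call_genotypes(observations, configs)
  lb <- lb_projection(calls, configs)
  alleles <- name_alleles(
    dplyr::distinct(
      dplyr::filter(
        dplyr::bind_rows(
          dplyr::select(calls, "locus", sequence = "allele_1",
                        flanks = "flanks_1"),
          dplyr::select(calls, "locus", sequence = "allele_2",
                        flanks = "flanks_2")
        ),
        !is.na(.data$sequence)
      )
    ),
    configs, catalog = catalog
  )
  acr <- acr_summary(calls)
  discard <- acr$locus[acr$discard_recommended]
  kept <- calls[!calls$locus %in% discard, , drop = FALSE]
  freqs <- allele_frequencies(
    dplyr::mutate(kept,
                  allele_1 = paste(.data$allele_1, .data$flanks_1, sep = "|"),
                  allele_2 = ifelse(is.na(.data$allele_2), NA_character_,
                                    paste(.data$allele_2, .data$flanks_2,
                                          sep = "|"))),
    configs
  )
  flank_freqs <- flank_variant_frequencies(kept, configs)
  params <- locus_parameters(kept, configs)
  panels <- NULL
  if (!is.null(combine_subsets)) {
    panels <- lapply(combine_subsets, function(sub) {
      combine_panels(params, subset = setdiff(sub, discard))
    })
  }
  manifest <- list(
    tool = "forenseqr",
    version = as.character(utils::packageVersion("forenseqr")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_observations = nrow(observations),
    n_samples = length(unique(observations$sample)),
    n_loci = length(unique(observations$locus)),
    n_calls = nrow(calls),
    n_distinct_alleles = nrow(alleles),
    discarded_loci = as.list(discard)
  )
  out <- list(calls = calls, alleles = alleles, acr = acr, lb = lb,
              freqs = freqs, flank_freqs = flank_freqs, params = params,
              panels = panels, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(lb, file.path(outdir, "genotypes.tsv"))
    readr::write_tsv(alleles, file.path(outdir, "alleles.tsv"))
    readr::write_csv(acr, file.path(outdir, "acr_summary.csv"))
    readr::write_csv(freqs, file.path(outdir, "allele_frequencies.csv"))
    readr::write_csv(flank_freqs, file.path(outdir, "flank_variant_frequencies.csv"))
    readr::write_csv(params, file.path(outdir, "locus_parameters.csv"))
    if (!is.null(panels)) {
      panel_df <- dplyr::bind_rows(lapply(panels, as_tibble), .id = "panel")
      readr::write_csv(panel_df, file.path(outdir, "panel_summaries.csv"))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
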