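#' Simulation specifications for synthetic MPS cohorts
#'
#' Defines the statistical structure of a synthetic cohort: the locus set,
#' a per-locus allele pool with planted frequencies, the cohort size and
#' sex split (default 54 females and 53 males, a typical population-survey
#' panel), the read-coverage model, the heterozygote balance model, and
#' stutter/noise rates. All randomness flows from the mandatory seed.
#'
#' * Coverage: total reads per sample and locus are negative-binomial with
#'   `coverage_mean` and dispersion `coverage_size` (overdispersion typical
#'   of amplicon sequencing).
#' * Balance: for heterozygotes the target minor/major read ratio is drawn
#'   from `Beta(balance_shape1, balance_shape2)` (default mean 0.83,
#'   matching well-behaved loci whose average ACRs sit between 0.70 and
#'   0.96); reads are then split multinomially. A severe-imbalance regime
#'   (e.g. `Beta(10, 40)`, mean 0.2) reproduces the behaviour of loci whose
#'   heterozygotes never reach ACR 0.5.
#' * Stutter: each true allele spawns reads one full repeat shorter at
#'   binomial rate `stutter_rate` (default 0.02 of the allele's reads,
#'   which keeps stutter below the 1.5% analytical threshold of total
#'   locus reads, since no stutter filter is applied downstream).
#' * Noise: `noise_rate` of total reads lands on a random pool allele not
#'   in the genotype.
#'
#' @param configs Named list of [locus_config()] objects.
#' @param pools Named list (by locus) of tibbles with columns `sequence`,
#'   `flanks` (optional) and `freq` (summing to 1).
#' @param n_female,n_male Cohort sex split.
#' @param coverage_mean,coverage_size Negative-binomial coverage model.
#' @param balance_shape1,balance_shape2 Default Beta balance parameters.
#' @param balance_overrides Named list (by locus) of `c(shape1, shape2)`
#'   overrides, e.g. a severe-imbalance regime for one locus.
#' @param stutter_rate,noise_rate Artifact rates in `[0, 1]`.
#' @param seed Mandatory integer seed.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(configs, pools, n_female = 54L, n_male = 53L,
                            coverage_mean = 1000, coverage_size = 10,
                            balance_shape1 = 50, balance_shape2 = 10,
                            balance_overrides = list(),
                            stutter_rate = 0.02, noise_rate = 0.005,
                            seed) {
  if (missing(seed) || !is_scalar_number(seed)) {
    stopf("a scalar integer seed is mandatory", class = "forenseqr_input_error")
  }
  missing_cfg <- setdiff(names(pools), names(configs))
  if (length(missing_cfg)) {
    stopf("pool locus '%s' has no configuration", missing_cfg[1],
          class = "forenseqr_input_error")
  }
  pools <- lapply(pools, function(pool) {
    pool <- as_tibble(pool)
    if (!"flanks" %in% names(pool)) pool$flanks <- ""
    pool$flanks[is.na(pool$flanks)] <- ""
    if (nrow(pool) == 0) {
      stopf("empty allele pool", class = "forenseqr_input_error")
    }
    if (abs(sum(pool$freq) - 1) > 1e-9) {
      stopf("pool frequencies must sum to 1", class = "forenseqr_input_error")
    }
    pool
  })
  rates <- c(stutter_rate, noise_rate)
  if (any(rates < 0 | rates > 1)) {
    stopf("rates must lie in [0, 1]", class = "forenseqr_input_error")
  }
  structure(
    list(configs = configs[names(pools)], pools = pools,
         n_female = as.integer(n_female), n_male = as.integer(n_male),
         coverage_mean = coverage_mean, coverage_size = coverage_size,
         balance_shape1 = balance_shape1, balance_shape2 = balance_shape2,
         balance_overrides = balance_overrides,
         stutter_rate = stutter_rate, noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a cohort of read observations with full truth records
#'
#' Autosomal genotypes are drawn under Hardy-Weinberg equilibrium from the
#' planted pool frequencies; X genotypes are sex-aware (two draws for
#' females, one for males); Y alleles are drawn for males only. Read
#' counts follow the specification's coverage, balance, stutter and noise
#' models (see [simulation_spec()]).
#' Output is byte-identical for a fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `forenseq_sim` with `observations` (a tibble
#'   ready for [call_genotypes()]) and `truth` (per-sample planted
#'   genotypes plus the planted frequency table).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  samples <- tibble(
    sample = sprintf("S%03d", seq_len(spec$n_female + spec$n_male)),
    sex = rep(c("female", "male"), c(spec$n_female, spec$n_male))
  )
  obs_rows <- list()
  truth_rows <- list()
  for (locus in names(spec$pools)) {
    cfg <- spec$configs[[locus]]
    pool <- spec$pools[[locus]]
    bal <- spec$balance_overrides[[locus]] %||%
      c(spec$balance_shape1, spec$balance_shape2)
    stutter_seq <- vapply(pool$sequence, function(s) {
      stutter_sequence(s, cfg)
    }, character(1))
    for (r in seq_len(nrow(samples))) {
      sex <- samples$sex[r]
      ploidy <- if (cfg$chrom_class == "Y" ||
                    (cfg$chrom_class == "X" && sex == "male")) 1L else 2L
      if (cfg$chrom_class == "Y" && sex == "female") next
      gt <- sample.int(nrow(pool), ploidy, replace = TRUE, prob = pool$freq)
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        sample = samples$sample[r], sex = sex, locus = locus,
        truth_1 = pool$sequence[gt[1]], truth_flanks_1 = pool$flanks[gt[1]],
        truth_2 = if (ploidy == 2L) pool$sequence[gt[2]] else NA_character_,
        truth_flanks_2 = if (ploidy == 2L) pool$flanks[gt[2]] else NA_character_
      )
      total <- stats::rnbinom(1, mu = spec$coverage_mean,
                              size = spec$coverage_size)
      if (total == 0) next
      distinct_gt <- unique(gt)
      if (length(distinct_gt) == 2L) {
        ratio <- stats::rbeta(1, bal[1], bal[2])
        major_first <- stats::runif(1) < 0.5
        pr <- if (major_first) c(1, ratio) else c(ratio, 1)
        reads <- as.integer(stats::rmultinom(1, total, pr / sum(pr)))
      } else {
        reads <- total
      }
      alleles <- tibble(
        sequence = pool$sequence[distinct_gt],
        flanks = pool$flanks[distinct_gt],
        reads = reads
      )
      # stutter: reads one full repeat shorter, drawn per true allele
      if (spec$stutter_rate > 0) {
        st_reads <- stats::rbinom(nrow(alleles), alleles$reads,
                                  spec$stutter_rate)
        st_seq <- stutter_seq[match(alleles$sequence, pool$sequence)]
        keep <- st_reads > 0 & !is.na(st_seq)
        if (any(keep)) {
          alleles <- dplyr::bind_rows(alleles, tibble(
            sequence = st_seq[keep], flanks = alleles$flanks[keep],
            reads = st_reads[keep]
          ))
        }
      }
      if (spec$noise_rate > 0 && nrow(pool) > length(distinct_gt)) {
        n_noise <- stats::rbinom(1, total, spec$noise_rate)
        if (n_noise > 0) {
          others <- setdiff(seq_len(nrow(pool)), distinct_gt)
          pick <- others[sample.int(length(others), 1)]
          alleles <- dplyr::bind_rows(alleles, tibble(
            sequence = pool$sequence[pick], flanks = pool$flanks[pick],
            reads = n_noise
          ))
        }
      }
      alleles <- alleles |>
        dplyr::group_by(.data$sequence, .data$flanks) |>
        dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
      obs_rows[[length(obs_rows) + 1L]] <- dplyr::mutate(
        alleles, sample = samples$sample[r], sex = sex, locus = locus,
        .before = 1
      )
    }
  }
  planted <- dplyr::bind_rows(lapply(names(spec$pools), function(locus) {
    dplyr::mutate(spec$pools[[locus]], locus = locus, .before = 1)
  }))
  out <- list(
    observations = dplyr::bind_rows(obs_rows) |>
      dplyr::select("sample", "sex", "locus", "sequence", "flanks", "reads"),
    truth = list(genotypes = dplyr::bind_rows(truth_rows),
                 frequencies = planted),
    spec = spec
  )
  class(out) <- "forenseq_sim"
  out
}

# one full repeat shorter: decrement the longest counted variable run
stutter_sequence <- function(sequence, config) {
  st <- tryCatch(bracket_encode(sequence, config), error = function(e) NULL)
  if (is.null(st)) return(NA_character_)
  cand <- which(st$counted & !is.na(st$count) & st$count >= 2 &
                  st$role %in% c("variable", "novel_run"))
  if (!length(cand)) return(NA_character_)
  pick <- cand[which.max(st$count[cand])]
  st$count[pick] <- st$count[pick] - 1L
  expand_structure(st)
}

#' @export
print.forenseq_sim <- function(x, ...) {
  cat(sprintf("<forenseq_sim> %d observations, %d loci, %d samples (seed %d)\n",
              nrow(x$observations), length(unique(x$observations$locus)),
              length(unique(x$observations$sample)), x$spec$seed))
  invisible(x)
}

#' End-to-end recovery check of the pipeline on a synthetic cohort
#'
#' Simulates (or takes) a cohort, runs genotype calling, naming,
#' classification and frequency estimation, and scores each stage against
#' the planted truth:
#'
#' * genotype accuracy: fraction of sample-locus calls whose unordered
#'   allele set equals the planted genotype;
#' * classification accuracy: agreement between the variant classes of the
#'   called alleles and those of the planted pool (computed from the pool
#'   itself, or taken from a `variant_class` pool column when planted
#'   explicitly);
#' * frequency recovery: per locus, whether every allele count lies inside
#'   its simultaneous 99% exact binomial acceptance region
#'   (Bonferroni-adjusted across the locus's alleles) around the planted
#'   frequency.
#'
#' @param sim A `forenseq_sim` (or a [simulation_spec()], which is
#'   simulated first).
#' @return A `recovery_report` list; [generics::tidy()] gives the
#'   per-locus table and [generics::glance()] the overall summary.
#' @export
recovery_suite <- function(sim) {
  if (inherits(sim, "simulation_spec")) sim <- simulate_cohort(sim)
  stopifnot(inherits(sim, "forenseq_sim"))
  configs <- sim$spec$configs
  calls <- call_genotypes(sim$observations, configs)
  truth <- sim$truth$genotypes
  key <- function(s1, f1, s2, f2) {
    a <- paste(s1, f1, sep = "|")
    b <- ifelse(is.na(s2), a, paste(s2, f2, sep = "|"))
    ifelse(a <= b, paste(a, b, sep = "&"), paste(b, a, sep = "&"))
  }
  j <- dplyr::inner_join(calls, truth, by = c("sample", "sex", "locus"))
  j$called_key <- key(j$allele_1, j$flanks_1, j$allele_2, j$flanks_2)
  j$truth_key <- key(j$truth_1, j$truth_flanks_1, j$truth_2,
                     j$truth_flanks_2)
  j$gt_correct <- !is.na(j$allele_1) & j$called_key == j$truth_key
  genotype_acc <- j |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n = dplyr::n(), genotype_accuracy = mean(.data$gt_correct),
                     .groups = "drop")

  pool_named <- dplyr::bind_rows(lapply(names(sim$spec$pools), function(locus) {
    dplyr::mutate(sim$spec$pools[[locus]], locus = locus, .before = 1)
  }))
  planted_class <- if ("variant_class" %in% names(pool_named)) {
    pool_named
  } else {
    name_alleles(pool_named, configs)
  }
  called_alleles <- dplyr::bind_rows(
    dplyr::select(calls, "locus", sequence = "allele_1", flanks = "flanks_1"),
    dplyr::select(calls, "locus", sequence = "allele_2", flanks = "flanks_2")
  ) |>
    dplyr::filter(!is.na(.data$sequence)) |>
    dplyr::distinct()
  called_named <- name_alleles(called_alleles, configs)
  cls <- dplyr::inner_join(
    called_named,
    dplyr::select(planted_class, "locus", "sequence", "flanks",
                  planted_class = "variant_class"),
    by = c("locus", "sequence", "flanks")
  )
  class_acc <- mean(cls$variant_class == cls$planted_class)

  freqs <- allele_frequencies(
    dplyr::mutate(calls,
                  allele_1 = paste(.data$allele_1, .data$flanks_1, sep = "|"),
                  allele_2 = ifelse(is.na(.data$allele_2), NA_character_,
                                    paste(.data$allele_2, .data$flanks_2,
                                          sep = "|"))),
    configs
  )
  freq_check <- pool_named |>
    dplyr::mutate(allele = paste(.data$sequence, .data$flanks, sep = "|")) |>
    dplyr::left_join(freqs, by = c("locus", "allele")) |>
    dplyr::group_by(.data$locus) |>
    dplyr::group_modify(function(df, key) {
      n <- max(df$denominator, na.rm = TRUE)
      level <- 0.01 / nrow(df)  # simultaneous 99% across the locus's alleles
      df$count[is.na(df$count)] <- 0L
      lo <- stats::qbinom(level / 2, n, df$freq)
      hi <- stats::qbinom(1 - level / 2, n, df$freq)
      tibble(
        n_alleles = nrow(df),
        max_abs_error = max(abs(df$count / n - df$freq)),
        recovered = all(df$count >= lo & df$count <= hi)
      )
    }) |>
    dplyr::ungroup()

  per_locus <- genotype_acc |>
    dplyr::left_join(freq_check, by = "locus")
  out <- list(
    per_locus = per_locus,
    classification = cls,
    overall = tibble(
      n_calls = nrow(j),
      genotype_accuracy = mean(j$gt_correct),
      classification_accuracy = class_acc,
      freq_recovery_rate = mean(freq_check$recovered)
    )
  )
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$overall)
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$per_locus

#' @export
glance.recovery_report <- function(x, ...) x$overall
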