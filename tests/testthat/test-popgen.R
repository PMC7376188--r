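cfgs <- test_configs()

test_that("counting frequencies use ploidy-aware denominators", {
  # X locus: 54 females (2 chromosomes) + 53 males (1) = 161
  calls <- tibble::tibble(
    sample = sprintf("S%03d", 1:107),
    sex = rep(c("female", "male"), c(54, 53)),
    locus = "DXS8378",
    allele_1 = c("VAR", rep("REF", 106)),
    allele_2 = c(rep("REF", 54), rep(NA, 53))
  )
  ft <- allele_frequencies(calls, cfgs)
  expect_equal(unique(ft$denominator), 161L)
  expect_equal(ft$frequency[ft$allele == "VAR"], 1 / 161)
  expect_equal(round(ft$frequency[ft$allele == "VAR"], 4), 0.0062)
  expect_equal(sum(ft$frequency), 1)
  # autosomal: homozygotes count twice, denominator 2N = 214
  calls <- tibble::tibble(
    sample = sprintf("S%03d", 1:107), sex = "female", locus = "D6S1043",
    allele_1 = c("VAR", rep("REF", 106)),
    allele_2 = c(rep("REF", 10), rep(NA, 97))
  )
  ft <- allele_frequencies(calls, cfgs)
  expect_equal(unique(ft$denominator), 214L)
  expect_equal(round(ft$frequency[ft$allele == "VAR"], 4), 0.0047)
  # Y locus: males only
  calls <- tibble::tibble(
    sample = sprintf("S%03d", 1:107),
    sex = rep(c("female", "male"), c(54, 53)),
    locus = "DYS481",
    allele_1 = "REF", allele_2 = NA_character_
  )
  ft <- allele_frequencies(calls, cfgs)
  expect_equal(unique(ft$denominator), 53L)
  expect_equal(ft$frequency, 1)
})

test_that("flanking-variant frequencies count chromosomes carrying the variant", {
  # 53 males; alleles with the downstream G carried on 23 chromosomes
  n_carrier <- c(7, 15, 1)
  seqs <- c(strrep("TCTA", 10), strrep("TCTA", 11), strrep("TCTA", 12))
  calls <- tibble::tibble(
    sample = sprintf("M%03d", 1:53), sex = "male", locus = "Y-GATA-H4",
    allele_1 = c(rep(seqs, n_carrier), rep(strrep("TCTA", 11), 30)),
    allele_2 = NA_character_,
    flanks_1 = c(rep("16,631,756-G", 23), rep("", 30)),
    flanks_2 = NA_character_
  )
  ff <- flank_variant_frequencies(calls, cfgs)
  expect_equal(ff$count, 23L)
  expect_equal(ff$denominator, 53L)
  expect_equal(round(ff$frequency, 4), 0.4340)
  # a repeat-region deletion is reported but not counted
  calls <- tibble::tibble(
    sample = "M1", sex = "male", locus = "DYS448",
    allele_1 = paste0(strrep("AGAGAT", 11), strrep("N", 36),
                      strrep("AGAGAT", 8)),
    allele_2 = NA_character_,
    flanks_1 = "22,218,995–22,219,000 DEL", flanks_2 = NA_character_
  )
  ff <- flank_variant_frequencies(calls, cfgs)
  expect_false(ff$counted)
  expect_true(is.na(ff$frequency))
})

test_that("gene diversity follows the unbiased estimator", {
  expect_equal(round(genetic_diversity(c(47, 6) / 53, 53), 4), 0.2046)
  expect_equal(genetic_diversity(1, 50), 0)
  # uniform k alleles approach (k-1)/k as n grows
  expect_equal(genetic_diversity(rep(0.25, 4), 1e9), 0.75,
               tolerance = 1e-6)
  expect_error(genetic_diversity(c(0.5, 0.5), 1), "undefined")
})

test_that("haplotype diversity matches the worked singleton-heavy example", {
  expect_equal(round(haplotype_diversity(c(rep(1, 48), 2, 3)), 4), 0.9971)
  # all distinct haplotypes give exactly 1
  expect_equal(haplotype_diversity(rep(1, 53)), 1)
  expect_equal(haplotype_diversity(c(10)), 0)
  expect_error(haplotype_diversity(c(1)), "undefined")
})

test_that("effective allele number is the reciprocal homozygosity", {
  expect_equal(effective_alleles(rep(0.25, 4)), 4)
  expect_equal(effective_alleles(c(0.5, 0.5)), 2)
  p <- random_freqs(6)
  expect_lte(effective_alleles(p), 6)
  expect_gte(effective_alleles(p), 1)
})

test_that("closed forms match their definitions at p = (0.5, 0.5)", {
  p <- c(0.5, 0.5)
  expect_equal(rmp(p), 0.375)
  expect_equal(1 - rmp(p), 0.625)
  expect_equal(pic(p), 0.375)
  expect_equal(pe_trio(p), oracle_pe_trio(p), tolerance = 1e-14)
  expect_equal(mec_duo_x(p), oracle_mec_duo_x(p), tolerance = 1e-14)
  expect_equal(mec_trio_x(p), oracle_mec_trio_x(p), tolerance = 1e-14)
  # degenerate single-allele locus excludes nobody
  expect_equal(mec_duo_x(1), 0)
  expect_equal(mec_trio_x(1), 0)
  expect_equal(pe_duo(1), 0)
  expect_equal(pe_trio(1), 0)
})

test_that("exclusion closed forms equal enumeration oracles on random vectors", {
  set.seed(13)
  for (i in 1:60) {
    p <- random_freqs(sample(2:5, 1))
    expect_equal(pe_duo(p), oracle_pe_duo(p), tolerance = 1e-12)
    expect_equal(pe_trio(p), oracle_pe_trio(p), tolerance = 1e-12)
    expect_equal(mec_duo_x(p), oracle_mec_duo_x(p), tolerance = 1e-12)
    expect_equal(mec_trio_x(p), oracle_mec_trio_x(p), tolerance = 1e-12)
    expect_equal(rmp(p), oracle_rmp(p), tolerance = 1e-12)
    # trio information never hurts
    expect_gte(mec_trio_x(p), mec_duo_x(p) - 1e-12)
    expect_gte(pe_trio(p), pe_duo(p) - 1e-12)
    # PIC is bounded by expected heterozygosity
    expect_lte(pic(p), 1 - sum(p^2) + 1e-12)
  }
})

test_that("locus parameter tables tie the estimators together", {
  set.seed(17)
  pool <- c("A", "B", "C", "D")
  pfreq <- c(0.4, 0.3, 0.2, 0.1)
  n <- 200
  g1 <- sample(pool, n, TRUE, pfreq)
  g2 <- sample(pool, n, TRUE, pfreq)
  calls <- tibble::tibble(
    sample = sprintf("S%03d", 1:n), sex = "female", locus = "D7S820",
    allele_1 = pmin(g1, g2), allele_2 = pmax(g1, g2)
  )
  calls$allele_2[calls$allele_1 == calls$allele_2] <- NA
  params <- locus_parameters(calls, cfgs)
  ft <- allele_frequencies(calls, cfgs)
  p <- ft$frequency
  # Hexp is the gene-diversity estimator with n = chromosome count
  expect_equal(params$hexp, genetic_diversity(p, 2 * n))
  expect_equal(params$gd, params$hexp)
  expect_equal(params$dp + params$rmp, 1)
  expect_equal(params$hobs,
               mean(!is.na(calls$allele_2)))
  expect_equal(params$n_chromosomes, 2L * n)
  # X loci additionally carry MEC values
  xcalls <- dplyr::mutate(calls, locus = "DXS8378")
  xp <- locus_parameters(xcalls, cfgs)
  expect_false(is.na(xp$mec_duo))
  expect_equal(xp$mec_trio, mec_trio_x(allele_frequencies(xcalls, cfgs)$frequency))
  # Y loci report diversity only
  ycalls <- tibble::tibble(sample = sprintf("S%03d", 1:50), sex = "male",
                           locus = "DYS481",
                           allele_1 = sample(pool, 50, TRUE, pfreq),
                           allele_2 = NA_character_)
  yp <- locus_parameters(ycalls, cfgs)
  expect_true(is.na(yp$rmp))
  expect_false(is.na(yp$gd))
})
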