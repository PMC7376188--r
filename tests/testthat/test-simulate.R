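cfgs <- test_configs()

test_that("simulation specs validate their inputs", {
  pools <- build_test_pools(cfgs, "D7S820")
  expect_error(simulation_spec(cfgs, pools), "seed")
  bad <- pools
  bad$D7S820$freq <- bad$D7S820$freq * 2
  expect_error(simulation_spec(cfgs, bad, seed = 1), "sum to 1")
  expect_error(
    simulation_spec(cfgs, list(NOPE = pools$D7S820), seed = 1),
    "no configuration"
  )
  expect_error(
    simulation_spec(cfgs, list(D7S820 = pools$D7S820[0, ]), seed = 1),
    "empty"
  )
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  pools <- build_test_pools(cfgs, c("D7S820", "DYS481", "DXS8378"))
  spec <- simulation_spec(cfgs, pools, n_female = 10, n_male = 10, seed = 99)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$truth$genotypes, s2$truth$genotypes)
})

test_that("sex-aware ploidy: Y male-only haplotypes, hemizygous male X", {
  pools <- build_test_pools(cfgs, c("DYS481", "DXS8378"))
  spec <- simulation_spec(cfgs, pools, n_female = 12, n_male = 8, seed = 5)
  sim <- simulate_cohort(spec)
  truth <- sim$truth$genotypes
  y <- truth[truth$locus == "DYS481", ]
  expect_true(all(y$sex == "male"))
  expect_true(all(is.na(y$truth_2)))
  xm <- truth[truth$locus == "DXS8378" & truth$sex == "male", ]
  expect_true(all(is.na(xm$truth_2)))
  xf <- truth[truth$locus == "DXS8378" & truth$sex == "female", ]
  expect_true(all(!is.na(xf$truth_2)))
})

test_that("autosomal genotypes are drawn under Hardy-Weinberg", {
  pool <- tibble::tibble(sequence = c(strrep("TATC", 9), strrep("TATC", 10)),
                         flanks = "", freq = c(0.5, 0.5))
  spec <- simulation_spec(cfgs, list(D7S820 = pool), n_female = 500,
                          n_male = 500, stutter_rate = 0, noise_rate = 0,
                          seed = 7)
  sim <- simulate_cohort(spec)
  het <- mean(sim$truth$genotypes$truth_1 != sim$truth$genotypes$truth_2)
  # expected heterozygote fraction 0.5; 99% binomial band for N = 1000
  expect_gt(het, 0.5 - 2.58 * sqrt(0.25 / 1000))
  expect_lt(het, 0.5 + 2.58 * sqrt(0.25 / 1000))
})

test_that("emitted observations pass through the reader unchanged", {
  pools <- build_test_pools(cfgs, c("D7S820", "D21S11"))
  spec <- simulation_spec(cfgs, pools, n_female = 5, n_male = 5, seed = 3)
  sim <- simulate_cohort(spec)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$observations, tmp)
  back <- read_observations(tmp)
  expect_equal(as.data.frame(back), as.data.frame(sim$observations))
})

test_that("simulated balance is recovered by the ACR summary", {
  pool <- tibble::tibble(sequence = c(strrep("TATC", 9), strrep("TATC", 10)),
                         flanks = "", freq = c(0.5, 0.5))
  spec <- simulation_spec(cfgs, list(D7S820 = pool), n_female = 300,
                          n_male = 300, balance_shape1 = 50,
                          balance_shape2 = 10, stutter_rate = 0,
                          noise_rate = 0, seed = 11)
  sim <- simulate_cohort(spec)
  calls <- call_genotypes(sim$observations, cfgs)
  s <- acr_summary(calls)
  target <- 50 / 60  # Beta(50, 10) mean
  se <- sqrt(stats::var(calls$acr, na.rm = TRUE) / s$n_het)
  expect_lt(abs(s$mean_acr - target), 3 * se + 0.01)
  expect_false(s$discard_recommended)
})

test_that("stutter lands one repeat short and below the analytical threshold", {
  pool <- tibble::tibble(sequence = strrep("TATC", 10), flanks = "",
                         freq = 1)
  spec <- simulation_spec(cfgs, list(D7S820 = pool), n_female = 30,
                          n_male = 0, stutter_rate = 0.02, noise_rate = 0,
                          seed = 13)
  sim <- simulate_cohort(spec)
  seqs <- unique(sim$observations$sequence)
  expect_true(strrep("TATC", 9) %in% seqs)
  st <- sim$observations[sim$observations$sequence == strrep("TATC", 9), ]
  tot <- sim$observations |>
    dplyr::group_by(sample) |>
    dplyr::summarise(total = sum(reads))
  frac <- st$reads / tot$total[match(st$sample, tot$sample)]
  expect_lt(max(frac), 0.045)
  # homozygote calls are unaffected
  calls <- call_genotypes(sim$observations, cfgs)
  expect_true(all(calls$allele_1 == strrep("TATC", 10)))
  expect_true(all(is.na(calls$allele_2)))
})

test_that("the recovery suite reports truthful accuracies on a clean cohort", {
  pools <- build_test_pools(cfgs, c("D7S820", "D16S539", "DXS8378"))
  spec <- simulation_spec(cfgs, pools, n_female = 30, n_male = 30,
                          balance_shape1 = 90, balance_shape2 = 10,
                          stutter_rate = 0, noise_rate = 0, seed = 17)
  rep <- recovery_suite(spec)
  expect_equal(glance(rep)$genotype_accuracy, 1)
  expect_equal(glance(rep)$classification_accuracy, 1)
  expect_true(all(tidy(rep)$n > 0))
})
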