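cfgs <- test_configs()

obs_row <- function(sample, locus, seqs, reads, sex = "female",
                    flanks = "") {
  tibble::tibble(sample = sample, sex = sex, locus = locus,
                 sequence = seqs, flanks = flanks, reads = reads)
}

test_that("balanced heterozygotes are called with their ACR", {
  obs <- obs_row("S1", "D7S820", c(strrep("TATC", 10), strrep("TATC", 11)),
                 c(500L, 400L))
  call <- call_genotypes(obs, cfgs)
  expect_equal(call$acr, 0.8)
  expect_equal(sort(c(call$allele_1, call$allele_2)),
               sort(c(strrep("TATC", 10), strrep("TATC", 11))))
  expect_equal(call$flags, "")
})

test_that("the balance threshold separates homozygote calls from flagged imbalance", {
  # ratio 0.12: below the default 0.60 cutoff -> homozygote
  obs <- obs_row("S1", "D7S820", c(strrep("TATC", 10), strrep("TATC", 11)),
                 c(500L, 60L))
  call <- call_genotypes(obs, cfgs)
  expect_true(is.na(call$allele_2))
  expect_equal(call$allele_1, strrep("TATC", 10))
  # the same read pattern at the 0.10-threshold locus is a heterozygote,
  # flagged as imbalance-suspect (ACR < 0.5)
  obs <- obs_row("S1", "D22S1045", c(strrep("ATT", 14), strrep("ATT", 15)),
                 c(500L, 60L))
  call <- call_genotypes(obs, cfgs)
  expect_false(is.na(call$allele_2))
  expect_equal(call$acr, 0.12)
  expect_match(call$flags, "imbalance_suspect")
})

test_that("alleles between AT and IT are flagged and not called", {
  obs <- obs_row("S1", "D7S820",
                 c(strrep("TATC", 10), strrep("TATC", 11), strrep("TATC", 9)),
                 c(1000L, 30L, 20L))
  # total 1050: AT = 15.75, IT = 47.25; 30 and 20 sit between the two
  call <- call_genotypes(obs, cfgs)
  expect_true(is.na(call$allele_2))
  expect_equal(call$allele_1, strrep("TATC", 10))
  expect_match(call$flags, "below_interpretation")
})

test_that("hemizygous loci never yield two alleles", {
  obs <- obs_row("S1", "DYS481", c(strrep("CTT", 22), strrep("CTT", 23)),
                 c(500L, 450L), sex = "male")
  call <- call_genotypes(obs, cfgs)
  expect_true(is.na(call$allele_2))
  expect_match(call$flags, "surplus_alleles")
  obs <- obs_row("S1", "DXS8378", c(strrep("ATAG", 10), strrep("ATAG", 11)),
                 c(500L, 450L), sex = "male")
  call <- call_genotypes(obs, cfgs)
  expect_true(is.na(call$allele_2))
  # the same locus in a female is an ordinary heterozygote
  obs$sex <- "female"
  call <- call_genotypes(obs, cfgs)
  expect_false(is.na(call$allele_2))
})

test_that("calling is deterministic and ACR is scale-invariant", {
  obs <- obs_row("S1", "D7S820", c(strrep("TATC", 10), strrep("TATC", 11)),
                 c(531L, 402L))
  c1 <- call_genotypes(obs, cfgs)
  obs10 <- dplyr::mutate(obs, reads = reads * 10L)
  c2 <- call_genotypes(obs10, cfgs)
  expect_equal(c1$acr, c2$acr)
  expect_identical(c1$allele_1, c2$allele_1)
})

test_that("zero reads and third balanced alleles raise the right flags", {
  obs <- obs_row("S1", "D7S820", strrep("TATC", 10), 0L)
  call <- call_genotypes(obs, cfgs)
  expect_true(is.na(call$allele_1))
  expect_match(call$flags, "no_call")
  obs <- obs_row("S1", "D7S820",
                 c(strrep("TATC", 10), strrep("TATC", 11), strrep("TATC", 9)),
                 c(500L, 450L, 400L))
  call <- call_genotypes(obs, cfgs)
  expect_match(call$flags, "mixture_suspect")
})

test_that("the absolute threshold profile uses fixed reads and a 0.40 balance", {
  obs <- obs_row("S1", "D7S820", c(strrep("TATC", 10), strrep("TATC", 11)),
                 c(100L, 45L))
  rel <- call_genotypes(obs, cfgs)             # ratio 0.45 < 0.60 -> hom
  abs <- call_genotypes(obs, cfgs, profile = "absolute")  # 0.45 >= 0.40
  expect_true(is.na(rel$allele_2))
  expect_false(is.na(abs$allele_2))
})

test_that("ACR summaries flag loci whose heterozygotes never reach 0.5", {
  calls <- tibble::tibble(
    sample = rep(c("S1", "S2", "S3"), 2),
    locus = rep(c("GOOD", "BAD"), each = 3),
    acr = c(1, 1, 1, 0.2, 0.3, 0.45)
  )
  s <- acr_summary(calls)
  expect_equal(s$mean_acr[s$locus == "GOOD"], 1)
  expect_false(s$discard_recommended[s$locus == "GOOD"])
  expect_true(s$discard_recommended[s$locus == "BAD"])
  # loci without heterozygotes are omitted with a notice
  calls2 <- dplyr::bind_rows(calls,
                             tibble::tibble(sample = "S1", locus = "HOMONLY",
                                            acr = NA_real_))
  expect_message(s2 <- acr_summary(calls2), "HOMONLY")
  expect_false("HOMONLY" %in% s2$locus)
})

test_that("length-based projection merges same-CE heterozygotes", {
  obs <- dplyr::bind_rows(
    obs_row("S1", "D7S820", rep(strrep("TATC", 10), 2), c(500L, 420L),
            flanks = c("", "84,160,204-A")),
    obs_row("S2", "FGA", c(
      paste0(strrep("GGAA", 2), "GGAG", strrep("AAAG", 16),
             "AGAGAAAGAGAAAAAA", strrep("GAAA", 3)),
      paste0(strrep("GGAA", 2), "GGAG", strrep("AAAG", 17),
             "AGAGAAAGAGAAAAAA", strrep("GAAA", 3))), c(480L, 450L))
  )
  calls <- call_genotypes(obs, cfgs)
  lb <- lb_projection(calls, cfgs)
  d7 <- lb[lb$locus == "D7S820", ]
  expect_equal(d7$ce_1, 10)
  expect_true(is.na(d7$ce_2))
  expect_true(d7$lb_merged)
  fga <- lb[lb$locus == "FGA", ]
  expect_equal(sort(c(fga$ce_1, fga$ce_2)), c(26, 27))
})

test_that("concordance reports count discordances where they occur", {
  a <- tibble::tibble(sample = rep(c("S1", "S2"), each = 2),
                      locus = rep(c("L1", "L2"), 2),
                      ce_1 = c(10, 12, 10, 12), ce_2 = c(11, NA, 11, 13))
  r <- concordance_report(a, a)
  expect_equal(sum(tidy(r)$discordant), 0)
  expect_equal(glance(r)$concordance, 1)
  # drop one heterozygote to a homozygote at one locus
  b <- a
  b$ce_2[1] <- NA
  r2 <- concordance_report(a, b)
  expect_equal(sum(tidy(r2)$discordant), 1)
  expect_equal(tidy(r2)$discordant[tidy(r2)$locus == "L1"], 1)
  # samples present in one set only are listed, not counted
  b2 <- b[b$sample != "S2", ]
  r3 <- concordance_report(a, b2)
  expect_equal(nrow(r3$unmatched_samples), 2)
  expect_equal(sum(tidy(r3)$n), 2)
})
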