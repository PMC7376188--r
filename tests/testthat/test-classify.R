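cfgs <- test_configs()

test_that("variant classification partitions alleles into the four classes", {
  d7 <- cfgs$D7S820
  ref <- bracket_encode(strrep("TATC", 10), d7)
  # reference pattern + flanking substitution -> FRVO
  expect_equal(classify_variant(sequence_allele(d7, ref, "84,160,204-A"), d7),
               "FRVO")
  # interrupted repeat + flanking substitution -> RRFR
  irr <- bracket_encode(paste0(strrep("TATC", 9), "TGTC", "TATC"), d7)
  expect_equal(classify_variant(sequence_allele(d7, irr, "84,160,204-A"), d7),
               "RRFR")
  # interrupted repeat alone -> RRVO
  expect_equal(classify_variant(sequence_allele(d7, irr), d7), "RRVO")
  # pure count change of the reference pattern -> REFERENCE
  expect_equal(classify_variant(sequence_allele(d7, ref), d7), "REFERENCE")
  w <- bracket_encode(strrep("TATC", 12), d7)
  expect_equal(classify_variant(sequence_allele(d7, w), d7), "REFERENCE")
})

test_that("an extra segment relative to a two-block reference pattern is RRVO", {
  # reference pattern [TAGA]n [CAGA]m with no tail: the trailing tetramer
  # is repeat-region variation
  vcfg <- locus_config(
    "vWA", "autosomal", "12", 5983977, 5984044, 4,
    list(list(unit = "TAGA", count = 11, counted = TRUE, kind = "variable"),
         list(unit = "CAGA", count = 5, counted = TRUE, kind = "variable")),
    "16"
  )
  st <- bracket_encode(paste0(strrep("TAGA", 10), strrep("CAGA", 5), "TAGA"),
                       vcfg)
  expect_equal(classify_variant(sequence_allele(vcfg, st), vcfg), "RRVO")
})

test_that("repeat-region deletions drive classification, not flank tallies", {
  d448 <- cfgs$DYS448
  st <- bracket_encode(paste0(strrep("AGAGAT", 11), strrep("N", 36),
                              strrep("AGAGAT", 8)), d448)
  al <- sequence_allele(d448, st, "22,218,995–22,219,000 DEL")
  expect_equal(al$flanks$region, "repeat_region")
  # the deletion sits in the repeat region: class is RRVO, not RRFR
  expect_equal(classify_variant(al, d448), "RRVO")
  # and it must not shift the CE designation (length change is already in
  # the shortened gap)
  expect_equal(format_ce(al$ce), "18")
})

test_that("classification also works on parsed names (re-encoding path)", {
  nm <- paste0("D19S433 [CE12.2]-Chr19-GRCh38 29,926,235–29,926,298 ",
               "[CCTT]11 cctt CCTT tt CCTT")
  al <- parse_isfg(nm, cfgs$D19S433)
  expect_equal(classify_variant(al, cfgs$D19S433), "RRVO")
})

test_that("novelty is exact catalog membership and monotone in the catalog", {
  catalog <- read_allele_catalog(golden_catalog_path())
  inside <- tibble::tibble(locus = "D7S820",
                           isfg_name = catalog$isfg_name[catalog$locus ==
                                                           "D7S820"][1])
  outside <- tibble::tibble(locus = "D7S820", isfg_name = "D7S820 [CE99]-x")
  expect_false(flag_novel(inside, catalog))
  expect_true(flag_novel(outside, catalog))
  # enlarging the catalog never creates new novel flags
  bigger <- allele_catalog(dplyr::bind_rows(catalog, outside))
  expect_false(any(flag_novel(dplyr::bind_rows(inside, outside), bigger) &
                     !flag_novel(dplyr::bind_rows(inside, outside), catalog)))
  # a catalog containing a whole simulated pool leaves nothing novel
  pools <- build_test_pools(cfgs, "D7S820")
  named <- name_alleles(
    dplyr::mutate(pools$D7S820, locus = "D7S820",
                  variant_class = NULL), cfgs)
  pool_cat <- allele_catalog(named[c("locus", "isfg_name")])
  expect_false(any(flag_novel(named, pool_cat)))
})

test_that("allele gain bookkeeping decomposes by variant class", {
  # 5 length-based alleles split into 9 sequence-based alleles
  alleles <- tibble::tibble(
    locus = "L1",
    ce = c("10", "10", "10", "11", "11", "12", "13", "14", "14"),
    isfg_name = paste0("a", 1:9),
    variant_class = c("REFERENCE", "RRVO", "RRVO", "REFERENCE", "RRVO",
                      "REFERENCE", "REFERENCE", "REFERENCE", "FRVO")
  )
  gain <- summarize_allele_gain(alleles, totals = TRUE)
  row <- gain[gain$locus == "L1", ]
  expect_equal(row$lb_count, 5L)
  expect_equal(row$sb_count, 9L)
  expect_equal(c(row$gain_rrvo, row$gain_frvo, row$gain_rrfr), c(3L, 1L, 0L))
  expect_equal(gain$gain[gain$locus == "TOTAL"], 4L)
  # locus with no sequence variation gains nothing in any category
  flat <- tibble::tibble(locus = "D22S1045", ce = c("15", "16"),
                         isfg_name = c("x", "y"),
                         variant_class = "REFERENCE")
  g2 <- summarize_allele_gain(flat, totals = FALSE)
  expect_equal(g2$sb_count, g2$lb_count)
  expect_equal(g2$gain, 0L)
  # invariant: sequence-based counts never fall below length-based counts
  expect_true(all(gain$sb_count >= gain$lb_count))
})
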