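cfgs <- test_configs()

test_that("bracket encoding reproduces interrupted repeat structures", {
  s <- bracket_encode(paste0(strrep("TATC", 9), "TGTC", "TATC"), cfgs$D7S820)
  expect_equal(format_segments(s), "[TATC]9 TGTC TATC")
  s <- bracket_encode(paste0(strrep("ATCT", 5), "ATGT", strrep("ATCT", 2),
                             "ATC", strrep("ATCT", 11)), cfgs$D6S1043)
  expect_equal(format_segments(s), "[ATCT]5 ATGT [ATCT]2 ATC [ATCT]11")
  # a single motif is an unbracketed counted singleton
  s <- bracket_encode("GATA", cfgs$D16S539)
  expect_equal(format_segments(s), "GATA")
  expect_equal(repeat_unit_count(s), 1L)
})

test_that("bracket encoding rejects bad input", {
  expect_error(bracket_encode("TATX", cfgs$D7S820), "non-nucleotide")
  expect_error(bracket_encode("TA", cfgs$D7S820), "shorter than one motif")
})

test_that("expansion of an encoding is the identity on random motif concatenations", {
  set.seed(7)
  loci <- c("D7S820", "D21S11", "FGA", "DYS390", "DXS10074", "D19S433")
  for (i in seq_len(300)) {
    cfg <- cfgs[[sample(loci, 1)]]
    seq <- random_repeat_sequence(cfg)
    st <- bracket_encode(seq, cfg)
    expect_equal(expand_structure(st), seq, label = paste(cfg$name, seq))
  }
})

test_that("CE designation is length-anchored, not unit-count-anchored", {
  # flanking insertion adds one nucleotide: allele 10 becomes 10.1
  s <- bracket_encode(strrep("TATC", 10), cfgs$D7S820)
  al <- sequence_allele(cfgs$D7S820, s, "84,160,204-A; 84,160,204.1A")
  expect_equal(format_ce(al$ce), "10.1")
  # length-preserving substitutions do not move the CE
  al2 <- sequence_allele(cfgs$D7S820, s, "84,160,204-A")
  expect_equal(format_ce(al2$ce), "10")
  # allele identical to the reference gets the anchor CE
  ref <- bracket_encode(expand_structure(
    template_as_structure(cfgs$FGA$reference_structure)), cfgs$FGA)
  expect_equal(format_ce(ce_designation(ref, cfgs$FGA)), "27")
  # 1-nt flanking deletion steps the partial down
  del <- flank_variant("deletion", pos = 84160210L, end = 84160210L)
  expect_equal(format_ce(ce_designation(s, cfgs$D7S820, del)), "9.3")
})

test_that("repeat-region gaps count toward CE length but not unit count", {
  s <- bracket_encode(paste0(strrep("AGAGAT", 10), strrep("N", 42),
                             strrep("AGAGAT", 7)), cfgs$DYS448)
  expect_equal(format_ce(ce_designation(s, cfgs$DYS448)), "17")
  expect_equal(repeat_unit_count(s), 17L)
})

test_that("formatting matches the printed layout byte for byte", {
  s <- bracket_encode(paste0(strrep("AGAGAT", 10), strrep("N", 42),
                             strrep("AGAGAT", 7)), cfgs$DYS448)
  al <- sequence_allele(cfgs$DYS448, s)
  expect_identical(
    al$isfg_name,
    "DYS448 [CE17]-ChrY-GRCh38 22,218,923–22,219,078 [AGAGAT]10 N42 [AGAGAT]7"
  )
  s <- bracket_encode(strrep("ATAG", 10), cfgs$DXS8378)
  al <- sequence_allele(cfgs$DXS8378, s, "9,402,257-G")
  expect_identical(
    al$isfg_name,
    "DXS8378 [CE10]-ChrX-GRCh38 9,402,262–9,402,301 [ATAG]10 9,402,257-G"
  )
})

test_that("parsing recovers structure, flanks and counted totals", {
  nm <- paste0("FGA [CE26]-Chr4-GRCh38 154,587,736–154,587,823 ",
               "[GGAA]2 GGAG [AAAG]16 AGAG AAAG AGAA AAAA [GAAA]3")
  al <- parse_isfg(nm, cfgs$FGA)
  expect_equal(nrow(al$structure), 8L)
  expect_equal(repeat_unit_count(al$structure), 26L)
  expect_identical(format_isfg(al, cfgs$FGA), nm)
  # lowercase segments parse as uncounted
  nm <- paste0("D21S11 [CE28]-Chr21-GRCh38 19,181,973–19,182,099 ",
               "[TCTA]5 [TCTG]5 [TCTA]3 ta [TCTA]2 tca [TCTA]2 tccata ",
               "[TCTA]11")
  al <- parse_isfg(nm, cfgs$D21S11)
  expect_false(al$structure$counted[al$structure$unit == "TA"])
  expect_equal(repeat_unit_count(al$structure), 28L)
  expect_error(parse_isfg("not a name", cfgs$FGA), "malformed")
})

test_that("format/parse round trips hold on random synthetic alleles", {
  set.seed(11)
  loci <- c("D7S820", "D21S11", "FGA", "DYS390", "DXS8378")
  for (i in seq_len(200)) {
    cfg <- cfgs[[sample(loci, 1)]]
    st <- bracket_encode(random_repeat_sequence(cfg), cfg)
    fl <- if (i %% 3 == 0) {
      flank_variant("substitution", pos = cfg$flank_upstream[1] + 2L,
                    alt = sample(c("A", "C", "G", "T"), 1))
    } else NULL
    al <- sequence_allele(cfg, st, fl)
    al2 <- parse_isfg(al$isfg_name, cfg)
    expect_identical(format_isfg(al2, cfg), al$isfg_name)
    expect_true(same_structure(al2$structure, al$structure))
  }
})

test_that("tolerant parsing accepts ASCII hyphens, strict mode does not", {
  nm_ascii <- "DXS7132 [CE10]-ChrX-GRCh38 65,435,647-65,435,702 [TAGA]10"
  al <- parse_isfg(nm_ascii, cfgs$DXS7132)
  expect_equal(format_ce(al$ce), "10")
  # canonical output restores the en dash
  expect_match(al$isfg_name, "65,435,647–65,435,702", fixed = TRUE)
  expect_error(parse_isfg(nm_ascii, cfgs$DXS7132, strict = TRUE), "en dash")
})

test_that("batch naming annotates observation tables", {
  obs <- tibble::tibble(
    sample = "S1", locus = c("D7S820", "D7S820"),
    sequence = c(strrep("TATC", 10),
                 paste0(strrep("TATC", 9), "TGTC", "TATC")),
    flanks = c("84,160,204-A; 84,160,204.1A", "84,160,204-A")
  )
  named <- name_alleles(obs, cfgs)
  expect_equal(named$ce, c("10.1", "11"))
  expect_equal(named$variant_class, c("FRVO", "RRFR"))
  expect_match(named$isfg_name[1], "84,160,204.1A", fixed = TRUE)
})
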