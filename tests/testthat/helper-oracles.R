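# Independent brute-force oracles for the exclusion probabilities.
# These enumerate the full mother/child/random-man genotype space from the
# exclusion definitions directly; they share no code with the closed forms
# in R/popgen.R.

oracle_pe_duo <- function(p) {
  k <- length(p)
  total <- 0
  for (c1 in 1:k) for (c2 in 1:k) {            # child, ordered
    pc <- p[c1] * p[c2]
    for (f1 in 1:k) for (f2 in 1:k) {          # random man, ordered
      excluded <- !(f1 %in% c(c1, c2)) && !(f2 %in% c(c1, c2))
      if (excluded) total <- total + pc * p[f1] * p[f2]
    }
  }
  total
}

# possible paternal alleles given mother genotype and child genotype
obligate_set <- function(m, child) {
  s <- integer()
  if (child[2] %in% m) s <- c(s, child[1])
  if (child[1] %in% m) s <- c(s, child[2])
  unique(s)
}

oracle_pe_trio <- function(p) {
  k <- length(p)
  total <- 0
  for (m1 in 1:k) for (m2 in 1:k) {            # mother, ordered
    pm <- p[m1] * p[m2]
    for (x in c(m1, m2)) {                     # maternal allele (1/2 each)
      for (y in 1:k) {                         # true paternal allele
        s <- obligate_set(c(m1, m2), c(x, y))
        excl <- 0
        for (f1 in 1:k) for (f2 in 1:k) {
          if (!(f1 %in% s) && !(f2 %in% s)) excl <- excl + p[f1] * p[f2]
        }
        total <- total + pm * 0.5 * p[y] * excl
      }
    }
  }
  total
}

oracle_mec_duo_x <- function(p) {
  k <- length(p)
  total <- 0
  for (c1 in 1:k) for (c2 in 1:k) {            # daughter, ordered
    pc <- p[c1] * p[c2]
    for (f in 1:k) {                           # alleged father, hemizygous
      if (!(f %in% c(c1, c2))) total <- total + pc * p[f]
    }
  }
  total
}

oracle_mec_trio_x <- function(p) {
  k <- length(p)
  total <- 0
  for (m1 in 1:k) for (m2 in 1:k) {
    pm <- p[m1] * p[m2]
    for (x in c(m1, m2)) {
      for (y in 1:k) {
        s <- obligate_set(c(m1, m2), c(x, y))
        # hemizygous alleged father: excluded iff his X allele is not in s
        total <- total + pm * 0.5 * p[y] * (1 - sum(p[s]))
      }
    }
  }
  total
}

oracle_rmp <- function(p) {
  k <- length(p)
  total <- 0
  for (i in 1:k) for (j in i:k) {
    g <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + g^2
  }
  total
}

random_freqs <- function(k) {
  x <- stats::rgamma(k, shape = 1)
  x / sum(x)
}

test_configs <- function() {
  read_locus_config(forenseqr_example("forenseq_strs.json"))
}

golden_catalog_path <- function() {
  forenseqr_example("novel_alleles_tibetan107.tsv")
}

# random repeat-region sequences built from a locus's motifs, for
# round-trip properties
random_repeat_sequence <- function(cfg) {
  tpl <- cfg$reference_structure
  units <- unique(tpl$unit[tpl$kind %in% c("variable", "tail")])
  n_blocks <- sample(2:4, 1)
  paste(vapply(seq_len(n_blocks), function(i) {
    strrep(sample(units, 1), sample(2:12, 1))
  }, character(1)), collapse = "")
}

# deterministic synthetic allele pools per locus, with the variant class
# of each allele planted by construction
build_test_pools <- function(cfgs, loci = names(cfgs)) {
  pools <- list()
  for (locus in loci) {
    cfg <- cfgs[[locus]]
    ref <- template_as_structure(cfg$reference_structure)
    base_seq <- expand_structure(ref)
    # length variants of the reference pattern (class REFERENCE)
    widen <- function(delta) {
      st <- ref
      v <- which(st$role == "variable" & st$count >= 2)
      pick <- v[which.max(st$count[v])]
      st$count[pick] <- st$count[pick] + delta
      expand_structure(st)
    }
    # one base of the central repeat changed (class RRVO)
    rrvo_seq <- local({
      st <- ref
      v <- which(st$role == "variable")
      pick <- v[which.max(st$count[v])]
      prefix_len <- if (pick > 1) {
        structure_length(st[seq_len(pick - 1), , drop = FALSE])
      } else 0L
      pos <- prefix_len + (st$count[pick] %/% 2) * nchar(st$unit[pick]) + 2L
      s <- strsplit(base_seq, "")[[1]]
      s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[1]
      paste(s, collapse = "")
    })
    flank_pos <- cfg$flank_upstream[1] + 3L
    flank_ann <- paste0(fmt_coord(flank_pos), "-A")
    pools[[locus]] <- tibble::tibble(
      sequence = c(base_seq, widen(1L), widen(-1L), base_seq, rrvo_seq),
      flanks = c("", "", "", flank_ann, ""),
      freq = c(0.35, 0.25, 0.15, 0.15, 0.10),
      variant_class = c("REFERENCE", "REFERENCE", "REFERENCE", "FRVO",
                        "RRVO")
    )
  }
  pools
}
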