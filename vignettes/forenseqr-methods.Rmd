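---
title: "Models and methods behind forenseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forenseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forenseqr)
```

`forenseqr` turns per-sample MPS allele-sequence observations at
forensic STR and identity-SNP loci into bracketed sequence-based allele
names, QC'd genotypes, variant classifications and population
statistics. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic cohorts do and do
not demonstrate.

## Locus configurations

Everything is anchored in a per-locus configuration: chromosome class
(autosomal/X/Y), the GRCh38 repeat-region interval (1-based, inclusive
at both ends — the convention used in printed allele names such as
`84,160,226–84,160,277`), the motif length (2–6 bp), the analysed
flanking intervals, the calling thresholds, and a *reference template*.
The template is an ordered list of segments: variable motif runs whose
counts differ between alleles, fixed interruptions (lowercase when they
do not count toward the repeat total), gap blocks of stated length
(`N42` for a stretch the assay does not resolve), and optionally a
fixed-length terminal *tail* tetramer whose sequence varies between
alleles. Reference structures and CE anchors are data, not code: the
bundled `forenseq_strs.json` covers the loci exercised in the test
suite, and new loci are added by editing configuration, never the
package.

All sequences are stored on the GRCh38 plus strand; any
reverse-complement handling belongs upstream of this package.

## Bracketed encoding

The encoder works repeat-region sequence → structure in two passes.

*Tokenization.* Maximal runs (two or more copies) of the template's
variable motifs are located greedily left to right. When runs of two
motifs overlap in shifted reading frames (in an FGA-like junction
`GGAG AAAG AAAG…`, a frame-shifted `GAAA` run starts one base before
the true `AAAG` run), the run whose start preserves the current motif
frame wins. `N` runs become gap tokens; everything between tokens is an
unmatched stretch.

*Template alignment.* Tokens are aligned to the template by a small
dynamic program. Exact template matches cost nothing — including
folding reference singletons out of a longer physical run, which is how
a run of 13 physical `CCTT` copies renders as `[CCTT]11 cctt CCTT`
when the template interleaves uncounted copies. Truncated lowercase
interruptions (a stretch matching a prefix or suffix of a lowercase
template literal, as in the `tt` remnant of a `cctt` interruption)
cost 1; novel motif runs cost 2; novel interruption words, chopped at
motif length, slightly more; skipped template segments cost 1. The
minimum-cost alignment is unique on every fixture locus and, by
construction, expanding the result always reproduces the input
sequence. Casing is template-driven: novel interruptions render
uppercase and count one unit each (an `[GGAA]2 GGAG [AAAG]16 …`
structure counts 26 units because its five uppercase singletons count),
lowercase uncounted status is inherited from the reference only.

Any alignment that needed a novel segment, a truncated literal, an
altered gap length, a skipped template segment or a non-canonical tail
unit marks the allele as deviating from the reference repeat pattern;
variant classification consumes exactly this flag.

## CE designation is length-anchored

A CE ladder measures length, not repeat counts, so the package never
counts units to assign a CE number. Each configuration carries a
reference allele with a known CE anchor; an observed allele's
designation comes from its analysed-fragment length offset ΔL
(flanking insertions and deletions included, repeat-region variants
excluded since their length is already in the structure):

$$\mathrm{whole} = a_w + \left\lfloor \frac{\Delta L + a_p}{m}\right\rfloor,
\qquad \mathrm{partial} = (\Delta L + a_p) \bmod m$$

with $(a_w, a_p)$ the anchor and $m$ the motif length. This reproduces
the microvariant behaviour of flanking InDels (a `[TATC]10` allele with
a 1-nt upstream insertion is CE 10.1) and locus-specific ladder offsets
are carried entirely by the anchor. Insertion positions that are
ambiguous within a homopolymeric flank are left-aligned to the 5'-most
equivalent anchor so that naming is deterministic.

## Genotype calling and QC

At each sample × locus, alleles below the analytical threshold (AT) are
discarded; alleles between AT and the interpretation threshold (IT) are
flagged `below_interpretation` and not callable; among callable
alleles a second allele is kept only if its reads reach the intralocus
balance threshold relative to the first. Defaults: AT 1.5% and IT 4.5%
of total locus reads, balance 0.60, with per-locus overrides (0.10 for
the severely imbalanced D22S1045). The percentages-of-total reading of
AT/IT is a deliberate choice — instrument software expresses them
relatively — and an absolute profile (AT = 2 reads, balance 0.40, the
convention of string-matching callers) is available via
`profile = "absolute"`. Y and male-X loci are hemizygous: a second
balanced allele raises `surplus_alleles` rather than a diploid call.

The allele coverage ratio (ACR) of a heterozygote is min/max reads;
calls under 0.5 are flagged, and a locus whose heterozygote ACRs *never*
reach 0.5 is recommended for discard, because its heterozygotes sit in
the range where they collapse into false homozygotes. No stutter filter
is applied: stutter in the data (and in the simulator's defaults) is
expected to sit below AT.

## Population statistics

Frequencies are obtained by counting with ploidy-aware denominators:
2N chromosomes for autosomal loci, 2F+M for X, M for Y; homozygotes
count twice on diploid chromosomes. Exact rational counts are kept
internally; files round to 4 decimals.

Gene diversity uses the unbiased estimator
$GD = n(1-\sum p_i^2)/(n-1)$ with $n$ the number of sampled
*chromosomes*; haplotype diversity is the same form over haplotypes
(53 sampled haplotypes with 48 singletons and counts {2, 3} give
0.9971). Expected heterozygosity is the identical estimator — two names
for one quantity, and the test suite asserts the identity. The
effective allele number $A_e = 1/\sum p_i^2$ is reported with the
conventional screening thresholds (>2 useful, >3 strong) for
microhaplotype-style mixture interpretation.

RMP is the sum of squared *expected* HWE genotype frequencies computed
from sample allele frequencies (an observed-genotype variant sits
behind the `observed` argument); DP = 1 − RMP by construction. The
paternity exclusion powers are derived in closed form from exhaustive
case analysis of the mother/child/random-man genotype space under HWE:

* duo (child only): $\sum_a p_a^2(1-p_a)^2 +
  \sum_{a<b} 2p_ap_b(1-p_a-p_b)^2$;
* trio (mother + child): $\sum_a p_a^2(1-p_a)^2 + \sum_{a<b}\left[
  p_ap_b(p_a+p_b)(1-p_a-p_b)^2 + p_ap_b\{(1-p_a)^3+(1-p_b)^3\}\right]$;
* X-chromosomal MEC duo/trio: the same case analyses with a hemizygous
  alleged father, dropping one power of the exclusion factor.

Because these derivations are easy to get subtly wrong, the test suite
keeps independent brute-force enumeration oracles (explicit loops over
every genotype combination with the exclusion predicate evaluated from
its definition) and requires agreement to 1e−12 on hundreds of random
frequency vectors.

The Hardy-Weinberg test is the exact conditional test: given allele
counts, a genotype table has probability
$N!\,2^h \prod_i m_i! / \{(2N)!\prod_{i\le j} n_{ij}!\}$, and the
p-value sums tables no more probable than the observed one. Small
tables are fully enumerated (recursive allocation with margin pruning,
budget 10^6 states); larger ones fall back to a seeded Monte-Carlo
shuffle of the 2N allele copies (default 10^5, p-value with the +1
correction). The LD test permutes one locus's genotypes across
individuals and uses the genotype × genotype contingency chi-square as
composite statistic — the statistic is a documented package choice,
since pedigree-software internals are not specified anywhere usable.
Bonferroni is the only multiple-testing correction offered, and
`pair_count()`/`bonferroni()` keep the bookkeeping exact (325 pairs for
26 loci, 4,371 for 94, 7,140 for 120).

Panel combination accumulates in log10 space: CMP as the sum of
log-RMPs, CPE complements as sums of log(1−PE). Numeric values
underflow near 1e−308 but the log magnitudes stay exact, and display
strings follow the tables' conventions: scientific notation with four
significant digits, and `1-(x)` for probabilities indistinguishable
from 1 in floating point. X loci are excluded from combined panels by
default (identity panels conventionally combine autosomal STRs and
identity SNPs); `include_x = TRUE` folds them in via their MECs.

## The synthetic cohort generator

`simulation_spec()`/`simulate_cohort()` emulate the data the analysis
assumes: HWE autosomal genotypes, sex-aware X ploidy, male-only Y
alleles, with a default cohort of 54 females and 53 males (a typical
population-survey panel). Coverage is negative-binomial (default mean
1000, size 10 — amplicon-scale overdispersion); heterozygote balance
draws a target minor/major ratio from a Beta distribution, default
Beta(50, 10) (mean 0.83, matching well-behaved loci whose average ACRs
sit between about 0.70 and 0.96), with per-locus overrides such as
Beta(10, 40) (mean 0.2) for a severe-imbalance regime; stutter spawns
reads one full repeat shorter at 2% of the parent allele's reads,
deliberately below the 1.5%-of-total analytical threshold since no
stutter filter exists downstream; unassigned noise lands on a random
out-of-genotype pool allele at 0.5%. Everything is driven by one
mandatory seed and is byte-identical across runs for a fixed seed.

What the simulator does *not* emulate: read-level errors and alignment
artifacts, PCR drift beyond single-step stutter, related individuals,
population substructure, and locus-specific stutter spectra. Passing
recovery tests therefore show that the pipeline's logic is faithful to
its own model assumptions at realistic sample sizes — not that any
real cohort satisfies those assumptions.

## Problem sizes and statistical checks in the test suite

The suite runs the golden nomenclature set (39 published allele names,
byte-identical round trips), 1,000-case random round-trip properties,
500-vector oracle comparisons, and recovery on five seeded cohorts of
107 individuals across the 21 bundled loci. Type-I error of the HWE and
LD tests is estimated from 500 null replicates each (N = 100
individuals; 499/199 permutations per replicate) and required to land
in (0.03, 0.07) at α = 0.05.

Frequency recovery is judged per locus with *simultaneous* 99% exact
binomial acceptance regions: each allele count must fall inside its
Bonferroni-adjusted (0.01/k per allele) interval around the planted
frequency. Unadjusted per-allele 99% intervals would make a
multi-allele locus fail with probability well above 2% by construction,
so the simultaneous reading is the statistically coherent way to say "a
locus recovered its frequencies at the 99% level"; with it, at least
98% of locus replicates are expected to pass, and the suite asserts
exactly that.

## Degenerate inputs and tie-breaks

Sequences shorter than one motif are rejected as degenerate; a single
motif encodes as an unbracketed counted singleton. Zero total reads is
a no-call. Monomorphic loci return HWE p = 1 with a notice. Gap blocks
never contribute repeat units but always contribute length to CE
designation. Ties in the encoder are broken deterministically: template
order first, then position, so one sequence always yields one name.
Allele names print the en dash and thousands separators exactly as the
nomenclature convention does; the parser's tolerant mode (default)
accepts ASCII hyphens everywhere, strict mode does not.

## Known limitations

* Bracketing requires a configured reference template; loci without
  one, and motifs absent from every configured segment, are out of
  scope by design.
* The LD statistic is a generic genotypic association measure; its
  p-values are exchangeable-null exact, but they will not numerically
  match any particular third-party program.
* Catalog novelty is exact string membership — a renamed but
  biologically identical allele counts as novel, which is what a
  registry lookup does and is intended behaviour.
* Mixture deconvolution, kinship likelihood ratios beyond the listed
  exclusion parameters, FASTQ-level processing and assembly liftover
  are out of scope.
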