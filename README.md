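# forenseqr

Sequence-based STR allele nomenclature, genotype QC and forensic
population statistics for massively parallel sequencing (MPS) panels.

## The problem

Capillary electrophoresis types a forensic STR allele by fragment length
alone; MPS reads the sequence, so alleles of identical length split into
distinct *sequence-based* (SB) alleles — interrupted repeats, motif
substitutions and flanking SNPs/InDels all become visible. Working with
these data needs four things that `forenseqr` provides for forensic
geneticists and population-data curators:

1. **Nomenclature.** Repeat regions are bracketed against a per-locus
   reference template ([TCTA]5 [TCTG]6 … with lowercase uncounted
   interruptions, `N42` gap blocks, flanking variants as `pos-ALT`,
   `pos.1ALT`, `start–end DEL`) and every allele gets a CE designation
   that is *length-anchored*: with ΔL the analysed-fragment length offset
   from the reference allele (flanking InDels included),

   ```
   whole   = anchor_whole + floor((ΔL + anchor_partial) / motif_len)
   partial = (ΔL + anchor_partial) mod motif_len
   ```

   so a [TATC]10 allele carrying a 1-nt flanking insertion is CE 10.1
   even though it has exactly 10 repeats — which is what a CE ladder
   would report.
2. **Genotype QC.** Threshold-based calling from read counts (analytical
   and interpretation thresholds as fractions of locus reads, default
   1.5%/4.5%), intralocus balance cutoffs with per-locus overrides,
   allele coverage ratios (ACR = min/max reads), and concordance
   reporting against length-based call sets.
3. **Population statistics.** Counting-method frequencies with
   ploidy-aware denominators (2N autosomal, 2F+M for X, M for Y), gene
   diversity `GD = n(1−Σp²)/(n−1)`, haplotype diversity, effective
   allele number `Ae = 1/Σp²`, Hobs/Hexp/PIC/RMP/DP, paternity exclusion
   powers (duo/trio), X-chromosomal mean exclusion chances, exact/
   permutation Hardy-Weinberg and linkage-disequilibrium tests with
   Bonferroni correction, and log-domain panel combination
   (CMP/TDP/CPE) that survives 1e−70-scale products.
4. **Synthetic cohorts.** A fully seeded generator (HWE genotypes,
   sex-aware X/Y ploidy, negative-binomial coverage, Beta heterozygote
   balance, stutter and noise) with truth records, so the entire
   pipeline is testable at desk scale.

## Worked example

```r
library(forenseqr)
cfgs <- read_locus_config(forenseqr_example("forenseq_strs.json"))

obs <- tibble::tibble(
  sample = "S1", sex = "female", locus = "D7S820",
  sequence = c(strrep("TATC", 10),
               paste0(strrep("TATC", 9), "TGTC", "TATC")),
  flanks   = c("84,160,204-A; 84,160,204.1A", "84,160,204-A"),
  reads    = c(512L, 434L)
)

calls <- call_genotypes(obs, cfgs)
calls$acr
#> [1] 0.8476562

name_alleles(obs, cfgs)[, c("ce", "variant_class", "isfg_name")]
#> # A tibble: 2 × 3
#>   ce    variant_class isfg_name
#>   <chr> <chr>         <chr>
#> 1 10.1  FRVO          D7S820 [CE10.1]-Chr7-GRCh38 84,160,226–84,160,277 [TATC]10 84,160,204-A; 84,160,204.1A
#> 2 11    RRFR          D7S820 [CE11]-Chr7-GRCh38 84,160,226–84,160,277 [TATC]9 TGTC TATC 84,160,204-A
```

The heterozygote is balanced (ACR 0.85, above the 0.60 cutoff). The
first allele has the reference repeat pattern but a flanking
substitution plus insertion (class FRVO) — the insertion lengthens the
fragment by one base, hence CE 10.1. The second has an interrupted
repeat region *and* a flanking substitution (RRFR); its 44-nt repeat
region is one full motif longer than the CE 10 anchor, hence CE 11.

Haplotype diversity of a Y panel with 50 distinct haplotypes among 53
males (48 singletons plus counts 2 and 3):

```r
haplotype_diversity(c(rep(1, 48), 2, 3))
#> [1] 0.9970972
```

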