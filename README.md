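# cernet

Correlation-based construction and querying of competitive-endogenous-RNA
(ceRNA) networks from matched mRNA / lncRNA / miRNA expression profiles.

## The scientific problem

Under the ceRNA (miRNA-sponge) hypothesis, a long non-coding RNA can
de-repress an mRNA by sequestering a miRNA that targets both. If that
mechanism is active in a cohort of expression profiles, it leaves a
characteristic correlation signature on the triple
(lncRNA *l*, miRNA *µ*, mRNA *g*):

- r(µ, l) < 0 — the miRNA is anti-correlated with the sponge,
- r(µ, g) < 0 — the miRNA is anti-correlated with its target, and
- r(l, g) > 0 — sponge and target rise and fall together.

`cernet` builds all pairwise Pearson correlation tables between RNA
classes, then enumerates **triangle motifs**: triples whose three edges
satisfy the sign pattern above with |r| ≥ t (inclusive) on every edge,
optionally gated by curated miRNA-target interaction evidence. The
evidence gate is a conjunction across the two miRNA axes and a disjunction
within each axis: a motif survives only if *at least one* source supports
µ–l **and** at least one source supports µ–g.

Around that core query the package provides the companion analyses such a
correlation database needs:

- **Expression filtering** — keep features positive in at least
  ⌈f·n⌉ samples (default f = 0.75), so correlations are not driven by
  shared zeros.
- **P-values** — Pearson r is converted by the exact t-transform
  t = r·√((n−2)/(1−r²)) on n−2 degrees of freedom, with optional
  Benjamini–Hochberg adjustment.
- **Sense–antisense pairs** — opposite-strand overlapping lncRNA/mRNA
  loci are detected on 0-based half-open coordinates and classified as
  `convergent` (3′ ends overlap), `divergent` (5′ ends overlap), or total
  containment (`lncRNA_within_mRNA` / `mRNA_within_lncRNA`), with
  per-isoform overlap-length summaries.
- **TF target search** — transcription factors are linked to targets of
  any RNA class through asymmetric per-class correlation cutoffs, gated by
  ChIP-seq binding evidence (disjunction across binding sources), and
  summarized into "frequent regulators" hitting a minimum number of
  distinct targets.
- **Expression views** — per-feature expression grouped or ordered by
  categorical/numeric clinical parameters, plus a min/median/max →
  0/0.5/1 piecewise-linear heatmap scale.
- **Synthetic fixtures** — seeded generators that plant triangles with a
  known expected correlation (a latent-factor model: at the defaults
  a = b = c = 1, σ = 0.5 the planted edges have E[r] ≈ ±0.8), planted
  overlap geometries of every class, and planted TF regulons, so the whole
  pipeline is testable offline against ground truth.
- **CLI** — `exec/cernet` with subcommands `simulate`, `build`,
  `circuits`, `antisense`, `tf-search`, `expression`, YAML config support,
  deterministic outputs and run logs.

## Worked example 1: re-querying a published stringent axis table

The package ships a small curated table of uveal-melanoma ceRNA axes at a
stringent cutoff (`inst/extdata/um_stringent_axes.tsv`).
`load_stringent_axes()` rebuilds pair-correlation tables and
interaction-evidence records from it; re-running the motif query at
threshold 0.6 with evidence gating reproduces the published 11 axes:

```r
library(cernet)
ex <- load_stringent_axes()
motifs <- find_motifs(ex$pairs_mi_lnc, ex$pairs_mi_m, ex$pairs_lnc_m,
                      interactions = ex$interactions,
                      threshold = 0.6, require_evidence = TRUE)
motifs_to_table(motifs)
```

```
# A tibble: 11 × 11
   lnc_id    mi_id           m_id     r_mi_lnc r_mi_m r_lnc_m p_mi_lnc   p_mi_m
   <chr>     <chr>           <chr>       <dbl>  <dbl>   <dbl>    <dbl>    <dbl>
 1 LINC01128 hsa-miR-195-5p  TPRG1L     -0.668  -0.66    0.82 1.36e-11 2.75e-11
 2 SNHG7     hsa-miR-199a-5p RPL15      -0.69   -0.66    0.8  1.45e-12 2.75e-11
 3 LINC00518 hsa-miR-199a-5p CDCA7L     -0.66   -0.65    0.65 2.75e-11 6.84e-11
 4 LINC01128 hsa-miR-195-5p  CTNNBIP1   -0.668  -0.65    0.72 1.36e-11 6.84e-11
 5 SNHG7     hsa-miR-199a-5p CDCA7L     -0.69   -0.65    0.73 1.45e-12 6.84e-11
 6 LINC00518 hsa-miR-199a-5p RPL15      -0.66   -0.66    0.64 2.75e-11 2.75e-11
 7 LINC00518 hsa-miR-199a-5p ZNF415     -0.66   -0.63    0.72 2.75e-11 3.82e-10
 8 WDFY3-AS2 hsa-miR-199a-5p RPL15      -0.63   -0.66    0.62 3.82e-10 2.75e-11
 9 HCP5      hsa-miR-508-3p  GPR176     -0.7    -0.61    0.63 5.00e-13 1.90e- 9
10 LINC01128 hsa-miR-195-5p  BSDC1      -0.668  -0.65    0.61 1.36e-11 6.84e-11
11 LINC01128 hsa-miR-195-5p  SDC3       -0.668  -0.6     0.72 1.36e-11 4.06e- 9
```

(p-values from the t-transform at n = 80; motifs are ranked by their
weakest edge, ties broken lexicographically, so the order is
deterministic.)

## Worked example 2: planted triangles from the synthetic generator

```r
gen <- make_expression(n_samples = 80, n_mrna = 30, n_lncrna = 15,
                       n_mirna = 15, n_triangles = 5, sigma = 0.5, seed = 7)
cl <- function(c) subset_features(gen$matrix,
                                  names(which(feature_classes(gen$matrix) == c)))
found <- find_motifs(pearson_pairs(cl("miRNA"), cl("lncRNA")),
                     pearson_pairs(cl("miRNA"), cl("mRNA")),
                     pearson_pairs(cl("lncRNA"), cl("mRNA")),
                     threshold = 0.6)
found[, c("lnc_id", "mi_id", "m_id", "r_mi_lnc", "r_mi_m", "r_lnc_m")]
```

```
# A tibble: 5 × 6
  lnc_id mi_id  m_id    r_mi_lnc r_mi_m r_lnc_m
1 LNC001 MIR001 GENE001   -0.850 -0.848   0.842
2 LNC003 MIR003 GENE003   -0.847 -0.816   0.829
3 LNC002 MIR002 GENE002   -0.798 -0.800   0.800
4 LNC005 MIR005 GENE005   -0.820 -0.775   0.791
5 LNC004 MIR004 GENE004   -0.766 -0.765   0.798
```

All five planted triangles — and nothing else — are recovered at
threshold 0.6; across 20 seeds mean recall is ≥ 0.95 with a false-positive
rate ≤ 0.01 (see `tests/testthat/test-synthetic.R`).

## Worked example 3: sense–antisense overlap classification

```r
loci <- make_loci(planted = c(convergent = 2, divergent = 1,
                              lncRNA_within_mRNA = 1), n_decoys = 3, seed = 5)
ov <- find_antisense_overlaps(loci$lnc_loci, loci$mrna_loci)
ov[, c("lnc_id", "m_id", "overlap_class", "containment", "overlap_mean")]
```

```
# A tibble: 4 × 5
  lnc_id m_id    overlap_class      containment overlap_mean
1 LNC001 GENE001 convergent         partial              896
2 LNC002 GENE002 convergent         partial             1445
3 LNC003 GENE003 divergent          partial             1025
4 LNC004 GENE004 lncRNA_within_mRNA total               2643
```

## Command-line interface

```sh
exec/cernet simulate --out-dir sim --seed 1
exec/cernet build --expression sim/expression.tsv \
    --annotation sim/annotation.tsv --out-dir pairs
exec/cernet circuits --pairs-dir pairs --interactions sim/interactions.tsv \
    --threshold 0.6 --require-evidence \
    --out-graph out/circuits.json --out-table out/circuits.tsv
exec/cernet antisense --lnc-bed sim/lncrna_loci.bed \
    --mrna-bed sim/mrna_loci.bed --out-table out/antisense.tsv
exec/cernet tf-search --expression sim/expression.tsv \
    --annotation sim/annotation.tsv --tf-list sim/tf_list.txt \
    --binding sim/binding.tsv --out-table out/tf.tsv
```

Exit codes: 0 on success, 1 on validated input failures (with the
offending path named on stderr), 2 on usage errors. Identical seed and
config give byte-identical outputs; every run writes a `run_log.yaml`
recording the package version and effective configuration.

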