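---
title: "Methods: correlation-based ceRNA network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-based ceRNA network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

This vignette records the statistical model, the parameter choices and
their rationale, and the numerical conventions used throughout `cernet`.
It is the reference for anyone auditing the pipeline or extending it.

## 1. Model and assumptions

### 1.1 The ceRNA correlation signature

A competitive-endogenous-RNA axis (lncRNA *l*, miRNA *µ*, mRNA *g*) is
operationalized as a **triangle motif** over pairwise Pearson
correlations computed across matched samples:

- r(µ, l) ≤ −t (miRNA anti-correlated with its sponge),
- r(µ, g) ≤ −t (miRNA anti-correlated with its target),
- r(l, g) ≥ +t (sponge and target co-expressed),

with a single magnitude threshold t applied **inclusively** on every
edge (`find_motifs(threshold = t)`). The inclusive convention (≥ t, not
> t) is deliberate: the bundled stringent axis table contains edges
whose printed coefficient equals the cutoff exactly (e.g. −0.60), and an
exclusive rule would silently drop them. Assumptions: expression is
approximately continuous after upstream normalization; Pearson linear
association is an adequate proxy for regulatory coupling at the sample
sizes involved; and no causal claim is made — motifs are candidates, not
validated axes.

### 1.2 Interaction-evidence gating

Correlation alone over-generates. When `require_evidence = TRUE`, a
motif must be supported by curated miRNA-target interaction records with
the logic **OR within an axis, AND across axes**: at least one source
reporting µ–l *and* at least one source reporting µ–g. Sources are
free-form strings grouped by the `partner_class` column of the
interaction table, so new databases require no code change. The
surviving sources are carried along as list-columns
(`evidence_mi_lnc`, `evidence_mi_m`) and rendered as solid vs dotted
edges on export.

### 1.3 Expression filtering

`filter_expressed(x, min_fraction = 0.75)` keeps a feature when it is
strictly positive in at least `ceiling(min_fraction * n_samples)`
samples. The ceiling rule makes the boundary explicit: with 80 samples
the requirement is exactly 60; a feature positive in 59 is dropped. The
default 0.75 reflects the convention that correlations computed over
mostly-zero vectors are artifacts of shared dropout, not co-regulation.

### 1.4 P-values

For a Pearson coefficient r over n samples,
`correlation_pvalue(r, n)` uses the exact t-transform
t = r·√((n−2)/(1−r²)) on n−2 degrees of freedom (two-sided). This is
the same statistic `stats::cor.test` uses; we expose it directly so
p-values can be recomputed for correlation tables read from disk, where
only (r, n) survive. |r| = 1 maps to `.Machine$double.xmin` rather than
0 so downstream −log10 transforms stay finite. Optional multiplicity
control is Benjamini–Hochberg (`adjust_p = TRUE`); with motif queries the
optional `p_max` is applied conjunctively to all three edges.

The test suite validates the t-transform against a permutation oracle
(10⁵ label permutations, vectorized via a crossproduct against a
permutation matrix) at 10% relative tolerance. The oracle's resolution
floor is 1/10⁵, so the comparison is run at moderate correlations where
the true p-value is ≈10⁻² — a strong correlation at n = 80 has a true
p-value around 10⁻⁶, far below what any feasible permutation count can
estimate, and comparing there would be meaningless.

## 2. Sense–antisense overlap classification

Loci are held internally in **0-based half-open** coordinates
(BED-native; GTF starts are decremented by one on import via
`read_loci()`), so overlap length is simply `min(end) − max(start)`.
Overlap detection (`find_antisense_overlaps`) requires opposite strands
and at least one base of overlap, implemented on
`GenomicRanges::findOverlaps` with strand ignored and then filtered.

Classification operates on the **union span** of each gene's isoforms
and applies containment first:

1. one union span inside the other → `lncRNA_within_mRNA` or
   `mRNA_within_lncRNA` (`containment = "total"`); identical spans are a
   degenerate tie broken as `lncRNA_within_mRNA`;
2. otherwise the overlap interval is tested against the transcriptional
   termini: if it covers both genes' 3′ ends the pair is `convergent`,
   if both 5′ ends, `divergent` (`containment = "partial"`).

On the minus strand the 5′ end is the *highest* coordinate; because ends
are half-open they are decremented before the terminus comparison.
Overlap-length statistics (`overlap_mean`, `overlap_min`, `overlap_max`)
are taken over the *overlapping* isoform×isoform combinations only, so a
short isoform that misses the partner entirely does not drag the minimum
to zero. Percentages in `summarize_overlap_classes` are rounded to one
decimal, matching how such tables are conventionally reported.

## 3. TF target search

`tf_target_search` screens TF–target correlation tables with
**asymmetric per-class cutoffs** — the correlation strength needed to
call a TF–mRNA link differs from a TF–miRNA link. Defaults (CLI):

| target class | negative cutoff | positive cutoff |
|---|---|---|
| mRNA | −0.9 | +0.9 |
| miRNA | −0.6 | +0.7 |
| lncRNA | −0.7 | +0.8 |

A record passes when r ≤ the class's negative cutoff or r ≥ its positive
cutoff, and is labeled `"(-)"` or `"(+)"` accordingly. With
`require_binding = TRUE` the record must additionally have at least one
ChIP-seq binding flag (OR across binding sources, mirroring the
interaction-evidence convention). `frequent_tfs(min_targets = 3)`
summarizes regulators hitting at least three *distinct* targets across
all classes; the floor of three is a parameter precisely because
reasonable reports sometimes include regulators one target short of the
stated rule — callers can lower it rather than the function silently
bending.

## 4. The synthetic generator

### 4.1 Design

`make_expression` plants each triangle on a shared latent factor
z ~ N(0, 1):

- lncRNA = a·z + ε, mRNA = b·z + ε′, miRNA = −c·z + ε″, with
  ε ~ N(0, σ²) i.i.d.

so the planted cross-correlations are analytic, e.g.
E[r(l, g)] = ab / √((a²+σ²)(b²+σ²)). At the defaults
(a = b = c = 1, σ = 0.5) every planted edge has expected magnitude
exactly **0.8** — comfortably above the working threshold 0.6 at
n = 80 (sampling sd of r ≈ 0.04), yet far from degenerate. Background
features are independent noise. All values receive a constant shift
(+6) so the matrix passes the positivity filter; shifting does not
change Pearson correlations. The defaults (80 samples) mirror the
cohort size the correlation conventions above were calibrated for —
they are study conditions, not tuning knobs.

Determinism: every generator takes a `seed` and runs under an internal
`with_seed()` that saves and restores `.Random.seed`, so generation is
bit-reproducible and does not perturb the caller's RNG state.

### 4.2 Planted geometry and regulons

`make_loci` constructs overlap pairs of each requested class by explicit
geometry (e.g. a convergent pair is a `+`-strand mRNA on the left
overlapping a `−`-strand lncRNA on the right, so the overlap covers both
3′ ends), placed in disjoint 50 kb windows so no unintended overlaps
arise; decoys are strand-opposed but disjoint. `make_tf_regulons` plants
TF→target links with chosen sign and a `binding_coverage` fraction of
links carrying ChIP-seq flags, giving exact ground truth for the gating
logic. `simulate_bundle` writes the full input set (expression,
annotation, interactions, loci BEDs, binding, TF list, clinical,
truth JSON) as plain text.

### 4.3 Scope and limits

The generator is linear-Gaussian: it does not model count overdispersion,
dropout, batch effects, or miRNA-mediated *nonlinear* repression, and
planted triangles share no features. It is a correctness instrument —
recall/false-positive checks against known truth — not a realism
benchmark. Observed performance at defaults over 20 seeds: mean recall
≥ 0.95, false-positive rate ≤ 0.01 per non-planted triple.

## 5. Numerical conventions and tie-breaking

- **Inclusive thresholds everywhere** (|r| ≥ t; filter rule ≥ ⌈f·n⌉).
- **Duplicated printed coefficients**: the bundled stringent-axis table
  stores one row per published axis; the same pair can appear with two
  slightly different printed coefficients (rounding in the source
  material). Pair tables deduplicate by the **mean** of the printed
  values — both candidates exceed the working cutoff, so the motif set
  is unaffected, and the convention is recorded rather than silently
  picking one row.
- **Deterministic ordering**: motifs are ranked by descending
  min(|r₁|,|r₂|,|r₃|) (a motif is as strong as its weakest edge) with
  lexicographic (lnc, mi, m) tie-break, so output order is invariant
  under input permutation. Overlap tables sort by (lnc_id, m_id).
- **Zero-variance features** yield `NA` correlations (flagged, not
  dropped silently); computed r is clamped to [−1, 1] against
  floating-point excursions.
- **Degenerate identical spans** classify as `lncRNA_within_mRNA`.
- **Problem sizes** exercised in tests: full-cohort tables up to
  14,500 × 733 features (≈10.6 million coefficients, computed in the
  matrix form), 733 × 612 tidy tables, 200-locus overlap scans against a
  quadratic oracle, and 10⁵-permutation p-value oracles.

## 6. Known limitations

- Pearson correlation misses monotone-nonlinear coupling; no rank-based
  option is currently exposed.
- Evidence gating treats all interaction sources as exchangeable; no
  source weighting or score thresholds.
- Overlap classification uses union spans, so a pair whose individual
  isoforms would classify differently is summarized by its envelope.
- The CLI loads whole expression matrices into memory; cohorts far
  beyond ~20k features × hundreds of samples would need a chunked
  correlation path.
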