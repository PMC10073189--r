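---
title: "Methods: signature connectivity and summary-data MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature connectivity and summary-data MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sigmr)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable constants and
the choices made where the design was genuinely open.  It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The connectivity model

A *signature* is the vector of per-gene z-scores induced by one
perturbation (compound, cell line, dose, time).  Roughly a thousand
*landmark* genes are directly measured; the rest are inferred and taken
as given (we do not reimplement the inference model).

**Query construction.** For each query compound the `k = 50` landmark
genes with the largest z-scores form the *up* set and the `k` smallest
the *down* set (`build_query()`).  Sensitivity alternates `k = 100` and
`k = 150` are plain config changes.  Ties in z are broken by gene id so
the query is a pure function of the signature, not of storage order.
Queries never truncate silently: fewer than `2k` landmark genes is an
error.

**Weighted KS enrichment.** For a reference ranked by descending z, the
running sum gains `|z|^w / sum_set |z|^w` at each set member and loses
`1/(N-n)` otherwise; the enrichment score ES is the extreme of largest
magnitude, signed (`weighted_ks_enrichment()`, default weight `w = 1`;
`w = 0` recovers the classic unweighted statistic).  One numerical
choice is ours: when the positive and negative extremes tie in magnitude
(which happens exactly, e.g. at rational masses like ±1/3), the positive
deviation is returned.  Some tie rule is required for determinism; the
tolerance (1e-12) makes the rule robust to floating-point accumulation
order, which matters because an oracle summing in a different order
would otherwise flip the sign of the returned score.

**WTCS, NCS, Tau.** `wtcs = (ES_up − ES_down)/2` when the two scores
disagree in sign, else 0 — a connectivity claim requires the up set
near the top *and* the down set near the bottom.  Raw scores are
normalized within (cell line × perturbation type) groups by the mean
|WTCS| of same-sign scores (`normalize_scores()`), and Tau is the
signed percentile of |NCS| against the touchstone members of the
group: `tau = sign(ncs) · 100 · frac(|ncs_t| < |ncs|)`, strict
inequality (`tau_percentile()`).  The scored reference is excluded from
its own percentile background, so a score larger than every other
touchstone magnitude reaches exactly ±100.  Groups without any
touchstone member fall back to the full group.  Per-cell-line Tau
values are summarized by the maximal-magnitude tercile: the nearest-rank
33rd and 67th percentiles are computed and whichever has larger absolute
value wins, ties favouring the upper one (`summarize_across_cells()`).
The cross-query summary ("average Tau across the six statins") is the
arithmetic mean; the source analysis does not specify the summary and
the arithmetic mean is the simplest choice consistent with it.

**Class enrichment.** References above the Tau cutoff (default 90,
strict `>`) are cross-tabulated against class membership and tested
with a Pearson chi-square, 1 df, *without* continuity correction by
default — the uncorrected statistic reproduces the magnitude of the
published example better than the Yates-corrected one, and both (plus
Fisher's exact test) are exposed.  The query compounds themselves are
excluded from the reference universe before classification; the
published construction is ambiguous on this point, which is why the
acceptance check on the published p-value is a one-sided bound rather
than an equality.

## 2. Concordance and term enrichment

Genes perturbed by a compound are `z > t` (up) and `z < −t` (down),
strict on both sides, default `t = 1` with sensitivity alternates 1.5
and 2.  For a compound pair the same-direction set is
`(up_a ∩ up_b) ∪ (down_a ∩ down_b)` and the opposite-direction set the
cross terms.  Pair-level gene sets feed a one-sided hypergeometric
over-representation test per ontology term, with annotations
materialized up the DAG (a gene annotated to a term counts for all
ancestors) and the background defaulting to all profiled genes.
Reporting is union-of-evidence: a term is reported when significant in
at least one query×target pair.

The graph-aware g:SCS correction used by gProfiler2 is deliberately out
of scope; Bonferroni (default, comparably stringent in spirit) and
Benjamini–Hochberg are provided instead.  Ancestor roll-up maps each
significant term to its ancestor(s) at depth `ancestor_level = 1` from
the roots (depth = shortest path from a root); the published procedure
lives in supplementary material that does not pin the level, so it is
config.  A term with no ancestor at exactly the level maps to its
deepest ancestors above it, and roots map to themselves.

## 3. Summary-data Mendelian randomization

For instrument selection the F-statistic is approximated by the squared
z-score `(b/se)²`; the exact small-sample F needs per-study variances
that summary files rarely carry, and at the F > 10 cutoff the two agree
to the third decimal for the sample sizes involved.  Among records
passing the cutoff the smallest eQTL p wins, ties by variant id.

Harmonization aligns the GWAS record to the eQTL effect allele (sign
flip + frequency complement when coded on the other allele), errors on
genuinely different allele pairs, and warns on strand-ambiguous
palindromic pairs (A/T, C/G) with frequency within 0.08 of 0.5 —
configurably dropping them.  *Inhibition framing* (effects per SD
decrease of expression, mimicking pharmacological target inhibition) is
a final sign flip applied to reported SMR effects only; stored summary
statistics are never rewritten.

The SMR estimate is `b_xy = b_zy / b_zx` with
`T = z_zx² z_zy² / (z_zx² + z_zy²)` ~ chi-square(1) under the null,
`se_xy = |b_xy|/sqrt(T)`, Wald 95% CI.  The default multiple-testing
threshold is `alpha / (n_genes × n_traits)` — 0.05/(3×29) ≈ 5.7e-4 for
a three-gene, 29-trait screen.

**HEIDI.** Candidates are SNPs with eQTL chi-square > 10 and r² with
the top SNP in [0.05, 0.9] (close proxies are excluded because their
deviation estimates are numerically unstable; distant ones carry no
information), capped at the 20 strongest by eQTL p — all constants are
the cited method's defaults and are config-exposed.  For each candidate
`d_i = b_xy(i) − b_xy(top)`; the delta-method covariance of the ratios
uses the *signed* LD correlation r (which is why LD is stored as r, not
r²) and cross-cohort independence.  The statistic `T = Σ z_d²` follows
a weighted sum of 1-df chi-squares with weights equal to the
eigenvalues of the z_d correlation matrix.  Its tail probability is
computed by Imhof's inversion formula via numerical quadrature, not the
Satterthwaite two-moment match: on spot checks the moment match is off
by a few 1e-2 in the far tail while the quadrature tracks a 2×10^5-draw
Monte-Carlo oracle to ~1e-3 (see `test-mr.R`), and a calibration test at
the 0.01 tail needs that accuracy.  Satterthwaite and Monte-Carlo
remain available as `p_method` options, equal eigenvalues short-circuit
to the exact chi-square, and negative eigenvalues from numerical noise
are clipped at zero.  Fewer than `min_snps = 3` candidates yields an
explicit *not computed* flag, never a silent p.  With estimated (not
true) LD and delta-method variances the test runs slightly
conservative: the packaged calibration (1000 single-causal replicates)
observes a rejection rate below the nominal 0.01, inside the central
99% binomial band, which the acceptance suite checks.

## 4. The synthetic world and what a green test establishes

**Signatures.** Compound `j` of class `c` in a cell line gets
`z_j = strength_c · L_c + N(0, noise_sd²)` per gene, column-scaled to
unit SD (correlation structure is unaffected; the scale is z-like).
Classes pointing at the same latent `L` are pharmacologically
concordant by construction.  The default world: 978 landmark genes, 6
statins and 12 of 38 antidepressants sharing one latent, 26
antidepressants on a second latent, 2 controls, 100 background
compounds each with a private latent, `strength = 2`, `noise_sd = 1`
(within-class correlation `4/5`, between-class ≈ 0).  The gene count
matches the landmark space; the compound universe (146) is a ~17×
scale-down of the published 2,522-compound screen chosen so the full
suite runs in minutes — the class-recovery statistics are rank-based
and do not depend on the universe size, but absolute Tau percentiles
are coarser here (1/145 granularity instead of 1/2521).

**Cohorts.** Genotypes come from a latent Gaussian AR(1)
(`rho = 0.8`) thresholded to Hardy–Weinberg dosages at `maf = 0.3` —
tunable LD without haplotype machinery.  Expression and trait are unit
variance before effect injection (`b_zx = 0.3` SD/allele,
`b_xy = 0.2` SD/SD), eQTL and GWAS cohorts of `n = 10,000` are drawn
independently (the two-sample setting), and LD is estimated from a
third reference panel of 2,000 (a 5× scale-down of the published
10,000-sample panel; LD estimation error ~1/sqrt(n) is negligible at
both sizes).  The linkage scenario drives the trait directly through
the variant whose realized r² with the eQTL variant is closest to the
target 0.6, echoing the moderate-LD sensitivity case in the source
analysis.  Half the GWAS records are randomly recoded to the other
allele so harmonization is always exercised.

What the generator does *not* emulate: realistic genome-wide LD,
population structure, dose–response and time-course structure,
signature replicate noise, inferred-gene error, or annotation bias in
real ontologies.  A green suite therefore establishes that the
*statistics are implemented correctly and calibrated under their own
assumptions* — not that the published biological conclusions replicate;
those depend on external data this artifact deliberately does not
fetch.

## 5. Numerical and degenerate-input choices

- GCT 1.3 values are written at `%.17g` so text round-trips are
  bit-exact; empty metadata fields use the format's `-666` sentinel
  (a trailing empty field would be dropped by line splitting).
- Summary-statistics rows violating invariants are dropped with counts
  reported; a reported p inconsistent with `2Φ(−|b/se|)` by more than a
  decade is only flagged, since some GWAS report genomic-control-
  adjusted p-values.
- All-zero weights in the KS statistic (every set member at z = 0)
  fall back to uniform hit mass rather than 0/0.
- `wtcs` drops query genes missing from a reference with a warning but
  errors when fewer than half of a side survives.
- Monomorphic variants make LD undefined and are an error naming the
  variants.
- Simulated p-values are floored at 1e-300 to stay inside the (0, 1]
  invariant when the normal tail underflows.
- Every simulator takes a seed; pipeline stages derive sub-seeds via
  `stage_seed(seed, stage_name)` (kept below 2^31), so a fixed master
  seed reproduces every output byte for byte.

## 6. Known limitations

- Tau percentiles are computed against the simulated touchstone, which
  is far smaller than the real reference compendium; with 146 compounds
  the cutoff 90 sits between the 131st and 132nd order statistics.
- The quadrature for the weighted chi-square tail is accurate to ~1e-3;
  p-values much smaller than that are effectively "very small" rather
  than precise.
- The concordance filter threshold (mean pairwise r ≥ 0.2) for
  discarding a discordant query compound is a free choice: the source
  analysis discards one statin for "low correlation" without printing a
  number.  It is config-exposed.
- Only single-instrument SMR is implemented; multi-instrument MR
  estimators, colocalization and binary eQTL storage formats are
  non-goals.
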