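---
title: "Integrated permutation-based transcriptome comparison and TF network analysis"
author: "ihtnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated permutation-based transcriptome comparison and TF network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihtnet)
```

# Scope

`ihtnet` compares log2-scale gene expression between two patient groups
(call them A and B; in the motivating prostate-cancer disparity setting
these are Black and White men) and then asks which gene sets and which
transcription factors (TFs) organize the observed differences. This
vignette documents the statistical model of each stage, the tunable
parameters and their defaults, the synthetic cohort generator used for
validation, the numerical conventions, and the known limitations. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

# The integrated differential-expression model

## Observed statistics

For each gene the package computes three two-group statistics, all signed
so that positive means "higher in group A":

* **Welch's t** — the unequal-variance two-sample t. Welch rather than the
  pooled-variance form is the default because the groups are typically of
  unequal size and variance; `compute_group_stats()` exposes nothing else,
  but the permutation null makes the distributional choice immaterial for
  calibration (only the ordering of evidence matters).
* **Rank-sum z** — the Wilcoxon rank-sum statistic of group A,
  standardized with the tie-corrected variance
  `Var(W) = n_A n_B / 12 · ((S+1) − Σ(t³−t)/(S(S−1)))`.
* **Log2-median-ratio (LMR)** — `median_A − median_B` of the log2 values.
  Because the inputs are already log2-scale intensities, the difference of
  medians *is* the log2 ratio of (geometric) medians; the package does not
  exponentiate and re-log.

Genes that are constant within both groups get all three statistics set
to 0 and a `zero_variance` flag; they can never satisfy the DEG rule.

## Permutation null and empirical p-values

`build_null()` permutes the sample labels (preserving group sizes,
identity permutation not excluded, permutations drawn uniformly with
replacement from the permutation space) and recomputes all three
statistics for every gene. The permutation kernel — group means,
variances, rank sums and medians over thousands of label reassignments —
is implemented in C++ (`src/perm_stats.cpp`); everything around it is
plain R.

Null values are **pooled across genes** by default. With 10,000
permutations a per-gene null caps the smallest attainable p at about
1e-4; pooling across *G* genes refines the granularity to
`1/(G·n_perm + 1)`, which the Stouffer combination needs to separate
strong signals. The assumption behind pooling — that the null statistics
are approximately exchangeable across genes after standardization — is
reasonable for standardized statistics (t, z) and for the LMR when genes
share a noise scale; a `per_gene` mode is available where it is not.
Pooled storage is capped (`max_pool`, default 6e6 values per statistic);
beyond the cap a uniform random reservoir is kept and logged.

Empirical p-values are two-tailed by doubling the smaller smoothed tail:
`p = min(1, 2·min(#{null ≥ obs}+1, #{null ≤ obs}+1)/(N+1))`. The add-one
smoothing guarantees `p > 0`, which the normal-quantile transform of the
next step requires.

## Stouffer combination and Storey q-values

Each p is mapped back to a signed quantile `z_i = sign_i·Φ⁻¹(1 − p_i/2)`
with the sign of the observed statistic (a statistic of exactly 0
contributes `z = 0`), combined as `z = (z_t + z_r + z_l)/√3`, and
converted to `p_combined = 2(1 − Φ(|z|))`. Storey's q-value uses the
fixed-λ estimator `π̂0 = min(1, #{p > λ}/((1−λ)m))` with λ = 0.5 — the
simplest published variant; no spline smoothing. With `π̂0 = 1` the
q-values reduce exactly to Benjamini–Hochberg, an identity the test suite
asserts.

## The DEG rule and the LMR cutoff

A gene is a DEG when `q < 0.05` **and** `|lmr|` exceeds a data-driven
cutoff: the 95th percentile of the pooled absolute null LMR from 1,000
label permutations (`lmr_cutoff()`). The absolute-value convention is
used because the DEG rule is symmetric in direction. On a typical
noise-sd 0.5, 60+60 synthetic cohort this cutoff lands around 0.25 log2
units; on large real cohorts with small per-gene noise it is
correspondingly smaller.

## Known limitation: the combined p-value is anti-conservative

The three statistics are computed on the *same* data and are strongly
correlated (rank correlations around 0.8–0.98 between t, rank-sum z, and
LMR under the null). Stouffer's rule assumes independent evidence, so
`z = Σz_i/√3` has null variance well above 1 and `p_combined` is **not**
uniform under the complete null: the acceptance script measures a
fraction of about 0.25 of all-null genes with `p_combined < 0.05`
(`null_frac_combined_p_lt_05`), while the per-statistic empirical
p-values are individually calibrated (`null_frac_t_p_lt_05` ≈ 0.05).
This is a property of the integrated-combination method itself, which the
package reproduces deliberately; it is partly offset in practice by the
LMR effect-size gate, but users who need strict type-I control should
treat `p_combined` as a ranking score, not a calibrated p-value. The
acceptance suite records the calibration check as failing, by design.

# Preranked gene-set enrichment

Genes are ranked by descending LMR, ties broken lexicographically by gene
identifier so the ranking is reproducible. The enrichment score walks the
ranking: hits increment the running sum by `|score|^w / Σ_hits|score|^w`,
misses decrement by `1/(N−k)`; the ES is the deviation of maximal
absolute value (positive preferred on exact ties). Two conventions are
exposed:

* `weight_exponent = 1` (default) — the weighting used by the standard
  GSEA software, cross-checked in the tests against an independent
  implementation (`fgsea::calcGseaStat`);
* `weight_exponent = 0` — the literal unweighted Kolmogorov–Smirnov form.

Significance uses **gene-tag permutation**: `n_perm` random gene sets of
the same size drawn from the ranked genes. Because the module operates on
a precomputed ranking (phenotype information is already consumed by the
ranking), phenotype permutation is out of scope here. The p-value is
one-sided within the sign of the observed ES with add-one smoothing, and
`NES = ES / mean(|null ES| of the same sign)`. No across-set FDR is
computed — per-set enrichment p-values are reported as-is.

# Master-regulator analysis

For each TF regulon the observed count of targets among the DEGs is
compared with counts in `n_perm = 100,000` draws of |DEG| genes sampled
uniformly **without replacement** from the universe. The universe
defaults to the genes present in the expression matrix — the measured
gene space is the population from which DEGs could have been drawn; an
explicit universe can be supplied instead. Sampling without replacement
makes the exact reference distribution hypergeometric, which the tests
use as an oracle: the empirical p must match `P(X ≥ k)` for
`X ~ Hypergeom(N, K, n)` within Monte-Carlo error.

Selection (`select_mrs()`): FDR < 0.01 (Benjamini–Hochberg on the
smoothed empirical p), more than 5 targets, top 10 by FDR with
deterministic tie-break (FDR, then p, then TF name). "More than 5
targets" counts targets **among the DEGs** by default — that is the
quantity the test statistic counts — with a switch to count targets on
the platform instead, since either reading is defensible.

The DEG set used for MR discovery defaults to the union of both
directional sets; per-direction analyses run the same operation on each
set separately.

# Activity scores and the co-regulation network

The activity of gene set *M* in sample *s* is
`a_s = Σ_{g∈M} z_{gs} / √|M|`, where `z_{gs}` standardizes gene *g*
across **all** samples jointly with the population (1/n) variance.
Group-blind standardization keeps between-group differences
interpretable; the `1/√|M|` scaling makes scores comparable across
regulon sizes and gives the sum unit variance under an independence
idealization. Consequences asserted in the tests: activities sum to zero
over samples, are invariant to gene-wise affine transforms of the input,
and a shift δ planted on *m* targets with noise sd σ produces a group
difference of approximately `δ√m/σ_total`. Zero-variance and absent
genes are dropped with a logged count. The "network activity" of a TF
list is the activity of the **union** of their regulons, each gene
counted once.

The network model of the selected TFs maps analysis quantities onto
display attributes: node size `|regulon ∩ DEG|/|DEG|`, node color the
mean activity difference of the TF's regulon, edge weight
`|regulon_i ∩ regulon_j ∩ DEG|/|DEG|` (edges exist only for positive
weight, undirected). The denominator |DEG| — rather than the union of
the two regulons — is the deliberate reading of "proportion of
co-regulated genes among the DEGs"; it makes edge weights comparable
across TF pairs at the cost of small absolute values. Export is lossless
to GraphML (via igraph) and JSON node-link (via jsonlite).

# Supporting cohort statistics

* **Chi-square** (clinical tables, DEG overlaps): Pearson's statistic
  **without continuity correction**. This choice is verified against
  fully printed clinical contingency tables in the acceptance suite —
  the uncorrected form reproduces the published p-values (0.614, 0.733,
  0.315 at printed precision); the Yates-corrected form does not.
* **Fisher's exact** (2×2): two-sided by the point-probability rule (sum
  of tables no more probable than the observed), checked against full
  enumeration.
* **Wilcoxon rank-sum**: exact enumeration for small tie-free inputs
  (total ≤ 20); otherwise the normal approximation with tie *and*
  continuity correction. The continuity correction is kept here (unlike
  the chi-square) because the corrected approximation tracks the exact
  tail to within about 0.01 already at group sizes of 8, while the
  uncorrected one deviates by up to 0.05; the printed clinical p-values
  that pin down the chi-square convention do not discriminate the
  rank-sum convention at cohort sample sizes.
* **Stratified comparisons**: the activity comparison runs within each
  stratum level; a stratum with fewer than 2 samples in either group is
  reported as `NA` with a `degenerate` flag rather than an error.
* **Clinical summaries**: mean/sd and median/IQR per group for
  continuous covariates, n (%) for categorical ones (percent rounded
  half away from zero to integers), with rank-sum or chi-square
  p-values per covariate.

# The synthetic cohort generator

`simulate_cohort()` draws from a linear-additive model on the log2 scale:

```
x[g, s] = baseline_g + Σ_t r[g, t] · a[t, group(s)] + direct_g · 1[group(s) = A] + ε,   ε ~ N(0, sd_g)
```

* `baseline_g ~ Uniform(4, 12)` log2 units — the dynamic range typical of
  normalized microarray intensities.
* `sd_g = noise_sd = 0.5` log2 units by default (a per-gene range can be
  supplied via `baseline_sd_range`); 0.5 is a realistic per-gene
  residual sd for bulk array data after normalization.
* **Direct differential genes**: a fraction `frac_de_genes = 0.10` of
  genes, drawn from genes outside every regulon, shifted by
  `effect_size = 1.0` log2 units in group A; half up in A, half up in B
  (`de_up_frac = 0.5`), so both DEG directions are exercised.
* **TF structure**: `n_tfs = 10` regulons of 20–60 targets;
  `regulon_overlap = 0.2` of consecutive regulons' targets are shared
  (chained), guaranteeing non-trivial co-regulation edges.
  `n_active_tfs = 3` TFs get a group-A activity shift
  `tf_activity_shift = 1.0`; every covered target's mean shifts by that
  amount per covering active TF. Targets of active TFs are therefore
  true differential genes and appear in the ground truth with their
  summed effects — necessary for DEG recovery and MR recovery to be
  jointly consistent.
* TF activity is a latent per-group constant, not a per-sample random
  effect, so expected activity-score differences have a closed form the
  tests can check; per-sample variability enters only through the noise.
* **Strata** are independent categorical draws per sample (defaults:
  Gleason category 25/55/20%, molecular subtype 2/59/39% — proportions
  in the ballpark of a radical-prostatectomy cohort). Stratum assignment
  uses a fixed sub-seed derived from the master seed, so it does not
  depend on when it is called.
* The default cohort — 2000 genes, 60+60 samples — is a deliberate
  scale-down from a several-hundred-patient, ~20,000-gene study. It
  keeps the default test suite and the acceptance script near one
  minute while preserving every structural feature the pipeline
  consumes.

What the generator does **not** emulate: probe-level artifacts, batch
effects, intensity-dependent variance, correlated noise between genes
outside the planted TF structure, library-size effects, or any
copy-number/methylation layer. Passing recovery tests on this generator
demonstrates the pipeline's internal correctness — statistics, nulls,
selection rules, ranking — not robustness to those real-data
complications.

# Numerical conventions and degenerate inputs

* All empirical p-values use add-one smoothing; none can be 0.
* Ties: ranking ties broken lexicographically (GSEA); rank ties handled
  by average ranks with tie-corrected variance (rank-sum); ES extremum
  ties resolved toward the positive deviation; MR selection ties broken
  by (FDR, p, name).
* Degenerate inputs: zero-variance genes are flagged (DE) or dropped
  (activity); empty set/expression intersections raise errors naming the
  set; strata with under-filled groups are flagged NA; a TF with no
  targets in the universe gets p = 1 with a log message.
* Seeds: every stochastic function takes an explicit integer seed and is
  deterministic given it; `run_pipeline()` derives fixed per-stage
  sub-seeds from one master seed. Random state is restored after each
  call (`withr::with_seed`).
* Serialization: TSV with header, floats at 6 significant digits;
  reading back is part of the tested round-trip contract.
* With equal group sizes the permutation null is drawn identically
  whichever group is labelled A (permutations index the canonical column
  order), so swapping labels negates all statistics exactly and leaves
  the derived LMR cutoff identical; combined p-values agree up to the
  finite-sample asymmetry of the sampled null.

# Problem sizes used in validation

The acceptance computations use: 2000-gene cohorts (30+30 all-null,
60+60 with planted signal), 1000 permutations for the statistic null and
the LMR cutoff, 100,000 draws for the master-regulator null, and a
12-case hypergeometric oracle grid. These sizes were chosen once as
realistic desk-scale study conditions for the generator and are not
tuned to outcomes.
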