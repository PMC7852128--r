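---
title: "Models and methods behind microtide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microtide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtide)
```

This vignette documents the statistical content of the package: the
transforms and models it implements, the defaults and why they were chosen,
the numerical safeguards, and what the simulation-based tests do and do not
demonstrate about real data.

## The micro_set and the CLR transform

Sequencing counts are compositional: a library's reads are a budget of fixed
(and arbitrary) size `N`, so raw counts of different libraries are not
comparable and log-ratios are the natural scale. Every micro_set row carries
four derived views of the same count: the raw count, the percent relative
abundance `ra = 100 cts / N`, the presence indicator, and the centered
log-ratio

$$Z_p = \log\!\frac{X_p}{g(X)}, \qquad X_p = \mathrm{cts}_p + \tfrac1N,
\qquad g(X) = \Big(\prod_{p=1}^{P} X_p\Big)^{1/P},$$

with `P` the number of taxa in the OTU table. The pseudocount of one part
per sequencing depth is added to **every** taxon, not just zeros, so the
adjustment is uniform within a library and vanishes as depth grows; it
exists solely to keep `log(0)` finite. The geometric mean is evaluated in
log space, which is exact for any counts a sequencer can produce and
immune to overflow. CLR vectors of a library sum to zero by construction;
the package treats this and `sum(ra) = 100` and depth conservation as hard
invariants, recomputed (never patched) every time counts change.

Relative abundance is stored in percent (0–100) because the filtering
cutoffs and all figures use the percent scale.

## Taxa filtering

`otu_filter()` aggregates a taxon into `"Other"` when it is present in fewer
than `prev_cutoff` percent of libraries, or never reaches `ra_cutoff`
percent abundance in any library, or is explicitly listed. Both rules are
evaluated on the unfiltered table, independently, and the union is
aggregated in one pass, so the result does not depend on rule order.
Aggregation sums counts, so per-library depth is conserved; `ra`, `clr` and
`bin` are then recomputed because `P` has changed. The operation is
idempotent: survivors keep their counts, and `"Other"` is never re-filtered
into itself. The prevalence and abundance rules use raw relative abundance
(percent of depth), not the pseudocount-adjusted values.

## Alpha diversity

For a count vector with observed taxa proportions `p_i`:

- `S_obs` — number of observed taxa; Chao1 `= S_obs + F1^2 / (2 F2)` with
  `F1`, `F2` the singleton and doubleton counts, falling back to the
  bias-corrected `S_obs + F1 (F1 - 1) / 2` when `F2 = 0`;
- Shannon `H = -Σ p_i log p_i` (natural log) and evenness `H / log S_obs`
  (defined as 1 for a single-taxon library);
- Simpson concentration `D = Σ p_i^2`, diversity `1 - D`, evenness
  `(1/D) / S_obs`;
- Good's coverage `100 (1 - F1 / N)`, the estimated chance the next read
  belongs to an already-seen taxon.

`alpha_div()` first gates libraries on the **raw** data — depth below
`min_depth` or coverage below `min_goods` disqualifies a library, with the
reason recorded rather than the row dropped — then draws `iter` bootstrap
rarefactions (multinomial resampling *with* replacement to exactly
`min_depth` reads) and reports the mean of each index across iterations.
Means rather than medians were chosen as the bootstrap summary; at
`iter = 100` the difference is negligible for every index. Defaults
(`iter = 100`, `min_depth = 10000`, `min_goods = 90`) reflect common
practice for 16S libraries sequenced to ~10k+ reads. Because subsampling
cannot invent taxa, bootstrap mean richness never exceeds raw richness — a
property the test suite checks. Diversity should be computed on the lowest
taxonomic rank available: aggregating counts into few coarse groups biases
richness and evenness.

## Beta diversity and PERMANOVA

`beta_dissimilarity()` produces Bray–Curtis (on counts) and binary Jaccard
(on presence) via vegan, and the Aitchison distance as plain Euclidean
distance between CLR vectors. `permanova()` implements the one-way
McArdle–Anderson partition directly: with `G = -\tfrac12 J D^2 J` the
Gower-centered matrix and `H` the group-membership hat matrix,
`SSB = tr(HGH)`, `SSW = SST - SSB`, and

$$F = \frac{SSB/(g-1)}{SSW/(n-g)},$$

with the p-value estimated by label permutation using the add-one estimator
`p = (1 + \#\{F^\pi \ge F\})/(1 + n_\text{perm})`, which can never report
an impossible `p = 0`. Only one-way designs are supported. The statistic and
`R^2` agree with `vegan::adonis2` to machine precision in the test suite,
and a 300-replicate null simulation confirms the nominal 5% type-I error.
Degenerate input (all points coincident) returns `F = 0, p = 1` rather than
`0/0`.

## Ordination

`pca_clr()` centers the libraries × taxa CLR matrix and takes the SVD;
scores are left singular vectors scaled by singular values and
`explained_i = σ_i^2 / Σ σ^2`. `pcoa()` eigendecomposes the Gower matrix,
keeps eigenvalues above a relative tolerance of `1e-10`, scales eigenvectors
by `√λ`, and reports negative eigenvalues (expected for Bray–Curtis, which
is not Euclidean-embeddable) as diagnostics without applying a Cailliez or
Lingoes correction — explained fractions are over the positive part only.
On the Aitchison distance, PCoA and CLR-PCA agree up to rotation (classical
MDS/PCA duality), which the suite verifies to `1e-8` Procrustes error. Both
methods fix axis signs by making the largest-magnitude loading (or score)
positive, so results are reproducible across platforms.

### Three-mode ordination for repeated measures

With libraries indexed by subject and time, naive ordination mixes
within-subject and between-subject variation. The package collapses the
time mode onto one set of axes:

- **PCA**: the subjects × taxa × time array of CLR values is unfolded by
  stacking time slices along the sample mode (a Tucker-1 style unfolding),
  giving a `(subjects · times) × taxa` matrix that shares a single set of
  taxa loadings; columns are centered and decomposed as usual, and each
  score row is tagged with its (subject, time).
- **PCoA**: the dissimilarity among all (subject, time) samples is computed,
  each time slice's sub-matrix is Gower-centered, the centered matrices are
  averaged across time to define common axes, and every sample is projected
  onto those axes via its own slice's centered matrix.

Only subjects observed at **all** time points enter (complete cases;
exclusions are logged). With a single time point both constructions reduce
exactly to the standard methods, and identical slices produce identical
per-time scores — the two degeneracies the tests pin down. This collapse is
the package's own design for the repeated-measures problem; no equivalence
with any particular three-mode factorization in the literature is claimed.

Confidence ellipses on 2-D scores are bivariate-normal: mean and covariance
per group, scaled by the χ²₂ quantile at the requested level, drawn as a
closed 100-point path. Groups need at least 3 points.

## Per-taxon regression

`nb_mods()` fits, per taxon, the NB2 model `log μ = Xβ + log N` with
variance `μ + μ²/θ` by alternating iteratively reweighted least squares for
`β` with safeguarded Newton updates for `log θ` (a Newton step is accepted
only when it improves the profile likelihood; otherwise a Brent line search
takes over). Convergence requires a relative log-likelihood change below
`1e-8` within 50 outer iterations, with `θ` confined to `[1e-4, 1e6]`. The
offset makes coefficients log rate ratios for a taxon's share of reads —
the standard device for compositional count data. `bb_mods()` fits the
beta-binomial by joint BFGS over `(β, logit ρ)` with a logit link on the
mean proportion, starting from the binomial GLM; the logit parameterization
of the intra-class correlation keeps the optimizer unconstrained, and the
model collapses to the binomial GLM as `ρ → 0`. Both report the inverse
observed information (numerical Hessian over all parameters, `β` block) as
the covariance, so Wald intervals account for dispersion estimation. On
test fixtures the fits agree with `MASS::glm.nb` and glmmTMB's
beta-binomial to at least 4 decimals, and 100-replicate simulations at
`n = 200` confirm unbiased effect recovery with 90–98% Wald coverage.

Non-convergence — all-zero taxa, rank-deficient designs, divergence — is
data, not an exception: failed taxa are listed on the model set and flow to
`rank_taxa_test()` (Wilcoxon for two groups, exact when both groups have ≤8
untied observations; Kruskal–Wallis otherwise, or on request) and
`presence_chisq()` (Pearson χ² without continuity correction; degenerate
tables flagged, expected counts below 5 flagged). Rank tests default to the
relative-abundance scale with CLR available by flag.

`covariate_lrt()` removes a covariate *and every interaction containing it*
and compares twice the log-likelihood difference to χ² with the number of
removed columns as df — the whole-covariate analogue of an F-test.
`profile_ci()` inverts the likelihood-ratio statistic per coefficient,
re-maximizing all other parameters (including the dispersion) at each fixed
value, bracketing from the Wald interval outward; when profiling fails on a
side the Wald limit is substituted and the row is marked. In the quadratic
(large-n) regime profile and Wald intervals agree within a few percent of
width, which the suite checks.

`estimate_table()` exponentiates coefficients into rate (NB) or odds (BB)
ratios with Wald intervals. For an interaction coefficient `a:b`, contrast
rows `a + a:b` and `b + a:b` are emitted with variance
`Var(a) + Var(a:b) + 2 Cov(a, a:b)` — the effect of one factor within the
other's non-reference level. FDR adjustment (Benjamini–Hochberg via
`p.adjust`) pools across taxa **within** each coefficient label, matching
how per-covariate results are displayed and tested; pooling across
coefficients would mix hypotheses of different families. Categorical
covariates use treatment coding with the first-seen level as reference.

## Plot data

Every figure has a separable data layer, which is what the tests exercise;
rendering is a thin ggplot2 wrapper. Stacked bars report mean relative
abundance per group (raw) or model-estimated composition
`100 μ̂_p / Σ_q μ̂_q` on a covariate grid (estimated; other covariates held
at reference/mean, 20 grid points over the observed range by default, the
mean log depth standing in for the offset — it cancels in the
normalization). `top_taxa` keeps the most abundant taxa and merges the rest
into `"Other"`, with an abundance-cutoff exemption. Rocky Mountain plots
put taxa on the x-axis colored by phylum (parsed as the second element of
the `/`-separated rank path) with signed magnitude on y: a rank correlation
against a covariate (exploratory), or `sign(β)·|log fdr_p|` for a model
coefficient, so taxa enriched in the exposed group point up. The log base
defaults to natural with base 10 available; an FDR p of exactly zero is
capped at the smallest positive double with a logged note. Forest plots
and correlation heatmaps are passthroughs of the estimate rows and the
taxa × covariate rank-correlation matrix.

## The simulator

`simulate_micro()` draws, per library, a depth uniform on
`[10000, 60000]` reads (typical of modern 16S runs), a composition from
`Dirichlet(c · p(x))` with concentration `c = 50` by default, and counts
from `multinomial(depth, π)`. The Dirichlet layer induces exactly the
between-library overdispersion the NB and BB models assume, and `c = ∞`
recovers pure multinomial sampling. Covariate effects shift the log-scale
Dirichlet mean and renormalize; because of the renormalization the
"true β" for recovery tests is the **induced** log fold change of the focal
taxon's expected proportion, which the truth record stores alongside the
nominal effect. The clinical generator mirrors a two-arm adult cohort:
balanced binary group, age `N(71.7, 11.2²)`, three-level smoking status
(31/42/27%). `simulate_longitudinal()` mirrors a preterm-infant airway
design: 24 subjects at 3 scheduled time points with 15 complete cases by
default, each subject's latent log-composition random-walking with
innovation SD `drift` per step.

What the fixtures do *not* emulate: phylogenetic correlation among taxa,
batch effects, chimeras or other artifacts, and zero-inflation beyond what
Dirichlet-multinomial sparsity produces. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the assumed
sampling model, not robustness to every failure mode of real amplicon data.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so each
check is statistically informative yet completes in seconds to a couple of
minutes: 1000-library property sweeps for the CLR contract, 20 random
fixtures for the PCoA/PCA equivalence, 300 null replicates (n = 20, 199
permutations) for the PERMANOVA size check, and 100 replicates at n = 200
for NB/BB recovery and coverage. Tolerances: hard invariants at `1e-9`;
cross-implementation agreement at `1e-8`–`1e-12`; frozen worked values at
the precision quoted. Ties in rank tests switch the Wilcoxon test to its
tie-corrected normal approximation automatically (via `wilcox.test`).

## Known limitations

- PERMANOVA is one-way only; no strata, no PERMDISP companion test.
- No phylogeny-aware distances (UniFrac) or tree-based filtering.
- No zero-inflated or random-effects models; repeated measures are handled
  only descriptively (three-mode ordination), not inferentially.
- PCoA negative eigenvalues are reported, not corrected.
- The beta-binomial likelihood is evaluated through `lbeta`; for extreme
  `ρ` beyond about `1e-6` of the boundary the fit effectively degenerates
  to the binomial GLM, which is also its correct limit.
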