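---
title: "Ranking gene-variant severity from targeted metabolomics: models and methods"
author: "metabOPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking gene-variant severity from targeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabOPLS)
```

## The problem

A recurring question in rare-disease genetics is whether the cellular
phenotype of a missense variant can be graded, not just classified. The
workflow implemented here addresses one instance: mouse embryonic fibroblasts
(MEFs) in which the endogenous *Opa1* gene is deleted and replaced by one of
several human *OPA1* alleles — the wild-type cDNA (ISO1) and variants of
increasing clinical severity (I382M, a hypomorph; D603H; G439V; R445H) — are
profiled on a targeted metabolomics panel (a Biocrates p180-style kit:
40 acylcarnitines, 21 amino acids, 21 biogenic amines, 90
glycerophospholipids, 15 sphingomyelins, 1 hexose; concentrations in µM).
The question the chemometrics answers is whether the metabolome, an
unsupervised readout, orders these alleles along their severity axis, and
which metabolites carry that ordering.

The package implements the full chain as reusable, tested functions:

1. **Preprocessing** — limit-of-detection (LOD) filtering, bridge-sample
   batch normalization, total-sum (row) normalization, autoscaling.
2. **Latent-variable models** — NIPALS PCA with Hotelling T² limits;
   single-response OPLS and OPLS-DA with VIP, written from scratch.
3. **Validation** — venetian-blind k-fold Q²Y, permutation null models,
   CV-ANOVA, Mann–Whitney–Wilcoxon, Spearman ρ.
4. **Signature pipeline** — the knockout-vs-wild-type OPLS-DA (analysis A),
   the transfected-only PCA → t1 → OPLS severity model (analysis B),
   VIP/loading and VIP/ρ volcano tables, derived lipid/polyamine indices and
   their regressions on t1.
5. **Synthetic data** — a generator reproducing the study design with
   planted ground truth, so every downstream stage is testable without
   access to raw instrument data (none is published in machine-readable
   form).

## Preprocessing model

**LOD filter.** A metabolite is excluded iff the fraction of its
measurements strictly below its LOD exceeds 20% (strict `>`: exactly one of
five low values keeps the analyte). Retained values are never imputed —
downstream methods are variance- and rank-based, and inventing values below
the limit would manufacture precision. Missing (`NA`) measurements count as
non-detections.

**Bridge normalization.** The study runs in two instrument batches with the
five wild-type samples measured in both. One bridge sample — by default the
lexicographically first one present in every batch, overridable — provides a
per-metabolite factor `f_bj = value(bridge, reference batch, j) /
value(bridge, batch b, j)` that rescales every measurement of batch *b*.
The factor is per metabolite, not global, because FIA/LC-MS batch drift is
analyte-specific; a scalar factor cannot remove analyte-specific drift. The
bridge runs actually consumed (one per batch) are removed from the analysis
table; the remaining bridge replicates stay for verification, and
`collapseBridge()` reduces them to one row per sample (reference batch)
before modelling.

**Row normalization.** Each sample is divided by its total metabolite sum —
guarding against differences in collected cell mass — then multiplied by the
grand mean of the original totals so values keep a µM-like magnitude. The
restoration is cosmetic (pure proportions satisfy the same contract) and is
recorded in the stage report.

**Autoscaling.** Each metabolite is centered to mean 0 and scaled to unit
sample standard deviation (n−1 denominator; either convention satisfies the
invariants, one must be fixed and this one is recorded). Centers and scales
are kept for the inverse transform.

The order is fixed: filter → bridge → row → scale. Ratios and other derived
indices are computed on the row-normalized concentrations, *before*
autoscaling — a ratio of autoscaled values would be meaningless.

## Latent-variable core

**PCA by NIPALS.** Components are extracted one at a time by power
iteration (`p = X't/t't` normalised, `t = Xp`), with deflation
`X ← X − t p'`. NIPALS rather than a direct SVD because it is the
chemometrics reference algorithm for the small-n / large-J shape of panel
data; a full SVD serves as the independent oracle in the test suite.
Numerical choices: the iteration starts from the column of maximal variance
(no random initialisation — all fits are deterministic); convergence is a
relative score change below 1e−12; the iteration cap is 10000, generous
because power iteration converges at rate λ₂/λ₁ and legitimately slows when
neighbouring eigenvalues are within a few percent of each other (a cap of
~1000 is exhausted by inputs whose first two eigenvalues are nearly
degenerate, e.g. designs where two groups coincide). Signs are fixed by
making the largest-magnitude loading of each component positive.

**Hotelling T².** `T²_i = Σ_a t_ia²/var(t_a)` with critical limit
`A(n−1)(n+1)/(n(n−A)) · F_{1−α}(A, n−A)`; used for outlier flagging on PCA
scores.

**Single-response OPLS.** The predictive weight is `w ∝ X'y`. Each
orthogonal component takes the part of the current loading not aligned with
`w` (`w_o ∝ p − (w'p)w`), deflates X by its score/loading pair, and the
predictive component is recomputed on the filtered matrix. Two algebraic
identities follow and are tested exactly: orthogonal scores carry zero
covariance with y (`t_o'y = 0`, because deflation leaves `X'y` invariant),
and adding y-orthogonal structured variation to X changes the orthogonal
variance bookkeeping but not the predictions. Only one predictive component
is supported — the severity axis is one-dimensional by design, and multi-y
variants are out of scope. OPLS-DA encodes a two-class label as 0/1
(`positiveClass` selects which class is 1, so loading signs follow a chosen
convention) and decodes predictions to the nearest encoded value.

**VIP.** With a single predictive component of unit-norm weights,
`VIP_j = √J · |w_j|`, so the mean squared VIP is exactly 1 and the
conventional cut-off VIP ≥ 1 selects metabolites of above-average
contribution.

A structural point worth knowing: when the OPLS response is exactly the
first principal score of the same matrix (as in analysis B), the predictive
component *is* PC1 and no orthogonal component is extractable from the
full-data fit — `p − (w'p)w` vanishes identically. Cross-validation folds,
fitted on subsets, do not share this degeneracy, so the pipeline caps the
cross-validation-selected component count at what the full fit supports.

## Validation

**Q²Y.** Venetian-blind k-fold assignment (samples ordered by identifier,
sample *i* to fold *i* mod *k*; k = 7, the de-facto chemometrics default).
Centering and scaling are recomputed inside every training fold — scaling on
the full data before cross-validation is a classic source of optimistic Q²,
and a dedicated test verifies that perturbing one sample cannot change its
fold-mates' out-of-fold predictions. `Q² = 1 − PRESS/SSY`.

**Orthogonal-component count.** The smallest A whose successor improves Q²
by less than 0.01, scanned from 0 to `maxOrth` (default 5).

**Permutation null.** y is randomly reordered (seeded) and the full
cross-validation repeated; the summary is the *mean* permuted Q². The
identity permutation is not excluded — at realistic n its probability is
negligible. Default 200 permutations; the acceptance script uses 100.

**CV-ANOVA.** `F = ((SSY − PRESS)/d1)/(PRESS/d2)` with d1 the number of
fitted latent components and `d2 = n − d1 − 1`, upper-tail F p-value. The
components-as-degrees-of-freedom construction is the published
approximation and is documented as approximate; a type-I-error simulation
in the test suite checks the null rejection rate stays near nominal.

**Verdict.** A model counts as predictive-not-overfitted iff Q²Y_cum > 0.5,
the mean permuted Q² is negative, and CV-ANOVA p < 0.05 — the conventional
triple.

**Univariate statistics.** Mann–Whitney U is computed from rank sums
(average ranks for ties; `min(U_a, U_b)` reported) with exact p by the exact
rank distribution for tie-free samples up to n = 12 and the tie- and
continuity-corrected normal approximation otherwise; Spearman ρ is the
Pearson correlation of average ranks. Both are thin wrappers over base R's
`wilcox.test`/`cor` behind the package's interface, cross-checked in the
tests against a full enumeration oracle and a rank-Pearson oracle.

## The two analyses

**Analysis A (knockout vs wild type).** Autoscale → OPLS-DA with the
knockout encoded 1 (positive loadings = elevated in knockout) → validation →
signature from VIP ≥ 1, ranked by |loading| (no hard loading threshold; a
configurable top-fraction, default all). The volcano table pairs each
metabolite's loading with its VIP.

**Analysis B (severity ranking).** Restricted to the five transfected
groups. Autoscale → two-component PCA → t1 oriented so the declared
most-severe group (default R445H) has positive mean score → OPLS with raw
(centered) t1 as the quantitative response (scaling a single y would only
rescale the regression coefficient) → validation → per-metabolite Spearman ρ
against t1 → signature from VIP ≥ 1 with direction = sign(ρ) → groups
ordered by mean t1 → Mann–Whitney on t1 for a configured contrast pair
(default I382M vs ISO1, the hypomorph against the wild-type cDNA). Using t1
of the same matrix as the response makes the OPLS nominally circular; that
is deliberate and mirrors the workflow being implemented — the model's value
is the per-metabolite decomposition (VIP, ρ), and the validation quantifies
how stably the axis is predicted from held-out samples, not biological
truth.

**Derived indices.** Amino-acid sum, t4-OH-Pro, spermine/spermidine,
SM 18:0/SM 16:0, the two hydroxylated sphingomyelins SM (OH) C22:1/C22:2,
PUFA aa sum, PUFA/MUFA aa, MUFA/SFA ae. PUFA/MUFA/SFA are defined on the
summed double-bond count of the sum-composition shorthand (≥ 2, = 1, = 0)
within the diacyl (aa) or acyl-alkyl (ae) phosphatidylcholine subclass — the
panel does not resolve individual chains, so total unsaturation is the only
well-defined reading. Missing analytes (e.g. removed by the LOD filter)
yield a missing index with a warning, never an infinity. Each index is
regressed on t1 by ordinary least squares with R² the squared Pearson
correlation.

## The synthetic generator

Concentration of measurement *i*, metabolite *j*:

    c_ij = exp( mu_j + slope_j * rank_i + tau_j * transfected_i
                + beta_{batch(i), j} + eps_ij )

* `mu_j`: log-uniform baselines over 0.01–100 µM, fixed by a panel-level
  seed so the panel's dynamic range is a constant of the package, not of the
  run. The range gives the LOD filter something realistic to remove.
* `slope_j`: per-severity-rank log-slope, assembled from per-class (or
  per-subclass) slopes thinned to a `signal_fraction`, plus per-metabolite
  overrides. A log-normal model because concentrations are positive and MS
  panels are approximately log-normal; severity acts linearly on
  log-concentration so monotone index regressions hold by construction.
* `tau_j ~ N(0, 0.10)`: a per-metabolite offset shared by the five
  transfected groups, orthogonal in expectation to severity — reproducing a
  transfection effect on the second principal component.
* `beta ~ N(0, batch_sd)`: per-batch, per-metabolite effects (default 0.10;
  the batch-correction tests use 0.50).
* `eps ~ N(0, 0.10)`: replicate noise, i.e. roughly 10% CV — a reasonable
  figure for targeted MS panels; the source study reports no replicate
  variance, so this is a package choice, fixed once.
* LODs: a fraction `lod_quantile = 59/188` of metabolites receive an LOD
  slightly above their baseline (they fail the 20% rule); the rest an LOD
  far below (`exp(mu_j − 1.5)`). This calibrates the expected attrition to
  the 129-of-188 retention reported for the real panel.

Default slope directions encode the published signature: amino acids,
biogenic amines and phosphatidylcholines fall with severity; (hydroxylated)
sphingomyelins and spermine rise; spermidine, putrescine, taurine,
methionine sulfoxide and t4-OH-Pro fall; glutamine rises. Magnitudes
(0.05–0.15 log-units per rank) are package choices — the study publishes no
effect sizes — set once to values a targeted-metabolomics practitioner would
call moderate relative to 10% replicate noise.

**What the generator does not emulate**: censoring at the LOD (values below
the limit are reported as measured; the LOD table only marks the limit),
injection-order drift within a batch, missing-at-random dropouts,
heteroscedastic noise, metabolite–metabolite correlation beyond what the
shared group/batch/transfection structure induces, and any real biochemical
pathway structure. Passing tests therefore demonstrate that the *pipeline*
recovers planted structure through the full preprocessing chain — not that
the biological conclusions of any particular study are correct.

## A compositional caveat the tests exposed

Total-sum normalization closes the data: every value becomes relative to the
sample total. A consequence verified explicitly during development is that
the relative direction of a concentration-weighted *sum* index (such as the
amino-acid sum) is not a planted invariant when several classes carry
slopes: the panel total can fall faster than the class itself, flipping the
class's relative trend, because the log-uniform baselines concentrate the
total's mass in a few large analytes. Ratio indices (spermine/spermidine,
SM 18:0/SM 16:0, PUFA/MUFA) are immune, as are strong per-analyte overrides
relative to the mild total drift. The test suite therefore asserts sum-index
sign recovery under a single-class effect specification, and ratio/override
directions under the full default cocktail. Anyone interpreting total-sum
normalized panel data should carry the same caution: "relatively decreased"
statements are statements about composition, not concentration.

## Problem sizes and determinism

The test suite exercises the oracle comparisons on 20×15 random matrices,
the verdict behaviour on 50 simulated null studies and 2 planted ones,
severity-order recovery on 100 simulated studies, the hypomorphic-null
contrast on 40, batch-correction effectiveness on 50, and signature
precision/recall on 5 — sizes chosen so the full suite completes in a few
minutes on one CPU while keeping the binomial error of each fraction
comfortably inside the asserted margins. Every stochastic element is seeded;
`runAll()` with a fixed config and seed is byte-identical across runs apart
from one isolated timestamp field, and the report carries an MD5 hash of its
configuration.

## Limitations

* Single predictive component only; O2PLS, multi-block and kernel variants
  are out of scope, as is missing-data NIPALS (preprocessing must leave a
  complete matrix).
* No false-discovery-rate control across metabolites: selection is
  VIP/loading based, matching the workflow implemented, not a
  multiple-testing framework.
* CV-ANOVA degrees of freedom are the published components-as-df
  approximation; its p-values are indicative, not exact.
* The Q²Y-permutation summary (mean of permuted Q²) is one convention among
  several (maximum, intercept of the permutation plot); the full permuted
  distribution is kept in the report so other summaries can be derived.
* The generator's effect sizes are tuning knobs of a simulation, not
  estimates of any real study; quantitative agreement with published
  percentages is not claimed anywhere and could not be checked without the
  raw concentration matrix.
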