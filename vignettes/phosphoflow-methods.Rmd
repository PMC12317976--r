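---
title: "Models and methods behind phosphoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoflow)
```

phosphoflow implements the quantitative core of a TMT phosphoproteomics
analysis: aggregation of peptide spectral matches (PSMs) into phosphopeptide
profiles, normalization of phospho signal by the input proteome, a
variance-stabilizing transform, batch correction, k-nearest-neighbour
imputation, imputation-weighted moderated differential testing with two-tier
classification, and downstream clustering, enrichment and cell-type
specificity analysis. This vignette explains each model, the assumptions it
makes, the tunable parameters, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The data model

A quantified experiment travels as a long tibble: one row per
(feature, sample) cell with an `intensity` and an explicit `status` mask
(`observed`, `missing`, `imputed`). Reporter intensities of exactly zero in
raw tables encode non-quantified channels and are converted to missing at
ingestion; no sentinel numerics survive past the readers. The measurement
scale is tracked as an attribute (`raw` → `input_normalized` → `glog2` →
`glog2_batch_corrected`) so stages can refuse inputs on the wrong scale.

## PSM filtering and aggregation

PSMs enter the analysis when the phosphosite localization probability is
strictly greater than 0.5 and the protein has at least two razor peptides in
the protein table. Both boundaries follow common practice for this kind of
pipeline: a localization probability above one half means the reported site
placement is more likely right than wrong, and two razor peptides guard
against one-hit protein identifications. The strict inequality at 0.5 is a
deliberate choice and is configurable (`min_loc_prob`). PSMs whose protein
is absent from the protein table cannot demonstrate razor support and are
dropped (conservative).

Reporter intensities of all PSMs sharing a phosphopeptide ID — protein
accession + modified sequence + site count, e.g. `P01_T*AY*K_2` — are
summed per channel on the raw scale. A cell whose contributing PSMs are all
missing stays missing: summing absences is not evidence of zero abundance.
The same peptide observed with different numbers of phosphosites yields
distinct features, and multiplicities above 3 are labelled with their true
count rather than capped.

## Input-proteome normalization

For phosphopeptide $g$ in sample $c$ with phospho intensity $P_{g,c}$ and
input protein intensity $I_{g,c}$,

$$\mathrm{Norm}_{g,c} \;=\;
\frac{P_{g,c}/I_{g,c}}
     {\operatorname{med}_c(P_g)/\operatorname{med}_c(I_g)}
\cdot \operatorname{med}_c(P_g),$$

with medians over the observed samples of that feature or protein. The
ratio removes protein-abundance changes from the phospho signal; the two
median factors rescale the ratios back onto the phospho intensity scale so
the downstream transform sees comparable magnitudes. The formula is applied
per sample (one TMT channel): with four replicates per condition it is only
well defined per quantified column, and medians over all observed samples
make the scaling factors condition-agnostic. Features without a matching
input protein, or with an undefined/zero median denominator, are excluded
and reported with a reason code. Two algebraic identities are tested
numerically: multiplying a feature's phospho values by $k$ multiplies its
normalized values by $k$, and rescaling its input values leaves them
unchanged.

## Variance stabilization

TMT reporter intensities carry multiplicative noise at high intensity and
an additive floor near the detection limit, so the SD of raw (or plainly
logged) intensities depends strongly on the mean. The transform works in
two steps:

1. **Calibration.** Each sample is regressed on the row-median
   pseudo-reference, $x_{gs} \approx a_s + b_s\,\mathrm{ref}_g$, by
   iterated trimmed least squares: after each fit only the best-fitting
   fraction $1-\mathrm{trim}$ of features (default half) is kept for the
   next iteration. Trimming makes the fit robust to a differential minority
   and to MNAR missingness at the low end. Samples with fewer than 10
   observed values cannot be calibrated and raise an error; a non-positive
   fitted scale $b_s$ is also an error rather than silently flipping ranks.

2. **Generalized log.** Calibrated intensities $x' = (x-a_s)/b_s$ pass
   through $\operatorname{glog}_2(x) = \log_2\!\big((x' + \sqrt{x'^2 +
   c^2})/2\big)$, which equals $\log_2 x'$ up to $O((c/x')^2)$ at high
   intensity and is linear near zero. The offset $c$ controls where the
   transform switches from linear to logarithmic behaviour. It is chosen by
   direct optimization of the property we actually want: candidate offsets
   spanning the calibrated intensity range are scored by the dispersion of
   stratum-wise residual MADs of the transformed data (10 intensity
   strata), and the flattest wins. On purely multiplicative data this
   drives $c$ to the bottom of the range — the transform collapses to a
   plain $\log_2$ and fold changes are not compressed — while an additive
   noise floor of SD $\sigma_a$ against multiplicative log2-scale SD
   $\sigma_m$ reproduces the closed-form balance point $c =
   \sigma_a/(\sigma_m \ln 2)$. Simpler plug-in estimates (e.g. the residual
   MAD of the lowest-intensity quartile) systematically over-estimate $c$
   on multiplicative data, which compresses low-intensity fold changes and
   costs sensitivity; the optimization view avoids that failure mode and is
   still deterministic.

A full maximum-likelihood vsn fit is intentionally not re-implemented; the
calibrated glog above is the package's variance-stabilization contract, and
the property test (SD-vs-intensity slope across ten strata below 0.05 after
the transform, against above 0.2 before) is its acceptance surface.

## Batch correction

The replicate index doubles as the batch factor — replicate pairs are
processed together, so replicate is the natural blocking variable. Per
feature, condition and batch (sum-to-zero coded) are fitted by least squares
and the fitted batch component is subtracted; sum-to-zero coding keeps
condition means untouched. This is the standard removeBatchEffect contract
and the computation delegates to `limma::removeBatchEffect`; the package
adds the scale guard, an explicit rank check that names aliased factors when
batch is confounded with condition, and a pass-through for single-batch
designs. Features missing from an entire batch receive no correction for
that batch.

The default stage order is input-normalization → calibration/glog → batch
removal: calibration needs raw-scale intensities, and batch removal assumes
an additive (log-like) scale. The alternative order — batch removal on
plain log2 intensities before calibration — is available via
`pipeline_config(batch_first = TRUE)` for designs where batch dominates the
calibration fit; both orders are deterministic and tested.

## Imputation

Missing cells are filled by k-nearest neighbours (default $k = 10$, the
de-facto convention for this method family). Distances between features are
Euclidean over co-observed samples, rescaled by $\sqrt{n/n_{co}}$ so that
sparsely co-observed pairs are not spuriously close; each missing cell
becomes the inverse-distance-weighted mean of the neighbours observed in
that sample, with distances floored at $10^{-9}$ so exact duplicates
dominate without dividing by zero. Ties between equidistant neighbours break
toward the lower feature index (input order) — documented, deterministic,
and the only sense in which feature order matters. Features missing more
than `max_missing_frac` (default 0.5) of their cells carry too little
profile information for neighbour matching and fall back to their observed
feature mean. Observed cells are never altered, and every imputed cell is
recorded in the mask together with the neighbour count, because the
differential test needs to know which values are real.

## Moderated differential testing

Each feature is fitted by weighted least squares on condition plus the
replicate factor. Observed cells weigh 1; imputed cells weigh 0.05 in the
phospho arm and 0.01 in the cell-type arm, so imputed values stabilize the
fit without pretending to be measurements; still-missing cells are excluded.
Features whose condition coefficient is inestimable, or with no residual
degrees of freedom, are flagged untestable and excluded from moderation.

Variance moderation follows the empirical-Bayes moment-matching approach:
with residual variances $s_g^2$ on $d_g$ degrees of freedom, the prior
$(d_0, s_0^2)$ is estimated by matching the mean and variance of
$\log s_g^2$ to a scaled-F model, inverting the trigamma function by Newton
iteration (error after 100 iterations, with diagnostics). The posterior
variance is

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

the moderated statistic is $t_g = \hat\beta_g/(u_g \tilde{s}_g)$ with $u_g$
the unscaled coefficient SD, and p-values are two-sided on $d_0 + d_g$
degrees of freedom (capped at the pooled total). Two limits are exposed for
verification and are tested exactly: `prior_df = 0` reproduces the ordinary
per-feature t-test, and data whose log-variance spread does not exceed
chi-square sampling noise drive $d_0 \to \infty$, where every feature gets
the common variance — taken as the arithmetic mean of the $s_g^2$, so that
exactly equal variances reproduce the common value. Degenerate $s_g^2 = 0$
features are excluded from the moment match and assigned $s_0^2$. On
unweighted data the whole chain agrees with `limma::eBayes` to near machine
precision (a cross-check in the test suite; limma is never the
implementation).

FDR is Benjamini–Hochberg. Classification is two-tier: **hit** = FDR < 0.05
and at least a two-fold change ($|\log_2 FC| \ge 1$); **candidate** = FDR <
0.2 and at least 1.5-fold. "At least 100%/50% fold change" is read
inclusively for the phospho arm; the cell-type preset uses strict
inequalities ("greater than two-fold"), matching how each arm's thresholds
are phrased. The hit tier must not be looser than the candidate tier —
violations are a configuration error raised before any computation. Fold
changes are model coefficients on the glog2 scale, i.e. approximately log2
ratios for well-measured intensities; this choice is deliberate and
documented rather than back-transformed.

The three matrices — phospho, input-normalized phospho and input proteome —
are tested separately with the same design, mirroring how such experiments
are reported (phospho changes, phospho changes beyond protein abundance, and
protein changes).

## Downstream analyses

**Clustering.** Hit features, centred on the control-condition median, are
clustered by k-means (Euclidean). For each candidate $k$ the best of 25
seeded restarts is kept, plus a warm start grown from the previous
solution's centers (previous centers plus the worst-fitted point), which
guarantees the within-cluster sum of squares is non-increasing in $k$. The
elbow is the interior $k$ maximizing the second difference of $\log$ WSS —
the log makes the kink detection scale-free, so an early large absolute
drop cannot mask a later sharp elbow — provided the relative WSS drop at
that $k$ exceeds 5%; otherwise the smallest candidate $k$ is returned, so a
single homogeneous blob yields $k = 1$.

**Enrichment.** For each annotation term, the gene ratio $k/n$ (hits
annotated / hits) is compared with the background ratio $K/N$; their
quotient is the reported odds ratio, with a hypergeometric upper-tail
p-value $P(X \ge k)$ and BH adjustment across terms. The background
defaults to the genes the analysis actually quantified — the only
background the pipeline can justify; the annotation table is a user input
and no ontology is shipped.

**Sample similarity.** Pairwise Spearman correlations over co-observed
features, clustered hierarchically on $1-\rho$ with average linkage.

**Cell-type specificity.** Proteins need qupm ≥ 2 (quantified unique
peptides) and quantification in at least two of three runs. After
calibration, run-batch removal and imputation, each cell type is tested
one-vs-rest with imputed weight 0.01; a protein is *specific* when its
one-vs-rest log2 fold change exceeds 1 with unadjusted p < 0.05 in exactly
one cell type. The unadjusted p is intentional — specificity is a
descriptive screen, and FDR is reserved for the differential tiers.
One-vs-rest is the contrast structure of choice here because "enriched in a
cell type" is a claim against the other cell types pooled. The proteins
quantified in all cell types are reported alongside as the always-detected
set, and `overlap_with_phospho()` intersects specificity calls with
differential phosphoproteins, split by direction.

## The synthetic-data generator

`simulate_experiment()` emulates the structure the pipeline assumes: a
TMT16-style plex with four control (Sham) and four treated (TAC) replicates,
replicate pairs sharing a batch; log-normal protein baselines
($\log_2$ uniform 10–16); peptide offsets (SD 1.5 log2 units);
$1+\mathrm{Poisson}(2)$ PSMs per phosphopeptide with per-PSM intensity
jitter (SD 0.25) so summation is exercised; per-batch offsets (SD 0.3);
feature-level measurement noise (SD 0.3); a differential fraction (default
10%) with ±2 log2-unit effects; serine-dominant sites (S/T/Y =
0.85/0.13/0.02) with multiplicities 1–3 (0.75/0.2/0.05); localization
probabilities from Beta(8, 1) so a small tail falls below the filter; 5% of
phosphopeptides mapped to proteins absent from the protein table and razor
counts of $1+\mathrm{Poisson}(3)$ (so ~5% razor-1 proteins) as deliberate
filter bait. Missingness (default rate 0.1) is a mixture of MCAR and
left-censoring: half the expected missingness (mnar_weight 0.5) follows a
logistic weight that rises as intensity falls below the first quartile,
because low-abundance features drop out preferentially in TMT data. The
input proteome is flat across conditions with light (rate/5) MCAR
missingness, emulating the much more complete protein-level tables. The
cell-type generator plants proteins enriched in exactly one cell type
(default 10% at +2 log2 units) plus qupm-1 and single-run bait for the
quality filters.

What the generator does **not** emulate: isotopic interference and ratio
compression between TMT channels, co-eluting peptide interference, plex-to-
plex bridging, peptide-level missingness that differs between PSMs of the
same feature, non-normal noise tails, and correlated regulation (each
feature's effect is independent). Passing recovery tests on this generator
therefore demonstrates that the statistical machinery is correct and well
calibrated under the stated noise model — not that any particular real
dataset will reach the same sensitivity.

All generation is seeded: the same `sim_config(seed = )` reproduces every
table byte for byte.

## Test and verification sizes

The suite verifies oracle examples at hand-computable sizes (a six-PSM
fixture; 1-row formula examples), property tests at moderate sizes, and the
end-to-end checks at sizes chosen to keep Monte-Carlo noise well below the
asserted margins: 10,000 features for null calibration of the moderated
test (the null matrix draws feature variances from the scaled
inverse-chi-square hierarchy, making moderated p-values exactly uniform);
ten generator seeds at 600 phosphopeptides for recovery, where sensitivity
is measured among truly differential features passing the QC filters (the
planted unmatched/razor bait belongs to the filter contract, which is
asserted separately) and the empirical FDR against all truly differential
features; ten seeds of 240-feature block-correlated matrices for the
imputation comparison; 2,000 features for the variance-stabilization slope.
`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.

## Known limitations

- Fold-change thresholds are applied to glog2-scale coefficients, which are
  slightly conservative for features near the additive-noise floor.
- The knn imputer biases heavily-missing features toward their neighbours'
  level, which shrinks fold changes of features with MNAR dropout
  concentrated in one condition; the 0.05/0.01 weighting limits, but cannot
  eliminate, the effect.
- One TMT plex at a time: no bridge-channel normalization across plexes.
- Site-level collapse (peptides sharing a phosphosite) and isoform
  resolution are out of scope; features are phosphopeptide forms.
- The moderated test assumes approximately normal residuals on the glog2
  scale; gross outliers are not down-weighted (no robust eBayes variant).
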