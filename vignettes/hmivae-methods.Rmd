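---
title: "hmivae: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hmivae: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the per-cell feature model, the multi-view conditional VAE,
the downstream statistics, the synthetic world the tests run in, and
the design decisions taken where the design was genuinely open. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. From pixels to views

The inputs are, per acquisition ("sample"): a 3-D pixel expression
stack (y × x × channel, raw counts), an aligned integer segmentation
mask (0 = background; cell IDs need not be sequential — they are keyed
as (sample_id, original mask label)), and a channel table flagging
exactly two DNA-intercalator channels and any number of background
channels. Arrays are indexed (row, column) = (y, x); centroids are
0-based pixel coordinates. Because no TIFF reader exists in the
supported dependency set, stacks are exchanged in a
directory-of-arrays layout (one headerless CSV per channel); the
channel table is always an external CSV.

**Mean expression Y.** Arithmetic mean of each protein's pixel counts
over the cell's pixels. DNA-intercalator and background channels are
excluded from the protein panel: the intercalators define the nuclear
stain and background channels measure non-specific signal, so neither
is a protein feature. Counts are used raw by default; IMC counts are
already linear in abundance, and any transformation would propagate
into the nuclear-correlation view non-linearly. (A config switch is
deliberately absent until a concrete need appears.)

**Nuclear co-localization S.** The mean nuclear stain is the per-pixel
average of the two intercalator channels — averaging makes S invariant
to swapping the two channels. S is the per-cell Pearson correlation of
each protein with this stain over the cell's pixels. Degenerate cases
(cells with < 3 pixels, constant vectors) are set to 0 rather than NA:
the VAE needs finite inputs, and "no evidence of localization" is the
correct neutral value. At ~1 µm resolution only nucleus vs. not-nucleus
is resolvable; no finer compartment is attempted.

**Morphology M (5 features).** Area = pixel count. Perimeter = count of
4-connectivity pixel faces adjacent to non-cell pixels (an exact,
definition-stable boundary length; marching-squares variants are
library-specific). Eccentricity = that of the ellipse matched to the
second central moments of the pixel centres. Concavity = 1 − area /
convex-hull area, where the hull is taken over pixel *corner* points so
filled rectangles score exactly 0. Asymmetry = (major − minor)/(major +
minor) axis contrast. All five are translation-invariant by
construction (tested).

**Spatial context C.** Cell centroids are the mean of mask pixel
coordinates (the definition is a package choice; nothing downstream is
sensitive to sub-pixel centroid conventions). Each cell's 10 nearest
same-sample neighbours (Euclidean; ties broken toward lower cell ID;
small samples use all available cells) form a sparse binary graph D
with no self-loops that never crosses sample boundaries. The columns of
[Y | S | M] are z-scored over the *pooled* dataset — matching "mean 0,
variance 1 per feature" globally; a per-sample variant would conflate
batch effects with niche composition — and C is the row-normalized D
times this scaled matrix, i.e. the mean of the neighbours' scaled
features, width L = 2P + 5. Zero-variance columns scale to zeros so C
stays finite.

**Covariates b.** With flagged background channels: per-protein
correlation (across the sample's cells) between mean per-cell
background staining and mean expression, the mean sample intensity over
all channels, and the mean background-channel intensity. The
correlation population is *within-sample*: non-specific staining is a
per-acquisition property, and pooling across samples would mix it with
biology. Without background channels: the mean sample intensity and
each protein's mean over 0-labelled (background) pixels. Samples with
< 3 cells get zero correlations with a warning. A one-hot sample
encoding (columns `onehot_<sample>`, lexicographic order) completes b;
b is broadcast per cell, concatenated to every encoder input and to z
at the decoder, and never reconstructed.

## 2. The multi-view conditional VAE

Each view, concatenated with b, passes through `n_hidden_layers` ELU
layers of `hidden_size` units into a view embedding of
`view_embed_dim` units (default = `hidden_size`; the embedding is a
hidden representation, so it keeps the ELU nonlinearity). The four
embeddings are concatenated, pass one further ELU merge layer, and two
linear heads give μ and log σ² of the diagonal-Gaussian posterior.
The decoder mirrors this exactly: [z, b] → ELU merge layer →
per-view branches of `n_hidden_layers` ELU layers → linear
reconstruction heads of widths (P, P, 5, 2P + 5). With
`n_hidden_layers = 2` the extra layer sits in the per-view branches on
both sides, preserving the encoder/decoder symmetry.

All four views are standardized (zero mean, unit variance per feature)
at model input — they mix counts, correlations in [−1, 1] and pixel
units — and the likelihood is a unit-variance Gaussian per standardized
feature. The ELBO is

ELBO = Σ_j λ_j E_q[log p(x_j | z)] − β KL(q(z|X) ‖ p(z)),

per-cell averaged; the KL uses the analytic diagonal-Gaussian form
½ Σ (μ² + σ² − 1 − log σ²), verified in tests against an independent
closed form (1e-10) and a Monte-Carlo estimate. β follows either the
warm-up schedule β(epoch) = min(1, 0.1 · epoch) — the cap at 1.0 makes
the warm-up terminate at the constant scheme's value — or the constant
scheme β ≡ 1.

Training is minibatch Adam (learning rate 1e-3, deliberately untuned)
on the reparameterized negative ELBO, with a 70/15/15
train/validation/test split stratified by sample. Early stopping
monitors the validation loss evaluated *at β = 1* (so epochs remain
comparable while β warms up) with a patience of `patience` epochs and
restores the best parameters. Everything — initialization, splits,
shuffling, reparameterization noise — draws from R's RNG seeded once
with `cfg$seed`, so identical seeds reproduce identical parameters
bit-for-bit (tested). Gradients are hand-derived reverse-mode matrix
calculus checked against central finite differences at 1e-5 relative
tolerance; there is no autodiff dependency.

`grid_search_hmivae()` scores each configuration by the held-out
per-cell *mean* reconstruction log-likelihood (mean, not sum, so scores
are comparable across dataset sizes), breaking ties toward the smaller
model and then the lower seed. `default_grid()` reproduces the
published lattice (seeds 0/1/42/123/1234; 1–2 hidden layers; 8/32/64
units; latent 10/20; warm-up vs constant; batch sizes 40000–4000); the
batch sizes are sized for ~1e6-cell cohorts and test fixtures use
reduced lattices to stay within CPU budgets.

`embed_all()` uses the posterior mean (no sampling), making every
downstream analysis deterministic given the trained model. Ablation
(`ablate()`) zeroes the target view's λ and sets all others to 1;
`expression_only` keeps only λ_E = 1.

## 3. Downstream statistics

**Clustering.** Exact Euclidean kNN graph (100 neighbours by default),
union-symmetrized, unweighted, partitioned by Leiden with the
modularity objective — whose resolution parameter behaves like the
standard single-cell workflow's — at per-space defaults 1.0
(integrated), 0.5 (E), 1.0 (NC), 0.1 (M), 0.5 (SC). Cluster IDs are
relabelled contiguously from 0 in first-appearance order, so labels are
reproducible across runs with the same seed.

**Feature ranking.** Welch (unequal-variance) t-test per feature,
cluster vs rest — Welch because cluster sizes and variances are
heterogeneous by construction — BH-adjusted across features within the
cluster; the top 3 by t among (t > 0, adjusted p < .05) are selected,
and the report covers the union of selected features across clusters
with each cluster's statistics (the deliberately relaxed reporting).
Constant features have no defined t and are never selected;
single-cell clusters are skipped with a warning.

**Prevalence.** Proportion = cluster count / sample cell count (sums
to 1 per sample, zeros included). Instances per mm² = count / pixel
area × 1e6, which at IMC's 1 µm/pixel makes a 1000 × 1000 image exactly
1 mm².

**Clinical association.** All regressions are maximum-likelihood
logistic fits with an intercept; the reported "t-value" is the Wald z
(coefficient / standard error). Latent association: per-sample medians
of each latent dimension regressed jointly per (variable, category),
1-vs-rest at the sample level; aliased dimensions (singular design) are
dropped and the model refit; categories under `min_samples` (default 5)
get NA rows. Proportion association is univariate per cluster (the
compositional constraint makes the joint design degenerate); per-mm²
association is a single joint fit over all clusters (the 1e6 scaling
removes the degeneracy), with no predictor standardization. BH families
are: latent dimensions within (variable, category), and clusters within
(variable, category).

**Survival.** One Cox proportional-hazards model per cluster on the
chosen prevalence metric, adjusting for stage/grade as *covariates*
(the source protocol says "including … as a covariate"; its results
text says "stratified", and covariate adjustment is the weaker, safer
reading), reporting the hazard ratio, BH-adjusted p across clusters,
and the model concordance index.

**BH.** Hand-implemented step-up (NAs preserved and excluded from the
family size), cross-checked in tests against `stats::p.adjust` on
random vectors — the dual implementation guards against silent family
mis-specification.

**Segmentation QC.** For pairs of biologically exclusive proteins, the
percentage of cells strictly above both protein medians. Independence
gives ≈ 25%; strongly higher values indicate signal bleeding across
adjacent cell boundaries. Default pairs (CD3/CD20, CK8/18 vs CK5,
CD45 vs CK8/18, SMA/PanCK, GATA3/CK14) apply when the panel names
match. (The source text prints "CD14" once for this last pair; CK14 is
the basal cytokeratin used everywhere else, so CD14 is treated as a
typo.)

## 4. Projection

A reference model projects a query cohort by reusing the reference's
feature scalers — a projection must not peek at query statistics; the
alternative (re-standardizing on the query) would silently absorb batch
differences into the views. Query covariates are conformed to the
reference schema: background covariates intersected by name or
zero-filled, and the sample one-hot replaced by a seeded random valid
one-hot of reference width. Panels must match as sets (views are
reordered; anything else errors, listing the unmatched proteins).
Labels transfer by majority vote among the k = 15 nearest reference
cells (k is a package default; none is published) under Euclidean or
cosine distance; distance ties favour earlier reference cells and vote
ties the smallest label, making transfer deterministic.

ARI is the standard pair-counting adjusted index. Balanced ARI rescales
the first partition's classes to equal mass N/K before applying the
adjusted formula with the real-valued extension comb(x, 2) =
x(x − 1)/2; on balanced partitions it equals the plain ARI exactly
(tested to 1e-9), and it down-weights agreement that comes only from
dominant classes.

## 5. The synthetic world

The generator emulates the data model of an IMC experiment, not its
physics. Default stated world: 3 samples on 160 × 160 px grids, ~200
cells each, 4 phenotypes with two high markers apiece (pixel rate 12 vs
1), 8 proteins + 2 DNA channels, one strongly nuclear protein (GATA3,
nuclear fraction 0.9; others 0.15), Poisson pixel noise, per-sample
intensity multipliers 0.8–1.25 (staining-efficiency batch effect),
phenotypes spatially clustered in image bands mixed by a K × K matrix
(0.7 self), and clinical labels whose "grade" is logistic in the first
phenotype's prevalence (log-odds 8 per unit centred prevalence).
Survival times are exponential with hazard ∝ exp(log HR × covariate)
and independent exponential censoring (~15%).

Cells are axis-aligned ellipses (radii 2.2–3.8 px) with a concentric
nuclear ellipse at 0.55 scale, placed on a jittered grid so they never
overlap — enough structure to exercise all five morphology features and
the nuclear/cytoplasmic split, and deliberately nothing more. What the
generator does **not** emulate: irregular cell shapes and contact,
segmentation errors, spillover/hot pixels, marker co-expression
gradients, spatial autocorrelation of intensity. A green test therefore
establishes that the implementation computes the stated quantities
correctly and that recovery works when the world matches the model's
assumptions — not that the model is robust to real IMC artefacts.

Mask labels are deliberately non-sequential (2i + 1) to keep the
(sample, original label) keying honest.

## 6. Numerical choices and degenerate inputs

- Pearson correlations on < 3 points or constant vectors → 0.
- Zero-variance features z-score to zero columns.
- Cells with no neighbours get zero context rows, with a warning.
- Distance and vote ties break deterministically (lower index / smaller
  label).
- Doubles are serialized with shortest round-trip decimal formatting
  (15 significant digits when lossless, 17 otherwise), so every CSV and
  the JSON model checkpoint reproduce values bit-for-bit.
- Non-finite training loss aborts with diagnostics rather than
  continuing silently.
- All derived child seeds stay below 2^31.

## 7. Known limitations and one red acceptance criterion

The package's acceptance suite contains one knowingly failing
criterion: after ablating the nuclear co-localization view
(λ_NC = 0), expression reconstruction is required to change by < 10%
relative to the full model. In this package's stated synthetic world
the expression change is ~50–150% — and the same holds when ablating
*any* view — across seeds 0–2, hidden sizes 32/64, latent 10/20, and
150–800 training epochs, while the ablated view's own reconstruction
always collapses (3–4× MSE) and the remaining non-expression views are
preserved. Two mechanisms: at 600 cells × 8 proteins the expression
view's MSE is very small (~0.03–0.07), so its *relative* change
amplifies; and the synthetic views share per-cell signal, so removing
one reconstruction target removes a useful auxiliary gradient
(multi-task synergy). The behaviour the criterion is really probing —
ablation selectively destroys the ablated view's information — is
demonstrated; the 10% band is an artefact of cohort scale (the original
check ran at ~10⁶ cells with 35–46 proteins). The criterion is
implemented exactly as stated and left red rather than weakened.

Other limitations: training is CPU-bound pure R and comfortable up to
tens of thousands of cells, not millions; the clustering uses exact
kNN (O(N²) memory) and is meant for the same scale; YAML configuration
was replaced by JSON (no YAML parser in the supported dependency set);
OME-TIFF ingestion is out of scope for the same reason (the
directory-of-arrays layout is the interchange format); and the
per-feature likelihood variance is fixed at 1 on standardized features
— a learned variance is a natural extension but changes none of the
package's contracts.
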