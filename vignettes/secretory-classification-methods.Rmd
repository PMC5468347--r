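---
title: "Classifying Sec-secretory proteins from N-terminal sequence windows: models and methods"
author: "secmature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Sec-secretory proteins from N-terminal sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most exported bacterial proteins reach the periplasm through the Sec
translocase. A preprotein consists of a cleavable N-terminal signal peptide
(a basic n-region, a hydrophobic h-region, and a short c-region ending at the
cleavage site) followed by the mature domain — the polypeptide that remains
after cleavage. Signal peptides are easy to recognize; the scientifically
interesting question is whether the *mature domain alone* carries enough
signal to distinguish secretory from cytoplasmic proteins. `secmature`
implements a full pipeline for that question: window extraction, feature
engineering, automated model selection with honest performance estimation,
model interpretation as sequence-logo-like weight stacks, and a combined
two-model verdict.

## Windows and coordinates

All features are computed from fixed-length N-terminal windows. Coordinates
are 1-based and inclusive; `cleavage_pos` is the last residue of the signal
peptide. The *preprotein* view windows residues `1..W` (default `W = 84`).
The *mature* view starts at `cleavage_pos + 3`: the first two mature
positions are skipped because they carry conserved cleavage-site motifs
(e.g. the invariant lipoprotein +1 Cys) that would let a classifier cheat
with signal-peptide information; the default mature window is `W = 80`,
matching the observation that roughly the first 65–80 mature residues carry
the minimal secretion information. Windows running past the sequence end are
right-padded with `-`; windows with fewer than 20 non-gap residues are
flagged `short`. Nonstandard residue codes (X, B, Z, U, O) stay in the
string but encode as all-zero binary columns and are excluded from
composition counts.

## Feature groups

Nine feature groups can be assembled into one named matrix
(`build_feature_matrix()`), with a per-group column manifest so the merged
dimensionality is always accounted for rather than assumed:

1–4. **Position-specific binary encodings** under four residue groupings:
  `individual` (20 singleton groups — one bit per residue type per
  position), `relaxed` (11 overlapping physicochemical groups: `@` = D/E,
  `+` = K/R, `sml` = V/G/A/P, `sm` = A/G, `h` = I/L/V/M, `ph` = L/I/F,
  `b` = Y/W/F, `o-` = T/S, `x` = Y/T/S, `pol` = N/Q/C, `q` = N/Q/H),
  `compact` (a 5-group partition), and `disorder_order` (disorder-promoting
  A/R/G/Q/S/P/E/K, order-promoting W/C/F/I/Y/V/L/N, neutral H/M/T/D).
  Because groups may overlap, several bits can be set at one position.
  All schemes are replaceable from a JSON config (`read_scheme_json()`).

5–7. **k-mer fractions** for k = 1, 2, 3: overlapping counts divided by
  `L - k + 1`; k-mers touching a nonstandard residue are dropped from the
  numerator.

8. **cPseAAC** — type-I pseudo-amino-acid composition customized with a
  single hydrophobicity property (Kyte–Doolittle by default, standardized to
  zero mean/unit variance across residues). The lag-j term is the mean
  squared difference of scale values at sequence distance j; the output is
  `c(f, w*theta) / (1 + w*sum(theta))` with defaults `lam = 5`, `w = 0.05`.
  Feature names carry the scale abbreviation and lag (e.g. `cpseaac:K/D.2`).

9. **Folding-component energies.** Following the frequency-based estimate of
  a sequence's total inter-residue interaction energy, `E/L = n' P n` with
  `n` the composition vector and `P` a symmetric 20×20 energy predictor
  matrix. Eigendecomposing `P = sum_k lambda_k V_k V_k'` breaks "folding"
  into components; the per-component feature is
  `e_k = sign(lambda_k) (V_k . n)`. Note this is *not* the
  quadratic spectral contribution `lambda_k (V_k . n)^2`; the quadratic term
  is exposed separately as a diagnostic rather than silently substituted.
  Eigenvectors are ordered by decreasing eigenvalue (degenerate ties broken
  by the first differing coordinate after sign fixing) and sign-fixed so the
  largest-magnitude coordinate is positive, making the decomposition — and
  therefore the features — fully deterministic. **The bundled matrix is a
  synthetic stand-in** (hydrophobic-attraction outer product plus a fixed
  ripple); the published predictor matrix can be dropped in as a plain text
  file (`load_energy_matrix()`).

## Redundancy reduction

`hobohm2_reduce()` removes homologous sequences before training: an edge
connects two sequences whose percent identity over the first 100 residues
exceeds 40, and the record with the most neighbors is removed repeatedly
until no edges remain (Hobohm algorithm 2), treating secretory and
cytoplasmic sets separately. Identity here is computed from a deterministic
global alignment (match 1, mismatch 0, linear gap −1) rather than iterative
PSI-BLAST; this removes the external-binary dependency while preserving the
cutoff and the elimination logic. Ties in neighbor count remove the
latest-index record, so earliest occurrences survive deterministically.

## Model selection pipeline

A *configuration* pairs a feature-selection spec (significance level
`alpha`, signature cut-off `max_features` ∈ {25, 50} by default) with a
classifier spec (ridge logistic regression, linear/polynomial/Gaussian SVM,
or random forest, each over a small hyper-parameter grid). The default grid
(`make_config_grid()`) has N = 56 configurations; `linear_only = TRUE`
restricts to families with humanly interpretable coefficients.

For each configuration, stratified K-fold cross-validation (default K = 10)
computes out-of-fold scores; standardization constants and the feature
signature are always computed on the training folds only (a regression test
corrupts held-out rows and checks the fold models do not move). One run fits
exactly `N × K + 1` models, the `+1` being the final model refit on all data
with the winning configuration (highest mean CV AUC, ties to the earlier
configuration). The decision threshold is set where sensitivity equals
specificity on the winning configuration's pooled out-of-fold scores —
candidate thresholds are midpoints between adjacent unique scores, scores at
or above the threshold are called positive.

**Feature selection (SES-lite).** The statistically-equivalent-signatures
idea is implemented as: sure-independence screening to a bounded candidate
pool (top `max(200, 4 * max_features)` by unconditional association), then
forward selection of the candidate with the strongest partial correlation
with the outcome given the selected set (Fisher-z test at `alpha`,
conditioning performed by residualization on the growing set), then a
backward purge of features no longer significant given the rest. Candidates
that pass the test and are nearly collinear with a selected feature
(|r| ≥ 0.99 in residual space) are recorded as statistically equivalent
substitutes, and alternate signatures are reported with one substitution
applied. The "maximum conditioning set size" of the original algorithm is
subsumed here by conditioning on the full selected set.

**Bootstrap bias correction (BBC).** The CV estimate of the *selected*
configuration is optimistic for the same reason multiple testing inflates
significance. Over B = 1000 bootstrap resamples of the sample indices, the
configuration maximizing AUC on the in-bag samples is chosen and scored on
the out-of-bag samples; the corrected estimate is the mean of the B
out-of-bag AUCs, with a percentile confidence interval. Replicates whose
out-of-bag set lacks a class are redrawn up to 50 times, then skipped with a
count. With a single configuration the corrected value equals the pooled CV
AUC up to Monte-Carlo error, and in a pure-noise grid it recenters the
best-of-grid AUC at 0.5.

**Classifier payloads.** Ridge logistic regression is fitted by glmnet
(`alpha = 0`, fixed penalty) on standardized selected features; a signature
of size one falls back to an unpenalized logistic fit and an empty signature
to an intercept-only model. Linear payloads (ridge, linear SVM) store
explicit coefficients and score through `1 / (1 + exp(-z))`,
`z = intercept + sum c_i x_i`. Kernel SVM decision values are squashed
through the logistic everywhere — during cross-validation, threshold setting
and prediction — so all scores live on one scale; Platt scaling is
deliberately not used to avoid mixing two probability calibrations across
CV and final models. Random forests are probability forests (ranger) seeded
from the run seed.

## Logo export

For linear models over position-specific binary features, coefficients are
first normalized by the feature's standard deviation, `w_ik = c_k / sd_k`.
Per position i the negative and positive weights are summed separately
(`s_i-`, `s_i+`), each sum is rescaled by the maximal per-sign absolute sum
over positions, so positive stack totals live in [0, 1] and negative ones in
[−1, 0] with each sign's maximum reaching exactly ±1, and each entry's
height is its share of the per-sign sum times the stack total. All outputs
are invariant to positive rescaling of the coefficients. Non-positional
selected features (k-mer, cPseAAC, folding components) cannot be drawn at a
position and are listed in a side table instead. The tested surface is the
TSV rendering; SVG output is a thin convenience layer. Rendering order is
negative stacks below, positive above the zero axis.

## The combined verdict

Two models are applied jointly: a preprotein-view model (signal-peptide
aware) and a mature-view model. If the preprotein model fires, the cleavage
site is estimated by scanning candidate positions p (default 15..40) and
scoring the mature model on the window starting at p + 3; the argmax wins,
ties to the smallest p. The decision table is: both negative → `cytoplasmic`;
preprotein negative but mature positive (scored from position 1, the
sequence being taken as already mature) → `mature`; both positive →
`secretory-preprotein`; preprotein positive but mature negative →
`non-secretory` (a signal peptide fused to an incompatible mature sequence).
The mature-scan heuristic for the cleavage site is a documented stand-in —
the original tool's estimation procedure is unpublished — and its range is
configurable; when the signal-peptide length distribution is known (as it is
for the synthetic generator, 18–25), narrowing the range to it reduces the
selection inflation inherent in taking a maximum over overlapping windows.

## The synthetic-data generator

`generate_dataset()` emulates the class differences the classifiers are
built to detect. Secretory sequences are Met + a basic n-region (K/R
enriched), a hydrophobic h-region (A/L/I/V/F/M), an A-x-A style c-region,
then a mature domain depleted of L/I/V/F and R in its first 15 positions
(with a mild Gly preference at the extreme N-terminus) and enriched in
S/T/N/Q/Y/D from positions 16–80. Cytoplasmic sequences are background with
a planted N-terminal hydrophobic stretch and downstream K/R enrichment.
Chimeras (`generate_chimeras()`) fuse valid signal peptides to
cytoplasmic-style downstream regions with an early basic/hydrophobic
insertion, emulating secretion-incompetent mutant derivatives. All
enrichment factors scale with one `effect` multiplier; at `effect = 0` every
weight collapses to the uniform background and the planted-stretch gate
closes, so the two classes are exactly exchangeable — this makes null
calibration tests clean. Sequence lengths are uniform on 120–400 so windows
never dominate whole sequences; the background is uniform over the 20
residues by default.

What the generator does *not* emulate: real signal-peptidase motifs beyond
the A-x-A sketch, lipoprotein lipoboxes, genome-wide composition biases,
homology structure between sequences, and the long-tailed length and
abundance distributions of real proteomes. Green tests on this generator
demonstrate that the pipeline's machinery is correct and calibrated, not
that the reported AUCs transfer to real proteomes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run end-to-end training at
200 + 200 sequences with the full 56-configuration grid and K = 10
(≈ 560 fold models + 1 final model, about a minute of CPU), null
calibrations at n = 200 over 20–50 repetitions, and decision-table
evaluations on batches of 100 sequences per class; these sizes give
stable Monte-Carlo estimates while keeping a full run on one CPU
comfortable. Other numerical choices: correlations are clamped away from ±1
before the Fisher transform; zero-variance columns standardize to constant
zero and are inert in selection; residualized candidates with vanishing
norm are dropped; eigen tie-breaks and sign conventions are fixed as above;
bootstrap replicates lacking a class out-of-bag are redrawn then skipped
with a logged count; the equal-error threshold resolves exact ties to the
middle candidate.

## Known limitations

* The per-component energy `e_k` follows the printed sign(λ)(V·n) form; its
  relation to the quadratic energy decomposition is left to the diagnostic
  output rather than reinterpreted.
* Cleavage-site estimation by mature-model scanning localizes weakly when
  the mature model is dominated by composition features (they change slowly
  as the window slides); position-specific models localize better but are
  less robust to the register of unannotated sequences. Expect the estimate
  to be approximate rather than residue-exact.
* The four-way verdict multiplies the error rates of two thresholded
  models, and the chimera/secretory branches additionally take a maximum
  over scanned windows; per-class accuracies are therefore bounded by the
  single-model accuracies, and on the synthetic generator's default effect
  size they sit near 0.85–0.93 even for models built on the generator's own
  generative statistics.
* The bundled energy matrix is synthetic; folding-component features are
  structurally faithful but their values are not those of the published
  predictor matrix.
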