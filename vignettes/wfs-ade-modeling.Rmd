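---
title: "Weighted Feature Significance models for adverse drug effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Feature Significance models for adverse drug effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfstox)
```

## The problem

Quantitative high-throughput screening (qHTS) programs test thousands of
drugs against panels of cell-based assays, producing binary activity
profiles per compound. A natural question is how predictive those in vitro
profiles are of adverse drug effects (ADEs) observed in humans, compared
with — and combined with — other compound descriptors: structure
fingerprints, literature drug-target annotations (DTAs), and animal
toxicity endpoints. `wfstox` implements the modeling method, the
evaluation protocol, and the controls for that comparison, together with a
synthetic data generator so the whole pipeline can be exercised and
validated without access to proprietary pharmacovigilance or screening
databases.

## The WFS model

For one adverse effect, training compounds are split into those reported
to have the effect (positives) and the rest. For every binary feature, a
one-sided Fisher's exact test asks whether the feature is enriched among
positives. Rows with a missing feature value are omitted from that
feature's 2x2 table. If the feature is strictly *less* frequent among
positives (depletion), its p-value is set to exactly 1: only enrichment is
evidence. Equal frequencies do not trigger the depletion rule — the
one-sided test is computed, and necessarily gives p >= 0.5. The map from
features to p-values, keyed by the features present in at least one
positive training compound, is the *comprehensive feature fingerprint* M.

A drug with feature set C is then scored

$$WFS = \frac{\sum_{i \in M \cap C} \ln p_i}
  {\min_{i \in M} \ln p_i \times (\alpha N_{C-M} + N_{M \cap C})}$$

with the weighting factor fixed at $\alpha = 1$. High scores indicate
strong ADE potential. Two index-set choices are deliberately pinned down
here because the formula leaves them implicit:

* the **sum** runs over $M \cap C$ only — p-values exist only for
  fingerprint features;
* the **minimum** runs over all of $M$, not $M \cap C$. This normalizes
  every drug against the best evidence attainable for the ADE. Taking the
  minimum over $M \cap C$ instead would let any drug carrying a single
  weak feature score exactly 1, which contradicts the intended reading
  that high scores flag strong potential. Both behaviors are easy to probe
  through `wfs_score()` by constructing fingerprints directly.

Consequences worth knowing: with $\alpha = 1$ and $C \subseteq M$ the
score lies in $[0, 1]$ and reaches 1 only for drugs whose every feature
attains the fingerprint minimum; each feature present in the drug but
absent from the fingerprint ($N_{C-M}$) strictly dilutes a positive score;
features with $p = 1$ in $M \cap C$ contribute nothing to the numerator
but still count in $N_{M \cap C}$, diluting the score — the literal
reading of the formula, kept. Natural logs are used; the ratio is
invariant to the log base (tested). Degenerate cases (empty $M \cap C$, or
a fingerprint with all $p = 1$, whose minimum log is 0) return score 0,
read as "no enrichment evidence". Missing feature values at scoring time
are treated as *not present*: an untested assay neither adds evidence nor
penalizes.

## Evaluation protocol

Compounds are randomly split into halves of near-equal size, models are
fit on one half and scored on the other, and the split is redrawn 10
times; each ADE's test AUC-ROC is averaged over splits, and a model set is
summarized by the mean of those per-ADE means, the best per-ADE mean, and
the count of ADEs above 0.75 (strict). Splits are unstratified uniform
draws. On small datasets a split can leave an ADE with a single class on
one side; such splits are redrawn for that ADE (deterministically seeded,
at most 100 attempts) and skipped with a warning otherwise. The same split
plan is shared by every model set in a comparison, so differences reflect
the inputs rather than split luck. AUC ties get 0.5 credit (Mann-Whitney
convention); `auc_roc()` is tested against an $O(n^2)$ pairwise
concordance oracle.

Two permutation controls mirror the protocol's calibration checks:

* **Label permutation** (`permutation_null()`): every ADE label column is
  permuted independently across compounds and the whole holdout protocol
  is rerun; over replicates the grand mean AUC centers at 0.50. The
  empirical one-sided p-value uses the add-one estimator
  $(1 + \#\{null \ge obs\})/(n_{perm} + 1)$.
* **Annotation permutation** (`permute_feature_block()`): the DTA block's
  rows are shuffled against the compound ids, preserving all column
  margins. The gain of a combined assay+DTA model over assay alone should
  collapse under this control, showing the gain is not an artifact of
  added dimensionality.

Model sets are compared by one-way ANOVA over per-ADE mean AUCs with
Bonferroni-adjusted pairwise t-tests (`compare_model_sets()`).

## Univariate screening

`univariate_eval()` rates each DTA (or assay readout) alone: the AUC
obtained using the 0/1 feature as the score, and the balanced accuracy
BA = (sensitivity + specificity)/2 of "predict positive iff present". For
a binary feature under the tie-corrected AUC these coincide at
$0.5 + (q - r)/2$, where $q$ and $r$ are the feature's prevalence among
positives and negatives — an identity the suite asserts. A feature is
selected if either value strictly exceeds the threshold for at least one
ADE: 0.6 for DTA blocks, 0.65 for assay readouts by convention. The screen
runs on the full compound set: it is a ranking step, not a validated
model, so selected-feature AUCs are optimistic and are never reported as
holdout performance. BA is computed at the single natural cutoff (feature
present); no cutoff search.

## Assay QC

`call_activity()` binarizes signed curve ranks: active iff
|curve rank| > 0.5 (strict; 0.5 itself is inactive), direction kept
separately (positive activation, negative inhibition). Triplicate calls
per (compound, assay) are classified as *active match* (all three active,
same direction), *inactive match* (all three inactive), *mismatch*
(opposite directions present), or *inconclusive* (anything else —
partial agreement or an inconclusive call). The reproducibility score is
2 x %active match + %inactive match - %inconclusive - 2 x %mismatch;
active matches are double-weighted because reproducing an active call is
the rarer, more informative event in a sparse screen, so scores can exceed
100. Grade bands are closed below and open above: A >= 90, B in [80, 90),
C in [70, 80), D below 70. The mismatch/inconclusive definitions are the
plain direction-aware reading; if an application's screening SOP defines
them differently, `triplicate_rates()` is the one place to adapt.

## The synthetic data generator

`generate_synthetic()` draws every matrix from one latent model so that
each pipeline stage has ground truth to recover:

1. a compound-by-target interaction matrix of independent Bernoulli draws
   at `p_interact`, with the probability raised by `scaffold_bias` for
   (compound, target) pairs linked through a latent scaffold the compound
   carries — this is what makes structure bits informative at all;
2. assay readouts that each report one of the first `n_assayed_targets`
   targets, flipped with probability `flip_noise` and masked missing at
   `missing_rate`;
3. DTA columns that annotate true interactions with probability
   `dta_coverage` and never annotate non-interactions;
4. ADE labels from a noisy-OR-like additive link: each ADE draws
   `targets_per_ade` causal targets (weighted `unassayed_bias` toward the
   targets the assays do *not* cover) and labels each compound with
   probability `ade_background + ade_link x (causal targets hit)`, capped
   at 1;
5. structure bits as noisy reporters of scaffold membership, and animal
   endpoints as noisy any-hit reporters of small random target subsets.

One global seed feeds a fixed set of pre-drawn sub-seeds, one per matrix,
so adding or regenerating a block never perturbs the others.

The additive capped link was chosen because it is simple, monotone in the
number of causal targets hit, and recoverable; no generative model is
asserted by the reference protocol, so this is an explicit stand-in. The
bias of causal targets toward unassayed ones (default weight 0.8) is what
gives annotation data genuine headroom over the assays — the "expanding
biological space" effect the pipeline is designed to measure.

### Default parameters and why

The defaults (300 compounds, 50 targets of which 15 assayed by 30
readouts, 50 DTAs, 64 bits, 20 ADEs; `p_interact = 0.12`,
`flip_noise = 0.05`, `missing_rate = 0.02`, `dta_coverage = 0.9`,
`ade_background = 0.05`, `ade_link = 0.6`, `targets_per_ade = 2`) were set
once, by design analysis rather than tuning: a binary feature with
prevalence $q$ in positives and $r$ in negatives has univariate
AUC $= 0.5 + (q - r)/2$, so for causal-target DTAs to be discoverable by a
0.6 screen the link must be strong relative to the background
($q - r > 0.2$). With the defaults a causal DTA reaches AUC ≈ 0.66 in
expectation while the per-ADE positive rate (~20%) stays compatible with
50/50 splits at n = 300. These sizes keep a full 50-replicate permutation
null under a minute on one core; they are the problem sizes used
throughout the test suite and the analysis scripts.

### What the generator does and does not emulate

It reproduces the *statistical* structure relevant to the method: sparse
binary features, multi-label outcomes linked through shared latent causes,
annotation incompleteness without false positives, assay noise and
missingness, and partial biological-space coverage. It does not attempt
realistic pharmacology: no dose-response simulation, no chemistry-aware
fingerprints (the structure block is a weak generic stand-in, so its
performance ranking relative to assay data is not calibrated to any real
screen), no correlated assay panels, no class-imbalanced rare ADEs below
the filtering threshold. Passing tests therefore demonstrate that the
pipeline is correct and calibrated — not that any particular real-world
AUC level will be attained.

## Known limitations

* The univariate screen's full-set evaluation choice follows the screening
  reading of the protocol; a holdout variant would be less optimistic.
* WFS fingerprint p-values are scoring weights, not inference; no
  multiple-testing correction is applied, on purpose.
* `filter_ades()` assumes label completeness (absence of a report = 0);
  under-reporting bias in real pharmacovigilance data is out of scope.
* Compound alignment is exact string matching on ids; registry
  normalization (e.g. CAS mapping) must happen upstream.
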