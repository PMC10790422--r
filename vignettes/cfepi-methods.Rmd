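---
title: "Multimodal epigenetic analysis of cfDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal epigenetic analysis of cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-free DNA (cfDNA) in blood plasma consists largely of
nucleosome-protected fragments released by dying cells. A single
non-destructive methylation-sequencing library therefore carries several
layers of epigenetic information at once: the methylation state of each
sequenced cytosine, and — because fragment boundaries are shaped by
nucleosome protection — the nucleosome organization of the contributing
cells. `cfepi` extracts four modalities from fragment-level alignments and
per-CpG methylation calls over a targeted panel (150 bp windows around CpG
markers; 1 kb regions flanking transcription start sites and
polyadenylation sites), and integrates them in a stacked ensemble for
case/control classification.

## The four modalities

**Methylation.** The per-site ratio is `n_meth / n_total`; zero-coverage
sites are missing. Region-level values pool counts
(`sum(n_meth) / sum(n_total)`) rather than averaging per-site ratios — the
pooled form is coverage-robust and is the convention used in low-coverage
whole-genome mode, where per-site ratios would be hopelessly noisy.
Per-site features are the default for CpG-marker panels
(`meth_mode = "site"`); region pooling is available everywhere.

**Nucleosome occupancy.** Raw occupancy at base `b` is the number of
kept fragments covering `b` — a full-fragment pileup of
mononucleosome-length molecules. The upstream literature delegates this
quantity to a nucleosome-positioning caller without recording its
parameters, so `cfepi` implements the underlying pileup directly and makes
every processing choice explicit: profiles are scaled so that each
sample's panel-wide mean occupancy is 1 (`panel_norm_factor()`), which
removes library-depth differences while preserving relative shape. A
consequence worth knowing: a depletion applied uniformly to *every* panel
region is cancelled by this normalization; class effects are only visible
where regions diverge.

**Nucleosome fuzziness.** Profiles are smoothed with a centered moving
average (73 bp, half a nucleosome; a config knob) and local maxima at
least 0.5 (normalized units) become nucleosome summits; summits closer
than 147 bp are merged keeping the higher (ties to the left). Fuzziness of
a nucleosome is the population standard deviation (divisor *n*) of the
midpoints of fragments whose midpoint falls within summit ± 73 bp;
midpoint of `[s, e)` is `floor((s + e - 1) / 2)`. The population form
keeps the all-identical case exactly 0; fewer than two supporting
fragments give a missing value. Region features average the fuzziness of
nucleosomes whose summit lies inside the region. Because the positional SD
of a handful of reads is meaningless, the modality is dropped automatically
when the mean supporting-fragment count per region falls below 20 (the
low-coverage whole-genome situation).

**Windowed protection score (WPS).** For each base `p` and the even window
`W(p) = [p - k/2, p + k/2 - 1]` (default `k = 120`, the long-fraction
window of the fragmentomics literature), WPS is the count of fragments
completely spanning `W(p)` minus the count of fragments with an endpoint
inside it. Fragments are not clipped to the region, so edge values are
exact; no smoothing or running-median detrending is applied (those
corrections target whole-genome tracks, not 2 kb targets). The package's
global 80–200 bp size filter replaces the cited method's 120–180 bp
restriction; a `--wps-frag-range`-style analysis can be reproduced by
filtering fragments to 120–180 bp before calling `compute_wps()`.

Coordinates are 0-based half-open (BED convention) throughout; BAM input
is converted at the boundary. The 80 and 200 bp filter bounds are read as
inclusive. Strand is ignored; all features here are strand-agnostic.

## Feature processing and selection

Inside every cross-validation iteration — never on the full cohort — the
training samples determine:

1. **NA filter:** any feature missing in at least one training sample is
   dropped. Features missing only in held-out samples are retained and
   imputed with the training median at predict time (the training-side
   rule says nothing about them, and prediction must still be possible).
2. **Low-variance filter:** training variance at or below `1e-8`
   (effectively constant-only; the threshold is a config knob because no
   canonical value exists).
3. **Shadow-feature (Boruta) selection**, when more features survive than
   the top-`k` cap (k = 100): each iteration permutes every original
   feature to create shadows, fits a 500-tree random forest on
   [real | shadow], and scores a hit for each real feature whose Gini
   importance exceeds the maximum shadow importance. Two-sided binomial
   tests of hits against Binomial(iter, 1/2), Bonferroni-corrected across
   features, confirm or reject; rejected features are eliminated from
   further consideration. Ranking is confirmed > tentative > rejected,
   within status by mean importance (ties by feature id); tentative
   features are eligible for the top 100, ranked below confirmed. When the
   feature universe is already at most `k`, the shadow iterations are
   skipped: every feature is selected either way, so the fitted models are
   identical and the run is much faster.

One design point deserves emphasis: the shadow pool is rebuilt from the
*full original* feature set at every iteration, even after rejections.
If the contrast pool shrinks with the rejections, late iterations compare
survivors against the maximum of only a few fresh permutations — a
trivially low bar that confirms chance-correlated noise almost always.
Even with the full pool, a caveat is inherent to the procedure at small
sample sizes: the chance-best of ~50 noise features keeps its spurious
label correlation across iterations while shadows re-randomize, so its
hit probability can stay above 1/2 and occasional false confirmations
occur (roughly half of all-noise runs at n = 60 confirm one feature).
Downstream models are insensitive to this — a spurious confirmation adds
one noise feature out of a hundred — but the selection report should not
be read as a false-discovery-controlled list.

## The stacked model and its evaluation

The outer loop is leave-one-out cross-validation. Per iteration, on the
n − 1 training samples only: per-modality selection and a 500-tree random
forest base model; stratified tenfold inner CV re-running the full
selection pipeline per fold to produce out-of-fold base probabilities;
and a meta-classifier on the stacked per-modality probabilities. The
held-out sample then receives base probabilities from the per-modality
models refit on the full training set, and the meta-classifier emits its
final probability. Inner folds derive their seed from (seed, outer
iteration), so runs are fully reproducible.

The meta-classifier family is not pinned down by the protocol the package
follows; for a 4-column input a low-variance choice matters more than
flexibility, so the default is an L2-regularized logistic model
(`glmnet`, ridge, fixed small penalty), with a random-forest meta option
(`meta = "rf"`). In three-class mode the base models emit per-class
probability vectors, the meta-model is ridge multinomial, predictions are
argmax with ties to the lexicographically first class, and accuracy
replaces AUC.

Evaluation aggregates the n held-out probabilities into a single report
(one ROC curve — not per-fold averages): rank-formulation AUC with midrank
tie correction; sensitivity at the smallest threshold whose specificity
reaches 0.90; F1 and the confusion matrix at probability 0.5 (both
operating points are config knobs); and pairwise Spearman correlations of
the per-modality probabilities. Cross-cohort validation fits the full
pipeline once on the training cohort and applies it unchanged to the test
cohort, over the intersection of feature universes.

## The synthetic cohort generator

No controlled-access data are required anywhere: `simulate_cohort()`
generates full cohorts on an artificial mini-genome. Per region, fragments
are sampled from a lattice of nucleosome positions (spacing 185 bp) with
a nucleosome-depleted region (NDR) at the TSS/PAS anchor: lattice sites
within `ndr_width / 2` (default 600 bp) of the anchor have their weight
multiplied by `ndr_depth`, and the realized fragment count is Poisson with
mean `depth * mean(weights)`, so deeper depletion yields fewer protected
fragments rather than merely reshaping the profile. Each molecule adds
Normal positional jitter to its lattice center (fuzziness control), draws
its length from Normal(167, 9) truncated to [50, 250] — the sharp
mononucleosome peak of cfDNA — with a configurable sub-nucleosomal
(~105 bp) component, and sits midpoint-at-center. Methylation calls are
Binomial per site with Poisson coverage; every sample carries an
unmethylated lambda spike-in at a configurable conversion rate (default
99.8%, safely above the 99% QC floor).

Between-sample variability has two deliberate layers. Region-level noise
(lognormal depth multipliers, Beta-distributed region methylation rates)
alone makes panel-scale effects nearly deterministic: averaging 10–40
regions removes it, single-modality AUCs pin to 1.0, and "stacking beats
the best single modality" becomes vacuous. Subject-level heterogeneity —
one draw per sample, shared across its regions (additive NDR-depth shift,
lognormal jitter multiplier, logit-scale shifts of methylation rate and
short-fragment fraction) — does not average away and keeps class overlap
realistic. Effect-size defaults were calibrated once against the
generator's own stated targets (strong preset: per-feature standardized
occupancy effect ≈ 2; complementary preset: each single-modality AUC
clearly below the stacked model; null preset: AUC ≈ 0.5) and then frozen:
cancer vs control NDR depth 0.3 vs 0.5 (strong preset 0.1 vs 0.5 with an
800 bp NDR), jitter 4.4 vs 4.0 bp, methylation rate 0.30 vs 0.25,
sub-nucleosomal fraction 0.30 vs 0.10.

WPS deliberately has a generative knob of its own (the sub-nucleosomal
fraction): fragments shorter than the protection window contribute only
negative scores, so the knob moves WPS strongly while perturbing
normalized occupancy only a few percent. Without it, WPS signal would be
entirely parasitic on the occupancy and jitter knobs and the
"disjoint-informative-regions" design would be impossible.

What the generator does *not* emulate: sequence-dependent coverage bias,
GC effects, chimeric and duplicate reads, tumor-fraction gradients within
the cancer class, correlated neighbouring regions, or realistic CpG
density. Passing tests therefore demonstrate the correctness and the
statistical behaviour of the pipeline under a controlled generative model,
not clinical performance on real plasma.

## Problem sizes and numerical choices

Simulation studies (tests and the acceptance script) run the default
preset sizes — 30 + 30 samples, 40 nucleosome regions (24 TSS + 16 PAS),
40 CpG regions × 5 sites, 300 fragments per region — chosen so the full
multimodal LOOCV (60 outer iterations × 11 selection+fit pipelines × 4
modalities) completes in minutes on one CPU. These studies use 200-tree
forests and region-pooled methylation features; `model_config()` defaults
stay at 500 trees and per-site methylation. With 40 features per modality
the top-100 cap never binds, so skipping the shadow iterations there is an
exact shortcut, and forest size only affects Monte-Carlo noise in the
probabilities, not the selection contract. Per-site mode (200 features,
cap binds) is exercised in the selection and leakage tests.

Other numerical conventions: occupancy smoothing uses truncated windows at
profile edges rather than padding; peak merging is greedy from the highest
summit with ties to the leftmost; the dinucleotide periodicity diagnostic
detrends with a 21 bp moving average and searches the 6–30 bp band of the
periodogram (restricting the band keeps harmonics of an impulse-like
repeat from masquerading as the period), calling a period only when the
band maximum exceeds 15× the in-band median power — a threshold placed
between the null distribution (max ≈ 10 across seeds) and planted signals
(≈ 100). Degenerate inputs are handled explicitly: empty fragment sets
give zero profiles and empty histograms; zero-coverage sites and
regions give missing ratios; samples without spike-in calls are failed
unless explicitly overridden; a selection that removes every feature
falls back to a class-prior predictor so LOOCV never aborts.

## Known limitations

* The nucleosome-positioning reimplementation is a deliberate
  simplification (pileup + moving average + greedy summits); it does not
  reproduce any specific external caller's output, and its parameters are
  exposed rather than tuned.
* Shadow selection at small n can confirm a stray noise feature (see
  above); interpret selection reports accordingly.
* Sensitivity at 90% specificity is read from the empirical ROC of n
  held-out probabilities; at n = 60 its granularity is 1/30.
* The CLI is a thin wrapper; programmatic use through the R functions is
  the primary interface.
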