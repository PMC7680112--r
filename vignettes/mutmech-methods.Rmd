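---
title: "Models and methods behind mutmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mutmech predicts whether an amino acid substitution is pathogenic and,
separately, *why*: which structural or functional property of the
protein the substitution is likely to destroy or create. This vignette
explains the models, the assumptions they rest on, the tunable
parameters and their defaults, what the synthetic data generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## The positive-unlabeled setting

Both layers of the model face the same epistemic situation: databases
record *known* pathogenic variants and *known* property sites, but the
absence of a record is not a negative label. Training therefore
contrasts a labeled-positive sample against an *unlabeled* mixture of
positives and negatives — positive-unlabeled (PU) learning. Two
consequences run through the package:

* **Calibration.** A classifier trained on positive-vs-unlabeled data
  underestimates the positive posterior by a constant factor (Elkan and
  Noto's result). We estimate that factor as `c`, the mean raw score on
  held-out labeled positives, and rescale raw scores by `1 / c`.
* **Class priors.** What fraction of the unlabeled pool is truly
  positive is itself estimable from score distributions
  (`estimate_mixture_proportion()`), and the same machinery quantifies
  label noise in the positive set and the pathogenic fraction of any
  scored cohort.

## Property predictors and mechanism calls

Each property predictor is a window classifier: the 11-residue window
(the site ± 5) is one-hot encoded and fed to a feed-forward network
with one hidden layer of tanh units trained by resilient propagation —
the same architecture family as the pathogenicity ensemble members.
Raw scores become posteriors of property presence via

    posterior = clip_[0,1]( (raw / c) * k )

where `k` is a prior-matching factor solved (by a fixed-point
iteration, clip inside the mean) so that the mean posterior over the
unlabeled reference pool equals the property's class prior. Solving
with the clip inside matters: a naive `min(1, raw/c)` followed by
rescaling saturates high-scoring wild-type *and* mutant windows at the
same value and erases the ordering between them, which defeats the
loss/gain comparison below. The prior itself is re-estimated from the
model's raw scores on the unlabeled pool (mixture-proportion
estimation) rather than hand-supplied, clamped to [0.005, 0.95].

For a substitution *XiY*, positions *i* − 5 … *i* + 5 are scored on the
wild-type sequence and on the **full** mutated sequence (never a
patched window), and per position

* loss = post_wt · (1 − post_mt)
* gain = (1 − post_wt) · post_mt

The property score is max(loss, gain) at the window position maximizing
it; site-specific (PTM-like) properties are restricted to the
substituted position itself, because a modification lives on an exact
residue while, say, helix propensity is a neighborhood notion. With
uninformative posteriors (0.5, 0.5), loss = gain = 0.25 — the baseline
above which a property is worth implicating. Properties that can move
in both directions for different partners (macromolecular binding) are
reported as "altered" with the same max score. Whether the reported
score should be the focal-position value or the window maximum is not
forced by the problem; we report the window maximum and record the
attaining position in the call.

Empirical p-values use the add-one estimator (r + 1)/(n + 1) against a
pool of property scores from putatively neutral substitutions, so no
p-value is exactly zero and Benjamini–Hochberg correction downstream
stays valid.

## The pathogenicity ensemble

Features come in six categories (sequence context, substitution deltas
over five fixed physicochemical scales, PSSM summaries, a predicted
conservation surrogate, homolog count profiles, and the per-property
wt/mt/loss/gain block). A category whose input is unavailable is
*masked*, not zeroed; masked entries are mean-imputed from the training
column with an indicator feature added, so "missing" is itself visible
to the model. The full published inventories of such predictors run to
over a thousand features; this implementation ships a representative,
fixed set (~80 with the default 8 properties) because the framework,
not the inventory, is what is being implemented.

Preprocessing is fitted on training rows only: two-sample Welch t-test
selection at p < 0.01 (zero-variance features are dropped with a
warning, since the statistic is undefined; if *nothing* survives — as
under label permutation — all non-constant features are kept with a
warning so the degenerate case still yields a model), z-scoring, PCA
keeping ≥ 99% variance. The ensemble has 30 members by default; each
draws a class-balanced bootstrap of 2 × the minority-class size (the
balanced-sample size is not forced by the stopping rules; this choice
keeps member data volume comparable across class imbalances), holds
out 25% as a validation set, and trains with Rprop under three stopping
rules: best-validation epoch identified, 1000 epochs, or 500
consecutive non-improving epochs ("validation checks" — we read one
check as one epoch without improvement, the most common reading). The
returned member carries the weights of its best validation epoch. Rprop
uses the canonical step-size constants (η⁺ = 1.2, η⁻ = 0.5, Δ₀ = 0.1,
Δmax = 50, Δmin = 10⁻⁶), the sign-only variant without weight
backtracking, minimizing MSE on ±1 targets (the loss is not stated in
the sources this re-implements; MSE is the default for this trainer
family). The output tanh unit is rescaled by (t + 1)/2 — the minimal
reconciliation of tanh-everywhere with scores in [0, 1]. The general
score is exactly the arithmetic mean of member scores.

## Evaluation

* **ROC/AUC** via the Mann–Whitney identity with midranks (ties count
  half), verified in the tests against an O(n²) pair-counting oracle.
* **Noise-corrected AUC**: with a fraction ρ⁺ of observed positives
  truly negative and ρ⁻ of observed negatives truly positive, the
  observed AUC is a linear attenuation of the clean one toward 0.5;
  inverting gives (A_obs − (ρ⁺+ρ⁻)/2)/(1 − ρ⁺ − ρ⁻). A simulation
  round-trip (inject noise, correct, recover) validates the linear
  form at Monte-Carlo precision; PU-specific cross terms, if any, are
  below that precision.
* **Fold assignment** is per-unit (protein or sequence-identity
  cluster) with round-robin dealing after a seeded shuffle, so no
  unit's variants ever span folds. Clustering is greedy and
  CD-HIT-like: longest-first, join the first representative with ≥
  threshold identity, identity = matches / shorter length under the
  best ungapped overlap. An external clustering binary would add a
  dependency without changing the property that matters here
  (partition integrity under the stated identity definition).
* **Fragment filter**: 25-mer neighborhoods centered on the mutation,
  compared center-aligned over their overlap; a candidate is removed
  iff any reference fragment reaches the identity threshold. Raising
  the threshold removes fewer candidates (tested).

## Class-prior estimation

`estimate_mixture_proportion()` re-implements the profile-likelihood
("largest plausible component fraction") idea at desk scale. Scores are
binned into 20 equal-frequency bins of the *pooled* sample — not
fixed-width bins — because rank-based binning makes the estimate
exactly invariant under strictly monotone transforms of both samples, a
property fixed-width histograms only approximate. The component density
is the smoothed (half-count pseudocount) histogram of the component
sample; the remainder density is free. For each α on a 101-point grid,
the remainder is optimized by EM; the profile is flat up to the largest
α consistent with the mixture and falls beyond it. The estimate is the
largest α whose profile stays within 10⁻³ · n (mean log-likelihood
tolerance 10⁻³) of the maximum. Recovery tests plant α ∈ {0.01, 0.05,
0.1, 0.3} in well-separated beta mixtures at n = 20,000 and require
mean absolute error ≤ 0.03; the estimator shows a small (~0.01) upward
bias from the plateau tolerance, well inside that band.

## Enrichment analyses

Per-property thresholds are calibrated on neutral calls at a target
FPR: the smallest observed score t with fraction(scores ≥ t) ≤ FPR
(1% by default). Affected fractions d_f (disease) and n_f (neutral)
give E = (d_f − n_f)/(d_f + n_f); significance is a one-sided Fisher
exact test in the direction of E's sign, BH-corrected within one
analysis family. PTM-like properties can be split into exact-site and
neighborhood sub-tests. The top-3 case/control comparison filters
variants at a general-score threshold, then tests each property's
case fraction-in-top-3 against the control fraction as a binomial null,
one-sided, BH-corrected. All comparisons use ≥ (a score equal to the
threshold counts).

## The synthetic world

The generator emulates the *shape* of the real inputs, not their
biology: i.i.d. sequences from a fixed background composition
(gamma-distributed lengths, mean 200, floor 30, 80 proteins by
default); eight properties planted as regular-expression motifs
(three PTM-like site-specific ones, one bidirectional binding-like
one) — motif lengths were chosen so each property clears the
20-positive training minimum at the default proteome size; pathogenic
variants either destroy a planted site or apply a large physicochemical
shift (≥ 2 SD in ≥ 3 scales), benign variants are conservative
substitutions away from planted sites; label noise plants a fraction
ρ⁻ of true pathogenic variants in the unlabeled pool and flips a
fraction ρ⁺ of pathogenic labels, with ground truth retained; PSSM
stand-ins derive from synthetic alignment columns with Beta(2,2)
conservation weights; score mixtures are beta mixtures (bounded
support matches [0, 1] scores, and the shape pairs control overlap —
the difficulty knob for prior estimation). Defaults: 400 pathogenic /
800 unlabeled variants, no noise unless asked.

What a green test therefore establishes: the *machinery* — PU
calibration, loss/gain algebra, preprocessing hygiene, ensemble
training, fold integrity, estimators and tests — behaves as specified
on data with known ground truth. What it does not establish: real-data
performance. Real proteomes have domain structure, compositional
autocorrelation and homology; real property sites are not regular
expressions; real pathogenic variants are vastly more heterogeneous.
The near-perfect cross-validated AUC on the fixture world reflects the
deliberately separable effect model, not expected clinical accuracy.

## Numerical choices and edge cases

* Probabilities are validated on entry ([0, 1]); out-of-range input is
  an error, not a clamp.
* Mechanism ranking breaks ties by ascending empirical p-value, then
  lexicographic property name — a deterministic total order.
* Window operations clip at the termini; window compositions drop
  ambiguity-code positions from the denominator; variants at `X`
  positions are rejected by name.
* The conservation surrogate is a linear model on windowed PSSM
  summaries, fitted once on synthetic columns and shipped as plain-text
  coefficients (`inst/extdata/`); a flat PSSM returns the intercept.
* Report TSVs are written with a fixed column order, a `#` header and
  six decimals, so round-trips are bit-stable at the stated precision.

## Known limitations

* The fixture world's separability overstates achievable accuracy by
  construction.
* Property predictors are trained once on the full site annotation;
  only the pathogenicity preprocessing/ensemble is re-fitted per CV
  fold. The site corpus and the variant labels are distinct label
  sources, but a fully nested re-training would be stricter.
* The PU prior re-estimation inherits the plateau-tolerance bias of
  the mixture estimator (small, upward).
* Greedy clustering is order-dependent (longest first) and its
  ungapped identity is a lower-fidelity stand-in for alignment-based
  identity; both are adequate for fold integrity, not for homology
  inference.
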