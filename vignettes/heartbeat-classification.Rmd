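---
title: "Methods: ICEEMD features and product-rule voting for inter-patient heartbeat classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICEEMD features and product-rule voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgvote)
```

This vignette explains the models and procedures behind `ecgvote`, the
choices made where the design was genuinely open, and what the package's
tests do and do not establish.

## The classification problem

Single-lead ambulatory ECG, sampled at 360 Hz, with expert beat annotations
(R-peak sample positions and beat-type symbols). Beat types collapse onto
the five AAMI super-classes N, S, V, F, Q; `map_aami_label()` implements the
standard grouping (bundle branch block and escape beats with N, atrial
premature variants with S, ventricular ectopy including flutter with V,
paced and unclassifiable beats with Q). Evaluation is inter-patient: the
canonical DS1/DS2 record partition (`split_ds1_ds2()`) keeps training and
test patients disjoint, and the four paced-rhythm records (102, 104, 107,
217) are excluded.

## Pre-processing

`denoise()` applies, in order: sample-mean removal, a 5-point centered
uniform moving average, a 1 Hz high-pass and a 45 Hz low-pass, both
4th-order Butterworth filters. Two choices deserve comment:

* **Filter order.** Only the cut-off frequencies are canonical for this
  chain; the order is a free parameter. 4th order is standard ECG practice
  and is numerically stable at 360 Hz for both corner frequencies.
* **Zero-phase application.** Both IIR stages run forward-backward
  (`signal::filtfilt`). A causal application would delay the waveform by a
  frequency-dependent lag, invalidating the annotated R indices; zero-phase
  filtering preserves peak timing exactly (the effective magnitude response
  is squared, which only strengthens the stop bands).

`segment_beats()` cuts a 300-sample window per annotated beat. The window's
placement relative to R is a documented choice: 100 samples (~0.28 s)
before and 200 (~0.56 s) after. This asymmetric split retains the P wave
before the QRS complex and the entire T wave after it, which a centered
window at this length would clip. Beats whose window would cross a record
boundary are dropped rather than padded — padding would inject artificial
morphology into the nonlinear features. Indices are 0-based throughout.

## ICEEMD

Empirical mode decomposition extracts oscillatory modes by subtracting the
local mean — the average of cubic-spline envelopes through the maxima and
minima — until the component is locally symmetric ("sifting"). Plain EMD
suffers from mode mixing on real data; the improved complete ensemble
variant estimates each residue as the *average local mean over noise-
perturbed copies* of the previous residue, which both regularizes the modes
and makes the reconstruction exact by construction (`iceemd()` satisfies
`sum(modes) + residue == x` to machine precision — a telescoping identity,
not a numerical approximation).

Numerical choices, none of which are canonical in the literature and all of
which are configurable via `sift_config()`:

* **Envelopes**: natural cubic splines through the extrema, with two
  extrema mirrored past each end. Mirroring is the standard remedy for
  spline end swings; natural boundary conditions keep the envelope tame at
  the mirrored knots.
* **Extrema**: strict interior extrema; a plateau counts once, at its
  midpoint. Sifting requires at least two maxima and two minima (otherwise
  an envelope cannot be formed and the component is a trend).
* **Sifting stop**: the classic SD criterion — the sum over samples of the
  pointwise squared relative change between consecutive sift iterates —
  with threshold 0.2 and at most 100 iterations. We deliberately use the
  original pointwise form rather than the looser ratio-of-total-energies
  variant: at 300-sample scale the pointwise form reproduces the
  dyadic-filter-bank behavior of EMD on white noise (6–8 modes), which the
  looser form does not (4–5 modes), and six modes per beat are needed for
  the 36-element feature vector.
* **Noise schedule**: `J = 50` realizations by default, amplitude
  `b_l = eps0 * sd(r_l)` with `eps0 = 0.2`. The per-level amplitude is
  implemented exactly as stated (proportional to the running residue's
  standard deviation); some ensemble-EMD variants instead normalize the
  first level by the noise mode's amplitude — we follow the plain formula
  and note the divergence here. With `eps0 = 0` the procedure degenerates
  to deterministic repeated local-mean peeling and never consults the seed.
* **Deep levels**: a short signal supports only a handful of noise modes.
  When a realization's decomposition has no l-th mode, that realization
  contributes the unperturbed local mean at level l (its noise term is
  zero), matching reference ensemble-EMD implementations; requesting more
  modes than *any* realization supports raises an error. The inner sifting
  loops are compiled (Rcpp), which is what makes the ensemble decomposition
  of thousands of beats practical.
* **Determinism**: one private RNG stream per `iceemd()` call, seeded
  explicitly; the caller's RNG state is untouched, and
  `beat_feature_table()` derives a per-beat seed so results are independent
  of evaluation order.

## Features

Six scalars per mode, first six modes, 36 per beat (`build_feature_vector()`):

* **Cumulants** (orders 2–4) at zero lag on the mean-removed mode:
  `cum2 = m2`, `cum3 = m3`, `cum4 = m4 - 3 m2^2`. These measure energy,
  asymmetry and non-Gaussianity; zero lag is the standard scalar-per-segment
  choice.
* **Entropies** on the raw sample values: Shannon
  `-sum(s^2 log s^2)`, log-energy `sum(log s^2)` (zero samples contribute
  zero), and norm `sum(|s|^p)`. All three are additive cost functions.
  Three conventions are deliberate: the Shannon form carries a leading
  minus (the common toolbox definition, which makes small-amplitude signals
  score positive); logarithms are natural; and the features are computed on
  raw amplitudes, *not* on a normalized probability vector — for 300-sample
  millivolt-scale modes this yields log-energy entropies of order −10³,
  the magnitude regime these features are known to occupy on real beats
  (asserted qualitatively in the tests). The norm exponent `p` is not
  canonical; the default is 1.1, configurable in `[1, 2)`.

## The classifier ensemble

Five base classifiers, all emitting class posteriors:

* **Naive Bayes** with supervised discretization: features are binned by
  Fayyad–Irani recursive entropy partitioning with the MDL stopping
  criterion (`mdl_discretize()`), and per-bin class likelihoods are
  Laplace-smoothed. Discretization (rather than the Gaussian or kernel
  likelihood) is the configuration used throughout, because heavy-tailed
  cumulant features violate per-class normality badly.
* **LDA / QDA**: Gaussian discriminants with pooled / per-class
  covariances, each regularized by `ridge * I` with `ridge = 1e-6` before
  inversion. With 36 features and classes holding a handful of beats, QDA's
  per-class covariances are near-singular; the ridge keeps them invertible
  but QDA remains fragile for rare classes — visible in its behavior on
  imbalanced data, and one reason the voting combinations that pair the
  trees with LDA tend to be the strongest.
* **Decision tree**: axis-aligned binary splits by information gain, with
  `min_objects = 1000` as the dominant capacity control (nodes below the
  threshold, or without a positive-gain split, become leaves) and
  Laplace-smoothed leaf posteriors. This approximates the C4.5 family
  without replicating toolkit-specific pruning mechanics; at full-database
  scale the minimum-objects rule dominates tree shape anyway.
* **Consolidated tree**: the tree's structure is voted by 10 class-balanced
  bootstrap subsamples — each proposes its best (feature, threshold); the
  majority feature wins, the median of its proposed thresholds is used, and
  every subsample is partitioned identically. Final leaf posteriors come
  from the full training data routed through the consolidated structure.
  Balanced subsampling is the mechanism by which a single interpretable
  tree resists class imbalance. The subsample count is not canonical;
  10 balances stability against runtime.

**Fusion** (`product_rule_combine()`): assuming the classifiers'
representations are conditionally independent given the class, the joint
posterior is proportional to `P(w_k)^-(R-1) * prod_i P(w_k|x_i)` — the
product of posteriors over-counts the prior R times, so R−1 factors are
divided out. Priors are the training-split class frequencies. Posteriors
are floored at 1e−6 before the product: the rule is undefined at exact
zeros, and the floor prevents any single classifier from vetoing a class
outright. Ties break by the fixed class order N, V, S, F, Q. Four standard
line-ups are provided (`make_voting_ensemble()`), pairing a tree variant
with a discriminant and naive Bayes.

## Evaluation conventions

`compute_metrics()` follows the class-specific false-positive exclusions of
the inter-patient benchmarking literature: F or Q beats predicted as V are
not counted as V false positives, and Q beats predicted as S are not
counted as S false positives (the rationale: confusing one ectopic or
unclassifiable type with another is clinically less damaging than calling a
normal beat ectopic). Two published-formula quirks are handled explicitly:

* The F and Q false positives are computed from their *own* columns
  (`C_F - Ff`, `C_Q - Qq`). Published statements of these formulas
  sometimes print `C_N` in both places, but only the own-column form is
  consistent with the published metric tables (e.g. a fusion-class
  predictivity of 10.7% requires `C_F`; the `C_N` form would give 0.6%).
* The V-class predictivity is ambiguous in the literature: with the
  exclusion convention `PPV_V = TP/(TP + FP_excl)`; published tables often
  use the plain column denominator. Both are returned (`PPV` and
  `PPV_raw`), with the exclusion form as default.

Overall accuracy is the diagonal fraction; reports round per-class values
to one decimal and OA to two, matching customary publication precision.
Reproduction of published metric tables from their confusion matrices
(bundled under `inst/extdata/`) is part of the test suite.

## The synthetic generator

`generate_record()` builds beats as sums of five Gaussian waves (P, Q, R,
S, T) with class modifiers: V widens the QRS 2.5× and suppresses P; S
shortens the RR interval to 70% and halves/advances the P wave; F averages
the N and V waveforms; Q is a narrow spike of random polarity. Records add
baseline wander (0.3 Hz), powerline interference (60 Hz — the database this
emulates is American; configurable to 50) and white noise.
`generate_imbalanced_dataset()` draws template parameters independently per
record (the inter-patient analogue) and uses the mix N 0.90 / S 0.03 /
V 0.06 / F 0.007 / Q 0.003, approximating the real DS2 proportions. Each
split is guaranteed at least 5 beats per class (excess N beats are
reassigned deterministically when a draw comes up short), because the
discriminant classifiers need at least two instances per class to estimate
covariances; at the default scale this guard rarely activates.

What the generator does *not* emulate: genuine physiological variability
(it is a static template model, not a dynamical one), rhythm-level
arrhythmia patterns (bigeminy, AF episodes), electrode artifacts, or the
morphological overlap between S and N beats that makes the real S class so
hard. Passing the end-to-end tests therefore demonstrates that the chain is
implemented correctly and can learn separable morphologies under realistic
imbalance and noise — it does not certify real-database performance, which
is why the published metric tables are validated separately through the
evaluation module.

## Problem sizes and determinism

The test suite exercises the full operating point — 2000 training and 1000
test beats, ICEEMD with J = 50 noise realizations, L = 6 modes — once, in
the acceptance tests; unit tests use smaller, explicitly-parameterized
configurations. All stochastic stages (generation, decomposition noise,
subsampling) derive from explicit seeds through private RNG streams, so
identical configurations reproduce bitwise-identical results, and the
pipeline caches feature tables content-addressed by the settings that
determine them (changing only the voting method reuses cached features).

## Known limitations

* EMD boundary handling and envelope interpolation are not standardized;
  other reasonable choices (not-a-knot splines, different mirror depths)
  produce slightly different modes, and downstream features inherit that
  sensitivity.
* The tree classifiers approximate, not replicate, C4.5 pruning mechanics;
  posterior calibration of all base classifiers is untouched (the product
  rule amplifies over-confident members).
* Three-class (N, V, S) operation simply restricts training and evaluation
  to those labels; no hierarchical scheme is attempted.
* The feature set is fixed at 36; no selection or dimensionality reduction
  is performed.
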