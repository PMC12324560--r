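---
title: "Comparing and scaling fMRI features for behavior prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and scaling fMRI features for behavior prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`bbpredict`: what each stage assumes, which parameters matter, what the
synthetic cohorts do and do not emulate, and where the implementation had to
settle genuinely open questions.

## The problem

Given a parcellated resting-state recording per subject (a `T x R` matrix of
BOLD values over `R` brain regions) and, optionally, a structural connectome
per subject (an `R x R` nonnegative symmetric fiber-density matrix), the task
is to (a) summarize each subject's recording into one of nine feature
vectors, (b) measure how well each feature predicts a continuous or binary
target across subjects, with an honest significance test, and (c) measure how
that performance scales with the number of training subjects and the amount
of scan time per subject.

## Preprocessing

The pipeline starts at the parcellated level. Two operations are provided:

* `discard_initial_frames()` removes equilibration frames (default 6) from
  the start of the first session.
* `nuisance_regress()` removes, **in one joint least-squares projection per
  session**: an intercept, a linear trend, the supplied confound regressors
  plus their backward-difference derivatives (first row zero-padded), and a
  discrete-cosine basis with `K = floor(2 * T * TR * f_c)` components,
  i.e. all periods longer than `1/f_c` (default cutoff `f_c = 0.01` Hz).

A single combined projection is used rather than sequential regression,
detrending and filtering steps because sequential orthogonalization can
reintroduce variance already removed by an earlier step; a joint projection
is order-free, idempotent, and leaves residuals exactly orthogonal to the
design. Processing is per session because sessions are separate
acquisitions; filtering across a session boundary would smear discontinuities.
The repetition time defaults to 0.72 s (the common fast-TR acquisition for
large young-adult cohorts) and is configurable everywhere.

## Feature definitions and conventions

* **mean / sd** — temporal mean and sample SD (denominator `N - 1`).
* **mssd** — mean squared successive difference with denominator `N - 1`.
  Sessions are concatenated first; one feature vector per subject per
  scan-time condition.
* **falff** — the FFT amplitude (square root of power) summed over bins whose
  center frequency lies in the closed band 0.01–0.08 Hz, divided by the sum
  over all positive-frequency bins of the demeaned concatenated series.
  Amplitude rather than power matches the original definition of the
  measure; a `mode = "power"` option is provided. Whether the measure should
  be computed per session and averaged is genuinely open; concatenation was
  chosen and is flagged here. Zero-variance regions yield 0 (with a warning)
  rather than an error so degenerate synthetic cases cannot abort a cohort
  run; the same policy gives `sd = 0`, `mssd = 0`.
* **fc** — Pearson correlation matrix; the strictly-upper triangle in
  **row-major order** is the canonical edge ordering everywhere in the
  package (features, edge labels `i_j`, reports). One fixed convention
  prevents silent edge permutation between modules. No Fisher z-transform is
  applied before modeling.
* **Graph features** are built from a spectrum `L = U Λ U'` of the
  normalized Laplacian `L = I − D^{-1/2} A D^{-1/2}` of a consensus
  structural connectome (eigenvalues ascending in `[0, 2]`; eigenvector signs
  fixed by making the largest-magnitude component positive, ties by first
  index, so decompositions are bitwise repeatable). Isolated nodes get
  `L_ii = 1`, keeping `L` symmetric PSD.
  * **psd** — `sqrt(sum_t x̂_k(t)^2)` per harmonic `k` of the temporally
    demeaned signal. The norm-over-time reading was chosen (consistent with
    the norm-based decoupling index below); a `mode = "mean_square"`
    normalization by `T` is available because the aggregation of the squared
    graph signal over time admits either reading.
  * **graph filtering** — the cutoff is `c = floor(R/2)` counted from the
    lowest graph frequency (137 at R = 274); low-pass keeps harmonics
    `1..c`. "Half the spectrum" does not specify the rounding or side of
    inclusion, so one convention is fixed, documented, and configurable.
  * **sdi** — per-region `‖x_high‖₂ / ‖x_low‖₂` over time, reported as the
    raw ratio; a `log2` option exists for users of the original decoupling
    literature. A numerically zero denominator (relative tolerance `1e-12`)
    maps to a configurable maximum with a warning.
  * **coupled / decoupled fc** — Pearson FC of the low-/high-pass filtered
    signal. Filtered regions whose variance is numerical residue (below
    `1e-10` of the input scale) are treated as degenerate and their
    correlations set to 0.
* **Consensus connectome** — per training set, edges are partitioned into
  `n_bins = 50` equal-count inter-region distance bins; within each bin the
  edges most consistently present across subjects are kept until the kept
  count equals the average per-subject edge count in that bin (ties broken
  by mean weight, then edge index). The mask multiplies the mean weight
  matrix. Distance binning corrects the short-connection bias of
  streamline-based connectomes; the bin count is not dictated by the method
  and is a configurable default. The quantile at which the per-bin density is
  matched (group mean) is likewise a documented choice.

Temporal demeaning is enforced locally inside `graph_psd()` and `sdi()` even
though preprocessing already centers each session, so the functions are
correct standalone.

## Prediction framework

`bb_predict()` evaluates one feature/target/model combination:

* **Splits** — 10 independent family-grouped splits with a 15 % test target;
  families are indivisible, so realized sizes vary by a few subjects.
  Grouping is required because family members resemble each other on
  heritable targets; splitting a family would leak that resemblance into the
  test set.
* **Nested CV** — a standard scaler (per-feature mean/SD) and all
  hyperparameter selection live strictly inside the training set; 3 inner
  folds, also family-grouped. Whether inner folds must respect families is
  an open point; grouping them costs nothing and keeps the leakage rule
  uniform, so it is applied.
* **Models** — elastic net (`glmnet`; penalty `1e-3..1e3`, 7 log-spaced
  points × mixing ratio `{0.1, 0.5, 0.9}`), linear-kernel ridge regression
  (closed-form dual solve; one eigendecomposition of the training kernel is
  reused across the whole ridge grid), and for binary targets an elastic-net
  classifier and a linear SVM (`e1071`; cost `1e-3..1e3`). Grids are exposed
  in `model_spec()` because none of them is canonical.
* **Targets** — continuous targets are standardized on the training set and
  predictions mapped back; R² is unaffected but grids stabilize.
* **Metric** — `R² = 1 − Σ(y−ŷ)² / Σ(y−ȳ_test)²` with the **test-set mean**
  baseline (a train-mean baseline is available via `r2_baseline`), and plain
  accuracy for classification. Held-out R² can be negative; that is the
  point of using it over correlation metrics.
* **Significance** — targets are reshuffled uniformly across all subjects
  (family structure deliberately ignored in the reshuffle, which mimics a
  plain relabeling null), 100 times per split, and the identical pipeline is
  rerun, giving 1000 null metrics. The verdict is
  `mean(real) > quantile(null, 0.95)` with a strict inequality; the reported
  p-value is `(1 + #{null ≥ mean(real)}) / (1 + #null)`. Because the mean of
  10 real metrics is much less variable than a single null draw, this rule
  is conservative: its empirical type-I rate sits below the nominal 5 %.
* **Summaries** — mean, SD, median, Q1, Q3 (type-7 quantiles — the exact
  interpolation is a documented choice) and p-value per
  feature/target/model row.

GSP features depend on the training set through the consensus connectome, so
`gsp_feature_provider()` wraps the rebuild; `bb_predict()` accepts either a
plain matrix or such a provider. Tests assert that scrambling test-subject
features or test-subject connectomes changes neither the scaler, the chosen
hyperparameters, nor the consensus matrix.

## Scaling experiments

`run_scaling()` crosses training fractions (default 0.2–1.0 in steps of 0.2)
with scan amounts (default 0.25, 0.5, 1, 2, 4 sessions; frame counts floored
so no cell exceeds acquired data; always anchored at the start of session
one to control for session-onset effects). Within a cell, truncation applies
to **both** training and test subjects — test features are measured under the
same scan-time condition — while the test subject *set* is identical in every
cell and only training data are degraded. Training subsets are nested across
fractions for a fixed seed (families shuffled once, prefixes taken); nesting
is not logically required but smooths the curves considerably. Split seeds
are shared across cells, so the `(1.0, max sessions)` cell reproduces the
plain pipeline bitwise — a property the tests assert. Whether the consensus
connectome should be rebuilt per cell or reused from the full-data run is
open; per-cell rebuilding (the strict leakage rule) is the default, with a
`spectrum` argument to pin a fixed basis instead.

## The synthetic cohort generator

The generator produces data with the *statistical structure* the analysis
assumes, not realistic physiology:

* **Cohort** — family sizes drawn with weights `{1: 0.4, 2: 0.3, 3: 0.2,
  4: 0.1}` (multi-member families make grouped splitting non-trivial,
  mirroring a twin/sibling cohort without claiming its exact distribution),
  ages uniform on 22–37, balanced sexes, optional exact-size hold-out
  partition (e.g. 145 of 979 subjects reserved for deriving target scores,
  leaving 834 for the main analysis).
* **Connectomes** — regions placed uniformly in a 100 mm cube; template edge
  probability and weight decay exponentially with distance (length scale
  2/5 of the max distance, giving moderate density with a genuine
  short-connection bias for the consensus step to correct); a minimum
  spanning tree guarantees connectivity; subjects perturb the template by
  multiplicative log-normal weight noise and distance-weighted edge
  drop/add, all scaled by one `noise_level` knob (0 ⇒ all subjects equal the
  template).
* **BOLD** — per-harmonic coefficient series (AR(1) noise with ρ = 0.3 mixed
  half-and-half with a slow oscillation drawn inside 0.01–0.08 Hz, so the
  temporal spectrum is informative for fALFF) are scaled to place exact
  expected energy fractions in the low and high graph bands, then rotated to
  region space. Noise is generated in the graph domain rather than region
  space: the harmonic basis is orthonormal, so the rotated noise is still
  AR(1) in every region, while band placement stays exact — with
  `band_energy = c(low = 1, high = 0)` the high-pass filtered signal is zero
  to machine precision and the decoupling index is 0.
* **Targets** — a standardized linear score on a chosen feature's measured
  values (weights drawn once per seed) mixed with Gaussian noise at a
  nominal `signal_fraction`; binary targets threshold the latent at its
  median. Because the score is built from the *measured* features, the
  nominal fraction is recoverable by regression up to estimation loss —
  approximately `(1 − s)·p/n` for a p-dimensional basis — which the tests
  account for. Target distributions are standardized Gaussians; no claims
  are made about the skew or variance of real behavioral factor scores,
  whose effect sizes are unknown and enter only through `effect_spec()`.

All randomness flows from one master seed through named substreams (cohort,
connectomes, per-subject series, targets), so any component can be
regenerated independently and full runs are bitwise reproducible.

What passing tests on these cohorts shows: the pipeline's identities,
leakage control, calibration and power behave as designed **given** the
generator's assumptions. What they do not show: robustness to head motion,
physiological confounds, parcellation error, non-Gaussian targets, or
site/scanner effects — none of which the generator emulates.

## Problem sizes used in the shipped tests

The test-suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each property is statistically meaningful: oracle
and identity checks on `50 x 10` inputs; permutation-null structure on a
60-subject, 20-region cohort (10 splits × 100 reshuffles); type-I
calibration over 20 null cohorts with 50 reshuffles each; power and effect
recovery on 800-subject cohorts with FC bases of 6–16 regions (recovery is
cross-fit over 5 folds and averaged over 3 replicate cohorts, since a single
160-subject held-out split estimates R² with a sampling SD of ≈ 0.06);
scaling monotonicity over 20 seeded 150-subject cohorts. Heavier statistical
tests use a reduced elastic-net grid (mixing ratio 0.5, 5 penalty points) —
the properties under test do not depend on grid resolution.

## Known limitations

* Kernel models other than the linear kernel are not implemented; the
  kernel trick's advantage here is the `n << p` regime, which the linear
  kernel already exploits.
* Deconfounding of targets (e.g. regressing age out of behavioral scores),
  feature-importance maps, multi-target models, fingerprinting and task
  decoding are out of scope.
* The generator's families share an id but not correlated features or
  targets; family grouping is therefore exercised structurally, but
  heritability-driven leakage itself is not simulated.
* `truncate_scan()` assumes equal session lengths when converting session
  units to frames (it uses the first session's length).
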