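---
title: "Methods: orthostatic HRV analysis and hierarchical partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthostatic HRV analysis and hierarchical partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvpart)
```

`hrvpart` quantifies how strongly echocardiographic aortic-valve parameters
are independently associated with the change of heart-rate-variability
indices between supine rest and active standing, in the presence of many
collinear covariables. This vignette is the package's account of the
methods: what each stage computes, which knobs matter, what the synthetic
data do and do not emulate, and where genuinely open design choices were
settled.

## 1. From raw signal to NN series

`detect_qrs()` implements a second-derivative QRS detector: moving-average
smoothing (40 ms window), a squared second derivative evaluated on a 20 ms
stencil (so the feature responds to curvature at the QRS scale rather than
to sample-to-sample noise), an adaptive threshold at 0.4 of the running
maximum over a 2 s window, and 200 ms refractory suppression. Candidates
are refined to the local maximum of the smoothed signal, which recovers
clean R-peak positions to within one sample. All four constants are
arguments; the defaults were chosen for single-lead chest-band recordings
at 100 Hz or more and give 100% sensitivity and precision on synthetic ECG
with additive white noise up to 10% of the R amplitude.

`clean_rr()` replaces manual artifact/ectopy editing with a reproducible
rule: an interval is removed (never interpolated) when it lies outside
300–2000 ms or deviates more than 20% from the median of the previous five
accepted intervals. Removal counts are recorded, and a series losing more
than 20% of its beats raises a data-quality error that names the series —
the pipeline turns that into a per-subject exclusion rather than a
failure. The rule is idempotent. `select_segment()` then cuts the
fixed-length analysis window (default 300 beats) after an optional `skip`,
which is exposed as a parameter precisely because which stretch of a longer
recording to analyse is an acquisition choice, not something the analysis
should guess.

## 2. The eleven HRV indices

Time domain (`hrv_time_domain()`): meanNN; SDNN with the n − 1
denominator (the HRV-standards convention); RMSSD; and pNN20 as the
percentage of successive differences *strictly* greater than 20 ms — the
boundary case matters, and an alternating ±20 ms series scores 0, not 100.

Frequency domain (`hrv_spectral()`): the tachogram — each interval placed
at its cumulative end-time — is linearly interpolated onto a uniform 3 Hz
grid anchored at the first beat's end-time, mean-removed, and passed
through a Welch estimate: Hann-windowed 256-sample segments (~85 s at
3 Hz), 50% overlap, per-segment mean removal, one-sided PSD scaling.
Band powers integrate the PSD by the trapezoid rule over LF = [0.04,
0.15) Hz and HF = [0.15, 0.4] Hz; normalized units divide by LF + HF, so
`lfn + hfn = 100` identically and Δ LFn = −Δ HFn by construction. A
`band_mean` switch reports the literal mean-of-PSD alternative instead of
integrated power; integrated ms² is the default because it is the field
convention for tabulated LF/HF values. Welch segmentation parameters are
arguments and echoed in the spectrum attributes. Degenerate inputs are
flagged, not guessed: zero band power makes the normalized units `NA`, and
zero HF makes the ratio `NA`.

Nonlinear: `dfa_alpha1()` integrates the mean-subtracted series, removes a
least-squares line in non-overlapping boxes of 4–11 beats (remainder
discarded), and takes the natural-log slope of RMS fluctuation versus box
size. `sampen()` uses template length m = 2, tolerance r = 0.2 times the
sample SD, Chebyshev distance, self-matches excluded — the canonical
defaults of the index. Both are scale-invariant (r tracks the SD), and
both flag constant input as undefined rather than returning 0.

### The small-box bias of DFA, and how the generator handles it

Order-1 DFA restricted to boxes of 4–11 beats is *biased* at the white end
of the spectrum: the exact expectation of the detrended fluctuation for
uncorrelated noise has log–log slope 0.617 on that scale range, not the
asymptotic 0.5 (at boxes 16–64 the same computation gives 0.504). The
estimator here deliberately stays the plain, field-standard algorithm —
published α₁ values carry this bias and comparability matters more than
asymptotic purity. Instead, the *generator* owns the correction:
`rr_params(fractal_alpha = a)` promises a series whose measured short-range
exponent is `a`, and `simulate_rr()` delivers that by mapping `a` to the
spectral exponent of the surrogate through a calibration solved from the
exact DFA expectation under the synthesis spectrum (`alpha_to_beta()`),
rather than through the asymptotic β = 2α − 1. Measured exponents of the
α = 0.5 and α = 1.0 draws are 0.50 and 1.00 to within ±0.01 at n = 2¹⁴.
The practical consequence: a `fractal_alpha = 0.5` draw is *slightly
anticorrelated* noise, engineered so the standard estimator reads 0.5.

## 3. Group comparison tables

`compare_groups()` reproduces the clinical baseline-table workflow: an
Anderson–Darling test (5% level, composite hypothesis, via
`nortest::ad.test`) per group, with the variable treated as normal only if
every group passes; groups under n = 8 are inconclusive and force the
non-normal branch. Normal variables are summarized mean ± SD and compared
by one-way ANOVA; non-normal ones median (p25, p75) (percentiles by linear
interpolation, quantile type 7) with Kruskal–Wallis; categorical ones as
count (percent) with Pearson chi-square *without* continuity correction —
the uncorrected statistic is what reproduces published three-group
p-values exactly (smoking counts 6/22, 26/73, 12/32 give p = 0.714).
Post hoc pairwise tests (Student's t / Mann–Whitney / chi-square by the
same rule) are always computed, but flags require both omnibus p < 0.05
and pairwise p < 0.05/3 = 0.017. Identical-valued groups short-circuit to
a degenerate p of 1 with a flag instead of a NaN from the test statistic.

## 4. Stepwise pre-selection

`stepwise_select()` is bidirectional from the empty model: the candidate
with the smallest partial-F p-value enters while ≤ 0.05, and after each
entry any included variable with p > 0.10 leaves; ties break
deterministically by (p, then name), so identical inputs give identical
step logs. These thresholds are the most common convention in clinical
statistics software; they are arguments, and the step log (`tidy()`) is
the audit trail. Under the null with five independent candidates the
probability of an empty selection is 0.95⁵ ≈ 0.77, and the test suite
checks the realized rate against exactly that bound. Complete cases are
taken within each category model, mirroring per-variable n reporting in
clinical tables; when n < 10 + k the candidate set is trimmed to the best
k by univariate p with a warning. `assemble_predictors()` unions the
per-category selections in stable order and enforces the partitioner's
k ≤ 12 budget (4096 subset fits).

## 5. Hierarchical partitioning

`hier_partition()` computes R² for all 2ᵏ predictor subsets from the
centered cross-product matrices (one small linear solve per subset;
singular subsets fall back to a pseudoinverse with a warning) and forms
each predictor's independent contribution by the closed-form subset
weighting w(s) = s!(k − s − 1)!/k! — the Shapley value of the R² game.
This is algebraically identical to Chevan–Sutherland level averaging and
to averaging marginal R² gains over all k! orderings; the test suite
verifies all three agree to 10⁻¹⁰ and that Σ I equals the full-model R² to
10⁻⁹. Because the closed form is exactly order-invariant, the historical
protocol of re-running with ten random predictor orders and averaging
(needed when per-run rounding drifts beyond 9 predictors) changes nothing
here — `hier_partition_repeats()` implements it anyway, both for fidelity
to the published procedure and as a self-check, and `partition_cohort()`
triggers it automatically above 9 predictors.

Two percentage conventions coexist in the literature: 100·I (share of
*total* outcome variance) and 100·I/ΣI (share of *explained* variance).
Both are always reported (`i_pct_abs`, `i_pct_r2`); the tabulated default
is the absolute convention. Negative independent or joint contributions
(suppressor variables) are reported as-is — truncating them would break
the conservation identity.

## 6. What the synthetic data emulate — and what they do not

`simulate_rr()` builds intervals as mean + LF sinusoid + HF sinusoid
(evaluated sequentially at cumulative beat times) + calibrated fractal
noise. `posture_shift()` encodes active standing as a shorter mean NN
(default −200 ms), damped HF modulation (×0.3), amplified LF (×1.6), and a
higher scaling exponent (+0.35); defaults were chosen so the four-way sign
pattern ΔmeanNN > 0, ΔHFn > 0, ΔLFn < 0, Δα₁ < 0 holds in ≥ 95% of
simulated subjects, matching the canonical orthostatic response
magnitudes (ΔmeanNN ≈ 0.2 ± 0.1 s in healthy subjects).

`simulate_cohort()` draws a three-group cohort (default 22/73/32) whose
covariate distributions follow published group summaries of CAVD cohorts:
valve parameters ordered NAV → AVSc → AVSt (AVA decreasing; Vmax, PGmean,
PGmax increasing), AVAi = AVA/BSA exactly, PGmax > PGmean per subject by
construction. Each Δ outcome is a linear model in standardized predictors
plus Gaussian noise; ΔmeanNN is generated first and then serves as a
covariable for the other outcomes, mirroring its dual role. Coefficients
are expressed per reference SD, where the reference moments are frozen
constants computed once from a very large draw — so the generating law
does not depend on the realized sample. The Δα₁ model is calibrated so
the valve area's absolute independent contribution is ≈ 4.6% of outcome
variance at the population level with a combined R² ≈ 0.24, and outcome
SDs and model R² across the eleven indices sit in the ranges published
for this design (R² 0.16–0.31).

One structural fact deserves emphasis: because AVA is strongly
group-separated and the influential covariables (age, SBP, medication,
MBF, ΔmeanNN) are group-structured too, AVA correlates 0.4–0.7 with them,
and its Shapley contribution has a *collinearity floor* — around 4% of
variance at this R² even if its direct coefficient were zero. The
recovery tests therefore validate the partitioner against the generator's
own population value (computed by `population_partition()` on a 10⁵-row
draw), not against the direct coefficient.

Not emulated: baroreflex dynamics or any mechanistic coupling between the
cohort covariates and the RR series (in `simulate_study()` the link is a
group-level scaling of the posture shift, not a subject-level regression);
ECG morphology beyond a detectable R wave; respiratory sinus arrhythmia
phase coupling; missingness mechanisms other than completely-at-random
(`missing_rate`, default 0 — real cohorts show per-variable patterns, e.g.
ventricular-geometry measurements missing in ~40% of subjects, which the
default deliberately does not imitate so that effect-recovery checks run
on complete data). Passing tests on these data demonstrate correctness of
the *computations*, not robustness to every pathology of real recordings.

## 7. Problem sizes and reproducibility

The test suite runs at deliberately desk-scale sizes: 300-beat series
(2¹⁴ for scaling-exponent checks), 50-seed oracle sweeps at n = 200 and
k ≤ 5, twenty n = 2000 cohorts for parameter recovery, 200 subjects for
the sign-pattern rate, and one 127-subject end-to-end pipeline run checked
for byte-identical reproduction under a fixed seed. Every random stage
takes an explicit seed; `NULL` means "use the caller's RNG stream", which
is how one outer seed makes a whole study reproducible.

## 8. Known limitations

The stepwise thresholds and direction of the original analyses in this
literature are rarely reported; the defaults here are declared
conventions, not recovered settings, and different choices change which
covariables reach the partitioning stage. Normalized units divide by
LF + HF rather than total-minus-VLF power; published tables are sometimes
ambiguous between the two. Welch segmentation of legacy MATLAB
implementations is unknown, so band powers are comparable across methods
only to within a few percent. And hierarchical partitioning quantifies
association under a linear model — the decomposition is exact, but it
inherits every assumption of OLS.
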