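# hrvpart

Heart-rate-variability (HRV) response to active standing, and hierarchical
partitioning of regression R² — an R package for asking *how much of the
orthostatic HRV response is independently explained by aortic-valve
function?*

## The problem

Calcific aortic valve disease (CAVD) progresses from a normal aortic valve
(NAV) through sclerosis (AVSc) to stenosis (AVSt). Standing up actively
triggers vagal withdrawal and sympathetic activation, and the size of that
autonomic adjustment — measured as the change Δ of each HRV index between
supine rest and active standing (Δ = supine − standing) — shrinks with
valve deterioration. But valve severity travels together with age, blood
pressure, medication and inflammation, so the interesting quantity is not a
correlation but the *independent* explanatory capacity of the valve
parameters once every covariable is on the table.

The package implements that full analysis chain:

1. **NN series preparation** — QRS detection on single-lead ECG
   (second-derivative detector), automated artifact/ectopy removal, and
   300-beat segment selection.
2. **Eleven HRV indices per series** — meanNN, SDNN, RMSSD, pNN20 (time
   domain); LF, HF, LFn, HFn, LF/HF from a Welch periodogram of the
   3-Hz-resampled tachogram, with LF = ∫[0.04, 0.15) Hz and
   HF = ∫[0.15, 0.4] Hz of the PSD and LFn = 100·LF/(LF+HF); the
   short-term detrended-fluctuation exponent α₁ (box sizes 4–11 beats);
   and sample entropy SampEn(m = 2, r = 0.2·SD).
3. **Group comparison tables** — Anderson–Darling normality gate, ANOVA /
   Kruskal–Wallis / Pearson chi-square omnibus tests, and post hoc pairwise
   tests flagged at the Bonferroni per-comparison level p < 0.05/3 = 0.017.
4. **Predictor pre-selection** — bidirectional stepwise linear regression
   (p-enter 0.05, p-remove 0.10) within each variable category (valve
   function, ventricular function, biochemical, anthropometric/clinical,
   breathing frequency, inflammatory markers, ΔmeanNN).
5. **Hierarchical partitioning** — the combined model's R² is decomposed
   into each predictor's independent contribution

   I_j = Σ_{S ∌ j} w(|S|) · [R²(S ∪ {j}) − R²(S)],  w(s) = s!(k−s−1)!/k!

   (the Shapley value of the R² game, equivalently the Chevan–Sutherland
   average over hierarchy levels), with joint contribution
   J_j = R²({j}) − I_j. Σ I_j equals the full-model R² exactly, and the
   closed form is invariant to predictor order; the literal
   repeated-random-order protocol is also provided
   (`hier_partition_repeats()`).

Because recordings from such studies are typically available only on
request, the package ships a first-class synthetic-data module: RR series
with controlled LF/HF sinusoids and fractal noise whose short-range DFA
exponent is exact by calibration, posture pairs with a parameterized
orthostatic shift, synthetic ECG and respiration waveforms, and a
three-group cohort generator with known linear effect structure, so every
stage is testable against ground truth.

## Worked example

```r
library(hrvpart)

# one subject: supine + standing NN series, eleven indices, deltas
pair <- simulate_posture_pair(seed = 8)
idx  <- hrv_compute(pair)
idx[, c("posture", "mean_nn", "rmssd", "lfn", "hfn", "alpha1")]
#>    posture mean_nn rmssd  lfn   hfn alpha1
#> 1   supine     899  43.9 40.5 59.52  0.781
#> 2 standing     698  19.9 93.0  7.02  1.791

idx$subject_id <- "S001"
hrv_delta(idx)[, c("delta_mean_nn", "delta_hfn", "delta_lfn", "delta_alpha1")]
#>   delta_mean_nn delta_hfn delta_lfn delta_alpha1
#> 1         0.201      52.5     -52.5        -1.01
```

Standing shortens the cardiac period (ΔmeanNN = 0.201 s > 0), shifts the
spectral balance from HF to LF (ΔHFn > 0, ΔLFn < 0: vagal withdrawal plus
sympathetic activation at rest relative to standing), and raises the
scaling exponent while standing (Δα₁ < 0) — the canonical orthostatic
pattern.

```r
# cohort level: how much of delta alpha1 does the valve area explain?
sim <- simulate_cohort(seed = 1)   # 22 NAV / 73 AVSc / 32 AVSt subjects
hier_partition(sim$cohort, "delta_alpha1",
               c("ava", "age", "sbp", "mbf", "delta_mean_nn"))
#> Hierarchical partitioning of R^2 for delta_alpha1
#>   full-model R^2 = 0.2120 over n = 127
#>   predictor     independent  joint i_pct_r2 i_pct_abs
#> 1 ava                0.0346 0.0776    16.3       3.46
#> 2 age                0.0286 0.0654    13.5       2.86
#> 3 sbp                0.0709 0.0724    33.5       7.09
#> 4 mbf                0.0170 0.0373     8.03      1.70
#> 5 delta_mean_nn      0.0608 0.0611    28.7       6.08
```

Here the aortic valve area independently accounts for 3.46% of the
Δα₁ variance (16.3% of the explained variance) in this 127-subject draw;
the large `joint` values show how much of each predictor's univariate R²
is shared with the rest — exactly the collinearity that hierarchical
partitioning is designed to untangle. `tidy()`, `glance()` and
`autoplot()` work on the result, and `run_hrv_pipeline()` drives the whole
chain (preprocessing → indices → deltas → tables → stepwise → partitioning)
from a beat table and a covariate table.

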