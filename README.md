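# ivimr

Intravoxel incoherent motion (IVIM) analysis of multi-b-value
diffusion-weighted MRI, aimed at radiology researchers evaluating imaging
biomarkers of treatment response — the motivating use case is predicting
pathologic complete response (pCR) to neoadjuvant chemotherapy in breast
cancer from changes in IVIM parameters between a baseline and an
early-treatment scan.

## What it computes

The IVIM model decomposes the diffusion decay of perfused tissue into a
slow tissue-water component and a fast capillary pseudo-diffusion
component:

```
S(b) = S0 · [ f · exp(−b·D*) + (1 − f) · exp(−b·D) ]
```

with `D` the true diffusion coefficient (mm²/s), `D*` the
pseudo-diffusion coefficient, and `f` the perfusion fraction. Estimation
uses the clinical **segmented** procedure: an unweighted log-linear fit of
`D` over b > 200 s/mm² (where the perfusion term has decayed away),
followed by a bounded Levenberg–Marquardt fit of `f`, `D*` and `S0` on the
full decay with `D` held fixed — per decay (`fit_ivim()`) or voxel-wise
over 4D volumes (`fit_parameter_maps()`, NIfTI + FSL-style bval I/O via
`read_dwi()`).

Around the fitter sit the pieces of a response-prediction study:

* digital phantoms with Rician magnitude noise and per-b NEX averaging
  (`generate_phantom()`, `add_rician_noise()`);
* ROI means with triplicate re-measurement, maximum transverse diameter,
  lesion volume, treatment deltas (pre − mid) and shrinkage percentages
  (`roi_summary()`, `max_diameter()`, `lesion_volume()`,
  `compute_deltas()`);
* a seeded two-group synthetic cohort generator (`simulate_cohort()`);
* the biomarker statistics: normality-routed t / Mann–Whitney group
  comparisons (exact small-sample p), pair-counting AUC with
  Hanley–McNeil CIs, Youden-optimal cutoffs, exact Clopper–Pearson
  diagnostic intervals, Hanley–McNeil AUC-difference z-tests, and
  Spearman correlation with mass shrinkage (`run_full_analysis()`).

Everything tabular flows through tibbles, fitted objects support
`tidy()` / `glance()` / `autoplot()`, and every stochastic component takes
a seed.

## Worked example

Fit a noiseless decay generated from a published baseline parameter
triple (D = 0.906×10⁻³ mm²/s, D* = 40.4×10⁻³ mm²/s, f = 35.7%):

```r
library(ivimr)
truth <- ivim_params(D = 0.906e-3, D_star = 40.4e-3, f = 0.357, S0 = 1000)
fit <- fit_ivim(ivim_decay(truth))
tidy(fit)
#> # A tibble: 4 × 3
#>   term      estimate estimate_reporting
#>   <chr>        <dbl>              <dbl>
#> 1 D         0.000906              0.906
#> 2 D_star    0.0404               40.4
#> 3 f         0.357                35.7
#> 4 S0     1000.                 1000.
```

The segmented fitter recovers the generating triple on the reporting
scales (×10⁻³ mm²/s, percent). Running the full statistics pipeline on a
default synthetic 28-patient cohort (9 pCR / 19 non-pCR):

```r
report <- run_full_analysis(simulate_cohort(seed = 1))
dplyr::filter(report$comparisons,
              startsWith(variable, "delta"))[, 1:4]
#>   variable    test_used statistic   p_value
#> 1 delta_D     student_t    -5.33  0.0000140
#> 2 delta_Dstar student_t     0.369 0.715
#> 3 delta_f     student_t     4.99  0.0000347
```

The change in `D` and `f` separates responders from non-responders
(p < 0.001) while the noisy `D*` change does not — the qualitative
pattern such a study reports. The ROC table gives each marker's AUC,
Youden cutoff and diagnostic metrics with exact CIs:

```r
dplyr::select(report$roc_table, marker, auc, cutoff, sens_pct, spec_pct)
#>   marker        auc cutoff sens_pct spec_pct
#> 1 delta_D     0.953 -0.278    100       84.2
#> 2 delta_Dstar 0.538 -4.43      88.9     36.8
#> 3 delta_f     0.930  9.15      88.9     84.2   (delta rows shown)
```

Here `delta_D` (pre − mid, so negative when D rises under therapy)
predicts pCR with AUC 0.95; patients at or below the cutoff are predicted
responders.

See `vignettes/ivim-response-analysis.Rmd` for the model, the segmented
fitter's validity region, the phantom and cohort generators, and every
numerical convention.

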