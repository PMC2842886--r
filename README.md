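# sodphrv

Time-domain heart-rate-variability (HRV) analysis for separating congestive
heart failure (CHF) from normal (N) subjects, built on the **second-order
difference plot (SODP)** of RR-interval series and an **ensemble 1-nearest-
neighbour classifier**. It is aimed at researchers working with Holter-style
RR recordings (e.g. PhysioNet RR databases) who want a fast, fully
reproducible time-domain classification pipeline — and at anyone who needs a
tested reference implementation of the SODP feature family.

## The method

For an RR series `x(1..n)` (seconds), the SODP scatters successive
differences against each other: points `(xx(i), yy(i))` with
`xx(i) = x(i+1) − x(i)` and `yy(i) = x(i+2) − x(i+1)`. Depressed HRV — the
hallmark of CHF — concentrates these points near the origin. The package
computes seven features per series or window:

- **CTM(r)** — fraction of the `n − 2` points strictly inside the disc of
  radius `r`: `CTM(r) = #{i : sqrt(xx(i)² + yy(i)²) < r} / (n − 2)`;
- **D(r)** — mean distance from the origin of the in-disc points;
- **CCTM₁..₄(r)** — the in-disc count split across the four quadrants
  (Q1 `xx ≥ 0, yy > 0`; Q2 `xx < 0, yy ≥ 0`; Q3 `xx ≤ 0, yy < 0`;
  Q4 `xx > 0, yy ≤ 0`; origin → Q1), each divided by `n − 2`;
- **SDRR** — the sample standard deviation of the RR intervals.

Radii are chosen per feature by sweeping a grid and minimizing the p-value
of a pooled two-sample t-test between cohorts (defaults: 0.015 s for the CTM
family, 0.035 s for D). Classification is leave-one-subject-out 1-NN
(Euclidean or Mahalanobis distance) with two layers of voting: each held-out
subject is classified on `mc` window realizations of its record for every
non-empty subset of the active feature set, a feature group "flags" the
subject when more than 95% of its realizations are misclassified, and the
subject counts as misclassified only when more than 95% of the `2^m − 1`
feature groups flag it. An SDRR threshold rule is included as the baseline
the ensemble is compared against.

Preprocessing (running-median ectopic-beat filter, moving-average
detrending) and a two-cohort synthetic RR generator (AR(1) with independent
control of long-term and successive-difference variability, plus trend and
ectopic contamination) make the whole pipeline testable offline.

## Worked example

```r
library(sodphrv)
spec_n   <- cohort_spec(6, n_beats = 5000, sd_base_s = 0.08, succ_diff_sd_s = 0.04,  seed = 7)
spec_chf <- cohort_spec(6, n_beats = 5000, sd_base_s = 0.04, succ_diff_sd_s = 0.015, seed = 7)
cohort <- generate_cohort(spec_n, spec_chf)

extract_features(cohort[[1]])          # one subject's feature vector
#>    ctm d_mean  cctm1  cctm2  cctm3  cctm4   sdrr
#> 0.0668 0.0223 0.0184 0.0160 0.0144 0.0180 0.0792

grid <- seq(0.005, 0.05, by = 0.005)
select_radii(feature_radius_grid(cohort, grid), grid)
#>   feature r_best        p h  ci_low ci_high
#> 1     ctm  0.030 3.92e-18 1 -0.6288 -0.6105
#> 2  d_mean  0.050 1.74e-15 1  0.0117  0.0124
#> ...
#> 7    sdrr     NA 3.24e-11 1  0.0377  0.0436

cfg <- ensemble_config("mahalanobis", window_length = 2000, train_length = 5000, mc = 7)
run_experiment(cohort, list(cfg))[[1]]
#> <classification_report> mahalanobis | {ctm,d_mean,cctm1,cctm2,cctm3,cctm4} |
#>   misclassified N=0 CHF=0 of 12
```

The feature vector shows the N subject's SODP spread (`ctm = 0.067`: only
6.7% of points within 0.015 s of the origin, SDRR 79 ms). Every selection
row rejects the null (`h = 1`) with a negative confidence interval for the
CTM family — N means sit *below* CHF means, i.e. CHF points crowd the origin
— and a positive one for SDRR (N more variable). The ensemble separates the
two synthetic cohorts perfectly, as does the full pipeline driver:

```r
run_pipeline(out_dir = "sodphrv-out")       # synth -> ... -> classify
# or from a shell:
#   Rscript -e 'sodphrv::sodp_cli()' all --config cohort.yaml --out sodphrv-out
```

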