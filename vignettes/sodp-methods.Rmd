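---
title: "SODP features and ensemble nearest-neighbour classification of RR series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SODP methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodphrv)
```

## The model and its assumptions

The package quantifies short-term heart-rate variability through the
second-order difference plot (SODP): for an RR series $x(1),\dots,x(n)$ in
seconds, the points $(xx(i),\,yy(i))$ with $xx(i)=x(i{+}1)-x(i)$ and
$yy(i)=x(i{+}2)-x(i{+}1)$, $i=1..n-2$. The two coordinates are one
difference stream shifted against itself, so the plot captures the joint
behaviour of consecutive beat-to-beat changes. Depressed variability — the
physiological signature of congestive heart failure — collapses the cloud
toward the origin.

Features per series or window:

- $\mathrm{CTM}(r)$: fraction of points **strictly** inside the disc of
  radius $r$, denominator $n-2$;
- $D(r)$: mean origin distance of the in-disc points;
- $\mathrm{CCTM}_k(r)$, $k=1..4$: the in-disc count split by quadrant,
  each over $n-2$;
- SDRR: sample standard deviation (denominator $n-1$) of the intervals.

The analysis assumes an approximately stationary series after preprocessing
(trend removal) dominated by sinus beats (ectopic removal); the features are
otherwise distribution-free summaries.

Classification is leave-one-subject-out 1-nearest-neighbour with a two-stage
vote. Training vectors are features of the other subjects' full records
(length `train_length`); the held-out subject contributes `mc` feature
vectors from windows of `window_length` beats placed evenly across its
record. For every non-empty subset $j$ of the active feature set
($fg = 2^m-1$ subsets), the subject receives
$P(i,j)=1$ iff the fraction of misclassified realizations exceeds 0.95
(strictly), and is declared misclassified iff the fraction of flagged
subsets exceeds 0.95 (strictly). With $mc=31$ that realization threshold is
crossed at 30 wrong windows and not at 29 — a boundary pinned exactly by the
tests. The repeated windows damp the variance of a single 1-NN decision;
the subset vote requires near-unanimity across feature combinations before
declaring an error, which is what drives the method's robustness.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `radii["ctm"]`, `radii["cctm1".."4"]` | s | 0.015 | best cohort separation for the CTM family on reference Holter data |
| `radii["d_mean"]` | s | 0.035 | same, for $D(r)$ |
| radius grid | s | 0.005–0.05 step 0.005 | covers both defaults; resolution of the reported optima |
| `tolerance_fraction` (ectopic filter) | — | 0.2 | standard percentage filter: sinus-to-sinus changes rarely exceed 20% |
| `window_beats` (detrend) | beats | 501 | ≈ 6–7 min of beats: removes circadian/positional trends, preserves short-term dynamics |
| `train_length` / `window_length` | beats | 70000 / 30000 | full-record training, multi-hour test windows |
| `mc` | — | 31 | realization count; odd so the 0.95 boundary is non-degenerate |
| both vote thresholds | — | 0.95 | strict near-unanimity rules |
| `k` | — | 1 | nearest neighbour; odd `k` with majority vote accepted |

Radii and RR values are in seconds throughout; SDRR is converted to
milliseconds only for display.

## The synthetic generator: what it emulates, and what it does not

Real cohorts of this kind are not redistributable, so the generator builds
a *statistical stand-in*: two groups that differ in successive-difference
variability. The clean signal is a stationary AR(1) around `mean_rr_s`,
parameterized by the long-term SD $\sigma$ (`sd_base_s`) and the
successive-difference SD $s$ (`succ_diff_sd_s`):
$\varphi = 1 - s^2/(2\sigma^2)$, innovation SD $\sigma\sqrt{1-\varphi^2}$.
This gives independent control of exactly the two axes the features probe
(SDRR vs. the SODP cloud size). Defaults: N-like $\sigma=0.08$ s,
$s=0.04$ s; CHF-like $\sigma=0.04$ s, $s=0.015$ s — SDNN and RMSSD scales
typical of healthy vs. depressed-HRV Holter recordings. Contamination is
optional: a two-cycle sinusoidal trend of amplitude `trend_amplitude_s`,
and ectopics injected at `ectopic_rate` as a short beat (0.6× the local
median) followed by a compensatory pause (1.4×). Per-subject streams are
hashed from `(seed, group, index)`, so cohorts are order-independent and
bit-reproducible.

What the surrogate does **not** reproduce: respiratory sinus arrhythmia and
other oscillatory structure, heavy-tailed or asymmetric difference
distributions, nonstationarity beyond a single slow sinusoid, and — most
consequentially — the *timescale composition* of long-term variability. An
AR(1) carrying SDNN $\sigma \gg s$ is forced to $\varphi \to 1$ with a
correlation time of only $\approx 2\sigma^2/s^2$ beats (8 beats at the
N-like defaults), whereas real SDNN power lives at minutes-to-hours scales
that a running-median filter tracks easily. For that reason the
preprocessing-recovery tests use fixtures with matched scales
($\sigma = 0.045$, $s = 0.04$, $\varphi \approx 0.6$): with the default
scales the surrogate's fast wander — an artifact of the AR(1), not a
property of ectopy or of real data — would be clipped by any local-median
filter. Consequently, a green test suite establishes that the machinery is
correct and that the method separates cohorts whose short-term variability
differs as specified; it does not establish clinical performance on real
Holter data.

## Numerical and convention choices

- **Strict disc membership** ($d < r$) in CTM, $D$ and CCTM, and the
  $n-2$ denominator, also after ectopic removal shortens a window.
- **Quadrant conventions.** The four quadrant conditions are half-open so
  they partition the plane: Q1 $xx\ge 0, yy>0$; Q2 $xx<0, yy\ge 0$; Q3
  $xx\le 0, yy<0$; Q4 $xx>0, yy\le 0$. A printed source for this feature
  family repeats Q2's sign pattern for Q4, which would double-count Q2 and
  leave Q4 empty; the Q4 condition used here restores the rotationally
  consistent partition. Origin points satisfy none of the half-open
  conditions and are assigned to Q1 (their count is reported as an
  attribute), making the count-level identity
  $\sum_k \mathrm{CCTM}_k(r) = \mathrm{CTM}(r)$ exact. The identity is
  asserted on integer counts; the sum of the four *rounded* fractions can
  differ from `ctm`'s fraction in the final ulp.
- **Empty disc.** $D(r)$ with no in-disc point is `NA`; in classification
  any realization lacking a feature value counts as misclassified for the
  groups containing that feature (a conservative default), and training
  rows lacking it are dropped.
- **Ties.** Nearest-neighbour distance ties resolve to the lowest training
  row index (stable, deterministic); radius-sweep p-value ties resolve to
  the smaller radius; both are reported via messages.
- **Mahalanobis covariance** is recomputed per held-out subject from the
  remaining training vectors of the active feature subset and ridge-
  regularized ($\lambda = 10^{-8}\,\mathrm{tr}(S)/p$) only when its
  reciprocal condition number falls below $10^{-10}$. Distances are
  computed in the whitened space (one Cholesky per subset), which makes the
  identity-covariance case coincide with Euclidean exactly.
- **Detrending edges.** The centered moving average shrinks symmetrically
  at the record ends, preserving length; the global mean is added back so
  radii keep their absolute meaning. The mean is therefore preserved only
  up to edge effects. If detrending would produce a non-positive interval
  the function raises an error rather than clipping — that situation
  signals pathological input.
- **Ectopic filter** compares each beat with the median of the 11
  previously *accepted* beats; the first 11 beats are accepted as-is.
  Because survivors were within tolerance of a median computed from the
  same accepted set, a second pass removes nothing (idempotence).

## Design decisions where the design was open

- **Preprocessing algorithms** are declared substitutes (running-median
  percentage filter; moving-average detrend), since the upstream
  description names only "removal of trends and ectopic beats"; both are
  standard HRV practice and every threshold is exposed.
- **Pooled (Student) t**, not Welch, matching the stated pooled-SD
  definition of the statistic; confidence intervals are for mean(N) −
  mean(CHF), so CTM-family intervals are negative and SDRR's positive when
  the cohorts separate as expected. No multiple-testing correction across
  the radius grid (a caveat, deliberately mirrored).
- **Window placement** is deterministic and evenly spaced (`floor(j(L−W)/
  (mc−1))`), with a seeded-random alternative in the configuration.
- **SDRR as an ensemble feature** is recomputed per test window, so the
  scalar feature gets genuine `mc` realizations.
- **No feature standardization** by default for Euclidean distance
  (matching the method's silence on scaling); a `scale_features` flag
  exists for exploration. Mahalanobis is scale-free by construction.
- **Type-I calibration** of the selection t-test is asserted at a single
  pre-chosen radius over 200 null cohorts (12 subjects each); the argmin
  over a grid inflates the nominal rate and is deliberately not asserted.

## Known limitations

- The AR(1) surrogate's timescale limitation above; no claim of clinical
  validity transfers from synthetic experiments.
- The ectopic filter's false-positive rate depends on the ratio of local
  wander to the 20% tolerance; highly erratic rhythms (e.g. atrial
  fibrillation) will be aggressively filtered.
- With 63 feature groups and the strict 0.95 group vote, a subject must be
  flagged by essentially *all* subsets to count as misclassified; the
  metric is intentionally conservative and not comparable to ordinary
  leave-one-out error rates.
- `read_rr_file` handles single-column plain-text RR files only (with a
  ms-to-s heuristic); WFDB binary annotations are out of scope.
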