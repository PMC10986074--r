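---
title: "Allometric aggregation: static, scale-local and time-dependent fractal dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric aggregation: static, scale-local and time-dependent fractal dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allofrac)
```

## The model

Physiological output signals such as minute-epoch activity counts carry
long-range correlations: values far apart in time remain statistically
dependent, a signature of the complex regulatory feedback that produced
them. Allometric aggregation quantifies this. The series
$T = \{y_i\}_{i=1..N}$ is summed into blocks of size $n$,

$$Y_k^{(n)} = \sum_{i=1}^{n} y_{(k-1)n+i},$$

and the mean and variance of the block sums are plotted against each other
on log-log axes for growing $n$. When the signal has fractal structure the
two obey a power law

$$\operatorname{var} Y^{(n)} = a \cdot \left(\overline{Y}^{(n)}\right)^{b},$$

and the slope $b$ of the log-log relation converts to the fractal dimension

$$D = 2 - b/2.$$

Two anchor processes calibrate the scale. For i.i.d. counts both the mean
and the variance of a block sum grow linearly in $n$, so $b = 1$ and
$D = 1.5$. For a fully regular (deterministic) signal the block sum is
essentially $n$ times a slowly varying value, so the variance grows as
$n^2$, giving $b = 2$ and $D = 1$. Positive autocorrelation adds covariance
terms to the block-sum variance, steepening $b$ above 1 and pulling $D$
below 1.5; healthy physiological signals live between the two extremes, and
*lower* $D$ is read as *higher* complexity. The exact oracle in between is
fractional Gaussian noise: block sums of fGn with Hurst exponent $H$ have
variance exactly $\sigma^2 n^{2H}$, so $b = 2H$ and $D = 2 - H$.

## The three estimators

**Classic static estimator** (`classic_fd`). Non-overlapping blocks at every
$n = 1..n_{max}$, one straight line fitted through all log-log points by
ordinary least squares, one global $D$. Its weakness motivates the rest of
the package: the answer depends strongly on $n_{max}$ whenever the slope
changes across scales, which is the rule rather than the exception for
activity data.

**Adapted estimator** (`aaa`, `local_fd`, `fd_profile`). Three changes.
(1) Block sizes follow a geometric schedule $n_{k+1} \approx s\,n_k$ with
$s > 1$ (`build_schedule`), spreading the fitted points evenly in log space
instead of crowding them at large $n$. (2) Blocks may overlap
(`compute_curve`): the stride between block starts is
$\max(1, \mathrm{round}(n(1-\text{overlap})))$, which multiplies the number
of segments available for the variance estimate at large $n$. (3) A cubic,
not a line, is fitted to the log-log relation; its derivative at any point
is a *scale-local* slope, hence a scale-local fractal dimension $D(n)$.

**Temporal extension** (`run_taaa`). A trailing window of fixed width
slides along the series; the adapted estimator runs inside every window and
the local $D$ (by default at the 3 h scale) is emitted at the window-end
time. The result is a complexity *signal*: each point is the fractal
dimension of the stretch of data that just ended.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `n_min`, `n_max` | 1, 540 | aggregation range in samples; 540 = 9 h at minute sampling keeps 3 h mid-range on 3-day windows |
| `s` | 1.1 | geometric spacing; ~49 levels between 1 and 540 |
| `overlap` | 0.5 | adjacent blocks share half their samples: doubles segment counts at large $n$ while keeping neighbours half-disjoint |
| eval scale | 180 | 3 h at minute sampling, the headline reporting scale |
| `width` | 4320 | 72 h window: long enough to average out the sleep/wake cycle, short enough to resolve changes on the scale of days |
| `step` | 5 | 5 min steps give a near-continuous track; 60 min is the scaled-down default used in this package's own test suite |

The window/scale guard: inside a window of width $W$, variance estimates at
the top scales rest on roughly $W/n_{max}$ disjoint stretches of data.
`window_spec` therefore warns below $W = 8\,n_{max}$ and refuses below
$W = 2\,n_{max}$.

## Numerical choices

* **Sample variance** (divisor $K-1$) at every level. At large $n$ the
  number of blocks is small and the divisor is material; the unbiased
  estimator is the conventional default.
* **Trailing partial blocks are dropped**, never padded: a padded block sum
  has the wrong distribution.
* **Base-10 logs** are stored (the fitted slope is invariant to the base).
* **Round-half-up** in the schedule recurrence, with a $+1$ progress guard
  so any $s > 1$ terminates; `round_half_up(4.5) = 5` keeps the schedule
  platform-independent (banker's rounding would not).
* **Centered cubic.** The predictor $\log_{10}\overline{Y}^{(n)}$ is
  centered before the least-squares solve. This conditions the design and
  makes the local slope exactly equivariant under positive rescaling of the
  input (which only translates both log coordinates); the package asserts
  invariance to 1e-9.
* **Evaluation at unscheduled $n$** (e.g. $n = 170$): the corresponding
  log-mean is found by log-linear interpolation of $\log_{10}\overline{Y}$
  against $\log n$ between the two adjacent scheduled levels. No
  extrapolation outside the fitted range.
* **Degenerate levels** (zero variance, or the zero mean of an all-zero
  window) cannot produce a log-log point; the static estimator treats them
  as an error, the adapted curve drops them with a warning (short sleep-time
  windows legitimately produce them), and a window whose fit fails entirely
  yields a missing track value rather than aborting — so the window-count
  formula $\lfloor (N - W)/\text{step} \rfloor + 1$ stays exact.
* **Non-monotone log-means** (possible in highly non-stationary windows,
  e.g. around extreme activity peaks) break the single-valued mean-variance
  relation; such windows are also reported as missing rather than fitted.
* **$D$ is never clamped** to $[1, 1.5]$: out-of-range values are
  diagnostically meaningful (anti-correlation above 1.5, super-regular
  scaling below 1).

## Design choices where the design was open

* **Week boundaries** follow recording days (day $k$ = samples
  $(k-1)\cdot 1440 .. k\cdot 1440$), not wall-clock midnight, and the three
  weeks partition as days 1–7, 8–14, 15–end. A
  `week3_from_day14` switch reproduces analyses that start week 3 at
  day 14.
* **Window-end timestamps**: every track point summarises the *past* window
  width, so no estimate exists before one full width has elapsed.
* **Complexity–activity sampling**: the track is sampled three times a day
  (every 8 h) starting at the first available track point, and each sampled
  $D$ is paired with the activity-count sum of the identical trailing
  window.
* **Small-sample Spearman p-values** (`spearman_small`): the coefficient is
  the Pearson correlation of average ranks, and the two-sided p-value comes
  from the $t$ reference distribution on $n-2$ degrees of freedom. On three
  items this yields the characteristic quantised pattern — $|\rho| = 1$
  significant ($p < 0.001$), $|\rho| = 0.866$ giving $p = 1/3$,
  $|\rho| = 0.5$ giving $p = 2/3$ — which is the behaviour the package's
  exhaustive 3-item enumeration tests pin down. (An exact permutation test
  on 3 items could never reach $p < 0.001$: its one-sided minimum is
  $1/6$.)

## The synthetic generators

All test inputs are generated in code, seeded and bit-reproducible
(`gen_iid`, `gen_regular`, `gen_ar1`, `gen_fgn`, `gen_diurnal`,
`inject_bout`); defaults mirror a 3-week, minute-resolution recording
(21 × 1440 samples, mean minute counts near 100–200).

* `gen_fgn` simulates fractional Gaussian noise *exactly* by Davies–Harte
  circulant embedding (the autocovariance is embedded in a circulant whose
  eigenvalues shape a complex Gaussian vector; an invalid embedding raises
  an error instead of approximating). Because it is the validation oracle
  for $D = 2 - H$, it must not carry method error; the test suite checks it
  against the closed-form autocovariance and the exact block-sum variance
  law.
* `gen_diurnal` emulates the gross structure of wrist actigraphy — a sleep
  span of near-zero counts, a modulated wake plateau, Poisson activity
  bouts — and is the fixture on which the 24 h oscillation of the
  complexity track and the scale-monotonicity of $D(n)$ are asserted.

What the generators do **not** emulate: non-wear gaps, weekday/weekend
structure, postural artefacts, or any genuine long-memory in behaviour
beyond the daily cycle. Passing tests on these fixtures therefore validate
the estimator's mathematics and its qualitative behaviour, not the clinical
interpretation of any particular recording.

## Estimator variance and bias near the scale ceiling

Two finite-sample effects are worth knowing. First, single-window (or
single-week) estimates at scales within a factor ~3 of $n_{max}$ are noisy:
the cubic's derivative near the domain edge rests on few, highly variable
variance estimates. The package's own checks therefore assert flatness of
the i.i.d. dimension profile on the seed-averaged curve and give individual
3-day windows a wide band around 1.5. Second, overlapping-block variance
estimates are slightly biased low when $n$ approaches the window length,
which bends the cubic down at the top and nudges the 3 h dimension inside
72 h windows upward by roughly +0.08 for i.i.d. input. Both effects shrink
as the window grows — the reason for the $8\,n_{max}$ rule. Problem sizes
used throughout the test suite and the acceptance script — 21-day series,
schedules up to $n_{max} = 256$ or 540, 20-seed ensembles, 60-min track
steps — were chosen as the smallest configurations at which these anchor
properties are stable.

## Worked sketch

```{r, eval = FALSE}
x <- gen_diurnal(days = 21, seed = 1)          # 3-week activity-like fixture
fit <- aaa(x)                                  # n_min 1, n_max 540, s 1.1
local_fd(fit, 180)                             # D at the 3 h scale
fd_profile(x)                                  # D across 30 min .. 8 h

tr <- run_taaa(x, window_spec(4320, 60))       # 72 h window, hourly step
wk <- weekly_summaries(x)                      # static weekly D + activity
fd_activity_correlation(x, tr)                 # Pearson r, 3 samples/day
functioning_rank_correlation(c("worst", "best", "average"), wk)
```

## Known limitations

* The method assumes uniform sampling and a positive-mean count signal;
  all-zero stretches (long non-wear) surface as missing track values, and no
  imputation is attempted.
* Each window is recomputed from scratch; an incremental update scheme
  would speed dense tracks but is deliberately out of scope.
* No confidence intervals on $D$ are provided.
* Exact reproduction of third-party tables computed with this family of
  methods depends on choices their authors rarely state (overlap stride,
  variance divisor, schedule rounding); the package documents its own
  choices and exposes them as parameters.
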