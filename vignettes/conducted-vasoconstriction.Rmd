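---
title: "Analysing conducted vasoconstriction with condvaso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing conducted vasoconstriction with condvaso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condvaso)
```

## The scientific problem

A constriction evoked at one point of an arteriole spreads along the vessel
wall: gap junctions couple endothelial and smooth-muscle cells electrically,
so a depolarising stimulus at the glomerular entrance of an afferent
arteriole also narrows the vessel tens to hundreds of micrometres upstream.
How far the response conducts is summarised by a *length constant*
$\lambda$: the distance over which the response decays to $1/e$ of its
local amplitude. Comparing $\lambda$ between wild-type mice and connexin
knockouts (Cx40, endothelial; Cx45, smooth muscle) asks which coupling
protein carries the conducted signal.

The measured quantity is the inner vessel diameter, sampled every 10 s at
positions spaced 50 µm from the stimulation site, through three 30-s
phases: baseline, electrical stimulation, recovery. `condvaso` implements
the full reduction and inference chain from those diameter time series to
group-level length constants and their comparison.

## The analysis model

For each vessel and position $x$, the response is the *relative
constriction*

$$ y(x) = \frac{\bar D_\text{rest}(x) - \bar D_\text{stim}(x)}
               {\bar D_\text{rest}(x)}, $$

where $\bar D_\text{rest}$ is the mean baseline-phase diameter at that
position and $\bar D_\text{stim}$ the mean of the three samples taken 10,
20 and 30 s after stimulation onset. Positive $y$ is narrowing; dilation
gives negative values. From the first position at which $y \le 0$, the
constriction is set to exactly 0 for that and all more distal positions
(`truncate_profile()`): a conducted *constriction* that has died out stays
dead, and occasional upstream dilations are not allowed to masquerade as
recovery of the signal.

Vessels enter the analysis only if (1) the local response is at least 5%
constriction, (2) the vessel recovers to at least 50% of its baseline
diameter after stimulation, and (3) diameters are measurable at three or
more positions including the stimulation site. Two readings of criterion
(2) are defensible — diameter fraction or constriction-reversal fraction —
and `apply_inclusion_criteria()` implements the literal one: the mean
recovery-phase diameter at the stimulation site must be at least half the
resting diameter there.

All $(x, y)$ measurements of a group's included vessels are then pooled and
the spatial decay model

$$ y = a\, e^{b x} $$

is fitted by unweighted nonlinear least squares over the pooled points
(`decay_fit()`). Because every vessel contributes at short distances but
only long vessels reach 400–500 µm, pooling itself produces the intended
weighting: distances with more measurements influence the fit more. This
is algebraically identical to fitting per-distance means weighted by their
counts — the pooled objective decomposes as
$\sum_d n_d (\bar y_d - a e^{b x_d})^2$ plus a parameter-free constant —
and the test suite verifies both routes agree to $10^{-6}$. Zero-truncated
points stay in the fit; dropping them would bias $b$ upward.

The intercept $a$ estimates the local constriction and $\lambda = -1/b$
(for $b < 0$) is the length constant (`length_constant()`). One printed
source row gives a decay rate and a length constant that are mutually
inconsistent ($-1/b$ of the stated $b$ is 263 µm, not the stated 363 µm);
throughout this package length constants are always *derived from* $b$,
never taken as independent numbers.

Supporting tests are those of the original analysis: a two-sided one-sample
*t*-test of the per-vessel constriction values against 0 at each distance
(`per_distance_tests()`, no multiple-testing correction, $\alpha = 0.05$),
and a one-way ANOVA comparing local constriction between groups
(`compare_local()`; with two groups $F = t^2$ of the pooled-variance
two-sample *t*, an identity the tests check to $10^{-10}$).

### Reporting the extent of significant conduction

"Significant constriction measurable up to $X$ µm" is defined here as the
largest distance such that the test is significant there *and at every
shorter testable distance* (`significance_extent()`). An isolated
significant distance beyond a non-significant one — possible with $n = 1$
or 2 at the far tail — does not extend the range. This is an
interpretation; the alternative (the largest significant distance
anywhere) can only report larger extents.

## Bootstrap comparison of decay rates

A single fit per group gives no sampling distribution for $b$, so the
analysis resamples: each replicate draws $N$ points with replacement from
the group's pooled point set ($N$ = original count), refits the decay
model, and records $(a, b)$; the default is 1,000 replicates
(`bootstrap_fit()`). Percentile intervals use midpoint-interpolated order
statistics (`stats::quantile` type 5), under which the 95% interval of the
samples $1,\dots,100$ is exactly $(3.0, 98.0)$. Replicates whose resample
spans fewer than two distinct distances, or whose fit does not converge,
are discarded and counted in `n_failed` — never silently refitted with
altered settings.

Decay rates are compared between genotypes by a two-tailed *t*-test on the
two sets of bootstrap $b$ samples (`compare_decay_rates()`), in the Welch
(unequal-variance) form since nothing justifies assuming equal variances.
Two caveats are built into the reporting rather than hidden:

* A *t*-test across bootstrap replicates treats each replicate as an
  observation, so its degrees of freedom (~2,000) vastly overstate the
  information in the original ~15–90 points; p-values from it are
  anti-conservative. The percentile interval of the replicate-wise
  difference $b_A - b_B$ is printed alongside as a labelled alternative.
* Resampling pooled points ignores the clustering of points within
  vessels. A vessel-level cluster bootstrap is available as
  `bootstrap_fit(..., unit = "vessel")`, a documented non-default.

## The synthetic-cohort generator

No raw per-vessel recordings are published for this preparation, so
`generate_vessel()`/`generate_cohort()` simulate recordings with the
statistical structure the analysis assumes:

$$ D(x, t) = D_0\,\{1 - c(x)\,g(t)\} + v(t) + \varepsilon(x, t), \qquad
   c(x) = a\,e^{-x/\lambda}, $$

with a mono-exponential temporal gate $g(t)$ (0 at baseline, rising with
time constant $\tau_\text{on}$ during stimulation, relaxing with
$\tau_\text{off}$ during recovery), a vessel-wide AR(1) vasomotion term
$v(t)$ (correlation 0.5 per 10-s step, stationary SD `vasomotion_sd`), and
white measurement noise $\varepsilon$. The traceable length is drawn
uniformly over the multiples of 50 µm in a group-specific range.

Defaults for the four study groups (`default_group_params()`) reproduce
the published group structure: vessel counts 8/7/9/11; generative $(a,
\lambda)$ equal to each group's published fit constants (0.26/263 µm,
0.15/179 µm, 0.23/455 µm, 0.17/222 µm); resting diameter means 28.7, 15.5,
30.6 and 23.6 µm. Published diameter spreads are SEMs, so the
between-vessel SD is recovered as $\mathrm{SEM}\sqrt{n}$, with the draw
truncated below at 5 µm (a physiological floor for a perfused afferent
arteriole). Traceable-length ranges ([100, 400], [100, 250], [200, 500],
[100, 500] µm) were chosen once so the uniform mean matches each group's
published mean length while staying inside the global 100–500 µm span.

Parameters the source does not report are documented **assumptions, not
estimates**: `vasomotion_sd = 0.5` µm and `measurement_noise_sd = 0.5` µm
(sub-pixel edge-tracking precision; modest vasomotion in an isolated
perfused preparation), and kinetics $\tau_\text{on} = 10$ s,
$\tau_\text{off} = 5$ s, which qualitatively reproduce a response
developing largely within 20 s and recovering most of the way within 10 s
of stimulation end.

One consequence worth knowing: with $\tau_\text{on} = 10$ s the 10/20/30-s
measurement window averages $g \approx 0.82$, so the *measured* local
constriction sits about 18% below the generative $a$. The decay rate $b$
and hence $\lambda$ are unaffected (the attenuation is
distance-independent), which is why parameter-recovery checks target
$\lambda$. With $\tau_\text{on} = 0$ the round trip is exact, and the
noiseless end-to-end identity (fitted $(a, \lambda)$ equal to the
generative values to $10^{-6}$) is asserted in the tests.

What the generator does **not** emulate: electrotonic cable physics or any
mechanism (it reproduces statistical shape only), between-vessel
variability in $a$ or $\lambda$ within a group, drift in baseline tone,
and heteroscedastic tracking error at small diameters. Passing tests
therefore demonstrate correctness of the *analysis machinery* under the
assumed data model, not biological validity on real recordings.

### Seeding

All randomness flows from one master seed. Vessel $j$ of group $i$ uses
seed $(\text{master} + 10^5 i + j) \bmod (2^{31}-1)$, so adding a group
never perturbs earlier groups' draws; each group's bootstrap uses
$\text{master} + 1000 + i$. Seeds are logged in `run_log.txt`.

## Numerical choices

* Optimisation: Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
  analytic Jacobian of $a e^{bx}$, `ftol = ptol = 1e-12`, at most 1,000
  iterations; $b$ is unconstrained (a positive $b$ is only rejected when a
  length constant is requested). Non-convergence is flagged in the result,
  never repaired silently.
* Starting values: $a_0$ = mean constriction at the shortest distance;
  $b_0$ from an ordinary linear regression of $\log y$ on $x$ over
  strictly positive $y$ (fallback $-5\times10^{-3}$ µm$^{-1}$ when fewer
  than two positive values span two distances).
* Standard errors: curvature of the least-squares objective,
  $\hat\sigma^2 (J^\top J)^{-1}$ at the optimum. Bootstrap percentile
  intervals are reported separately and labelled; the source does not say
  which its printed intervals are, so both are available.
* Degenerate inputs: a single distance is an error; constant data fit as
  $(a = \bar y, b = 0)$; all-zero data yield $a = 0$ with $b$
  unidentified (the fit is exact and the reported length constant should
  be ignored — `per_distance_tests()` reports such groups untestable).
* SEMs use the $n-1$ sample standard deviation; per-distance summaries
  with $n = 1$ have no SEM, matching points plotted without error bars.

## Simulation sizes used by the checks

The acceptance-grade tests simulate under the default study conditions:
100 cohorts for length-constant recovery (median absolute relative error
below 15% at the default noise), 200 cohorts for bootstrap coverage of the
generative $b$ (85–99% band, wide because pooled-point resampling ignores
vessel clustering) with 400 replicates per cohort, and 50 two-group
studies for WT/KO discrimination with 300 replicates per group. The
replicate counts per cohort are the package's own sizes for these
repeated-simulation studies; single analyses use the 1,000-replicate
default throughout.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  group_params = lapply(c("Cx40 WT", "Cx40 KO", "Cx45 WT", "Cx45 KO"),
                        default_group_params),
  n_bootstrap = 1000, master_seed = 1, output_dir = "report")
report <- run_pipeline(cfg)
print(report)
```

The report contains one decay fit, bootstrap and per-distance test table
per group and one ANOVA + decay-rate comparison per WT/KO pair; CSVs
mirror the printed tables at full precision (the human-readable view
rounds length constants to integers, $a$ to two decimals and $b$ to two
significant figures).

## Known limitations

* The pooled-point bootstrap understates within-vessel correlation; its
  intervals are honest only to the extent points are exchangeable. Use
  `unit = "vessel"` to check sensitivity.
* The *t*-test on bootstrap replicates is reproduced for fidelity to the
  original procedure, with the degrees-of-freedom caveat above.
* Exclusion is all-or-nothing: partial data from excluded vessels are
  never used, which is one reading of an underspecified rule.
* A single exponential is assumed; no bi-exponential or linear
  alternatives are fitted, and no model selection is performed.
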