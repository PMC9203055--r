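---
title: "Models and methods: sub-trial inactivation analysis and intrinsic timescales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`optotower` quantifies how brief, spatially defined optogenetic inactivation
of dorsal cortical areas changes the weight that pulsatile sensory evidence
carries on choice in the accumulating-towers task, and estimates cortical
intrinsic timescales from widefield calcium imaging via an autoregressive
encoding model. Because the package is validated entirely on synthetic data,
this vignette documents both the analysis models and the generative models
that stand in for real sessions, including every numerically consequential
choice.

## The task and the synthetic behavioral generator

In the accumulating-towers task a head-fixed mouse runs down a virtual
T-maze (30 cm start region, 200 cm cue region, 100 cm delay region) and
turns toward the side that showed more transient visual towers. Towers
appear at Poisson-distributed counts per trial — mean 7.7 on the rewarded
and 2.3 on the non-rewarded side over the 2 m cue region, i.e. 5 towers/m
overall — at uniform positions no earlier than y = 10 cm, with a 12 cm
within-side refractory spacing. A tower becomes visible when the mouse is
10 cm away, which defines its event time.

`task_config()` holds these constants. Two generator details deserve note:

* **Rate units.** The per-side rates are interpreted as mean counts per
  trial over the cue region (3.85 and 1.15 per meter), which is the only
  reading consistent with an overall density of 5/m.
* **Refractory sampling.** Rather than literally re-drawing position sets
  until the spacing constraint holds (acceptance probability is ~1e-4 at
  count 10), `draw_tower_positions()` draws order statistics on the
  interval shrunk by `refractory * (n - 1)` and re-inflates. This is
  exactly the uniform distribution conditioned on the spacing constraint,
  at O(n) cost. Counts are clipped to the maximum feasible number.

Running is modeled as one log-normal speed per trial (mean 50 cm/s, CV
0.15 — the data constrain only the mean, so the trial-to-trial dispersion
is a modeling choice), constant within trial except inside the laser
interval, where it increases by 8% (the average laser-induced speed change).
Trajectories are therefore piecewise linear and tower times, laser
onset/offset times, and segment speeds are all available in closed form.

Choices follow a ground-truth logistic rule (`choice_model()`): each tower
contributes its side sign times the mouse's evidence weight, multiplied by
a laser-modulation factor for the laser-aligned window it falls in (1 on
control trials), plus a per-mouse bias; a lapse parameter mixes in random
choices. Population defaults (`base_weight` 0.6, `bias_sd` 0.3, `weight_sd`
0.1, `lapse` 0.02) give aggregate performance in the high 80s percent with
visible individual differences — a deliberately idealized but recognizable
cohort. With all modulation factors at 1, laser trials are distributionally
identical to control trials, which the test suite verifies.

## Behavior metrics

`select_trials()` applies the inclusion rules: warm-up and easy-block
trials are dropped, whole blocks with control performance below 60%
correct are dropped, and trials that failed to reach the maze end or
traveled more than 110% of the nominal maze length are dropped.
`percent_correct()` scores choices against realized tower counts (ties
fall back to the rewarded label). Laser-induced performance changes use a
10,000-iteration trial bootstrap with a one-sided p-value (fraction of
iterations in which the laser-minus-control delta exceeds zero); speed
changes use a two-sided bootstrap (fraction of iterations whose sign
flips). A bootstrap p of exactly 0 is reported at the resolution floor
1/n_boot and flagged.

Psychometric curves bin net evidence (#R − #L) in increments of five
between −15 and 15 (half-open bins; a value on an edge goes to the upper
bin) and fit the four-parameter sigmoid
$p_R = b + a / (1 + e^{-(\Delta-\Delta_0)/\lambda})$
by trial-count-weighted least squares on the binned proportions; a
trial-wise maximum-likelihood variant is exposed but not the default.
Binomial confidence intervals are Clopper–Pearson by default with a
normal-approximation option.

Spatial evidence weighting regresses choice on the net evidence from four
equal segments of 10–200 cm by logistic MLE; coefficient dispersion comes
from 200 bootstrap resamples. Complete separation triggers a flagged,
lightly ridge-regularized fallback. Laser-minus-control curve differences
are signed so that negative values mean weaker evidence weights under
inactivation.

## The laser-aligned mixed-effects model

The core model explains choice from evidence binned in time relative to
the inactivation window. On every trial — using dummy windows on control
trials, defined by when that trial's own trajectory crossed the y
positions of the nearest (by trial index; ties to the earlier) laser
trial's window — towers are assigned to three 0.5 s bins before laser
onset, the whole laser interval, and two 0.5 s bins after offset. Bins are
half-open and closed toward the alignment point; a tower exactly at onset
counts as during. Net evidence per bin is duplicated into a control
partition (nonzero only on control trials) and a laser partition (nonzero
only on laser trials), so laser coefficients are total evidence weights on
laser trials rather than differences; this is what makes the normalized
weight $(E^L - E^C)/E^C$ read 0 for "no effect" and −1 for "complete loss
of influence". Each partition column is z-scored over the trials of its
own arm — z-scoring across all trials would destroy the structural zeros —
and the subtracted means are absorbed by separate control/laser bias
terms. Degenerate (all-zero) columns are dropped and recorded.

Random effects follow the grouping structure of the experiment: a random
intercept per inactivation epoch, and per-mouse random intercepts
(control and laser) plus a random slope for every evidence column.
Variances are independent (diagonal); a full covariance among 14 effects
is not identifiable at the scales analyzed here. Fitting uses
`lme4::glmer` with the `bobyqa` optimizer and `nAGQ = 0`, i.e. the
penalized-likelihood step only: with this many variance components the
full Laplace objective is slow and fragile, while the penalized step is
fast, stable, and — when variance components are truly zero — reduces
exactly to the ordinary logistic MLE (verified against an independent
Newton–Raphson oracle in the tests). `nAGQ = 1` is available.

Ten-fold cross-validation stratifies folds by mouse × laser condition,
predicts held-out choices from the fixed effects plus the training-set
random effects of the trial's mouse and epoch (the same animals appear in
training and test, so using their random effects is coherent), thresholds
P(right) at 0.5 with ties predicted right, and keeps the fit with the
highest held-out accuracy.

Inference on normalized weights combines two conditions: an FDR-corrected
t-test on each coefficient (estimate over delta-method SE, which
propagates the control- and laser-coefficient covariance), and
non-overlap of the estimate ± SE with the mean ± SD band of 30 shuffled
models in which laser labels are permuted within mouse × epoch strata.
The FDR rule is the literal per-rank rule — the i-th smallest p is
significant iff $P_i \le \alpha i / n$ — with the conventional
Benjamini–Hochberg step-up available as an option; the two differ only
when a low rank fails while a higher rank passes, and both are validated
against brute-force oracles. Two fitted models are compared per bin with
the z statistic $|\beta_1-\beta_2| / \sqrt{(\beta_1 SEM_1)^2 +
(\beta_2 SEM_2)^2}$; the even-combination test compares a multi-area
inactivation to the average of the single-area effects with SE
$\sqrt{\sum SE_i^2}/k$.

### What the recovery experiments can and cannot show

The package's validation fits the model to cohorts with known modulation
factors. Two design points matter:

* **Window tiling.** For parameter recovery the inactivation epoch is
  chosen as 75–140 cm, which makes the six laser-aligned windows tile the
  entire cue region at the average speed. With any of the six standard
  epochs, some towers fall outside all windows yet still drive choice;
  that omitted evidence is correlated with the binned evidence through the
  rewarded side and biases the laser-arm coefficients. This is a property
  of the model itself, not of the implementation, and it is why the
  recovery cohorts use the tiling epoch.
* **Information limits.** With 15 mice × 500 trials and at most ~35% laser
  trials, each per-bin normalized weight carries a sampling SE of roughly
  0.12–0.15 — a floor set by the Bernoulli information of ~2,600 laser
  choices spread over six correlated evidence bins, with most trials
  saturated by the 7.7-vs-2.3 tower imbalance. Point recovery at that
  scale is accurate to about ±1 SE per bin, and the test suite asserts
  recovery at bands of that order; tighter claims would require several
  times more inactivation trials, not a different estimator.

The type-I error of the full two-condition rule is checked over 20 null
cohorts (no laser effect; shuffle nulls at 10 iterations for tractability)
and is conservative, as expected from intersecting an FDR rule with a
null-band exclusion.

## Widefield traces, the encoding model, and timescales

### ΔF/F

`compute_dff()` implements the divisive dual-wavelength correction
$\Delta F/F = R_b/R_v - 1$ with $R_x = F_x/F_0$, where each channel's
baseline is the histogram mode (100 bins) of the fluorescence over a
centered 30 s sliding window with single-frame steps. Any artifact
multiplicative in both channels cancels exactly when baseline tracking is
exact; the tests verify ≥10× suppression of an injected slow sinusoidal
hemodynamic artifact on calcium-like sparse signals. Note that the mode is
a baseline estimator: it presumes the modal state of the trace is rest,
which holds for sparse positive transients but not, e.g., for symmetric
oscillations.

### The generator

Sixteen ROIs (seven named areas per hemisphere — V1, mV2, PPC, RSC, mM2,
aM2, M1 — plus one unnamed filler per hemisphere to honor the 16-ROI
coupling count) evolve as a coupled autoregressive system at 10 Hz while
the animal traverses 0 ≤ y ≤ 300 cm. Each ROI's kernel over the past 2 s
decays exponentially with its intrinsic timescale,
$a_i \propto e^{-i\,dt/\tau}$ with gain $\sum_i a_i = 0.7$; homotopic
pairs are coupled at lag 1; right/left towers drive the contralateral
hemisphere through a 0.3 s kernel; innovations are Gaussian. Stationarity
is verified by the spectral radius of the companion matrix before any
simulation. Default timescales are log-spaced from 0.2 s (V1) to 1.2 s
(aM2), expressing the posterior-to-frontal hierarchy.

A single-lag variant (`ar_order = 1`) gives a textbook AR(1) process whose
lag-1 autocorrelation equals its coefficient. It is not the default for a
structural reason: the timescale analysis reads τ from the decay of the
multi-lag regression coefficients, and an AR(1) process concentrates its
entire lag profile in the first coefficient — the joint regression on 20
lags recovers (φ, 0, …, 0), from which no decay constant can be read. A
generator whose lag *profile* carries the timescale is the structure this
analysis assumes; the AR(1) variant remains available for autocorrelation
checks.

### Encoding model and cross-validation

Per ROI, z-scored ΔF/F is modeled as a linear combination of its own
activity at lags 0.1–2 s (20 columns), the zero-lag activity of the 15
other ROIs, and task terms: tower events and cumulative evidence at lags
0–2 s, view angle, its derivative, and speed at lags −0.3 to +0.3 s,
position, and per-trial choice/previous-choice/previous-reward constants.
Rows whose lag window crosses a trial boundary are masked. Ridge
regression (predictors standardized, intercept unpenalized) is fit by
threefold cross-validation over trials, 10 repeats with re-randomized
folds, over a grid of 20 log-spaced penalties in [1e-3, 1e3]; the penalty
is applied per training observation so grid values mean the same thing at
any recording length. Accuracy is the Pearson correlation between
held-out prediction and data over the concatenated test set; the selected
penalty maximizes median accuracy, and median accuracy and coefficients
over the 30 runs are reported. Nested versions (task-only, task +
autoregressive, full) share the exact same partitioning for comparison,
with a repeated-measures ANOVA (ROI × model version) and pairwise paired
t-tests (Holm-corrected — the classical independent-groups post hoc is
inappropriate for repeated measures) on mouse-level averages.

### Timescale extraction

$B + A e^{-x/\tau}$ is fit by Levenberg–Marquardt nonlinear least squares
to the autoregressive coefficients at lags 0.1–2 s, normalized to the
0.1 s coefficient; τ is bounded to [1e-3, 20] s, and the optimizer is
started from several τ values (0.1, 0.3, 1, 3 s) with the best final
residual kept, because the three-parameter exponential has genuine local
minima on noisy profiles. Flat profiles are flagged non-identifiable
rather than fitted. Timescales are averaged over hemispheres and sessions
per mouse, summarized as per-area medians and IQRs, and compared across
areas with a one-way repeated-measures ANOVA.

One deliberate deviation in the timescale path: the cross-validated
accuracy curve is nearly flat over decades of penalty, while shrinkage
rotates the lag profile toward the marginal autocovariance — which decays
on the much slower system timescale τ/(1 − gain) — and inflates τ by
~25%. `estimate_timescales()` therefore resolves the penalty choice with
a one-SE rule toward the *smallest* penalty within one standard error of
the best median accuracy (`lambda_rule = "min_1se"`), trading a
negligible amount of predictive accuracy for a nearly unbiased
coefficient profile. `crossval_ridge()` itself defaults to the plain
arg-max.

Validated at six sessions of ~10,000 samples with per-area medians over
the session × hemisphere fits, ranks are recovered exactly (Spearman ρ = 1
against the generative hierarchy) and the median relative τ error is
under 10%; single-session fits of the slowest areas are markedly noisier
because a 2 s lag window weakly constrains τ > 1 s against the offset B.

## Statistics utilities

`bootstrap_pvalue()`, `fdr_correct()` (both rule variants), `rm_anova()`
(one- and two-factor within-subject, and mixed between × within designs,
via `aov` error strata; balanced complete designs enforced), and
`power_analysis()` are shared across modules. The power analysis
subsamples the cohort at n = 50, 75, …, 1000 inactivation trials (39
values) preserving the control:laser ratio, computes the bootstrap p for
the pooled performance delta, repeats the whole procedure 10 times, and
defines the power n as the first grid point where twice the SEM of p
across repeats falls below 0.05 — a precision criterion, taken literally;
the mean p at that n is reported alongside as a sanity check, since the
precision criterion alone does not require that p itself be small.

## Known limitations

* The synthetic cohort idealizes real behavior: no session-level drift,
  no position-dependent side biases, no trial-history dependence beyond
  the previous-choice/reward flags in the trace generator, and a
  piecewise-constant speed model. Passing recovery tests show the
  estimators are correct under the assumed generative structure, not that
  the structure captures everything in real data.
* Headline real-data quantities (e.g. held-out choice prediction near
  70%, encoding accuracies near 0.95, specific F statistics, power
  n = 250) depend on the deposited behavioral dataset and are not
  reproducible from synthetic cohorts; the pipeline computes all of them,
  and the tests assert the synthetic analogues only directionally or
  within sampling bands.
* Laser power ramp-down, inactivation spread, and all imaging
  preprocessing upstream of ROI traces (motion correction, atlas
  registration, retinotopy) are out of scope.
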