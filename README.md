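# optotower

Analysis of sub-trial optogenetic inactivation in the accumulating-towers
task, and estimation of cortical intrinsic timescales from widefield
calcium imaging — with a synthetic-data generator providing ground truth
so every stage of the pipeline is testable without access to real
recordings.

The package is aimed at systems neuroscientists analyzing pulse-based
evidence-accumulation behavior under temporally specific perturbation, and
at anyone who wants a worked, tested implementation of the statistical
machinery involved: laser-aligned mixed-effects logistic regression,
shuffle nulls with rank-based FDR control, bootstrap inference on
behavioral metrics, ridge-penalized linear encoding models of ROI
fluorescence, and exponential-decay timescale extraction.

## The models at the core

**Choice model.** The probability of a rightward choice is modeled as

    p_R = logistic( b0_C + E_C + b0_L + E_L + R )

where `b0_C`/`b0_L` are control/laser bias terms and `E_X` is a weighted
sum of the net evidence (#R − #L towers) in laser-aligned time bins:
three 0.5 s bins before laser onset, the laser interval itself, and two
0.5 s bins after offset, each with its own coefficient, computed
separately for control trials (using dummy laser windows derived from the
nearest inactivation trial) and laser trials. `R` contains a random
intercept per inactivation epoch and per-mouse random intercepts and
evidence slopes. The laser effect in each bin is summarized as the
normalized weight `(E_L − E_C) / E_C`: 0 means no change, −1 means
complete loss of that bin's influence on the decision. Significance
requires both an FDR-corrected t-test and non-overlap with a
label-shuffle null band.

**Encoding model.** Per-ROI ΔF/F (divisively corrected across two
excitation wavelengths, `R_b/R_v − 1`, with sliding-window-mode
baselines) is modeled as a ridge-penalized linear combination of task
events at 0–2 s lags, the ROI's own activity at lags 0.1–2 s, and the
zero-lag activity of the 15 other ROIs. The decay of the autoregressive
coefficients over lags is fit with `B + A·exp(−x/τ)`; τ is the ROI's
intrinsic timescale, which increases from posterior to frontal cortex.

## Worked example

```r
library(optotower)

# an inactivation epoch whose six laser-aligned windows tile the cue
# region (75-140 cm), so no evidence falls outside the model; the
# generative truth suppresses the during-laser evidence weight to 30%
cfg <- task_config(epochs = c(default_epochs(), list(midcue = c(75, 140))))
coh <- generate_cohort(
  n_mice = 6, trials_per_mouse = 500, laser_frac = 0.15, epochs = "midcue",
  config = cfg,
  gcm = choice_model(base_weight = 1.5, lapse = 0,
                     laser_modulation = c(during = 0.3)), seed = 1
)
coh <- select_trials(coh)
coh <- assign_dummy_laser_windows(coh)

percent_correct(coh)
#> [1] 0.9556667

pd <- performance_delta(coh, n_boot = 2000, seed = 2)
round(c(delta = pd$delta, sd = pd$sd, p = pd$p_value), 4)
#>   delta      sd       p 
#> -0.0228  0.0122  0.0235

des <- build_time_binned_design(coh)
fit <- fit_mixed_logistic(des)
null <- shuffle_null(coh, n_shuffle = 30, seed = 3)
sig <- coefficient_significance(normalized_weights(fit), null)
sig[, c("bin", "value", "se", "p_value", "significant")]
#> # A tibble: 6 x 5
#>   bin      value    se p_value significant
#>   <chr>    <dbl> <dbl>   <dbl> <lgl>      
#> 1 pre3    0.430  0.394 0.275   FALSE      
#> 2 pre2    0.0367 0.304 0.904   FALSE      
#> 3 pre1    0.561  0.424 0.186   FALSE      
#> 4 during -0.442  0.142 0.00189 TRUE       
#> 5 post1  -0.111  0.353 0.754   FALSE      
#> 6 post2  -0.0999 0.379 0.792   FALSE
```

Inactivation costs about 2.3 percentage points of performance (one-sided
bootstrap p = 0.024), and the during-laser bin is the only one passing
the two-condition significance rule (FDR-corrected t-test plus exclusion
from the 30-shuffle null band). Its normalized weight, -0.44 +/- 0.14,
sits within 2 SE of the generative truth of -0.7; per-bin estimates at
this small cohort size carry SEs of 0.1-0.4, which is why the package's
validation uses larger cohorts.

On the imaging side, three synthetic sessions of ~10,000 samples each,
taking the median timescale per area over session x hemisphere fits:

```r
ests <- NULL
for (s in 1:3) {
  traces <- generate_roi_traces(roi_model(), generate_cohort(
    n_mice = 1, trials_per_mouse = 170, n_warmup = 0, seed = 40 + s),
    seed = 50 + s)
  est <- estimate_timescales(traces, c("V1_L", "V1_R", "PPC_L", "PPC_R",
                                       "mM2_L", "mM2_R"),
                             n_repeats = 6, seed = s)
  ests <- dplyr::bind_rows(ests, est)
}
dplyr::summarise(dplyr::group_by(ests, area), tau_hat = median(tau))
#> # A tibble: 3 x 2
#>   area  tau_hat
#>   <chr>   <dbl>
#> 1 PPC     0.342
#> 2 V1      0.197
#> 3 mM2     0.828
```

The recovered timescales track the generative hierarchy (V1 0.20 s,
PPC 0.36 s, mM2 0.89 s). Estimates for the slowest areas are noisy in
single sessions — a 2 s autoregressive lag window only weakly constrains
time constants above 1 s — which is why `timescale_summary()` aggregates
over hemispheres and sessions per mouse.

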