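# tworate

Trial-by-trial analysis of visuomotor adaptation with interleaved test
trials: state-space modelling of reach training, rate-of-change estimation
for implicit measures, and proportional models of hand-localization shift.

## The scientific problem

When cursor feedback of a reach is rotated (here by 30°), participants
gradually deviate their reaches to compensate. Part of that compensation is
implicit — visible as reach aftereffects in no-cursor trials and as shifts
in where people feel their unseen hand to be. This package analyses
paradigms in which every training trial is followed by one test trial
(a no-cursor reach, an active or passive hand-localization judgement, or a
pause), over a schedule of 64 aligned trials, 160 rotated trials, 16
counter-rotated trials and 48 error-clamp trials, so the time course of the
implicit changes can be measured at single-trial resolution and compared
with what state-space models of adaptation predict.

Three model families are implemented:

**Two-rate state-space model.** Behaviour is the sum of a slow and a fast
process, each learning from the previous trial's error e and retaining part
of its state:

    x_s(t+1) = L_s e(t) + R_s x_s(t)
    x_f(t+1) = L_f e(t) + R_f x_f(t)
    x(t) = x_s(t) + x_f(t),   e(t) = p(t) - x(t)

with all four parameters in [0, 1], L_s < L_f and R_s > R_f. On error-clamp
trials e is forced to 0, so the fast process's counter-learning decays while
the slow process survives — producing the spontaneous rebound. A one-rate
comparator (single R, L) is fit the same way and compared by
AIC = n·log(MSE) + 2k and relative likelihood exp((AIC_min − AIC)/2).
Fitting is least squares via a grid search over the constrained box, with
bounded local refinement from the six best grid nodes.

**Exponential decay with asymptote ("rate of change").** Any per-trial
process is summarized by P(t+1) = P(t) + L·(A − P(t)), fit by multi-start
bounded least squares with L in [0, 1] and A in [0, 2·max(data)]. Parameters
are bootstrapped across participants (1000 resamples, percentile 95% CIs),
and the saturation trial is the first trial at which the modelled curve
enters the asymptote's CI.

**Proportional localization model.** Hand-localization shifts are modelled
as a fixed proportion b of the visual–proprioceptive discrepancy experienced
on the previous trial (the perturbation, or the participant's own reach
deviation on clamp trials): a one-parameter step-function fit with closed
form b = Σxy/Σx².

A synthetic-cohort generator (`generate_cohort()`) emulates the full
paradigm — per-participant two-rate parameters, motor noise, localization
betas in [0.20, 0.30] — and stores its generating truth, so the whole
pipeline is testable by parameter recovery without any experimental data.

## Worked example

```r
library(tworate)
sched  <- build_schedule()                      # 288-trial default paradigm
cohort <- generate_cohort(cohort_config(32, "pause", seed = 2026))
y      <- channel_means(cohort$data, "training", 288)

fit <- fit_state_space(y, sched)
fit
#> Two-rate state-space fit (target: total)
#>   Rs = 0.9996, Ls = 0.056, Rf = 0.8357, Lf = 0.2237
#>   MSE 0.5166 deg^2 over 288 trials (k = 4)

compare_models(list(two_rate = fit,
                    one_rate = fit_state_space(y, sched, "one_rate")))
#> Model comparison (AIC, relative likelihood vs best model):
#>     model k     mse    aic relative_likelihood
#>  two_rate 4  0.5166 -182.2           1.000e+00
#>  one_rate 2 31.7777 1000.1          1.791e-257

fit_decay(fit$trajectory$x_slow[first_rotation_window(sched)])
#> Exponential-decay fit: rate of change 2.6% per trial, asymptote 28.78 deg
#>   MSE 0.2441 over 160 trials

extract_trial_sets(y, sched)
#> Trial-set means (deg):
#>   R1        9.6
#>   R1_Late  29.1
#>   R2       -14.8
#>   EC       7.29
```

The fitted parameters recover the generating group means (Rs = 1,
Ls = 0.055, Rf = 0.825, Lf = 0.226) from a 32-participant cohort with 4° of
per-trial motor noise; the two-rate model decisively beats the one-rate
comparator; the slow process changes at ~2.6% per trial; and the trial-set
means show fast early learning (R1), near-complete adaptation (R1_Late),
counter-adaptation (R2) and the error-clamp rebound (EC > 0).

`run_pipeline()` chains the full analysis (outlier removal → baseline
normalization → trial sets → state-space fits and AIC comparison → decay
fits with bootstrap and saturation trials → proportional model) and writes
per-stage CSV/JSON results; `inst/scripts/tworate` exposes the same stages
as a command line (`simulate`, `fit-tworate`, `fit-decay`,
`fit-proportional`, `compare`, `run`).

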