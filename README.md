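# oritune

Orientation tuning of familiar-face identity recognition under picture-plane
inversion and contrast negation.

## The problem

Face-identity recognition draws preferentially on the *horizontal*
orientation content of the face image — the vertical alternation of light
skin and darker features. Inversion (180° rotation) and negation (contrast
polarity reversal) both impair recognition, but are thought to disrupt
partly different information: configural/shape cues versus surface and
pigmentation cues. Comparing the **orientation tuning profiles** of the two
impairments tells us what kind of information the horizontal band carries.

oritune implements that comparison end to end, for psychophysicists and
modellers who want the analysis chain as tested, reproducible code:

* **Stimuli** — wrapped-Gaussian orientation band-pass filters in the
  Fourier domain (centers 0°–150° in 30° steps, σ = 25°), mirror padding,
  exact mean-luminance / RMS-contrast equalization (0.5 / 0.12), contrast
  negation, inversion, soft elliptical apertures, 1/f noise masks, and a
  procedural **synthetic face generator** (no photographs are required or
  shipped).
* **Design** — the blocked same/different schedule: 90 blocks × 14 trials,
  60 trials per stimulus-type × filter condition, 630 distinct stimuli each
  used four times.
* **Observers** — signal-detection simulators with known Gaussian
  orientation tuning per stimulus type, giving every downstream stage a
  ground truth.
* **Scoring** — RT outlier exclusion (mean ± 2.5 sd), log-linear corrected
  d′, grand z-normalization, circular duplication of 0° at 180°, and
  per-subject inversion/negation effect curves.
* **Modelling** — a Bayesian nonlinear mixed-effects model (fit with JAGS)
  of the effect curves,

  d′effect(θ) = Base + Peak · exp(−(θ − Location)² / (2·SD²)),

  with each of the four Gaussian parameters regressed on effect type with
  correlated subject-level intercepts and slopes; equal-tailed 89% credible
  intervals and the non-overlap decision rule; a hierarchical GLMM
  comparing stimulus types; and cross-effect correlations of subject-level
  parameter estimates.

## Worked example

Simulate a 21-subject cohort whose inversion/negation effect tuning equals
the package's default population values, score it, and fit the hierarchical
Gaussian model at a reduced MCMC schedule:

```r
library(oritune)

trials <- simulate_cohort(population_params(), n_subjects = 21, seed = 1)
scores <- score_trials(trials)
fit <- fit_tuning_model(scores$effects,
                        mcmc = mcmc_config(4, 1500, 500, seed = 1))
print(fit)
#> Hierarchical Gaussian tuning model fit
#>   21 subjects, 294 observations, 4 chains x 1500 iterations
#>   converged (all pop. Rhat < 1.01): FALSE
#>
#>           parameter effect_type median  mean cri_lower cri_upper
#>       peak_location   inversion  82.76 82.55     77.33     87.22
#>       peak_location    negation  81.04 80.92     74.50     88.23
#>  standard_deviation   inversion  29.69 30.27     19.90     40.95
#>  standard_deviation    negation  34.78 34.78     27.81     42.23
#>      peak_amplitude   inversion   1.27  1.27      0.98      1.55
#>      peak_amplitude    negation   1.48  1.48      1.16      1.78
#>      base_amplitude   inversion   1.35  1.33      1.10      1.54
#>      base_amplitude    negation   0.53  0.52      0.32      0.70
```

Reading the output: both effects are tuned to the horizontal range (peak
locations in the low/mid 80s of degrees) with comparable width and peak
amplitude — their 89% credible intervals overlap — while the **base
amplitude** CrIs ([1.10, 1.54] vs [0.32, 0.70]) do not overlap: inversion
lowers performance across *all* orientations more than negation does, the
cohort's generative truth (1.20 vs 0.53, on the normalized d′ scale) lying
inside each interval.
The convergence flag is honest about the reduced schedule; the full
schedule is `mcmc_config(4, 6000, 2000)`. Subject-level estimates of the
two effects are strongly correlated parameter-by-parameter:

```r
print(subject_parameter_correlations(fit), digits = 2)
#>            parameter    r p_value ci_lower ci_upper  n
#> 1      peak_location 0.99 1.4e-16    0.968     0.99 21
#> 2 standard_deviation 0.86 4.8e-07    0.687     0.94 21
#> 3     peak_amplitude 0.95 1.8e-11    0.890     0.98 21
#> 4     base_amplitude 0.41 6.8e-02   -0.032     0.71 21
```

See `vignette("orientation-tuning")` for the model, priors, generator
assumptions and numerical choices.

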