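---
title: "Methods: orientation tuning of face-identity recognition under inversion and negation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation tuning of face-identity recognition under inversion and negation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Human face-identity recognition relies preferentially on the horizontal
orientation content of the face image — the vertical alternation of light
skin and darker features (brows, eyes, mouth) that characterizes an upright,
positive-contrast face. Two classic image manipulations disrupt recognition
through partially distinct routes: picture-plane **inversion** (a 180°
rotation, thought to disrupt configural/shape processing) and contrast
**negation** (polarity reversal, thought to disrupt surface and pigmentation
cues). Comparing the *orientation tuning profile* of the two effects asks
whether the horizontal band feeds shape processing, surface processing, or
both.

oritune implements the full analysis chain for this question as testable
code: stimulus construction, trial design, observer simulation with known
ground truth, signal-detection scoring, and Bayesian hierarchical
tuning-curve modelling.

# Stimulus generation

Orientation filtering happens in the Fourier domain. An image is mirror
padded by 100 px (reflection without edge duplication, to suppress border
artefacts), normalized to mean 0 / RMS contrast 1, transformed, and its
spectrum multiplied at every non-DC frequency by a **wrapped Gaussian**
weight

$$w(\theta) \propto \sum_{k=-3}^{3}
  \exp\!\left(-\frac{(\theta - \mu + 180k)^2}{2\sigma^2}\right),$$

evaluated at that frequency's image-plane orientation label
($\theta = \operatorname{atan2}(f_y, f_x) \bmod 180$, so 0° = vertical
structure, 90° = horizontal structure). The filter bank uses centers 0°–150°
in 30° steps with $\sigma = 25°$. Numerical choices worth knowing:

* the wrap sum is truncated at $|k| \le 3$ (truncation error is far below
  machine precision at the $\sigma$ in use) and peak-normalized to 1 at the
  center, making "passes the band fully" well defined;
* the DC term passes unchanged — mean luminance is re-equalized afterwards;
* at even image dimensions the Nyquist bins alias $+f$ and $-f$, leaving
  their orientation label sign-ambiguous; the weight map is symmetrized over
  frequency negation (a no-op at every other bin), which restores exact
  conjugate symmetry and a bit-real inverse transform;
* phase spectra are untouched (the weights are real and non-negative);
* the pad is cropped after the inverse transform, *before* the final
  normalization, so equalization statistics describe the face region only.

Filtered images are renormalized to the set statistics (mean 0.5, RMS
contrast 0.12), clipped to [0, 1] — the pre-clip clipped fraction is
recorded and asserted below 3% per image — and blended with a soft-edged
(6 px cosine ramp) elliptical aperture fitted to the average face. Negation
is reflection about the equalized mean (`1 - x`), applied after equalization
and before the aperture; since the aperture background equals the reflection
point, negating a blended image equals blending a negated one. Inversion is
the reversal of both pixel axes. Both are involutions and commute.

The **synthetic face generator** replaces photographs (no real images ship
with the package; all faces are synthetic and labelled as such). A face is a
bright ellipse on mid-grey carrying dark horizontal bands at brow, eye,
nose-shadow and mouth heights, plus a broad bright-forehead/dark-chin
shading gradient. Identities differ in geometry drawn once per identity;
images of one identity differ only by a small seeded jitter of band
positions and depths. The generator reproduces the statistics that matter
for this analysis — horizontal-band dominance (filtering at 90° retains more
RMS contrast than at 0°), sub-3% clipping, exact equalization — but not the
photographic richness of real faces (texture, hair, illumination,
viewpoint). Passing tests on synthetic stimuli therefore validate the
*pipeline*, not claims about any particular photograph set. 1/f noise masks
are generated by spectral shaping of seeded Gaussian white noise and
equalized to the same statistics.

# Trial design

The design module reproduces the experiment's arithmetic exactly: 90 blocks
of 14 trials (1260 trials); stimulus type (natural / inverted / negated)
blocked, with consecutive triplets containing each type once in random
order; within a block two trials per orientation filter plus two
full-spectrum trials; 60 trials (50% same) per stimulus type × filter cell.
The pair pool holds 30 same pairs (always two *different* images of one
identity) and 30 different pairs built from a random cyclic arrangement of
the 30 images with no same-identity neighbours, so each rendered stimulus is
used exactly four times (twice in same, twice in different trials) — 630
distinct stimuli in total. Pair-to-block assignment beyond these constraints
is uniform without replacement, and trial order is shuffled within blocks.

# Observer simulation

Simulated observers give every downstream stage a known ground truth. Each
subject carries a Gaussian orientation tuning of *raw* d′ for natural
stimuli, and Gaussian-tuned inversion and negation *effect* curves that are
subtracted from the natural curve; full-spectrum sensitivity is a separate
scalar per stimulus type (full-spectrum trials are excluded from tuning
fits). Responses follow equal-variance signal detection: with sensitivity
$d$ and criterion $c$, $P(\text{same}\mid\text{same}) = \Phi(d/2 - c)$ and
$P(\text{same}\mid\text{diff}) = \Phi(-d/2 - c)$. Expected d′ that goes
negative after subtraction is clamped at zero for response generation only —
the analysis pipeline never clamps. Response times are log-normal with a 2%
rate of extreme outliers (mostly slow lapses near the 4400 ms deadline, some
fast anticipations), giving the RT exclusion rule something to find.

Default population values are deliberate choices, made once: the effect
curves use the published population posterior means (inversion 91.52° /
34.06° / 1.11 / 1.20; negation 85.99° / 39.39° / 1.18 / 0.53); the
natural-condition curve (90° / 35° / 1.2 / 1.6 raw d′) was chosen so the
simulated condition means reproduce the observed ordering natural > negated
> inverted with a normalized-d′ spread near 1 (raw d′ is not published) and
so that expected sensitivity stays above chance in every condition, as it
was for the experiment's retained participants — the natural base raises all
three conditions equally, leaving the effect curves untouched;
between-subject sds (8° locations, 5° widths, 0.25 amplitudes) are plausible
for n = 21 psychophysical cohorts, the published random-effect spreads not
being available. The criterion defaults to 0 (d′ is analysed bias-free, so
bias is a nuisance knob, default off).

# Scoring

Per subject, trials with RT outside mean ± 2.5 sd (single pass, not
iterated) are excluded. Hits ("same" response to a same pair) and false
alarms ("same" to a different pair) are aggregated per subject × stimulus
type × filter, and sensitivity computed with the log-linear correction,
$d' = \Phi^{-1}\!\big(\tfrac{h+0.5}{n_s+1}\big) -
\Phi^{-1}\!\big(\tfrac{f+0.5}{n_d+1}\big)$ — +0.5 to the counts *and* +1 to
the totals, the standard form of that correction; a `counts_only` switch is
provided. d′ is z-normalized with a **grand** mean and sd over all subject ×
condition cells: a per-cell normalization would force every condition's mean
to zero and erase the very condition differences being modelled (a
per-subject scope is available as an option). The 0° cells are then
duplicated at 180° (orientation is circular with period 180°; the duplicated
point enters the likelihood twice, exactly as the curves are fit), and
effect curves computed per subject and filter as normd′(natural) −
normd′(inverted or negated).

# The hierarchical Gaussian tuning model

Effect values $y_{js}(\theta)$ for subject $j$, effect type $s$ (inversion /
negation) and filter $\theta \in \{0, 30, \dots, 180\}$ follow

$$y \sim \mathcal{N}\!\left(\beta_{js} + \alpha_{js}
  \exp\!\left(-\frac{(\theta - \mu_{js})^2}{2\tau_{js}^2}\right),
  \sigma\right),$$

with the four Gaussian parameters (peak location $\mu$, standard deviation
$\tau$, peak amplitude $\alpha$, base amplitude $\beta$) each modelled as
population intercept + effect-type slope (treatment coding, inversion as
reference) plus correlated per-subject (intercept, slope) deviations — an
unstructured 2×2 covariance per parameter, independent across the four
parameters. The exponent is negative (a decaying bell); the peak location is
unconstrained real, relying on its normal(90, 20) prior. Priors: intercepts
normal(90, 20), normal(35, 20), normal(1.5, 1), normal(1.5, 1); slopes
normal(0, 20), normal(0, 30), normal(0, 1.5), normal(0, 1.5); random-effect
sds exponential(0.1) (exponential(0.05) for base amplitude); uniform
random-effect correlations; a single residual sd shared across effect types
with an exponential(1) prior (the last two are this package's choices — no
published residual or correlation prior exists).

Sampling uses JAGS (conditional Metropolis/slice samplers). Two
JAGS-specific numerical choices matter:

* **hierarchical centering** — subject-level (intercept, slope) pairs are
  drawn *around* the population pair rather than as zero-mean offsets; the
  offset form leaves a translation ridge between the population mean and the
  subject deviations that conditional samplers traverse extremely slowly
  (we observed Rhat > 7 on base amplitude in the offset form, 1.0x when
  centered);
* the first half of warmup is JAGS adaptation, the second burn-in.

Convergence is reported per population parameter (Rhat, effective sample
size) and a fit with any Rhat > 1.01 is flagged and warned about, never
silently accepted; divergence counts are a gradient-sampler concept and are
reported as NA. Fixed seed + fixed data gives bit-identical summaries.
Comparisons between effect types use equal-tailed 89% quantile credible
intervals and the non-overlap decision rule. The companion GLMM
(normd′ ~ stimulus type + (stimulus type | subject), on d′ averaged over the
six filters) uses cell-means coding with effectively flat normal(0, 100)
fixed-effect priors, half-Student-t(3, 0, 2.5) scale priors and a scaled
inverse-Wishart (df = 4, hence marginally uniform correlations) random-effect
covariance.

Subject-level parameter estimates (posterior means of the centered
subject-level parameters; means rather than full posteriors, for
determinism) feed the cross-effect Pearson correlations, and first-order
partial correlations control for each subject's mean natural-condition
performance via the closed form
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}$ (t-test on $n-3$ df, Fisher interval on
$n-4$); a variable collinear with the control yields a partial correlation
of 0 by convention.

# Problem sizes and reduced schedules

The default `mcmc_config()` (4 chains × 1500 iterations, 500 warmup) is a
reduced schedule adequate for the package's simulation experiments; the
published schedule (4 × 6000, 2000 warmup) remains one argument away. The
recovery experiment simulates 21 subjects × 1260 trials and fits at the
reduced schedule. Simulation-based calibration uses 50 prior-drawn cohorts
of 10 subjects with effect curves generated directly from the model (the
correct generative process for checking the *fitting* procedure) at 2 × 1000
iterations; its expected 89% CrI coverage carries binomial noise, hence the
±7 percentage-point acceptance band.

# Known limitations

* JAGS's conditional samplers are not gradient-based; very sharp posteriors
  (noise-free fixtures) need the centered parameterization and can still
  show Rhat slightly above 1.01 at short schedules — the convergence flag
  makes this visible.
* The synthetic faces validate the pipeline, not photograph-level claims;
  in particular the aperture ellipse is fitted to synthetic head geometry.
* The generative tuning model and the fitted model share the Gaussian
  functional form; recovery experiments therefore test estimation, not the
  adequacy of the Gaussian shape for real data.
* A subject's tuning standard deviation enters the likelihood squared, so
  its sign is not identified; priors keep it positive in practice, and
  prior-drawn calibration cohorts with negative widths are fit as-is.
* Population tuning-width estimates are the least well determined quantity
  at this design size (21 subjects, 60 trials per condition, 7 orientation
  points): the response-generation clamp, the d′ ceiling implicit in
  30-trial hit rates near the horizontal peak, and the wrapped-generative /
  unwrapped-fitted endpoint mismatch each flatten or sharpen the measured
  curves slightly, and single simulated cohorts can return population widths
  a good 10° away from the generative value (cross-checked with direct
  nonlinear least squares on the cohort means). The base-amplitude contrast
  between effect types is far more stable than the width estimates.
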