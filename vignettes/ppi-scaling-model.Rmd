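---
title: "A scaling model of prepulse inhibition of the acoustic startle response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A scaling model of prepulse inhibition of the acoustic startle response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscale)
library(dplyr)
```

## The problem

Prepulse inhibition (PPI) is the reduction of the acoustic startle response
when a weak prepulse sound precedes the startling sound. The traditional
metric compares movement at a single startle level with and without a
prepulse,

$$\mathrm{PPI}_{ratio} = 1 - m_p / m_b,$$

and carries several hidden assumptions: that startle responses are
approximately Gaussian within animals, that the ratio is constant across
startle sound levels, and that it is independent of the animal's baseline
startle. None of these hold in practice — trial-level startle maxima are
closer to log-normal, the ratio systematically drifts with sound level, and
PPI covaries with the baseline curve. `ppiscale` implements a model-based
alternative together with the full validation and group-comparison
machinery around it, and a synthetic-data generator so that every stage of
the pipeline is testable without animal data.

## The model

Each animal's baseline startle curve (no prepulse) is a sigmoid in the
startle sound level $s$ (dB above background) on top of a sound-independent
floor:

$$m(s) = m_0 + N(s), \qquad
  N(s) = \frac{m_{max}}{1 + e^{-r (s - s_0)}},$$

where $m_{max}$ is the saturation (asymptotic maximal log-movement), $r$ the
slope (per dB) and $s_0$ the midpoint. Movement $m$ is measured as the mean
of log10-transformed, z-scored per-trial maxima (see below). A prepulse
condition $c$ — a (prepulse level, delay) pair — modifies this curve through
two bounded scaling parameters:

$$m_c(s) = m_0 + \alpha_c\, N(\beta_c\, s), \qquad
  \alpha_c, \beta_c \in [0, 1].$$

$\alpha_c$ scales the startle axis (how much the animal moves), $\beta_c$
scales the sound axis (how intense the sound is effectively processed).
The model that implicitly underlies the traditional ratio is the nested
variant with $\beta_c \equiv 1$. A closed-form argument shows why the nested
model cannot explain the data: under pure startle scaling with $m_0 \ge 0$
and $0 < \alpha \le 1$,

$$\mathrm{PPI}_{ratio}(s) = \frac{(1-\alpha) N(s)}{m_0 + N(s)}$$

is non-decreasing in $s$ (`theoretical_ppi_ratio()`, property-tested over
randomized parameters), whereas observed ratios decline with sound level.
A sound-axis scaling $\beta < 1$ produces exactly that decline, because the
gap between scaled and unscaled curves is maximal near the midpoint and
closes towards saturation.

Summary features for interpretation are the saturation $m_{max}$ and the
**threshold** — the sound level where the baseline curve reaches 5% of
saturation, $s_0 - \ln(19)/r$ — plus the two scalings, often reported as
percent scaling $100(1-\alpha_c)$ and $100(1-\beta_c)$.

## Preprocessing

Raw accelerometer traces are handled in three steps, matching standard
startle-chamber practice:

1. **Session baseline** (`fit_session_baseline()`): a Gaussian is fit by
   maximum likelihood to the pooled readings from the first 100 ms of every
   trial of an (animal, session) pair — always before the startle stimulus —
   and every reading is z-scored against it (`zscore_normalize()`). This
   removes gain differences between startle systems.
2. **Trial movement** (`extract_trial_movement()`): the maximal z-scored
   deflection in the 100 ms after startle onset, log10-transformed. Trials
   with a non-positive maximum have no defined log movement; they are
   flagged, counted and dropped with a warning rather than imputed, since
   real z-scored maxima are essentially always positive.
3. **Movement summaries** (`summarize_movement()`): per (animal, stimulus)
   mean of the log movements with its standard error (sample SD, $n-1$
   denominator, everywhere in the package), pooling trial repeats across
   sessions of an experiment. Habituation trials are flagged on input and
   excluded. We use the mean of logs (not the log of means) throughout; the
   distribution screen below is the empirical justification.

`distribution_screen()` quantifies the distributional assumption per
(animal, stimulus) cell: Shapiro–Wilk p-values on the raw and log10 scales,
and the difference in maximised log-likelihood between log-normal and
Gaussian fits (positive = log-normal preferred).

## Fitting

All of an animal's summaries are fit jointly — $3 + 2n$ free parameters for
$n$ prepulse conditions — by bounded nonlinear least squares on the stacked
residuals (Levenberg–Marquardt via `minpack.lm::nls.lm` with an analytic
Jacobian), which is equivalent to minimizing the total RMSE across stimuli.
Choices that matter:

* **Floor $m_0$**: estimated as the mean log movement over 0-dB no-prepulse
  stimuli and held fixed during optimization, keeping three free baseline
  parameters. This estimate deliberately absorbs the (tiny) $N(0)$; when no
  0-dB stimuli exist, $m_0 = 0$ with a warning.
* **Initialization**: scalings start at 1 (no scaling); baseline parameters
  start at a sigmoid fit to the no-prepulse summaries alone.
* **Bounds**: $\alpha, \beta \in [0,1]$ (unbounded fits invite compensation
  between parameters and are not implemented), $r \in (0, 2]$, $s_0$ within
  20 dB of the tested range, $m_{max}$ capped at four times the observed
  dynamic range.
* **Restarts**: up to three perturbed restarts on non-convergence; flat
  (unidentifiable) data are flagged rather than fitted silently.

`normalized_error()` scores predictions against held-out summaries in units
of each stimulus's standard error; stimuli with zero SEM carry no scale and
are excluded with a warning rather than given infinite weight.

## Validation machinery

**Cross-validation** (`cross_validate()`): 100 iterations (25 in the
reduced test configurations) of an 80/20 split. The default splits at the
trial level within each stimulus, so every stimulus appears in both the
training summaries and the held-out summaries — the per-stimulus normalized
error requires test-set summaries at every stimulus. A `"stimulus"` unit
that holds out whole stimulus-mean points is exposed as a configuration
switch. Both model variants are fit to the training summaries and scored on
the holdout; a positive error difference (startle-only minus both) means
the two-scaling model generalizes better.

**Parameter swapping** (`swap_parameters()`): every animal's summaries are
scored under every other animal's best-fit parameter set; a large median
error increase over the self-fit error demonstrates that fits are
animal-specific rather than generic.

**Jittered-refit confidence intervals** (`jitter_confidence()`): each refit
perturbs every stimulus mean by a Gaussian draw with SD equal to its SEM
(jitter centred on the observed mean, not the model prediction) and refits;
the 90% interval spans the 5th–95th percentiles over 10,000 refits (1,000
in the reduced calibration runs). Refits warm-start at the point estimate —
the jittered optimum is close to it, and this keeps $10^5$-refit
calibrations tractable without changing the optimum found.

## Group analysis

Per prepulse condition — prepulse-varying and delay-varying condition
families are tagged and never pooled:

* **LDA separability** (`lda_condition()`, `lda_by_condition()`): two-class
  Fisher discriminant on the five standardized parameters
  $(m_{max}, r, s_0, \alpha_c, \beta_c)$. Features are z-scored across
  animals first because the parameters have incommensurate units.
  Significance comes from label-permutation tests on the mean absolute
  distance to the hyperplane and on leave-one-out classification accuracy,
  with the add-one estimator $(1+b)/(1+n_{perm})$ so p is never 0. The
  discriminant core is a lean hand-written pooled-covariance solve
  (validated against `MASS::lda` in the tests) because it runs inside
  $10^3$–$10^4$-iteration permutation loops; a ridge fallback handles
  singular within-group scatter.
* **Multiplicity** (`ratio_multiplicity_test()`): the only multiplicity
  control, asking whether the count of significant conditions exceeds what
  independent chance at $\alpha$ would produce (bootstrapped binomial null,
  cross-checked against the exact binomial tail). The independence null
  ignores dependence between conditions measured on the same animals; this
  is documented, not resolved.
* **Scaling-versus-baseline structure**: PCA on the reduced 4-feature set
  (saturation, threshold, startle scaling, sound scaling) with a
  column-shuffling permutation test for PC1 (`pca_condition()`); Pearson
  correlations of $\alpha$ versus saturation and $\beta$ versus threshold
  with OLS lines (`scaling_baseline_correlation()`); robustness of those
  correlations to startle noise by re-fitting all animals to jittered data
  (`correlation_jitter_robustness()`); and a within-animal compensation
  null (`within_animal_null()`) — correlations across jittered refits of a
  single animal — against which across-animal correlations must exceed the
  75th percentile to be judged real.
* **ANCOVA** (`ancova_scaling()`): because the scalings covary with the
  baseline curve, group effects on $\alpha$ (covariate: saturation) and
  $\beta$ (covariate: threshold) are tested with baseline adjustment.
  Conditions with a group difference in the covariate itself (t-test
  p < 0.05) are excluded — ANCOVA is inappropriate under nonrandom
  covariate differences; a significant group-by-covariate interaction halts
  the stage (no common slope exists to compare); otherwise the additive
  model's group effect is reported.
* **Stimulus dependence** (`scaling_vs_stimulus_slopes()`): per-animal OLS
  slopes of the scalings against prepulse level or delay, with a one-sample
  t-test on the slope distribution.

## The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` generate cohorts with the statistical
structure the analysis assumes. What it emulates, and the defaults chosen
as the package's study conditions:

* **Design**: 13 distinct conditions — prepulse {3, 6, 9, 12, 15, 18} dB at
  100 ms (prepulse-varying family) plus delays {50, 100, 150, 200} ms at
  14 dB and {50, 150, 200} ms at 10 dB (delay-varying families). Real
  experiment series cover both families with overlapping stimuli across
  separate experiments; a single synthetic experiment needs distinct
  stimuli, so this set covers both families without duplicates. The
  baseline condition is paired with startle levels {0, 10, …, 60} dB (the
  0-dB stimulus anchors $m_0$); prepulse conditions with {20, …, 60} dB,
  matching the five-level designs used for ratio diagnostics and keeping
  the session size realistic (72 stimuli). 60 trial repeats per stimulus
  (the median design; 84 is the larger 12-session design), spread over 12
  sessions with 5 flagged habituation trials each.
* **Animal-level structure**: baseline parameters $m_{max} \sim (2, 0.35)$,
  $r \sim (0.25, 0.04)$ per dB, $s_0 \sim (30, 4)$ dB, $m_0 \sim (0.1,
  0.03)$ (means, SDs; floors clamp at physiological minima). Scaling means
  deepen with prepulse level and shorten with delay
  ($\alpha$ drops up to 0.45, $\beta$ up to 0.2 at the strongest
  condition), with animal-level SDs 0.08 / 0.05 and small per-condition
  jitter. A latent 4-d Gaussian couples $\alpha$ to $m_{max}$
  ($\rho = -0.5$) and $\beta$ to $s_0$ ($\rho = -0.65$), emulating the
  observed scaling-versus-baseline correlations; since the threshold also
  inherits independent slope variation, the realized $\beta$–threshold
  correlation is attenuated by roughly 10%. Infeasible correlation
  requests (non-positive-definite latent matrix) are refused.
* **Trial noise**: per-trial log10 movement is Gaussian around the model
  mean with SD $\sigma = 0.15$ — so raw maxima are log-normal, consistent
  with the distributional screening this package performs. $\sigma$ is a
  calibration choice (no published value exists for it), set so that
  log-scale Shapiro–Wilk behaviour is qualitatively right: at 60–84 repeats
  the log-normal/Gaussian likelihood contest resolves in favour of the
  log-normal in the vast majority of cells while log-scale normality is
  rejected at roughly the nominal 5% rate.
* **Raw traces** (`simulate_traces()`): stylized — Gaussian pre-startle
  baseline noise plus a noise-free half-sine startle transient whose peak
  encodes the intended z-scored maximum. They exercise the full
  preprocessing round trip exactly up to baseline-estimation error; they do
  not emulate real accelerometer spectra.

What passing tests on these cohorts do **not** show about real data: the
generator has no habituation drift, no intertrial dependence, no hearing
loss, and its trial noise is exactly log-normal — so recovery and
calibration results certify the pipeline's correctness, not the biology.

## Problem sizes and numerical choices

The test and acceptance configurations use the reduced settings the
protocol itself allows: 25 cross-validation iterations, 1,000 permutations
or jittered refits for calibration runs, 20-animal cohorts for recovery and
model-selection checks, 100 replicate animals for interval-coverage
calibration (single-condition design, 13 stimuli), and 500 null replicates
for type-I calibration with 6 + 6 animals per group. Optimizer tolerances
are `ftol = ptol = 1e-10` with at most 200 iterations; permutation and
bootstrap p-values use the add-one estimator; ties in the permutation
statistic count against rejection. Degenerate inputs (flat curves, zero
SEMs, zero variance features, singular scatter) are flagged or excluded
with warnings rather than silently absorbed.

## Known limitations

* The sound-axis modification is a pure multiplicative scaling; an additive
  sound-axis shift is deliberately out of scope.
* The bootstrapped ratio test assumes independent conditions.
* Trial-order dynamics (habituation) are neither modelled nor simulated.
* The traditional two-way ANOVA on PPI ratios is provided only as a
  convenience via the ratio table; it inherits all the flaws the model is
  designed to avoid.
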