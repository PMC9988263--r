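---
title: "Hybrid reinforcement-learning / drift-diffusion modelling of pain-relief gambling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid reinforcement-learning / drift-diffusion modelling of pain-relief gambling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliefrl)
```

# The experimental setting

`reliefrl` analyses a probabilistic relief-seeking ("wheel of fortune")
task: participants under tonic painful heat stimulation repeatedly choose
between two options; one option wins pain relief (a -3 °C step of the
thermode) with probability 0.75, the other with probability 0.25, and
losses deliver a +1 °C increase. A session has 45 trials in five blocks:
four active *test* trials, four passive *control* trials (same nociceptive
input, no decision), and one *neutral* trial per block. Two trial-wise
pain outcomes are recorded: a visual-analogue intensity rating
(VAS, 0-200) and a behavioral re-adjustment of the stimulation
temperature (°C of within-trial sensitization). Endogenous pain
modulation on a test trial is its outcome measure minus the mean of the
same session's outcome-matched control trials; negative values mean pain
inhibition. Each subject performs the task under three drug conditions
(placebo, levodopa, naltrexone).

The scientific questions the package addresses computationally are
(i) which variant of a hybrid reinforcement-learning / drift-diffusion
model (RL-DDM) best predicts choices and reaction times, (ii) whether the
drug conditions shift the model's parameters, and (iii) whether
trial-wise reward prediction errors extracted from the winning model
predict endogenous pain modulation.

# The model family

## Value learning

Each choice option carries an expected value $Q$, initialized at zero.
After a test trial with signed outcome $R_t \in \{+1, -1\}$ (win/lose),
the chosen option's value is updated with the prediction error
$\delta_t$ and dual learning rates:

$$\delta_t = \rho R_t - Q_{c,t}, \qquad
Q_{c,t+1} = Q_{c,t} + \begin{cases}
\eta^{+}\,\delta_t & \delta_t > 0\\
\eta^{-}\,\delta_t & \delta_t \le 0
\end{cases}$$

$\rho > 0$ is an individual outcome sensitivity; the *static* variants
fix $\rho = 1$. The unchosen option's value is carried forward. Ties
($\delta_t = 0$) take the $\eta^-$ branch; the increment is zero either
way, so this is a documentation convention rather than a behavioral
one. Only test trials update values: passive control and neutral trials
have no choice and no instrumental outcome, and trials without a button
press are excluded at load.

## Choice rule

Choices and reaction times are modelled jointly by a Wiener
first-passage process with boundary separation $\alpha$, relative start
point $\beta$ (0.5 = unbiased), non-decision time $\tau$, and a trial
drift rate $\nu_t$ driven by the decision-time value difference,
either linearly,

$$\nu_t = (Q_{\text{high},t} - Q_{\text{low},t})\,\nu,$$

or through a bounded sigmoid,

$$\nu_t = \frac{2\,\nu_{\max}}{1 + e^{-(Q_{\text{high},t} -
Q_{\text{low},t})\,\nu}} - \nu_{\max},$$

which saturates at $\pm\nu_{\max}$. (The bounded form is the only
reading of the sigmoid consistent with a zero crossing at equal values
and the stated $\pm\nu_{\max}$ limits.) The upper boundary is identified
with choosing the high-contingency option, so $\beta > 0.5$ means an a
priori bias toward it, and $Q_{\text{high}} - Q_{\text{low}}$ is the
natural drift argument. Crossing the two factors gives the four-model
grid: model 1 static/linear, 2 scaled/linear, 3 static/sigmoid,
4 scaled/sigmoid. Models 2 and 4 collapse exactly onto 1 and 3 at
$\rho = 1$ (a tested identity).

Values feed the drift at decision time, i.e. *before* that trial's
update — the standard sequential-sampling convention.

## Wiener density conventions

The likelihood of a (choice, RT) pair is the Wiener first-passage-time
density. Two numerical conventions matter:

* **Diffusion coefficient fixed to 1.** Part of the literature uses
  0.1; all drift rates and boundary separations here are on the
  unit-diffusion scale.
* **Dual series with adaptive truncation.** The density has a
  small-time and a large-time series representation. `wiener_logpdf`
  truncates each adaptively to an absolute tolerance of $10^{-7}$ and
  switches by comparing the required number of terms; the two
  representations agree to better than $10^{-6}$ across the switch
  region (tested), and the joint density over both boundaries
  integrates to 1 within $10^{-4}$ (tested against `integrate`).

The diffusion simulator (`simulate_ddm`) is Euler–Maruyama with a
Brownian-bridge boundary-crossing correction applied at every step: the
probability that the path crossed within a step of length $dt$, given
start and end distances $d, d'$ to a boundary, is $e^{-2 d d'/dt}$. The
correction removes the leading $O(\sqrt{dt})$ first-passage bias of the
plain scheme, so a $10^6$-path simulation at $dt = 10^{-4}$ is an
honest independent oracle for the analytic density at Monte-Carlo
tolerances (the package's acceptance experiments do exactly that
comparison, binning simulated RTs against bin-averaged analytic
densities).

# Hierarchical estimation

## Structure and priors

Each of the eight native parameters
$(\eta^+, \eta^-, \rho, \alpha, \tau, \beta, \nu, \nu_{\max})$ is
sampled on an unconstrained scale and transformed: logistic for
$\eta^\pm$ and $\beta$; exponential for $\rho, \alpha, \nu,
\nu_{\max}$; and for $\tau$ a logistic transform scaled by the
subject-session *minimum observed RT*, which keeps the non-decision
time strictly below every RT it must explain. On the unconstrained
scale, the subject-session value is the non-centered composition

$$u_{s,g} = \mu + \sigma z_s + \mathbb{1}[g \ne \text{ref}]\,
\big(d_g + t_g\, w_{s,g}\big),$$

with $z_s, w_{s,g}$ standardized subject deviates and the $w$ of the
two non-reference conditions sharing an LKJ(1)-prior correlation.
Drug coding is reference coding with placebo (when present) as the
reference; the two non-placebo conditions get separate effect
parameters, which makes `contrast_drug` directly interpretable.

The prior catalog (`prior_catalog()`, asserted by prior-moment tests):
locations $\mu \sim N(0,1)$ for $\eta^\pm$ and $\tau$, $N(0, 0.5)$ for
$\beta$, $N(0.1, 0.1)$ for $\rho$, $N(0, 0.1)$ for $\alpha$,
$N(0.2, 0.2)$ for $\nu$, $N(0.5, 0.2)$ for $\nu_{\max}$; scales
half-normal, $HN(0,1)$ for $\eta^\pm,\tau$ and $HN(0, 0.1)$ otherwise;
drug-effect locations $N(0,1)$ for $\eta^\pm,\tau$, $N(0,0.5)$
otherwise, with all drug-effect scales $HN(0, 0.1)$; standardized
deviates $N(0,1)$. The tight priors on the exponential-family
parameters deliberately regularize the weakly separated
$(\rho, \nu)$ direction of model 4.

## The sampler

No gradient-based probabilistic-programming backend is part of this
package's dependency set, so the posterior is sampled by a
**blockwise adaptive Metropolis-within-Gibbs** kernel written for this
model: every scalar coordinate (group locations, log scales, drug
effects, correlation transforms, and each standardized subject deviate)
gets a Gaussian random-walk proposal whose scale adapts toward an
acceptance rate of 0.44 during warmup (Robbins–Monro steps, frozen
afterwards so the post-warmup chain is a valid Markov chain). Proposals
touching a single subject only re-evaluate that subject's sessions; the
Wiener likelihood itself is compiled. Two fit profiles are provided:
`"desk"` (2 chains × 1500 iterations, 500 warmup — the default used by
every validation experiment below) and `"paper"` (4 chains × 4000,
1000 warmup) for full-scale reanalyses.

Convergence is monitored by split-$\widehat{R}$ on every group-level
quantity, with a warning above 1.01 and failure above 1.1. Random-walk
kernels mix more slowly than Hamiltonian ones; at the desk profile,
group-level $\widehat{R}$ values around 1.03–1.08 are typical and the
parameter-recovery experiment below shows the resulting intervals are
nevertheless well calibrated at the scales we use. Fits are exactly
reproducible given (data, seed).

## What the recovery experiments show

* **Parameter recovery** (15 subjects × 60 test trials, one condition,
  desk profile): 95% credible intervals cover the generating group
  locations for at least 7 of the 8 parameters, across three generator
  seeds. The generating population for this experiment sits inside the
  bulk of the priors — recovery assesses the sampler and the
  likelihood, so the data are simulated from the model. The
  non-decision time is checked on the native seconds scale (population
  mean $\tau$) because the generator references $\tau$ to a fixed
  scale while the inference model references it to each session's
  minimum RT; the unconstrained locations are not comparable between
  the two.
* **Model recovery** (10 subjects × 40 test trials, $k = 4$
  cross-validation, 10 replicates): data simulated from model 4 rank
  model 4 above model 1 in at least 8 of 10 replicates. The generating
  configuration uses a clearly scaled sensitivity ($\rho \approx 1.65$)
  and an engaged drift saturation, because model 4 *nests* model 1 at
  $\rho = 1$ with small drift arguments — simulating near the nesting
  point makes "the generating model" undefined and the ranking a coin
  flip, which we verified empirically.
* **Drug-contrast identifiability.** A simulated drug shift on a
  well-identified parameter (boundary separation, +0.3 unconstrained)
  is recovered with a 95% HDI excluding zero at 10 subjects. A shift
  of +1.0 on $\eta^+$, in contrast, is *detected but not attributed*:
  its posterior mass moves clearly positive, yet part of the effect is
  absorbed by correlated drug effects on the drift scaling, and the
  single-parameter HDI keeps enclosing zero even at 25 subjects × 60
  trials. This is a genuine identifiability property of the model
  family — learning-rate increases and drift-scaling increases mimic
  each other's likelihood signature at these trial counts — and it
  matches the broader experience that pharmacological effects on
  individual RL-DDM parameters are hard to resolve at typical
  behavioral-session sizes. Users should read `contrast_drug` output on
  learning-rate parameters accordingly.

# Model comparison

Predictive accuracy is scored by $k$-fold cross-validated ELPD with
*subjects* as the unit of exchange ($k = 10$ at 28 subjects gives folds
of 2–3). Held-out subjects have no subject-level posterior; by default
their predictive density marginalizes over a **new subject** drawn from
the group-level distribution of each retained posterior draw
(`method = "new_subject"`); a plug-in alternative (group means only) is
available for sensitivity analysis, and neither is claimed to be the
uniquely correct construction for unseen subjects. The standard error
of an ELPD difference comes from the pointwise difference vector, and a
difference is called decisive when it is at least twice its standard
error.

# Posterior predictive checks and prediction errors

`posterior_predict_choice` replays every fitted subject-session with
parameters drawn from the posterior on fresh schedules and computes the
proportion of high-contingency choices in the last two blocks — the
phase where learning should be expressed. The posterior predictive
p-value is reported one-sided (fraction of replicates at or above the
observed statistic) together with the two-sided $2\min(p, 1-p)$, since
sidedness is a reporting convention.

`extract_pe` plugs the posterior-*mean* subject-session parameters into
the exact Q recursion over each session's realized choices and
outcomes. Prediction errors are extracted per drug condition with
condition-specific subject parameters (the parameterization is
subject × condition, so this is the coherent choice). For the scaled
variants, wins always carry positive and losses negative prediction
errors because $|Q| < \rho$ is an invariant of the recursion.

# Linking prediction errors to pain modulation

`compute_modulation` subtracts, per test trial, the mean of the same
subject-session's control trials with the matching outcome, pooling all
blocks of the session (the differencing is session-level by design);
trials without a matching control outcome are flagged, never
zero-filled. `fit_pe_model` then fits

`modulation ~ pe * drug + (1 | subject) + (1 | subject:drug:outcome)`

by REML (`lme4`), with large-sample Wald intervals (a documented
simplification relative to small-sample degrees-of-freedom
corrections). The second random intercept is a deliberate addition: all
test trials of a subject-session-outcome cell share the *same*
subtracted control mean, so their residuals are correlated by
construction, and because prediction errors are sign-aligned with
outcome, ignoring the cluster makes the PE-slope standard error
anti-conservative. The PE-slope recovery check in the validation suite
runs against this corrected specification.
`cluster_controls = FALSE` reproduces the plain
subject-random-intercept specification. Session order is available as
an optional fixed covariate (`include_order`), defaulting to off in the
PE model.

`choice_preference` reports the per-subject proportion of
high-contingency choices in the last two blocks with a group summary
per condition and a mixed-effects logistic intercept test against
chance (falling back to an exact binomial test when the mixed model
cannot be fit).

# The synthetic cohort

`generate_cohort` is the package's study simulator and the ground truth
for every validation experiment. What it emulates:

* the 28 subjects × 3 conditions × 45 trials design with the 4/4/1
  block structure, pseudorandomized by a seeded within-block shuffle
  (the original fixed sequence is not public, so schedules are
  constrained-random rather than a reproduction);
* choices and RTs from the RL-DDM agent itself (default: model 4), so
  fitted models are confronted with data from their own generative
  class;
* control-trial outcomes matched post hoc to the session's realized
  test outcomes (a shuffled copy), as in the task design;
* pain outcomes linearly coupled to the trial prediction error,
  `modulation = slope × PE + drug offset + noise`, with default slopes
  −0.36 (VAS) and −0.06 (°C), noise SDs 21.51 and 0.64 taken from the
  reported dispersion of the modulation measures, and the modulation
  embedded in absolute VAS ratings around a per-subject baseline near
  the calibrated tonic target (VAS 150) so that the
  test-minus-control-mean differencing recovers it;
* optional missed responses (`miss_rate`, default 0, matching the
  analysis rule that such trials are excluded).

The default generating population was calibrated once so the *emergent*
placebo behavior matches the study's group signature — a late-block
preference near 64% with wide between-subject spread and sub-second
median RTs (both recomputed by the acceptance script) — and drug shifts
default to zero, reflecting that no parameter-level drug effect was
resolvable in this design. With the default noise
levels the VAS PE slope is recovered within its (wide) confidence
interval at full cohort scale; the behavioral slope, with its much
smaller noise-to-slope ratio, is recovered tightly. What the generator
does **not** emulate: the outcome-conditional mean split of the
modulation measures (which in real data reflects controllability
effects outside the PE pathway), thermode temperature dynamics,
staircase calibration, habituation drift across blocks, and
questionnaire phenotypes. Tests passing on synthetic cohorts therefore
validate the estimation and comparison machinery, not the physiological
claims.

# Numerical and design choices in brief

* Diffusion coefficient 1; upper boundary ≡ high-contingency option.
* Density truncation tolerance $10^{-7}$; normalization verified to
  $10^{-4}$; series-switch continuity to $10^{-6}$.
* Simulator step `dt = 1e-3` by default (bridge-corrected; `1e-4` in
  oracle comparisons).
* Sampler: adaptive scalar random-walk Metropolis-within-Gibbs on the
  non-centered parameterization; 0.44 target acceptance; adaptation
  frozen after warmup; split-$\widehat{R}$ thresholds 1.01/1.1.
* Desk-scale problem sizes: 15 × 60 (parameter recovery), 10 × 40
  × 10 replicates (model recovery), 28 × 3 × 45 (PE-slope and
  behavioral summaries); chosen as the smallest designs at which each
  property is identifiable.
* Degenerate inputs: empty trial tables, missing control outcomes,
  subjects absent from fits, mismatched fold sets, and non-positive
  RTs all raise informative errors rather than silently proceeding.

# Limitations

Across-trial variability parameters of the full diffusion model
(`sv`, `st`, `sz`) are out of scope, as are eligibility traces,
choice-kernel terms, and value forgetting. The random-walk sampler
trades efficiency for dependency-freeness: at paper-scale data sizes
expect long runtimes and prefer the `"paper"` profile with patience.
Single-parameter attribution of drug effects on learning rates is
weakly identified (see above); joint read-outs across parameters are
more trustworthy than any single contrast.
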