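---
title: "The GLAMPI model: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GLAMPI model: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the model

In an immersive-VR triangle completion task a participant walks two guided
legs ($l_1$, then a turn $\theta_2$, then $l_2$) and must return, unaided,
to the start. Path integration quality is read out from the unguided
return: the produced inbound distance $l_3$ and egocentric turn
$\theta_3$. The generative linear-angular model of path integration
(GLAMPI) explains these two numbers per trial as the output of three
error-prone stages.

**Encoding.** Walked distance is accumulated by a leaky integrator of
walking speed, $dl'/dt = -\beta\, l' + k\, v(t)$, with speed gain $k$ and
leak rate $\beta$ (1/s; $\beta < 0$ is growth). With speed constant within
a trial this integrates in closed form to
$$l_2' = l_2\,k\,\frac{1 - e^{-\beta T_2}}{\beta T_2},\qquad
  l_1' = l_1\,k\,\frac{1 - e^{-\beta T_1}}{\beta T_1}\,e^{-\beta T_2},$$
where $T_1, T_2$ are the leg durations; the extra factor on the first leg
reflects that its memory keeps leaking while the second leg is walked, so
the leak is an error of *calculation* (it persists until the return path
is computed). The $\beta \to 0$ limit is evaluated analytically
(`encode_distances()` is continuous at $\beta = 0$, where it reduces to
$k\,l$); a numerical-integration oracle in the test suite confirms the
closed form to machine-level relative accuracy, including the equivalence
with the distance-domain integrator used in desktop-VR work when
$\alpha = \beta / v$. The outbound turn is encoded as a pure gain,
$\theta_2' = g_2 \theta_2$.

**Calculation.** The intended return is the vector closing the encoded
outbound path: distance
$h = \sqrt{(l_1' + l_2'\cos\theta_2')^2 + (l_2'\sin\theta_2')^2}$ and the
egocentric turn $\alpha$ from the final heading onto $-\,(l_1' +
l_2'\cos\theta_2',\; l_2'\sin\theta_2')$.

**Production.** Produced values regress toward the session means of the
*correct* inbound distance and angle for that participant and condition
($\bar l_r$, $\bar\theta_r$):
$l_3' = m_3 h + (1 - m_3)\bar l_r$ and
$\theta_3' = g_3 \alpha + (1 - g_3)\bar\theta_r$. Observed responses are
Gaussian around the produced values with SDs $\sigma$ (m) and $\nu$
(rad). A complete trial contributes
$(l_3 - l_3')^2/2\sigma^2 + (\theta_3 - \theta_3')^2/2\nu^2 +
\log\sigma + \log\nu + \log 2\pi$ to the negative log-likelihood;
out-of-bound trials contribute the angular terms only.

## Two numerical decisions in the likelihood

*The NLL normalisation.* The literature shows the per-trial NLL with
squared residuals divided by $2\sigma$ and $2\nu$; the generative
densities it is derived from use $2\sigma^2$ and $2\nu^2$. This package
uses the Gaussian-consistent $2\sigma^2, 2\nu^2$ form throughout, so the
NLL is exactly $-\log$ of the joint density — the generative definition is
taken as authoritative, and the test suite asserts equality with
`dnorm(log = TRUE)` sums to $10^{-10}$.

*The inbound-angle form.* A closed form for the intended turn,
$\alpha = \pi - \arcsin(l_1' \sin\theta_2' / h)$, is exact whenever the
encoded triangle's angle at the release vertex is acute, and also for
encoded turns beyond $\pi$, but returns the reflected angle
$\pi - \gamma$ instead of $\gamma$ when that vertex angle is obtuse. With
the cone-placement geometry of this task about a fifth of trials fall in
the obtuse regime, and fitting with the arcsin form against responses
generated by the true geometry inflated $\hat\nu$ by a factor of more
than two in our measurements. `calculate_inbound()` therefore defaults to
the exact `atan2` (vector-addition) form in both the generator and the
likelihood; the arcsin form remains available (`method = "asin"`), and
every prediction carries a `flagged` column marking trials where the two
disagree by more than $10^{-9}$. Only the geometric form makes the
closure property — optimal parameters and zero noise return exactly to
cone 1 — a theorem, which the acceptance suite verifies to $10^{-9}$ m.

## Fitting

Each participant-condition cell (at least 7 usable trials, the parameter
count) is fitted by maximum likelihood with seeded multi-start bounded
optimisation (`nlminb` with an analytic gradient). The noise SDs are
*profiled out in closed form*: given the structural parameters, the
optimal $\sigma, \nu$ are the root-mean-square residuals (clamped to
$(10^{-4}, 3]$ m and $(10^{-4}, \pi]$ rad), which is the identical
constrained optimum evaluated on a search space of at most five
dimensions instead of seven. By the envelope theorem the gradient of the
concentrated objective is the partial gradient at the profiled noise
values, which is what the compiled gradient implements. The default 20
starts are the no-error point plus a Latin-hypercube sample of the box
$k, g_2 \in (0, 3]$, $\beta \in [-0.5, 1]$, $m_3, g_3 \in [-1, 2]$.
Reported $\sigma, \nu$ are on their natural scales. AIC is
$2\,n_\mathrm{free} + 2\,\mathrm{NLL}$ with $\sigma$ and $\nu$ counted as
free (they are estimated); BIC uses $\log n_\mathrm{trials}$. The
candidate lattice frees every subset of $\{k, g_2, \beta, m_3, g_3\}$
($2^5 = 32$ models); ties in mean AIC go to the smaller model.

# The synthetic cohort generator

The generator emulates the study conditions so the whole pipeline runs
without any clinical download: square tracking areas (3.5 m young, 4.5 m
elderly, 4.0 m MCI), pseudo-random triangles with cone 1 near the corner
farthest from the previous trial's goal and cones 2–3 near the two
opposite sides (uniform within 25% of the arena side — the placement
tolerance is not published, so a single value was chosen that reproduces
non-degenerate leg/turn distributions), a minimum cone 2–cone 3
separation of 1 m enforced by rejection, constant within-trial walking
speed that varies lognormally across trials, 10 Hz tracking with
orientation quaternions, and inbound truncation 0.3 m past the arena
boundary (the point where the in-task warning stops the participant),
after which the trial keeps its angle but loses its distance.

Per-participant parameters are truncated-normal draws around group
presets. The presets encode the directions the clinical literature
reports — healthy elderly with mild angular over-encoding ($g_2 = 1.1$),
angular regression to the mean ($g_3 = 0.8$), near-zero leak and
veridical distance production; MCI groups with larger $g_2$ and $\nu$,
most pronounced with positive biomarkers ($g_2 = 1.45$ vs $1.15$ for
MCI+/MCI−) — with SDs of 0.08–0.18 chosen once as plausible
between-participant spread. The fitted parameter values behind those
directions are not published numerically, so the presets are this
package's own study conditions, fixed in `glampi_presets()`. Under the
elderly preset the generator yields ~28% retained out-of-bound trials,
close to the published elderly share, but it produces somewhat stronger
under-walking than the real elderly data because the preset leak
$\beta = 0.05$ acts on ~6 s legs. Session means for the
regression-to-the-mean stage are computed from the laid-out triangles of
the same condition before responses are drawn, so the generated process
and the fitted model agree about $\bar l_r, \bar\theta_r$.

What the generator does *not* emulate: curved or hesitant walking (legs
are straight, speed exactly constant within trial), instruction
violations such as retracing (the preprocessing rule for them exists but
never fires on synthetic data), tracking dropouts, learning or fatigue
across trials, and condition effects (the same parameters generate all
three inbound conditions). Passing tests therefore demonstrate internal
consistency of the pipeline under the model's own assumptions, not
fidelity to every property of real head-tracking data.

# Preprocessing rules

Trials are standardised by moving cone 1 to the origin, rotating the
first leg onto $+x$, and mirroring right-turn trials so every turn is a
left (anticlockwise) turn; $\theta_2 \in (0, \pi]$ and all inbound turns
are wrapped to $[0, 2\pi)$ under the convention that the intended
response uses the short anticlockwise turn. Exclusions: out-of-bound
trials without a recorded boundary point (tracking fault), inbound paths
terminating within 0.5 m of cone 3 (no clear movement intention,
measured as straight-line distance since that is what the metrics use),
and — when tracking data are supplied — inbound trajectories re-entering
within 0.3 m of cone 2, a configurable proxy for the study's manual
screening of outbound retracing. Cells with fewer than 7 usable trials
are dropped entirely. Speed reconstruction uses the stated exponential
moving average ($\alpha = 0.9$, initialised at the first finite
instantaneous speed to avoid start-up bias), a Gaussian kernel whose
unspecified "1 s width" is interpreted as $\mathrm{SD} = 1$ s truncated
at $\pm 3$ SD with reflected edges, a 0.2 m/s stationary threshold, and a
1 s burn-in excluded from the mean.

# The replication experiments and their sizes

Three experiment drivers reproduce the study's methodological claims at
sizes chosen to complete on a single CPU within minutes; the acceptance
script recomputes all of them from scratch.

**Parameter recovery** (`parameter_recovery()`): 100 elderly-like
participants, 9 trials per condition, fitted per cell. The structural
parameters $k, g_2, g_3, m_3$ recover with median bias well under 10% of
their generating means. The noise SDs do not: with 9 trials per cell and
roughly 28% of distance observations lost to out-of-bound truncation,
the maximum-likelihood $\hat\sigma$ carries the classic downward
small-sample bias (measured around −40%, with $\hat\nu$ and $\hat\beta$
around −12%). Rerunning the identical pipeline at 90 trials per
condition brings every parameter within 5%, confirming a small-sample
property of the estimator itself rather than an implementation defect.
Since the estimator is deliberately the study's own (plain ML), no
bias correction is applied; users comparing noise SDs across groups
should compare like-for-like trial counts.

**Group detection** (`group_detection_experiment()`): 20 seeded
replicates of MCI+-like ($n = 11$) versus MCI−-like ($n = 14$) cohorts,
group × condition ANOVA on the fitted $g_2$ and $\nu$ (type-III sums of
squares with sum-to-zero contrasts, observation unit the
participant-condition cell, matching the published degrees of freedom;
Bonferroni post hocs cover the pairwise group contrasts within one
measure). Under the chosen presets $\nu$ reaches 80% detection; $g_2$
detects in about half the replicates at these small clinical sample
sizes — its 0.30 group difference competes with 0.18 between-participant
spread plus heavy-tailed 9-trial estimation noise.

**Model selection** (`model_selection_experiment()`): 40 participants,
27 trials each (conditions pooled, with session means computed over the
pooled trials in both generation and fitting), all 32 candidates fitted
per participant. The generating configuration for the full-model arm
deliberately activates every error source ($k = 0.8$, $g_2 = 1.3$,
$\beta = 0.2$, $g_3 = 0.6$, $m_3 = 0.7$, $\sigma = 0.25$,
$\nu = 0.35$): with elderly-like truth, where $\beta \approx 0$ and
$m_3 \approx 1$, the reduced model lacking those parameters *is* the
true model and no sane criterion should prefer the full one, so
demonstrating that AIC recovers the full model requires truth in which
all parameters matter. Under that truth the full model attains the
lowest mean AIC of all 32; under noise-only truth the noise-only model
sits within a few AIC units of the minimum, as the expected
overfitting-penalty bound implies.

# Classification

Single features (a fitted parameter or a behavioural error) are
classified with a linear-kernel SVM under 1000 stratified 60/40
hold-outs (stratification is this package's choice: with ~9–11
participants in the minority class, unstratified splits frequently lose
a class), regularisation constant 1.0. Posterior scores come from a
sigmoid calibration fitted on the training fold; for a single-feature
linear SVM the ROC is invariant to that calibration, so it affects only
the averaged posteriors. Mean ROC curves are averaged on a fixed grid of
101 false-positive rates; AUCs are computed per repetition (by the
midrank Mann–Whitney statistic) before averaging. DeLong's test for
correlated AUCs is implemented from its structural components so that
the degenerate case (identical scores: $z = 0$, $p = 1$) and the
variance terms are explicit; it is cross-checked in the tests against an
independent reference implementation and a 10,000-resample bootstrap of
the AUC-difference variance.

# Known limitations

* Angular residuals are linear-Gaussian, not circular: $\theta_3 -
  \theta_3'$ is not re-wrapped, exactly as the model's equations imply.
  Draws that cross the $0/2\pi$ seam (relevant only when $\nu$ is large
  and the produced turn is near the seam) are mis-scored by $2\pi$.
* The noise SDs inherit small-sample ML bias at clinical trial counts
  (quantified above).
* Condition cells are fitted independently; no partial pooling. A
  hierarchical estimator would be better-behaved at 9 trials per cell
  but would not be the study's estimator.
* The generator's previous-trial endpoint used for cone placement is the
  previous goal (cone 1), not the simulated response, to keep the layout
  sequence independent of the response draws.
* Proportional angular error is a ratio to a sometimes-small correct
  angle; its group means are right-skewed under large $\nu$. The metric
  follows the published definition; medians are more robust summaries
  when $\nu$ is large.
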