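---
title: "Modelling affect-modulated inequality aversion in the iterative Ultimatum Game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling affect-modulated inequality aversion in the iterative Ultimatum Game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectug)
```

## The task and its simulator

affectug models responder behaviour in an iterative Ultimatum Game in
which the proposer is an adaptive algorithm. On every trial the
participant sees the proposer's facial expression (one of 9 levels with
true valence $\varphi \in \{0.1, \dots, 0.9\}$), then an offer $R_S$
splitting a 1000-pence pot on a 19-level grid (50–950 in steps of 50; the
proposer keeps $R_O = 1000 - R_S$), and accepts or rejects. Acceptance
pays the split as proposed; rejection pays nothing to either side. After
the decision the proposer displays a reaction face, which becomes the
face opening the next trial. The joint stimulus space has
$9 \times 19 = 171$ states.

The proposer revises both streams by single steps on their grids, with
move probabilities conditioned on the response ("sliding windows"). The
default tables encode the qualitative strategy of the task — after an
accept the face tends to step positive and the offer down (probing the
threshold from above); after a reject the face tends negative and the
offer up:

| response | stream | step $-1$ | stay | step $+1$ |
|---|---|---|---|---|
| accept | face  | 0.10 | 0.30 | 0.60 |
| accept | offer | 0.50 | 0.35 | 0.15 |
| reject | face  | 0.60 | 0.30 | 0.10 |
| reject | offer | 0.15 | 0.35 | 0.50 |

At the grid boundary, out-of-range move mass is dropped and the row
renormalised (clamp-and-renormalise), which preserves the relative
stay/step odds; the alternative (reflecting the mass) would double the
inward pressure at the extremes. Sessions run 6 blocks of 40 trials;
each block restarts independently at the neutral face and the 500/500
split, and no state carries across blocks. At the end of a session 20
trials are drawn uniformly without replacement — irrespective of the
choices made — and paid out. One session-level seed makes a session
byte-identical across runs.

```{r session}
s <- run_session(policy_threshold(400), seed = 1)
dplyr::glimpse(s[1:3, ])
```

## Perception models

Ratings of the 9 faces (6 repetitions, 54 ratings on a 1–9 Likert scale)
are modelled with the Prelec two-parameter weighting function

$$\varepsilon = e^{-\delta(-\ln \varphi)^{\gamma}},$$

fit by least squares after dividing ratings by 10 so ratings and
predictions share the $(0,1)$ scale. $\delta = \gamma = 1$ is the
identity; the two parameters jointly set the curvature and the point
where perception crosses the diagonal. The fit minimises over
$\delta, \gamma \in (0.01, 5]$ from a $5\times5$ log-spaced start
lattice (best-of-starts), so it is reproducible without a seed. All 54
ratings are fit jointly rather than per-valence means — the repetition
noise is part of the error structure — with averaging available as an
option. The group-level crossover constant $\mu = 0.4$ is a fixed module
constant and is not re-estimated per participant; each participant's own
fitted $(\delta, \gamma)$ supplies their trial-wise perceived valence
$\varepsilon$.

Liking ratings for 100 offers are modelled by ordinary least squares as

$$\chi = \phi_0 + \phi_1 R_S + \phi_2 |R_S - R_O|.$$

$R_O$ never enters separately: with a fixed pot, the self-reward and the
inequality magnitude carry all monetary information. Inequality-averse
raters produce $\phi_2 < 0$.

## The decision-model family

Eleven candidate value functions map a trial to a decision value
$\tilde v$, converted to an acceptance probability by the softmax
$q_A = 1/(1 + e^{-\beta \tilde v})$ with inverse temperature
$\beta > 0$. Rewards are rescaled from pence to pounds (÷100) inside the
fitting layer so that one $\beta$ grid serves every model; the liking
model (3) is the exception — its value is the predicted Likert liking
from the rating-task coefficients, already on a well-conditioned scale.

1. CES: $\tilde v = (\alpha R_S^{\rho} + (1-\alpha)|R_S-R_O|^{\rho})^{1/\rho}$
2. fairness threshold: $\tilde v = \lambda - |R_S - R_O|$
3. liking-based: $\tilde v = \chi$
4. inequality aversion: $\tilde v = \kappa R_S - \omega|R_S-R_O|$
5.–7. exponential emotion modulation
   $\tilde v = \kappa^{(\varepsilon-\mu)} R_S - \omega^{(\varepsilon-\mu)}|R_S-R_O|$,
   acting on the self term, the inequality term, or both (the unmodulated
   term keeps a free linear weight)
8.–10. parabolic emotion modulation
   $\tilde v = (\kappa + (\varepsilon-\mu)^2) R_S + (\omega + (\varepsilon-\mu)^2)|R_S-R_O|$,
   acting on the self term, both terms, or the inequality term only
11. weighted integration: $\tilde v = w\,\tilde v_{\mathrm{base}} + (1-w)(\varepsilon-\mu)$,
   with $\tilde v_{\mathrm{base}}$ the inequality-aversion value at the
   participant's stage-1 fitted weights

In the parabolic family the inequality term enters with a plus sign and
$\omega$ is allowed to be negative ($[-10, 10]$): a negative base weight
expresses aversion, and faces further from neutral in either direction
relax it symmetrically — at $\varepsilon = \mu$ the parabola vanishes
and model 10 reduces exactly to the linear inequality-aversion model
with the sign of $\omega$ flipped. Weights that are exponentiated
(models 5–7) start at 0.01 because $0^x$ is undefined for negative
exponents. A single inequality parameter is used throughout; no
advantageous/disadvantageous split. Predicted choice is accept iff
$q_A \ge 0.5$, with the tie resolved toward accept.

## Grid Bayesian fitting and model selection

Each model is fit per participant by exhaustive grid Bayes: the
Bernoulli choice log-likelihood is evaluated at every node of the
Cartesian parameter grid (41 linear points per parameter within the
registry bounds; $\beta$ on 41 log-spaced points in $[0.01, 20]$), the
joint posterior is formed under a uniform node prior, and point
estimates are the posterior means — node values integrated against the
posterior, not the MAP. Acceptance probabilities are floored at
$10^{-10}$ on both sides so grid extremes stay finite. BIC is
$k \ln n - 2 \ln \hat L$ with $\hat L$ the grid maximum and $k$ the
free-parameter count including $\beta$. For the weighted-integration
model, $k$ also counts the two stage-1 weights it inherits: those were
estimated from the same choice data, and omitting them would let the
model free-ride on the inequality-aversion fit and win BIC comparisons
spuriously. The liking model's coefficients come from the independent
rating task and are not counted. Predictive accuracy is in-sample, at
the posterior-mean parameters, under the $q_A \ge 0.5$ rule.

Group-level selection combines (a) the summed-BIC ranking and (b)
random-effects Bayesian model selection, using $-\mathrm{BIC}/2$ as the
per-participant log model evidence in the standard variational Dirichlet
scheme; exceedance probabilities are the posterior probability that each
model is the most frequent in the population, computed by Dirichlet
sampling.

### Identifiability under the default study conditions

The `generate_recover()` simulation (closed-loop sessions regenerated
through the task engine with the model as the stochastic responder, then
refit) documents an intrinsic limit of the design rather than a property
of the estimator. In the value of model 10, $\beta$ multiplies every
term, so $(\beta\kappa)$ and $(\beta\omega)$ are strongly identified
while $\beta$ itself is separated only through the emotion-modulation
regressor $(\varepsilon-\mu)^2 |R_S-R_O|$ — a small-variance quantity
(its factor never exceeds 0.25 and is typically an order of magnitude
smaller). With 240 trials and the default truth sampler
($\kappa \sim U[0.5,2]$, $\omega \sim U[-4,-1]$, $\beta = 2 \pm 20\%$),
even a continuous maximum-likelihood estimator started at the true
values recovers $\beta$ with error several times the sampled truth
spread, and the noise propagates into $\kappa$ and $\omega$ through the
ratio. Recovery correlations for $\kappa$ and $\omega$ land near 0.8;
for $\beta$ they remain far lower regardless of grid resolution. The
same small-variance term limits the per-participant evidence separating
model 10 from its neighbours, which is why exceedance probabilities in
model-recovery simulations are far less decisive than the summed-BIC
ranking. Wider truth spreads or longer sessions would lift both; the
defaults are kept at the study's own conditions.

Two further structural facts shape model comparison within this family.
First, the grid maximum of the log-likelihood carries discretisation
noise comparable to the margins between neighbouring models (a model
whose weights include the trial-varying $(\varepsilon-\mu)^2$ term can
effectively dither around the static grid nodes); `fit_model()`
therefore polishes the maximum with a bounded quasi-Newton refinement
from the best grid node before computing BIC, while the posterior and
the posterior-mean estimates stay on the grid. Second, because the
single-term exponential variants estimate their unmodulated weight
freely, model 5 at $\kappa = 1$ reproduces the inequality-aversion
model exactly (the inverse temperature absorbs the scale), so it nests
model 4 at equal parameter count: on data with no emotion effect the
two are indistinguishable by likelihood, and BIC weakly prefers the
nesting model. Recovery of model 4 from ablated data is therefore not
decidable within this registry, a property of the family itself.

## Model-free behavioural statistics

The model-free layer works from the raw sessions: the 9×19 acceptance
heat map (unvisited cells are excluded, never zero-filled), per-participant
OLS of binned acceptance on z-scored face, offer and face×offer with
group one-sample t-tests and Cohen's $d = \bar b / s_b$; a lagged
logistic regression of the current choice on the face, offer,
face×offer and own-choice from each of the previous three trials
(12 regressors, z-scored within participant, first three trials of each
block dropped so no history crosses a block boundary) with a small ridge
penalty ($10^{-4}$) as a documented fallback under separation; variance
inflation factors $1/(1-R^2)$; a misprediction regression localising
where a fitted model disagrees with the observed choices; OLS of fitted
parameters on z-scored covariates (so the intercept is the mean
parameter value); and the expected outcome, i.e. acceptance rate times
mean offer. Face regressors in this layer use the true valence, not the
fitted $\varepsilon$ — these analyses are deliberately model-free.

One caveat the closed loop imposes: within a session whose offers never
cross the even split, $|R_S - R_O|$ is an exact affine function of
$R_S$, and regressors built from both become collinear. The pupil
design constructor relies on sessions visiting both sides of 500p;
`timepoint_regression()` detects the degenerate case and returns NA for
aliased regressors with a warning.

## The Bayesian filter

Trial-wise surprise, volatility and noise regressors come from a
grid-based recursive Bayesian observer, run independently on the offer
stream (in pounds) and the face-valence stream: a latent mean diffuses
between trials with standard deviation equal to an unknown static
volatility and is observed through Gaussian noise of unknown standard
deviation. The joint posterior over (mean, volatility, noise) is
propagated by exact predict–update cycles on a fixed grid — 61 mean
nodes spanning the observation range widened by 20%, and 21 log-spaced
volatility and noise nodes between 1% and 100% of the mean-axis span.
Surprise is the negative log of the grid-marginal predictive density of
the observation (a mixture over all nodes, not a single-node plug-in);
volatility and noise regressors are per-trial posterior means. This
internal model is the package's own reconstruction of a standard
volatility-tracking observer; hierarchical coupling between levels is
deliberately out of scope.

## Pupillometry

Preprocessing follows the standard pipeline: invalid samples (blinks,
dropouts) are linearly interpolated; the 500 Hz trace is low-pass
filtered at 3.75 Hz with a 3rd-order Butterworth filter applied
forward–backward (the order is a package default — zero-phase filtering
preserves event latencies, which matters for the binned inference);
the filtered trace is z-transformed across the session; epochs are cut
around offer onset with a 7.5 s pre-offer baseline (starting at trial
onset, so it spans the fixation and face period; shorter spans are used
when a trial begins early in the recording) and a 4.5 s response
window; and the baseline-window mean is subtracted per trial, making
the corrected baseline mean exactly zero. The outcome period is defined
as the final 1.5 s of the response window (offer + 3.0 s to + 4.5 s,
matching the generator's event layout of decision at +1.5 s and outcome
at +3.0 s); trials with more than 50% of that span interpolated are
excluded.

The time-resolved model regresses the corrected pupil samples, at each
of the 2250 timepoints, on 11 trial-wise regressors: a constant; the
trial index (a fatigue proxy); the self-reward value
$\hat\kappa R_S$ under the best-fitting decision model; the
emotion-modulated inequality weight $\hat\omega + (\varepsilon-\mu)^2$;
the inequality magnitude $|R_S - R_O|$; and surprise, volatility and
noise for both streams. All regressors except the constant are
demeaned. The per-timepoint fit is the closed-form normal-equation
solution across included trials. Because regressors compete for
variance within one multiple regression, coefficients are not further
corrected across regressors; binned group t-tests across the response
window (1 s bins, one-sample against zero) are reported uncorrected
with the bin count stated.

## The synthetic cohort and what it does (not) show

`synth_cohort()` draws per-participant truth in the regime where the
emotion effect is expressed and the parameters are identifiable:
$\delta \sim U[0.8, 1.6]$, $\gamma \sim U[0.5, 1.2]$,
$\kappa \sim U[0.5, 2]$, $\omega \sim U[-4, -1]$ (pound scale),
$\beta = 2$ with ±20% uniform jitter, generative model 10. Covariates
mirror the second-level design: a composite mood score, social value
orientation coupled to $\omega$ through a Gaussian copula (default
$r = -0.5$: more prosocial participants weigh inequality more
negatively), and balanced participant-sex and opponent-type binaries.
`synth_ratings()` emits the two rating tables (54 face rows from the
weighting truth, 100 offer rows from the liking truth, rating noise SD
0.5 Likert units — about half a scale step, a realistic repetition
noise for 9-point scales); `synth_sessions()` closes the loop through
the task engine with Bernoulli choices at the true softmax probability;
`synth_pupil()` renders a raw 500 Hz stream per session from injected
coefficient time-profiles (default: a gamma-shaped inequality response
peaking 0.5 s after offer onset), stationary AR(1) noise
($\phi = 0.95$, i.e. a 40 ms time constant) and Poisson blink gaps.

Synthetic data share the real task's structure but not all of its
texture: choices are exactly softmax-Bernoulli with no lapses, drift or
learning; rating noise is homoscedastic; the pupil signal has no
luminance component, gaze artefacts or slow drift beyond AR(1); and the
face–value coupling induced by the closed loop is somewhat stronger
than in the deposited behavioural data. Passing recovery tests
therefore demonstrates the correctness and stability of the estimators
under the model's own assumptions — not that real data meet those
assumptions.

Test and validation runs use reduced problem sizes chosen to keep the
full suite in the minutes range on a single core — e.g. 21-point grids
for the eleven-model comparison, single-block sessions for pupil
fixtures — with the full 41-point resolution exercised where the
quantity under test depends on it (parameter recovery, the headline
accuracy benchmark).

## Reproducing the pipeline end-to-end

`run_pipeline()` composes the whole study on a synthetic cohort and is
deterministic given its seed:

```{r pipeline, eval = FALSE}
bundle <- run_pipeline(list(n_participants = 5, seed = 1))
bundle$selection      # summed BIC + exceedance probabilities
bundle$accuracy$mean  # mean in-sample predictive accuracy
```

`scripts/acceptance.R` regenerates the headline benchmark (the mean
refit accuracy of model 10 on a 44-participant cohort) from scratch;
see the README for how to run it.
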