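# affectug

Simulation and model-based analysis of an **iterative Ultimatum Game**
in which the proposer's facial emotions and offers evolve adaptively
with the responder's decisions.

In the task, a proposer offers a split of a 1000-pence pot while
displaying one of 9 facial expressions (true valence
φ ∈ {0.1, …, 0.9}); the responder accepts (the split is paid) or
rejects (both sides get nothing). Offers (19 levels, 50–950p) and faces
are revised trial-to-trial by response-conditioned sliding-window
sampling — 171 joint stimulus states, 6 blocks of 40 trials. The
package asks how the proposer's affective reactions reshape the
responder's aversion to inequality, and what pupil-linked arousal
tracks while they do.

The core model family values an offer (R_S to self, R_O to the
proposer, in pounds inside the fitting layer) as variations on
inequality aversion,

    v = κ·R_S − ω·|R_S − R_O|,

with the perceived facial valence ε = exp(−δ(−ln φ)^γ) (a
two-parameter Prelec weighting of the true valence) allowed to modulate
the weights. In the best-fitting variant (model 10 of an 11-model
registry) the modulation is parabolic on the inequality term only:

    v = κ·R_S + (ω + (ε − μ)²)·|R_S − R_O|,      μ = 0.4,

so a proposer's increasingly negative *or* positive emotions relax an
(ordinarily negative) inequality weight symmetrically, while neutral
faces leave it alone. Choices follow the softmax
q_accept = 1/(1 + e^(−β·v)). Models are fit per participant by
exhaustive grid Bayes (full joint posterior, posterior-mean estimates),
compared by summed BIC and random-effects Bayesian model selection, and
validated by generate-recover simulation. A model-free layer
(acceptance heat maps, lagged logistic regressions, VIFs), a recursive
Bayesian filter producing trial-wise surprise/volatility/noise
regressors, and a time-resolved pupillometry regression complete the
pipeline. A synthetic-data module generates rating tables, closed-loop
sessions and raw 500 Hz pupil streams with known ground truth, so every
stage is testable without any participant data.

See `vignettes/affectug-methods.Rmd` for the full model descriptions,
parameter conventions, numerical choices and known limitations.

## Worked example

Simulate a participant: fit their face-rating nonlinearity, play a
closed-loop session with a known model-10 responder, and refit.

```r
library(affectug)

# rating task: 54 face ratings generated from delta = 1.3, gamma = 0.7
ratings <- synth_ratings(delta = 1.3, gamma = 0.7, seed = 42)
w <- fit_weighting(dplyr::filter(ratings, stimulus_type == "face"))
w
#> Valence weighting fit: delta = 1.291 , gamma = 0.7101  (SSE 0.1851 on 54 ratings)

# closed-loop session: 240 trials from a responder with kappa = 1.2,
# omega = -2 (pound scale), beta = 2
session <- run_session(
  policy_model(10, list(kappa = 1.2, omega = -2, beta = 2)),
  seed = 42
)
eps <- prelec_weight(session$phi, w$delta, w$gamma)
fit <- fit_model(session, epsilons = eps, model = 10)
fit
#> Grid Bayesian fit of model 10 (parabolic_inequality)
#>   estimates: kappa =  4.0497, omega = -6.8657, beta =  0.7932
#>   logLik -40.7036, BIC 97.849, accuracy 0.9417 (n = 240)
```

The weighting parameters come back essentially exactly (1.29/0.71 vs
1.3/0.7). The decision fit predicts 94% of this session's choices; the
posterior-mean weights land on the κβ/ωβ ridge rather than at the
generating values — with 240 trials, β is separated from the weights
only by the small emotion-modulation term, an identifiability limit of
the design that the methods vignette quantifies (and the reason
generate-recover correlations for β are intrinsically modest).

```r
expected_outcome(session)         # acceptance rate x mean offer (pence)
#> [1] 232.0625
select_payout_trials(session, seed = 42)$payout_pence
#> [1] 3300
```

Higher-level entry points: `run_pipeline()` composes cohort generation,
perception fits, decision fits, model selection and the behavioural
statistics into one seeded, reproducible bundle; `select_models()`,
`generate_recover()`, `session_filter_regressors()`,
`pupil_preprocess()` / `timepoint_regression()` /
`pupil_binned_ttests()` expose the individual stages; `autoplot()`
methods draw acceptance grids, weighting curves, recovery scatters and
pupil coefficient time courses.

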