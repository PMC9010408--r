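#' Decision-value functions for the Ultimatum responder
#'
#' The candidate models map an offer (self-reward `R_S`, other's amount
#' `R_O`) and, for the emotion-modulated variants, the perceived valence
#' `epsilon` of the proposer's face, to a scalar decision value. The value
#' is converted to an acceptance probability by the softmax rule
#' [accept_probability()]. All functions are pure, deterministic and
#' vectorised over offers.
#'
#' `value_ces()` is the constant-elasticity-of-substitution aggregate
#' \deqn{\tilde v = (\alpha R_S^{\rho} + (1-\alpha)|R_S-R_O|^{\rho})^{1/\rho}.}
#'
#' @param R_S,R_O Non-negative self and other reward amounts (any
#'   consistent unit; the fitting layer works in pounds).
#' @param alpha Weight on the self-reward component, in `[0, 1]`.
#' @param rho Nonzero power-utility curvature.
#' @return Decision value(s), same length as `R_S`.
#' @export
value_ces <- function(R_S, R_O, alpha, rho) {
  if (any(rho == 0)) stop("rho must be nonzero", call. = FALSE)
  stopifnot(all(R_S >= 0), all(R_O >= 0))
  (alpha * R_S^rho + (1 - alpha) * abs(R_S - R_O)^rho)^(1 / rho)
}

#' @rdname value_ces
#' @param lambda Fairness threshold, on the offer scale; the value is
#'   \eqn{\lambda - |R_S - R_O|}.
#' @export
value_threshold <- function(R_S, R_O, lambda) {
  lambda - abs(R_S - R_O)
}

#' @rdname value_ces
#' @param liking A [fit_liking()] object or a list with `phi0`, `phi1`,
#'   `phi2`; the value equals the predicted liking
#'   \eqn{\chi = \phi_0 + \phi_1 R_S + \phi_2|R_S-R_O|}.
#' @export
value_liking <- function(R_S, R_O, liking) {
  liking$phi0 + liking$phi1 * R_S + liking$phi2 * abs(R_S - R_O)
}

#' @rdname value_ces
#' @param kappa,omega Weights on the self-reward and inequality terms; the
#'   inequality-aversion value is \eqn{\kappa R_S - \omega|R_S-R_O|}.
#' @export
value_inequality <- function(R_S, R_O, kappa, omega) {
  kappa * R_S - omega * abs(R_S - R_O)
}

#' Emotion-modulated decision values
#'
#' In the emotion-modulated models the perceived valence `epsilon` of the
#' proposer's face shifts the weights of the inequality-aversion value
#' around the perceptual crossover constant `mu` (the valence at which
#' perception crosses the identity diagonal, fixed at 0.4 at the group
#' level).
#'
#' `value_emotion_exp()` modulates weights exponentially:
#' \deqn{\tilde v = \kappa^{(\varepsilon-\mu)} R_S -
#'   \omega^{(\varepsilon-\mu)}|R_S-R_O|}
#' with `variant` selecting whether the self term, the inequality term, or
#' both are modulated (the unmodulated term keeps its weight as a plain
#' linear multiplier).
#'
#' `value_emotion_parabolic()` modulates weights parabolically:
#' \deqn{\tilde v = (\kappa + (\varepsilon-\mu)^2) R_S +
#'   (\omega + (\varepsilon-\mu)^2)|R_S-R_O|}
#' Here the inequality term enters with a `+` sign and `omega` is typically
#' negative (aversion); faces further from neutral in either direction
#' relax the negative weight symmetrically. The `"inequality"` variant is
#' the best-fitting model of the family (model 10 in [model_registry()]).
#'
#' @inheritParams value_ces
#' @param epsilon Perceived valence in (0, 1), from [prelec_weight()];
#'   vectorised with `R_S`.
#' @param kappa,omega Base weights; for the exponential form any modulated
#'   weight must be positive.
#' @param mu Perceptual crossover constant (default 0.4).
#' @param variant One of `"self"`, `"inequality"`, `"both"`.
#' @return Decision value(s).
#' @export
value_emotion_exp <- function(R_S, R_O, epsilon, kappa, omega, mu = 0.4,
                              variant = c("both", "self", "inequality")) {
  variant <- match.arg(variant)
  e <- epsilon - mu
  mod_self <- variant %in% c("self", "both")
  mod_ineq <- variant %in% c("inequality", "both")
  if ((mod_self && any(kappa == 0 & e < 0)) ||
      (mod_ineq && any(omega == 0 & e < 0))) {
    stop("zero base weight with a negative exponent is undefined", call. = FALSE)
  }
  w_self <- if (mod_self) kappa^e else kappa
  w_ineq <- if (mod_ineq) omega^e else omega
  w_self * R_S - w_ineq * abs(R_S - R_O)
}

#' @rdname value_emotion_exp
#' @export
value_emotion_parabolic <- function(R_S, R_O, epsilon, kappa, omega, mu = 0.4,
                                    variant = c("inequality", "self", "both")) {
  variant <- match.arg(variant)
  e2 <- (epsilon - mu)^2
  w_self <- if (variant %in% c("self", "both")) kappa + e2 else kappa
  w_ineq <- if (variant %in% c("inequality", "both")) omega + e2 else omega
  w_self * R_S + w_ineq * abs(R_S - R_O)
}

#' @rdname value_emotion_exp
#' @param v_base Decision value from the stage-1 inequality-aversion model
#'   (\eqn{\kappa R_S - \omega|R_S-R_O|} with the participant's fitted
#'   weights).
#' @param w Integration weight in `[0, 1]`; the value is the convex
#'   combination \eqn{w\,\tilde v + (1-w)(\varepsilon-\mu)}.
#' @export
value_weighted_integration <- function(v_base, epsilon, mu = 0.4, w = 0.5) {
  if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]", call. = FALSE)
  w * v_base + (1 - w) * (epsilon - mu)
}

#' Softmax acceptance probability
#'
#' Maps a decision value to the probability of accepting the offer through
#' the logistic rule \eqn{q_A = 1 / (1 + e^{-\beta \tilde v})}, where the
#' inverse temperature `beta` controls choice stochasticity.
#'
#' @param v Decision value(s).
#' @param beta Positive inverse temperature.
#' @return Acceptance probability in (0, 1).
#' @export
accept_probability <- function(v, beta) {
  if (any(beta <= 0)) stop("beta must be positive", call. = FALSE)
  stats::plogis(beta * v)
}

#' Registry of the eleven candidate decision models
#'
#' Lists the full model family compared by the pipeline: (1) CES, (2)
#' fairness threshold, (3) liking-based, (4) inequality aversion, (5-7)
#' exponential emotion modulation of the self term, the inequality term, or
#' both, (8-10) parabolic emotion modulation of the self term, both terms,
#' or the inequality term only, and (11) weighted integration of monetary
#' value and facial affect. Model 10 (parabolic modulation of the
#' inequality term only) is the best-fitting model of the family on this
#' task.
#'
#' Parameter bounds are on the pound scale used by the fitting layer
#' (rewards divided by 100 so that `beta` grids are well conditioned):
#' `kappa`/`omega` in `[0, 10]` for the exponential family (weights that
#' are exponentiated start at 0.01 since `0^x` is undefined for negative
#' exponents), `omega` in `[-10, 10]` for the parabolic family so that
#' negative (averse) base weights can be relaxed, `lambda` spanning the
#' offer range, and `w` in `[0, 1]`. The inverse temperature `beta` is
#' shared by all models and fitted on a log-spaced grid (see
#' [fit_model()]).
#'
#' @return A tibble with one row per model: `model`, `name`, `family`,
#'   `variant`, `n_free` (parameters counted in the BIC: the model's free
#'   parameters plus `beta`, and for the weighted-integration model also
#'   the stage-1 inequality weights it inherits, since those were
#'   estimated from the same choices), and a `params` list-column of
#'   per-parameter `name`, `lower`, `upper` bounds.
#' @examples
#' model_registry()
#' @export
model_registry <- function() {
  par_tbl <- function(...) {
    rows <- list(...)
    if (!length(rows)) {
      return(tibble::tibble(name = character(), lower = numeric(),
                            upper = numeric()))
    }
    tibble::tibble(
      name = vapply(rows, `[[`, "", 1),
      lower = vapply(rows, function(r) as.numeric(r[[2]]), 0),
      upper = vapply(rows, function(r) as.numeric(r[[3]]), 0)
    )
  }
  reg <- tibble::tribble(
    ~model, ~name, ~family, ~variant, ~params,
    1L, "ces", "ces", NA_character_,
    par_tbl(list("alpha", 0, 1), list("rho", 0.1, 2)),
    2L, "threshold", "threshold", NA_character_,
    par_tbl(list("lambda", 0.5, 9.5)),
    3L, "liking", "liking", NA_character_,
    par_tbl(),
    4L, "inequality", "inequality", NA_character_,
    par_tbl(list("kappa", 0, 10), list("omega", 0, 10)),
    5L, "exp_self", "emotion_exp", "self",
    par_tbl(list("kappa", 0.01, 10), list("omega", 0, 10)),
    6L, "exp_inequality", "emotion_exp", "inequality",
    par_tbl(list("kappa", 0, 10), list("omega", 0.01, 10)),
    7L, "exp_both", "emotion_exp", "both",
    par_tbl(list("kappa", 0.01, 10), list("omega", 0.01, 10)),
    8L, "parabolic_self", "emotion_parabolic", "self",
    par_tbl(list("kappa", 0, 10), list("omega", -10, 10)),
    9L, "parabolic_both", "emotion_parabolic", "both",
    par_tbl(list("kappa", 0, 10), list("omega", -10, 10)),
    10L, "parabolic_inequality", "emotion_parabolic", "inequality",
    par_tbl(list("kappa", 0, 10), list("omega", -10, 10)),
    11L, "weighted_integration", "weighted_integration", NA_character_,
    par_tbl(list("w", 0, 1))
  )
  reg$n_free <- vapply(reg$params, nrow, 0L) + 1L # + beta
  # the weighted-integration model inherits the stage-1 kappa and omega,
  # which were estimated from the same choice data: they count toward its
  # complexity (the liking model's coefficients come from the independent
  # rating task and do not)
  reg$n_free[reg$model == 11L] <- reg$n_free[reg$model == 11L] + 2L
  reg
}

#' Evaluate any registry model's decision value
#'
#' Uniform dispatcher over the model family: given a model id from
#' [model_registry()] and a named parameter set, returns the trial-wise
#' decision value. Models 3 and 11 additionally need, respectively, the
#' liking coefficients (`params$liking`) and the stage-1 inequality weights
#' (`params$kappa`, `params$omega`) fixed from earlier fits.
#'
#' @param model Integer model id (1-11).
#' @param params Named list (or vector) of parameter values.
#' @param R_S,R_O Reward amounts (vectorised).
#' @param epsilon Perceived valence per trial (needed for models 5-11).
#' @param mu Perceptual crossover constant.
#' @return Decision value(s).
#' @export
decision_value <- function(model, params, R_S, R_O, epsilon = NULL, mu = 0.4) {
  if (!length(model) == 1 || !model %in% 1:11) {
    stop("unknown model id: ", model, call. = FALSE)
  }
  p <- as.list(params)
  needs_eps <- model >= 5
  if (needs_eps && is.null(epsilon)) {
    stop("model ", model, " requires per-trial epsilon", call. = FALSE)
  }
  switch(as.character(model),
    "1" = value_ces(R_S, R_O, p$alpha, p$rho),
    "2" = value_threshold(R_S, R_O, p$lambda),
    "3" = value_liking(R_S, R_O, p$liking),
    "4" = value_inequality(R_S, R_O, p$kappa, p$omega),
    "5" = value_emotion_exp(R_S, R_O, epsilon, p$kappa, p$omega, mu, "self"),
    "6" = value_emotion_exp(R_S, R_O, epsilon, p$kappa, p$omega, mu, "inequality"),
    "7" = value_emotion_exp(R_S, R_O, epsilon, p$kappa, p$omega, mu, "both"),
    "8" = value_emotion_parabolic(R_S, R_O, epsilon, p$kappa, p$omega, mu, "self"),
    "9" = value_emotion_parabolic(R_S, R_O, epsilon, p$kappa, p$omega, mu, "both"),
    "10" = value_emotion_parabolic(R_S, R_O, epsilon, p$kappa, p$omega, mu, "inequality"),
    "11" = value_weighted_integration(
      value_inequality(R_S, R_O, p$kappa, p$omega), epsilon, mu, p$w
    ),
    stop("unknown model id: ", model, call. = FALSE)
  )
}
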