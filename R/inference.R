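# Grid construction and the vectorised likelihood core shared by
# grid_log_likelihood() and fit_model(). Rewards are rescaled from pence to
# pounds before value computation so that the beta grid is well conditioned;
# the liking model (3) is the exception: its value is the predicted Likert
# liking, computed from the pence amounts its coefficients were fit on.

#' Default inverse-temperature grid
#'
#' `n` log-spaced points in `[0.01, 20]` (pound scale), shared by all
#' models in the registry.
#'
#' @param n Number of grid points.
#' @return Numeric vector of `beta` values.
#' @export
default_beta_grid <- function(n = 41) exp(seq(log(0.01), log(20), length.out = n))

model_spec <- function(model, registry = model_registry()) {
  row <- registry[registry$model == model, ]
  if (nrow(row) != 1) stop("unknown model id: ", model, call. = FALSE)
  row
}

# Cartesian grid over a spec's non-beta parameters: matrix n_nodes x k
# (k may be 0, giving a single empty node).
build_param_grid <- function(spec, n_points = 41) {
  pars <- spec$params[[1]]
  if (nrow(pars) == 0) {
    return(matrix(numeric(0), nrow = 1, ncol = 0))
  }
  axes <- lapply(seq_len(nrow(pars)), function(i) {
    seq(pars$lower[i], pars$upper[i], length.out = n_points)
  })
  names(axes) <- pars$name
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

# Decision values for every grid node: matrix n_nodes x n_trials.
grid_values <- function(model, P, session, epsilons, mu = 0.4,
                        liking = NULL, base_params = NULL) {
  Rs <- session$offer_pence / 100
  Ro <- session$other_pence / 100
  if (model == 3) {
    if (is.null(liking)) {
      stop("model 3 requires `liking` coefficients from fit_liking()",
           call. = FALSE)
    }
    return(matrix(value_liking(session$offer_pence, session$other_pence,
                               liking), nrow = 1))
  }
  if (model == 11) {
    if (is.null(base_params)) {
      stop("model 11 requires `base_params` (stage-1 kappa, omega)",
           call. = FALSE)
    }
    v_base <- value_inequality(Rs, Ro, base_params$kappa, base_params$omega)
    return(t(vapply(seq_len(nrow(P)), function(i) {
      value_weighted_integration(v_base, epsilons, mu, P[i, "w"])
    }, numeric(length(Rs)))))
  }
  t(vapply(seq_len(nrow(P)), function(i) {
    p <- as.list(P[i, ])
    decision_value(model, p, Rs, Ro, epsilon = epsilons, mu = mu)
  }, numeric(length(Rs))))
}

# Bernoulli log-likelihood for each (value-node, beta) pair.
# Returns matrix n_nodes x n_beta.
loglik_matrix <- function(V, choices, beta_grid, floor = 1e-10) {
  c1 <- as.numeric(choices)
  c0 <- 1 - c1
  out <- matrix(NA_real_, nrow(V), length(beta_grid))
  for (b in seq_along(beta_grid)) {
    Q <- stats::plogis(beta_grid[b] * V)
    Q <- pmin(pmax(Q, floor), 1 - floor)
    out[, b] <- log(Q) %*% c1 + log1p(-Q) %*% c0
  }
  out
}

#' Log-likelihood surface over the full parameter grid
#'
#' Evaluates the Bernoulli choice log-likelihood
#' \eqn{\sum_t [c_t \ln q_t + (1-c_t)\ln(1-q_t)]} at every node of the
#' Cartesian parameter grid of a registry model (including the log-spaced
#' `beta` axis). Acceptance probabilities are floored at `1e-10` on both
#' sides so the surface is finite everywhere.
#'
#' @param model Model id (1-11); see [model_registry()].
#' @param session Session tibble ([run_session()] schema).
#' @param epsilons Per-trial perceived valence (from [prelec_weight()] with
#'   the participant's fitted weighting parameters). Required for models
#'   5-11.
#' @param n_points Grid points per non-`beta` parameter (linear spacing
#'   within the registry bounds).
#' @param beta_grid Inverse-temperature grid (default 41 log-spaced points
#'   in `[0.01, 20]`).
#' @param mu Perceptual crossover constant.
#' @param liking For model 3: liking coefficients from [fit_liking()].
#' @param base_params For model 11: list with the stage-1 fitted `kappa`
#'   and `omega` (pound scale).
#' @param registry Model registry table.
#' @return A tibble with one row per grid node: the model's parameters,
#'   `beta`, and `logLik`.
#' @export
grid_log_likelihood <- function(model, session, epsilons = NULL,
                                n_points = 41, beta_grid = default_beta_grid(),
                                mu = 0.4, liking = NULL, base_params = NULL,
                                registry = model_registry()) {
  if (nrow(session) == 0) stop("empty session", call. = FALSE)
  spec <- model_spec(model, registry)
  P <- build_param_grid(spec, n_points)
  V <- grid_values(model, P, session, epsilons, mu, liking, base_params)
  LL <- loglik_matrix(V, session$choice, beta_grid)
  n_v <- nrow(P)
  n_b <- length(beta_grid)
  nodes <- if (ncol(P)) {
    tibble::as_tibble(P[rep(seq_len(n_v), times = n_b), , drop = FALSE])
  } else {
    tibble::tibble(.rows = n_v * n_b)
  }
  nodes$beta <- rep(beta_grid, each = n_v)
  nodes$logLik <- as.vector(LL)
  nodes
}

#' Fit one decision model to a session by exhaustive grid Bayes
#'
#' Computes the full joint posterior of the model's parameters over the
#' Cartesian grid (uniform prior), derives point estimates by integrating
#' the node values against the posterior (posterior means), and reports the
#' grid-maximum log-likelihood, BIC, and in-sample predictive accuracy
#' under the deterministic accept-iff-`q >= 0.5` rule at the posterior-mean
#' parameters.
#'
#' @inheritParams grid_log_likelihood
#' @param store_posterior Keep the joint posterior (as a grid tibble) in
#'   the returned object. Set to `FALSE` in large cohort loops.
#' @param refine_max Polish the likelihood maximum by a bounded
#'   quasi-Newton refinement started from the best grid node (default
#'   `TRUE`). The refined maximum feeds `logLik` and the BIC only; the
#'   posterior and the posterior-mean estimates stay on the grid.
#'   Without refinement, grid discretisation noise of the maximum is of
#'   the same order as the likelihood margins separating neighbouring
#'   models and can scramble BIC comparisons.
#' @return An object of class `ug_fit`: list with `model`, `name`,
#'   `estimates` (named numeric, posterior means incl. `beta`), `logLik`
#'   (grid maximum), `k` (free parameters incl. `beta`), `n` (trials),
#'   `bic`, `accuracy`, `predicted` (per-trial tibble of value, `q_accept`,
#'   predicted and observed choice), and optionally `posterior`. Supports
#'   `tidy()` and `glance()`.
#' @examples
#' \donttest{
#' s <- run_session(policy_threshold(400), seed = 2)
#' f <- fit_model(s, epsilons = s$phi, model = 4, n_points = 21,
#'                beta_grid = default_beta_grid(21))
#' glance(f)
#' }
#' @export
fit_model <- function(session, epsilons = NULL, model = 10,
                      n_points = 41, beta_grid = default_beta_grid(),
                      mu = 0.4, liking = NULL, base_params = NULL,
                      registry = model_registry(), store_posterior = TRUE,
                      refine_max = TRUE) {
  if (nrow(session) == 0) stop("empty session", call. = FALSE)
  spec <- model_spec(model, registry)
  P <- build_param_grid(spec, n_points)
  V <- grid_values(model, P, session, epsilons, mu, liking, base_params)
  LL <- loglik_matrix(V, session$choice, beta_grid)

  # uniform prior over the joint grid
  m <- max(LL)
  post <- exp(LL - m)
  post <- post / sum(post)

  n_v <- nrow(P)
  node_mass <- rowSums(post)   # marginal over beta, per value node
  beta_mass <- colSums(post)
  estimates <- c(
    if (ncol(P)) colSums(P * node_mass),
    beta = sum(beta_grid * beta_mass)
  )

  n <- nrow(session)
  k <- spec$n_free
  logLik_max <- m
  if (refine_max) {
    logLik_max <- max(m, refine_loglik_max(
      model, spec, P, LL, beta_grid, session, epsilons, mu, liking,
      base_params
    ))
  }
  fit_bic <- bic(logLik_max, k, n)

  p_est <- as.list(estimates)
  p_est$liking <- liking
  if (model == 11) {
    p_est$kappa <- base_params$kappa
    p_est$omega <- base_params$omega
  }
  pred <- predicted_choices(model, p_est, session, epsilons, mu)
  accuracy <- mean(pred$predicted == session$choice)

  out <- list(
    model = model, name = spec$name, estimates = estimates,
    logLik = logLik_max, k = k, n = n, bic = fit_bic,
    accuracy = accuracy, predicted = pred, mu = mu
  )
  if (store_posterior) {
    nodes <- if (ncol(P)) {
      tibble::as_tibble(P[rep(seq_len(n_v), times = length(beta_grid)),
                          , drop = FALSE])
    } else {
      tibble::tibble(.rows = n_v * length(beta_grid))
    }
    nodes$beta <- rep(beta_grid, each = n_v)
    nodes$posterior <- as.vector(post)
    out$posterior <- nodes
  }
  structure(out, class = "ug_fit")
}

# Continuous polish of the grid likelihood maximum: bounded quasi-Newton
# from the best grid node, within the registry bounds. Returns the refined
# maximum log-likelihood (the grid value if the refinement fails).
refine_loglik_max <- function(model, spec, P, LL, beta_grid, session,
                              epsilons, mu, liking, base_params) {
  idx <- arrayInd(which.max(LL), dim(LL))
  pars <- spec$params[[1]]
  start <- c(if (ncol(P)) P[idx[1], ], beta = beta_grid[idx[2]])
  lower <- c(pars$lower, max(min(beta_grid), 1e-6))
  upper <- c(pars$upper, max(beta_grid))
  nll <- function(theta) {
    p <- as.list(stats::setNames(theta[seq_len(nrow(pars))], pars$name))
    p$liking <- liking
    if (model == 11) {
      p$kappa <- base_params$kappa
      p$omega <- base_params$omega
    }
    v <- if (model == 3) {
      value_liking(session$offer_pence, session$other_pence, liking)
    } else {
      decision_value(model, p, session$offer_pence / 100,
                     session$other_pence / 100, epsilon = epsilons, mu = mu)
    }
    q <- stats::plogis(theta[length(theta)] * v)
    q <- pmin(pmax(q, 1e-10), 1 - 1e-10)
    -sum(ifelse(session$choice == 1, log(q), log(1 - q)))
  }
  out <- tryCatch(
    stats::optim(unname(start), nll, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL
  )
  if (is.null(out)) -Inf else -out$value
}

# Per-trial predicted acceptance under a parameter set.
predicted_choices <- function(model, params, session, epsilons, mu = 0.4) {
  v <- if (model == 3) {
    value_liking(session$offer_pence, session$other_pence, params$liking)
  } else {
    decision_value(model, params,
                   R_S = session$offer_pence / 100,
                   R_O = session$other_pence / 100,
                   epsilon = epsilons, mu = mu)
  }
  q <- accept_probability(v, params$beta)
  tibble::tibble(
    trial = session$trial, value = v, q_accept = q,
    predicted = as.numeric(q >= 0.5), observed = session$choice
  )
}

#' @export
print.ug_fit <- function(x, ...) {
  cat("Grid Bayesian fit of model ", x$model, " (", x$name, ")\n", sep = "")
  cat("  estimates:", paste(names(x$estimates),
                            format(x$estimates, digits = 4),
                            sep = " = ", collapse = ", "), "\n")
  cat("  logLik ", format(x$logLik, digits = 6), ", BIC ",
      format(x$bic, digits = 6), ", accuracy ",
      format(x$accuracy, digits = 4), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.ug_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @export
glance.ug_fit <- function(x, ...) {
  tibble::tibble(model = x$model, name = x$name, logLik = x$logLik,
                 BIC = x$bic, accuracy = x$accuracy, k = x$k, nobs = x$n)
}

#' Bayesian Information Criterion
#'
#' \eqn{\mathrm{BIC} = k \ln n - 2 \ln \hat L}, computed from the grid
#' maximum of the log-likelihood; lower is better.
#'
#' @param max_loglik Maximum log-likelihood.
#' @param k Number of free parameters (including `beta`).
#' @param n Number of trials.
#' @return The BIC value.
#' @export
bic <- function(max_loglik, k, n) k * log(n) - 2 * max_loglik

#' In-sample predictive accuracy of a parameter set
#'
#' Fraction of trials on which the deterministic model choice (accept iff
#' the softmax acceptance probability is at least 0.5) agrees with the
#' observed choice.
#'
#' @param model Model id.
#' @param params Named parameter list including `beta` (and `liking` /
#'   stage-1 weights where the model needs them).
#' @param session Session tibble.
#' @param epsilons Per-trial perceived valence.
#' @param mu Perceptual crossover constant.
#' @return Fraction in `[0, 1]`.
#' @export
predictive_accuracy <- function(model, params, session, epsilons = NULL,
                                mu = 0.4) {
  pred <- predicted_choices(model, as.list(params), session, epsilons, mu)
  mean(pred$predicted == session$choice)
}

#' Compare fitted models across a cohort
#'
#' Combines per-participant fits of competing models into (a) a group
#' ranking by summed BIC and (b) random-effects Bayesian model selection:
#' using `-BIC/2` as the per-participant log model evidence, the standard
#' variational Dirichlet scheme estimates the expected frequency of each
#' model in the population and its exceedance probability (the probability
#' that it is the most frequent generative model).
#'
#' @param fits Either a tibble with columns `participant`, `model`, `bic`,
#'   or a list (participants) of lists of `ug_fit` objects.
#' @param n_samples Dirichlet samples used for exceedance probabilities.
#' @param seed Optional seed for the exceedance sampling.
#' @return An object of class `model_selection`: list with `bic_table`
#'   (per-model summed BIC, ranked), `expected_frequency`, `exceedance`
#'   (both named by model), `alpha` (Dirichlet counts) and `n_participants`.
#' @export
select_models <- function(fits, n_samples = 1e5, seed = NULL) {
  if (!is.data.frame(fits)) {
    fits <- purrr::map_dfr(seq_along(fits), function(i) {
      purrr::map_dfr(fits[[i]], function(f) {
        tibble::tibble(participant = i, model = f$model, bic = f$bic)
      })
    })
  }
  stopifnot(all(c("participant", "model", "bic") %in% names(fits)))
  wide <- fits |>
    dplyr::select("participant", "model", "bic") |>
    tidyr::pivot_wider(names_from = "model", values_from = "bic") |>
    dplyr::arrange(.data$participant)
  B <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(B)) stop("every participant needs a BIC for every model", call. = FALSE)
  models <- as.integer(colnames(B))
  K <- ncol(B)
  n_subj <- nrow(B)

  bic_table <- tibble::tibble(model = models, summed_bic = colSums(B)) |>
    dplyr::arrange(.data$summed_bic) |>
    dplyr::mutate(rank = dplyr::row_number())

  # random-effects BMS: variational update of Dirichlet counts with
  # log-evidence L = -BIC/2
  L <- -B / 2
  alpha0 <- rep(1, K)
  alpha <- alpha0 + n_subj / K
  for (iter in 1:200) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)

  draw_xp <- function() {
    G <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    tabulate(max.col(G), nbins = K) / n_samples
  }
  xp <- if (is.null(seed)) draw_xp() else withr::with_seed(seed, draw_xp())

  structure(
    list(
      bic_table = bic_table,
      expected_frequency = stats::setNames(ef, models),
      exceedance = stats::setNames(xp, models),
      alpha = stats::setNames(alpha, models),
      n_participants = n_subj
    ),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Random-effects model selection over", length(x$alpha), "models,",
      x$n_participants, "participants\n")
  best <- x$bic_table$model[1]
  cat("  summed-BIC winner: model", best, "\n")
  cat("  exceedance probabilities:\n")
  print(round(x$exceedance, 4))
  invisible(x)
}

#' Generate-recover simulation for a decision model
#'
#' Quantifies estimator stability: for each iteration, true parameters are
#' drawn from the truth sampler, a closed-loop session is simulated through
#' the task engine with the model as the stochastic responder policy, the
#' model is refit by [fit_model()], and true versus recovered values are
#' compared. Sessions use the true valence as the perceived valence
#' (weighting parameters fixed at the identity).
#'
#' @param model Model id to generate from and refit.
#' @param n_iterations Number of generate-recover iterations.
#' @param truth_sampler Function `() -> named list` of true parameter
#'   values including `beta`. The default draws `kappa ~ U[0.5, 2]`,
#'   `omega ~ U[-4, -1]` (pound scale) and `beta = 2` with a +/-20%
#'   uniform jitter — the regime in which emotion effects are expressed and
#'   the parameters identifiable.
#' @param tables,state_space Task configuration.
#' @param n_blocks,trials_per_block Session structure.
#' @param n_points,beta_grid Fitting grid resolution.
#' @param mu Perceptual crossover constant.
#' @param seed Master seed; the whole report is reproducible given it.
#' @return An object of class `recovery_report`: list with `draws` (tibble
#'   of `iteration`, `parameter`, `true`, `recovered`) and `summary`
#'   (per-parameter Pearson correlation, mean bias and mean absolute
#'   error). Supports `autoplot()`.
#' @export
generate_recover <- function(model = 10, n_iterations = 50,
                             truth_sampler = default_truth_sampler(),
                             tables = ug_transition_tables(),
                             state_space = ug_state_space(),
                             n_blocks = 6, trials_per_block = 40,
                             n_points = 41, beta_grid = default_beta_grid(),
                             mu = 0.4, seed = 1) {
  draws <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_iterations), function(it) {
      truth <- truth_sampler()
      sess <- run_session(
        policy_model(model, truth, delta = 1, gamma = 1, mu = mu),
        tables, state_space, n_blocks, trials_per_block
      )
      fit <- fit_model(sess, epsilons = sess$phi, model = model,
                       n_points = n_points, beta_grid = beta_grid,
                       mu = mu, store_posterior = FALSE)
      est <- fit$estimates
      tibble::tibble(
        iteration = it,
        parameter = names(est),
        true = unlist(truth[names(est)]),
        recovered = unname(est)
      )
    })
  })
  summary <- draws |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      correlation = stats::cor(.data$true, .data$recovered),
      bias = mean(.data$recovered - .data$true),
      mae = mean(abs(.data$recovered - .data$true)),
      .groups = "drop"
    )
  structure(list(draws = draws, summary = summary, model = model,
                 n_iterations = n_iterations, seed = seed),
            class = "recovery_report")
}

#' @rdname generate_recover
#' @export
default_truth_sampler <- function() {
  function() {
    list(
      kappa = stats::runif(1, 0.5, 2),
      omega = stats::runif(1, -4, -1),
      beta = 2 * stats::runif(1, 0.8, 1.2)
    )
  }
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Generate-recover report: model", x$model, ",", x$n_iterations,
      "iterations (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}
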