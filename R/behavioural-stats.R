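# Model-free analyses: acceptance grids, per-participant OLS/logistic fits
# with group-level one-sample t-tests, VIF, misprediction and covariate
# regressions. Face regressors use the true valence (phi), not fitted
# epsilon: these analyses are deliberately model-free.

z_score <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Acceptance probabilities over the face-by-offer grid
#'
#' Bins one or more sessions into the 9 x 19 stimulus grid and reports the
#' average acceptance probability and trial count per visited cell.
#' Unvisited cells are absent (not zero-filled).
#'
#' @param sessions A session tibble or a list of session tibbles; a
#'   `participant` column is added when a list is given.
#' @return A tibble of class `acceptance_grid` with columns
#'   (`participant`,) `phi`, `offer_pence`, `p_accept`, `n_trials`.
#'   Supports [ggplot2::autoplot()].
#' @export
acceptance_grid <- function(sessions) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  out <- purrr::map_dfr(seq_along(sessions), function(i) {
    sessions[[i]] |>
      dplyr::group_by(.data$phi, .data$offer_pence) |>
      dplyr::summarise(
        p_accept = mean(.data$choice),
        n_trials = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(participant = i, .before = 1)
  })
  class(out) <- c("acceptance_grid", class(out))
  out
}

#' Main effects of face valence and offer on acceptance
#'
#' Per-participant OLS of the binned acceptance probability on the
#' normalised face valence, offer amount and their interaction, followed by
#' group-level one-sample t-tests (against zero) on the coefficients, with
#' Cohen's d = mean / sd. Regressors are z-scored within participant;
#' unvisited grid cells are excluded.
#'
#' @param grids An [acceptance_grid()] tibble (may pool participants).
#' @return A tibble with one row per term (`face`, `offer`,
#'   `face_x_offer`): group `mean`, `sd`, `t`, `df`, `p_value`, `cohens_d`.
#' @export
main_effects_ols <- function(grids) {
  coefs <- grids |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(g, key) {
      face <- z_score(g$phi)
      offer <- z_score(g$offer_pence)
      fit <- stats::lm(g$p_accept ~ face + offer + I(face * offer))
      co <- stats::coef(fit)
      tibble::tibble(
        term = c("face", "offer", "face_x_offer"),
        estimate = unname(co[2:4])
      )
    }) |>
    dplyr::ungroup()
  coefs$estimate[is.na(coefs$estimate)] <- 0
  group_ttests(coefs)
}

# One-sample t-tests against 0 on per-participant coefficients (df = n-1).
group_ttests <- function(coefs) {
  coefs |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sd = stats::sd(.data$estimate),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      t = ifelse(.data$sd > 0, .data$mean / (.data$sd / sqrt(.data$n)), NA_real_),
      df = .data$n - 1,
      p_value = 2 * stats::pt(-abs(.data$t), df = .data$df),
      cohens_d = ifelse(.data$sd > 0, .data$mean / .data$sd, NA_real_)
    )
}

# Lagged design for the history regression: regressors from trials t-1..t-lags
# (face valence, offer, face x offer, previous choice), z-scored within
# participant; the first `lags` trials of each block are dropped.
history_design <- function(session, lags = 3) {
  blocks <- split(session, session$block)
  rows <- purrr::map_dfr(blocks, function(b) {
    n <- nrow(b)
    if (n <= lags) return(NULL)
    idx <- (lags + 1):n
    out <- tibble::tibble(choice = b$choice[idx])
    for (l in seq_len(lags)) {
      out[[paste0("face_l", l)]] <- b$phi[idx - l]
      out[[paste0("offer_l", l)]] <- b$offer_pence[idx - l]
      out[[paste0("faceoffer_l", l)]] <- b$phi[idx - l] * b$offer_pence[idx - l]
      out[[paste0("choice_l", l)]] <- b$choice[idx - l]
    }
    out
  })
  rows |>
    dplyr::mutate(dplyr::across(-"choice", z_score))
}

#' Lagged logistic regression of choice on trial history
#'
#' Regresses the choice at trial `t` on the face valence, offer amount,
#' face-by-offer interaction and the participant's own choice from each of
#' the previous `lags` trials (12 regressors at the default 3 lags), within
#' block. Regressors are z-scored within participant. If the maximum
#' likelihood fit fails to converge or separates, a small ridge penalty
#' (1e-4) is applied with a warning.
#'
#' @param session A session tibble.
#' @param lags Number of lagged trials (default 3).
#' @return A tibble with `term` and `estimate` (log-odds per SD), one row
#'   per lagged regressor.
#' @export
history_logistic <- function(session, lags = 3) {
  d <- history_design(session, lags)
  X <- as.matrix(d[, -1, drop = FALSE])
  y <- d$choice
  if (length(unique(y)) < 2) {
    warning("all choices identical; history coefficients set to 0", call. = FALSE)
    return(tibble::tibble(term = colnames(X), estimate = 0))
  }
  est <- tryCatch(
    {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                             family = stats::binomial()))
      if (!fit$converged || any(abs(fit$coefficients) > 15)) stop("separation")
      fit$coefficients[-1]
    },
    error = function(e) {
      warning("logistic fit separated or failed to converge; ",
              "falling back to ridge penalty 1e-4", call. = FALSE)
      rfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                             lambda = 1e-4, standardize = FALSE)
      as.numeric(rfit$beta)
    }
  )
  tibble::tibble(term = colnames(X), estimate = unname(est))
}

#' Variance inflation factors
#'
#' For each column of a design matrix, `VIF = 1 / (1 - R^2)` where `R^2`
#' is from regressing that column on all the others. Values above `cap`
#' (perfect or near-perfect collinearity) are reported as `cap` with
#' `capped = TRUE`.
#'
#' @param X Numeric design matrix or data frame (no intercept column).
#' @param cap Ceiling for reported VIFs.
#' @return A tibble with `term`, `vif`, `capped`.
#' @export
vif <- function(X, cap = 1e6) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1) {
      return(tibble::tibble(term = colnames(X)[j], vif = 1, capped = FALSE))
    }
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    )
    v <- 1 / (1 - r2)
    tibble::tibble(
      term = colnames(X)[j],
      vif = min(v, cap),
      capped = !is.finite(v) || v > cap
    )
  })
  out
}

#' Where does the fitted model mispredict?
#'
#' Regresses the per-trial misprediction indicator (fitted model choice
#' disagrees with the observed choice) on normalised face valence, offer
#' and their interaction, per participant, followed by group one-sample
#' t-tests. A systematic interaction indicates the model fails at specific
#' stimulus combinations (e.g. unfair offers with very positive faces).
#'
#' @param fits List of `ug_fit` objects, one per participant.
#' @param sessions List of matching session tibbles.
#' @return A list with `coefficients` (per-participant term estimates),
#'   `tests` (group t-table), and `n_mispredicted` per participant.
#'   Participants with no mispredicted trials contribute zero coefficients
#'   and are flagged.
#' @export
misprediction_analysis <- function(fits, sessions) {
  stopifnot(length(fits) == length(sessions))
  coefs <- purrr::map_dfr(seq_along(fits), function(i) {
    s <- sessions[[i]]
    mis <- as.numeric(fits[[i]]$predicted$predicted != s$choice)
    face <- z_score(s$phi)
    offer <- z_score(s$offer_pence)
    if (sum(mis) == 0) {
      return(tibble::tibble(participant = i,
                            term = c("face", "offer", "face_x_offer"),
                            estimate = 0, n_mispredicted = 0L))
    }
    fit <- stats::lm(mis ~ face + offer + I(face * offer))
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    tibble::tibble(participant = i,
                   term = c("face", "offer", "face_x_offer"),
                   estimate = unname(co[2:4]),
                   n_mispredicted = as.integer(sum(mis)))
  })
  list(
    coefficients = coefs,
    tests = group_ttests(coefs),
    n_mispredicted = coefs |>
      dplyr::distinct(.data$participant, .data$n_mispredicted)
  )
}

#' Regress fitted parameters on participant covariates
#'
#' OLS of each fitted parameter on the normalised covariates (e.g.
#' composite mood score, social value orientation, sexes, opponent type).
#' Covariates are plain columns; each is z-scored before fitting, so the
#' intercept equals the mean parameter value.
#'
#' @param params Tibble with a `participant` column and one column per
#'   fitted parameter.
#' @param covariates Tibble with a `participant` column and numeric
#'   covariate columns.
#' @return A tibble with `parameter`, `term`, `estimate`, `std_error`,
#'   `t`, `p_value`.
#' @export
parameter_covariates_ols <- function(params, covariates) {
  dat <- dplyr::inner_join(params, covariates, by = "participant")
  par_cols <- setdiff(names(params), "participant")
  cov_cols <- setdiff(names(covariates), "participant")
  Z <- as.data.frame(lapply(dat[cov_cols], z_score))
  purrr::map_dfr(par_cols, function(p) {
    fit <- stats::lm(dat[[p]] ~ ., data = Z)
    sm <- summary(fit)$coefficients
    tibble::tibble(
      parameter = p,
      term = c("intercept", cov_cols)[seq_len(nrow(sm))],
      estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
      t = unname(sm[, 3]), p_value = unname(sm[, 4])
    )
  })
}

#' Expected monetary outcome of a session
#'
#' The participant's average acceptance rate multiplied by the average
#' offer they experienced — a model-free summary of how profitably they
#' played.
#'
#' @param session A session tibble.
#' @return Scalar expected outcome in pence.
#' @export
expected_outcome <- function(session) {
  mean(session$choice) * mean(session$offer_pence)
}
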