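test_that("acceptance grids are means of binary choices with conserved counts", {
  a <- run_session(policy_accept_all(), seed = 1)
  g <- acceptance_grid(a)
  expect_true(all(g$p_accept == 1))
  expect_equal(sum(g$n_trials), 240)

  s <- run_session(policy_threshold(500), seed = 2)
  gt <- acceptance_grid(s)
  expect_true(all(gt$p_accept[gt$offer_pence < 500] == 0))
  expect_true(all(gt$p_accept[gt$offer_pence >= 500] == 1))

  # recomputable from the raw session, exact match
  cell <- gt[which.max(gt$n_trials), ]
  raw <- s[s$phi == cell$phi & s$offer_pence == cell$offer_pence, ]
  expect_equal(mean(raw$choice), cell$p_accept)
})

test_that("main-effect OLS isolates planted effects", {
  # acceptance driven by the offer only: strong offer effect, null face
  sessions <- purrr::map(1:20, function(i) {
    s <- run_session(policy_threshold(500), seed = 400 + i)
    # add response noise so per-cell probabilities are graded in the offer
    s$choice <- withr::with_seed(500 + i,
                                 rbinom(240, 1, s$offer_pence / 1000))
    s$outcome_self <- as.integer(s$offer_pence * s$choice)
    s$outcome_other <- as.integer(s$other_pence * s$choice)
    s
  })
  res <- main_effects_ols(acceptance_grid(sessions))
  offer_t <- res$t[res$term == "offer"]
  face_t <- res$t[res$term == "face"]
  expect_gt(offer_t, 5)
  expect_lt(abs(face_t), 3)
  expect_lt(res$p_value[res$term == "offer"], 1e-6)

  # constant acceptance: all non-intercept coefficients vanish
  allacc <- purrr::map(1:4, function(i) run_session(policy_accept_all(),
                                                    seed = 700 + i))
  res2 <- main_effects_ols(acceptance_grid(allacc))
  expect_true(all(abs(res2$mean) < 1e-12))
})

test_that("planted interaction is detected at cohort scale", {
  # acceptance probability proportional to face x offer product
  sessions <- purrr::map(1:44, function(i) {
    s <- run_session(policy_accept_all(), seed = 800 + i)
    p <- pmin(pmax(s$phi * s$offer_pence / 500, 0), 1)
    s$choice <- withr::with_seed(900 + i, rbinom(240, 1, p))
    s
  })
  res <- main_effects_ols(acceptance_grid(sessions))
  expect_lt(res$p_value[res$term == "face_x_offer"], 0.001)
  expect_gt(res$t[res$term == "face_x_offer"], 0)
})

test_that("history logistic regression finds planted lagged rules", {
  # threshold-policy stimuli keep offers varied around the planted cut
  s <- run_session(policy_threshold(500), seed = 12)
  # choice at t = accept iff offer at t-1 exceeded 500 (within block)
  ch <- numeric(240)
  for (b in 1:6) {
    idx <- which(s$block == b)
    ch[idx] <- c(1, as.numeric(s$offer_pence[idx[-length(idx)]] > 500))
  }
  s$choice <- ch
  # a deterministic rule separates perfectly: the ridge fallback engages
  expect_warning(co <- history_logistic(s), "ridge")
  expect_equal(nrow(co), 12)
  dom <- co$term[which.max(abs(co$estimate))]
  expect_equal(dom, "offer_l1")
  expect_gt(co$estimate[co$term == "offer_l1"], 0)

  # i.i.d. random choices: term means stay inside their own null CI
  nulls <- purrr::map_dfr(1:50, function(i) {
    sn <- run_session(policy_accept_all(), seed = 1200 + i)
    sn$choice <- withr::with_seed(1300 + i, rbinom(240, 1, 0.5))
    suppressWarnings(history_logistic(sn))
  })
  band <- nulls |>
    dplyr::group_by(term) |>
    dplyr::summarise(m = mean(estimate), s = sd(estimate),
                     .groups = "drop")
  crit <- qt(0.9975, 49)
  expect_true(all(abs(band$m) <= crit * band$s / sqrt(50)))
})

test_that("history coefficients agree with an independent reference fit", {
  s <- run_session(policy_model(10, list(kappa = 1, omega = -1.5, beta = 2)),
                   seed = 17)
  co <- history_logistic(s)
  # independent route: formula-interface glm on an independently built design
  blocks <- split(s, s$block)
  ref <- purrr::map_dfr(blocks, function(b) {
    n <- nrow(b)
    idx <- 4:n
    tibble::tibble(
      y = b$choice[idx],
      face_l1 = b$phi[idx - 1], offer_l1 = b$offer_pence[idx - 1],
      faceoffer_l1 = b$phi[idx - 1] * b$offer_pence[idx - 1],
      choice_l1 = b$choice[idx - 1],
      face_l2 = b$phi[idx - 2], offer_l2 = b$offer_pence[idx - 2],
      faceoffer_l2 = b$phi[idx - 2] * b$offer_pence[idx - 2],
      choice_l2 = b$choice[idx - 2],
      face_l3 = b$phi[idx - 3], offer_l3 = b$offer_pence[idx - 3],
      faceoffer_l3 = b$phi[idx - 3] * b$offer_pence[idx - 3],
      choice_l3 = b$choice[idx - 3]
    )
  })
  ref <- dplyr::mutate(ref, dplyr::across(-y, ~ (.x - mean(.x)) / sd(.x)))
  rfit <- stats::glm(y ~ ., data = ref, family = stats::binomial())
  expect_equal(co$estimate, unname(coef(rfit)[-1]), tolerance = 1e-6)
})

test_that("variance inflation factors follow the closed form", {
  # centred orthonormal columns so sample correlations are exact
  centred_basis <- function(n, k) {
    M <- matrix(stats::rnorm(n * k), n, k)
    M <- sweep(M, 2, colMeans(M))
    qr.Q(qr(M))
  }
  withr::with_seed(30, {
    X <- centred_basis(200, 3)
    v <- vif(X)
    expect_true(all(abs(v$vif - 1) < 1e-9))

    # pair with exact sample correlation 0.6
    e <- centred_basis(100, 2)
    x1 <- e[, 1]; x2 <- 0.6 * e[, 1] + sqrt(1 - 0.36) * e[, 2]
    expect_equal(cor(x1, x2), 0.6, tolerance = 1e-12)
    v2 <- vif(cbind(a = x1, b = x2))
    expect_equal(v2$vif, rep(1 / (1 - 0.36), 2), tolerance = 1e-9)

    # duplicated column: capped and flagged
    v3 <- vif(cbind(x1, x1))
    expect_true(all(v3$capped))
  })
})

test_that("misprediction analysis localises planted model failures", {
  sessions <- purrr::map(1:30, function(i) {
    run_session(policy_threshold(450), seed = 1500 + i)
  })
  # perfect predictions: empty misprediction set is flagged as n = 0
  perfect <- purrr::map(sessions, function(s) {
    list(predicted = tibble::tibble(trial = s$trial, predicted = s$choice))
  })
  res0 <- misprediction_analysis(perfect, sessions)
  expect_true(all(res0$n_mispredicted$n_mispredicted == 0))
  expect_true(all(res0$tests$mean == 0))

  # failures planted at extreme-face x unfair-offer cells
  planted <- purrr::map(sessions, function(s) {
    flip <- s$phi >= 0.8 & s$offer_pence <= 300
    list(predicted = tibble::tibble(trial = s$trial,
                                    predicted = ifelse(flip, 1 - s$choice,
                                                       s$choice)))
  })
  res1 <- misprediction_analysis(planted, sessions)
  expect_lt(res1$tests$t[res1$tests$term == "face_x_offer"], 0)
  expect_lt(res1$tests$p_value[res1$tests$term == "face_x_offer"], 0.05)

  # uniformly random 10% mispredictions: no systematic effects
  rand <- purrr::map(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    flip <- withr::with_seed(1600 + i, runif(240) < 0.1)
    list(predicted = tibble::tibble(trial = s$trial,
                                    predicted = ifelse(flip, 1 - s$choice,
                                                       s$choice)))
  })
  res2 <- misprediction_analysis(rand, sessions)
  expect_true(all(res2$tests$p_value > 0.01))
})

test_that("parameter-covariate OLS recovers planted correlations", {
  withr::with_seed(40, {
    n <- 44
    omega <- runif(n, -4, -1)
    z <- (omega - mean(omega)) / sd(omega)
    # exact sample correlation -0.5 via an orthogonalised residual
    e <- rnorm(n)
    e <- residuals(lm(e ~ z))
    e <- (e - mean(e)) / sd(e)
    svo <- -0.5 * z + sqrt(0.75) * e
    params <- tibble::tibble(participant = 1:n, omega = omega)
    covs <- tibble::tibble(participant = 1:n, svo = svo, noise = rnorm(n))
    res <- parameter_covariates_ols(params, covs)
    expect_lt(res$estimate[res$term == "svo"], 0)
    expect_lt(res$p_value[res$term == "svo"], 0.05)
    # normalised regressors leave the intercept at the mean parameter value
    expect_equal(res$estimate[res$term == "intercept"], mean(omega),
                 tolerance = 1e-9)
    # independent covariate stays within its null band
    expect_gt(res$p_value[res$term == "noise"], 0.01)
  })
})

test_that("expected outcome is acceptance rate times mean offer", {
  a <- run_session(policy_accept_all(), tables = frozen_tables(), seed = 2)
  expect_equal(expected_outcome(a), 500)
  r <- run_session(policy_reject_all(), seed = 2)
  expect_equal(expected_outcome(r), 0)
  s <- a
  s$choice <- rep(c(1, 0), 120)
  expect_equal(expected_outcome(s), 0.5 * 500)
})
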