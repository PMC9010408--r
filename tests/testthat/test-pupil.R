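# Small sessions keep the synthetic pupil streams light: 1 block of 40
# trials at 500 Hz is 240k samples.

pupil_fixture <- function(seed = 70, noise_sd = 0, blink_rate = 0,
                          profiles = default_pupil_profiles(),
                          n_blocks = 1, trials_per_block = 40) {
  # threshold above the even split so offers cross 500 and the value and
  # inequality regressors are not collinear within the session
  s <- run_session(policy_threshold(550),
                   n_blocks = n_blocks, trials_per_block = trials_per_block,
                   seed = seed)
  f <- fit_model(s, epsilons = s$phi, model = 10, n_points = 11,
                 beta_grid = default_beta_grid(11), store_posterior = FALSE)
  filt <- session_filter_regressors(s, n_mean = 31, n_vol = 11, n_noise = 11)
  des <- pupil_design(s, f, filt)
  raw <- synth_pupil(des, profiles = profiles, noise_sd = noise_sd,
                     blink_rate = blink_rate, seed = seed + 1)
  list(session = s, fit = f, design = des, raw = raw)
}

test_that("the design holds eleven demeaned regressors tied to the fit", {
  fx <- pupil_fixture()
  des <- fx$design
  expect_equal(ncol(des) - 1, 11)
  nonconst <- setdiff(names(des), c("trial", "constant"))
  expect_true(all(abs(colMeans(des[nonconst])) < 1e-10))
  expect_true(all(des$constant == 1))
  # value term equals kappa-hat times the pound-scale self-reward
  k <- unname(fx$fit$estimates["kappa"])
  raw_col <- k * fx$session$offer_pence / 100
  expect_equal(des$value_self, raw_col - mean(raw_col), tolerance = 1e-12)
  # all-neutral-face session: emotion regressor collapses to zero
  s2 <- fx$session
  s2$phi <- 0.5
  des2 <- pupil_design(s2, fx$fit,
                       session_filter_regressors(s2, n_mean = 31,
                                                 n_vol = 11, n_noise = 11))
  expect_true(all(abs(des2$emo_inequality) < 1e-12))
})

test_that("preprocessing interpolates, epochs, and excludes by the outcome rule", {
  fx <- pupil_fixture(noise_sd = 0.05, blink_rate = 0)
  raw <- fx$raw
  ep <- pupil_preprocess(raw$samples, raw$events, keep_baseline = TRUE)
  expect_equal(nrow(ep$response), 40)
  expect_equal(ncol(ep$response), 2250)
  expect_true(all(ep$info$included))
  # baseline-window mean is exactly zero after correction
  bmeans <- rowMeans(ep$baseline, na.rm = TRUE)
  expect_lt(max(abs(bmeans)), 1e-9)

  # plant a trial whose outcome period is 60% invalid: excluded exactly
  samples2 <- raw$samples
  offer_ms <- raw$events$time_ms[raw$events$event_name == "offer_onset"][3]
  bad <- samples2$time_ms >= offer_ms + 3000 &
    samples2$time_ms < offer_ms + 3000 + 0.6 * 1500
  samples2$valid[bad] <- 0L
  ep2 <- pupil_preprocess(samples2, raw$events)
  expect_false(ep2$info$included[3])
  expect_equal(sum(!ep2$info$included), 1)
  expect_equal(ep2$info$interp_frac_outcome[3], 0.6, tolerance = 0.01)

  # constant trace collapses to zero with a warning
  const <- raw$samples
  const$pupil <- 3
  expect_warning(ep3 <- pupil_preprocess(const, raw$events), "constant")
  expect_true(all(ep3$response == 0))

  # mostly-missing sessions abort with diagnostics
  dead <- raw$samples
  dead$valid[seq_len(round(0.6 * nrow(dead)))] <- 0L
  expect_error(pupil_preprocess(dead, raw$events), "50%")
})

test_that("the low-pass filter attenuates 10 Hz by 20 dB more than 0.5 Hz", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  amp <- function(hz) {
    x <- sin(2 * pi * hz * t)
    samples <- tibble::tibble(time_ms = t * 1000, pupil = x, valid = 1L)
    events <- tibble::tibble(trial = 1, event_name = "offer_onset",
                             time_ms = 20000)
    ep <- pupil_preprocess(samples, events, z_transform = FALSE)
    stats::sd(ep$response)
  }
  ratio <- amp(10) / amp(0.5)
  expect_lt(20 * log10(ratio), -20)
})

test_that("injected coefficient profiles are recovered from the epochs", {
  # noiseless, blink-free, constant 0.5-unit inequality profile
  flat_half <- list(inequality = function(t) rep(0.5, length(t)))
  fx <- pupil_fixture(noise_sd = 0, blink_rate = 0, profiles = flat_half)
  ep <- pupil_preprocess(fx$raw$samples, fx$raw$events,
                         filter = FALSE, z_transform = FALSE)
  reg <- timepoint_regression(ep, fx$design)
  est <- reg$coefficients["inequality", ]
  expect_true(all(abs(est - 0.5) < 1e-6))
  other <- reg$coefficients[setdiff(reg$terms, "inequality"), ]
  expect_lt(max(abs(other)), 1e-6)

  # with mild noise the flat profile is still recovered within 0.05
  fx2 <- pupil_fixture(seed = 72, noise_sd = 0.02, blink_rate = 0,
                       profiles = flat_half)
  ep2 <- pupil_preprocess(fx2$raw$samples, fx2$raw$events,
                          filter = FALSE, z_transform = FALSE)
  reg2 <- timepoint_regression(ep2, fx2$design)
  expect_true(all(abs(reg2$coefficients["inequality", ] - 0.5) < 0.05))

  # pure-noise epochs: coefficients stay near zero
  silent <- list(inequality = function(t) rep(0, length(t)))
  fx3 <- pupil_fixture(seed = 73, noise_sd = 0.1, profiles = silent)
  ep3 <- pupil_preprocess(fx3$raw$samples, fx3$raw$events,
                          filter = FALSE, z_transform = FALSE)
  reg3 <- timepoint_regression(ep3, fx3$design)
  expect_lt(max(abs(reg3$coefficients["inequality", ])), 0.2)
})

test_that("per-timepoint OLS equals an independent lm fit", {
  withr::with_seed(80, {
    n_tr <- 30; n_tp <- 5
    X <- cbind(constant = 1, a = rnorm(n_tr), b = rnorm(n_tr))
    B_true <- matrix(rnorm(3 * n_tp), 3)
    Y <- X %*% B_true + matrix(rnorm(n_tr * n_tp, 0, 0.1), n_tr)
    ep <- structure(list(
      response = Y, times_s = (0:(n_tp - 1)) / 500,
      info = tibble::tibble(trial = 1:n_tr, interp_frac_outcome = 0,
                            included = TRUE, baseline_n = 1L)
    ), class = "pupil_epochs")
    des <- tibble::tibble(trial = 1:n_tr, constant = 1,
                          a = X[, "a"], b = X[, "b"])
    reg <- timepoint_regression(ep, des)
    for (j in seq_len(n_tp)) {
      ref <- stats::lm(Y[, j] ~ X[, "a"] + X[, "b"])
      expect_equal(unname(reg$coefficients[, j]), unname(coef(ref)),
                   tolerance = 1e-9)
    }
    # epochs equal to the constant column load only on the constant
    ep0 <- ep; ep0$response <- matrix(2, n_tr, n_tp)
    reg0 <- timepoint_regression(ep0, des)
    expect_true(all(abs(reg0$coefficients["constant", ] - 2) < 1e-9))
    expect_true(all(abs(reg0$coefficients[c("a", "b"), ]) < 1e-9))
  })
})

test_that("binned t-tests flag degenerate cohorts and detect planted peaks", {
  mk_reg <- function(B) {
    structure(list(coefficients = B, times_s = (0:2249) / 500,
                   terms = rownames(B), n_trials = 40, flagged = FALSE),
              class = "pupil_regression")
  }
  zeroB <- matrix(0, 2, 2250, dimnames = list(c("constant", "inequality")))
  res0 <- pupil_binned_ttests(list(mk_reg(zeroB), mk_reg(zeroB), mk_reg(zeroB)))
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p_value == 1))
  expect_equal(unique(res0$n_bins), 5)

  res1 <- pupil_binned_ttests(list(mk_reg(zeroB)))
  expect_true(all(is.na(res1$t)))
  expect_true(all(res1$flagged))

  # cohort with an inequality effect confined to the first second
  profile <- ifelse((0:2249) / 500 < 1, 0.4, 0.02)
  regs <- withr::with_seed(85, purrr::map(1:12, function(i) {
    B <- rbind(constant = rnorm(2250, 0, 0.05),
               inequality = profile + rnorm(2250, 0, 0.05))
    mk_reg(B)
  }))
  res2 <- pupil_binned_ttests(regs)
  first <- dplyr::filter(res2, term == "inequality", bin == 1)
  later <- dplyr::filter(res2, term == "inequality", bin > 1)
  expect_lt(first$p_value, 0.01)
  expect_true(all(later$mean < first$mean))
})
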