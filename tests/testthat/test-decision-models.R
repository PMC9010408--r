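test_that("value functions reproduce hand-computed examples", {
  # CES
  expect_equal(value_ces(200, 800, alpha = 0.5, rho = 1), 400)
  expect_equal(value_ces(500, 500, alpha = 1, rho = 2), 500)
  withr::with_seed(2, {
    rs <- runif(100, 0, 10); ro <- runif(100, 0, 10)
    a <- runif(100); err <- abs(value_ces(rs, ro, a, 1) -
                                  (a * rs + (1 - a) * abs(rs - ro)))
    expect_lt(max(err), 1e-9)
  })
  expect_error(value_ces(1, 2, 0.5, 0), "nonzero")

  # threshold
  expect_equal(value_threshold(500, 500, 300), 300)
  expect_equal(value_threshold(200, 800, 300), -300)
  expect_equal(value_threshold(950, 50, 900), 0)

  # liking plug-in
  lk <- list(phi0 = 2, phi1 = 0.01, phi2 = -0.005)
  expect_equal(value_liking(200, 800, lk), 1)
  expect_equal(value_liking(c(100, 900), c(900, 100),
                            list(phi0 = 0, phi1 = 0, phi2 = 0)), c(0, 0))

  # inequality aversion
  expect_equal(value_inequality(500, 500, 1, 0.5), 500)
  expect_equal(value_inequality(200, 800, 1, 0.5), -100)
  expect_equal(value_inequality(c(200, 700), c(800, 300), 2, 0),
               c(400, 1400))
})

test_that("emotion modulation follows the exponential and parabolic forms", {
  # at epsilon = mu exponents vanish: weights become 1
  expect_equal(value_emotion_exp(200, 800, 0.4, kappa = 3, omega = 7,
                                 mu = 0.4, variant = "both"),
               200 - 600)
  expect_equal(value_emotion_exp(200, 800, 0.9, kappa = 2, omega = 2,
                                 mu = 0.4, variant = "both"),
               sqrt(2) * 200 - sqrt(2) * 600, tolerance = 1e-12)
  # 2^0.5*200 - 2^0.5*600 = -565.685...
  expect_equal(value_emotion_exp(200, 800, 0.9, 2, 2, 0.4, "both"),
               -565.685, tolerance = 1e-3)
  # inequality-only: 4^0.5 = 2 on the inequality term, self term linear
  expect_equal(value_emotion_exp(100, 900, 0.9, kappa = 1, omega = 4,
                                 mu = 0.4, variant = "inequality"),
               1 * 100 - 2 * 800)
  expect_error(value_emotion_exp(100, 900, 0.1, kappa = 0, omega = 1,
                                 mu = 0.4, variant = "self"), "undefined")

  # parabolic, inequality-only (model 10)
  expect_equal(value_emotion_parabolic(200, 800, 0.4, 1, -1, 0.4,
                                       "inequality"),
               1 * 200 - 1 * 600)
  expect_equal(value_emotion_parabolic(200, 800, 0.9, 1, -1, 0.4,
                                       "inequality"),
               200 + (-1 + 0.25) * 600) # -250
  expect_equal(value_emotion_parabolic(200, 800, 0.4, 1, -1, 0.4,
                                       "inequality"), -400)

  # weighted integration
  expect_equal(value_weighted_integration(-5, 0.9, 0.4, w = 1), -5)
  expect_equal(value_weighted_integration(-5, 0.9, 0.4, w = 0), 0.5)
  expect_equal(value_weighted_integration(-0.2, 0.9, 0.4, w = 0.5), 0.15)
  expect_error(value_weighted_integration(1, 0.5, 0.4, w = 1.2), "\\[0, 1\\]")
})

test_that("parabolic modulation is symmetric about mu and nests the linear model", {
  # v(mu + d) = v(mu - d) whenever both valences are in (0, 1)
  withr::with_seed(3, {
    for (i in 1:200) {
      d <- runif(1, 0, 0.35)
      rs <- runif(1, 0.5, 9.5); ro <- 10 - rs
      k <- runif(1, 0, 5); o <- runif(1, -5, 5)
      expect_equal(
        value_emotion_parabolic(rs, ro, 0.4 + d, k, o, 0.4, "inequality"),
        value_emotion_parabolic(rs, ro, 0.4 - d, k, o, 0.4, "inequality"),
        tolerance = 1e-12
      )
    }
  })
  expect_equal(
    value_emotion_parabolic(2, 8, 0.7, 1, -1, 0.4, "inequality"),
    value_emotion_parabolic(2, 8, 0.1, 1, -1, 0.4, "inequality")
  )

  # model 10 at neutral valence equals the inequality-aversion value with
  # the sign of omega flipped
  withr::with_seed(4, {
    rs <- runif(1000, 0, 10); ro <- runif(1000, 0, 10)
    k <- runif(1000, 0, 10); o <- runif(1000, -10, 10)
    err <- abs(value_emotion_parabolic(rs, ro, 0.4, k, o, 0.4, "inequality") -
                 value_inequality(rs, ro, k, -o))
    expect_lt(max(err), 1e-9)
  })
})

test_that("softmax choice rule behaves like a logistic in beta * value", {
  expect_equal(accept_probability(0, 3.7), 0.5)
  expect_equal(accept_probability(log(3), 1), 0.75, tolerance = 1e-12)
  expect_gt(accept_probability(0.1, 1e6), 1 - 1e-9)
  expect_error(accept_probability(1, 0), "positive")
  # q(v) + q(-v) = 1
  withr::with_seed(5, {
    v <- rnorm(100); b <- runif(100, 0.1, 10)
    expect_true(all(abs(accept_probability(v, b) +
                          accept_probability(-v, b) - 1) < 1e-12))
  })
})

test_that("the registry lists the eleven-model family coherently", {
  reg <- model_registry()
  expect_equal(nrow(reg), 11)
  expect_equal(anyDuplicated(reg$model), 0)
  m10 <- reg[reg$model == 10, ]
  expect_equal(m10$family, "emotion_parabolic")
  expect_equal(m10$variant, "inequality")
  known <- c("alpha", "rho", "lambda", "kappa", "omega", "w")
  for (p in reg$params) expect_true(all(p$name %in% known))
  # beta is always free; model 11 additionally carries the stage-1 weights
  expect_equal(reg$n_free,
               vapply(reg$params, nrow, 0L) + 1L + 2L * (reg$model == 11L))
})

test_that("decision values are finite on the full stimulus grid", {
  sp <- ug_state_space()
  grid <- tidyr::expand_grid(phi = sp$faces$phi, offer = sp$offers)
  rs <- grid$offer / 100; ro <- (1000 - grid$offer) / 100
  params <- list(
    `1` = list(alpha = 0.5, rho = 0.7), `2` = list(lambda = 3),
    `3` = list(liking = list(phi0 = 2, phi1 = 0.01, phi2 = -0.005)),
    `4` = list(kappa = 1, omega = 2), `5` = list(kappa = 2, omega = 1),
    `6` = list(kappa = 1, omega = 2), `7` = list(kappa = 2, omega = 2),
    `8` = list(kappa = 1, omega = -1), `9` = list(kappa = 1, omega = -1),
    `10` = list(kappa = 1, omega = -1),
    `11` = list(kappa = 1, omega = 2, w = 0.5)
  )
  for (m in 1:11) {
    v <- decision_value(m, params[[as.character(m)]],
                        if (m == 3) grid$offer else rs,
                        if (m == 3) 1000 - grid$offer else ro,
                        epsilon = grid$phi)
    expect_length(v, nrow(grid))
    expect_true(all(is.finite(v)))
  }
  expect_error(decision_value(10, list(kappa = 1, omega = -1), rs, ro),
               "epsilon")
  expect_error(decision_value(12, list(), 1, 1), "unknown model")
})
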