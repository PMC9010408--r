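# Shared fixtures, built in code.

# Frozen tables: deterministic stimuli (face and offer never move).
frozen_tables <- function() {
  ug_transition_tables(
    accept_face = c(0, 1, 0), accept_offer = c(0, 1, 0),
    reject_face = c(0, 1, 0), reject_offer = c(0, 1, 0)
  )
}

# Exact (non-integer) rating tables for noiseless regression checks.
exact_liking_ratings <- function(phi0 = 2, phi1 = 0.01, phi2 = -0.005) {
  rs <- seq(50, 950, by = 50)
  tibble::tibble(
    R_S = rs, R_O = 1000 - rs,
    likert = phi0 + phi1 * rs + phi2 * abs(rs - (1000 - rs))
  )
}

# Small model-10 session generated from known truth.
model10_session <- function(truth = list(kappa = 1, omega = -1.5, beta = 2),
                            seed = 11) {
  run_session(policy_model(10, truth), seed = seed)
}

# Independent brute-force grid posterior used as the oracle for fit_model.
brute_force_posterior <- function(kappas, omegas, betas, session, mu = 0.4) {
  rs <- session$offer_pence / 100
  ro <- session$other_pence / 100
  dr <- abs(rs - ro)
  post <- array(NA_real_, dim = c(length(kappas), length(omegas), length(betas)))
  for (i in seq_along(kappas)) {
    for (j in seq_along(omegas)) {
      for (b in seq_along(betas)) {
        v <- kappas[i] * rs + (omegas[j] + (session$phi - mu)^2) * dr
        q <- 1 / (1 + exp(-betas[b] * v))
        q <- pmin(pmax(q, 1e-10), 1 - 1e-10)
        post[i, j, b] <- prod(ifelse(session$choice == 1, q, 1 - q))
      }
    }
  }
  post / sum(post)
}
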