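# Synthetic cohorts with known ground truth. The generators emulate the
# three empirical input kinds of the study design — Likert rating tables,
# closed-loop task sessions, and raw pupil sample streams — so that every
# pipeline stage can be validated by recovery simulation without any
# participant data.

clip_likert <- function(x) pmin(pmax(round(x), 1), 9)

#' Generate synthetic Likert rating tables
#'
#' Face ratings follow the valence weighting model: for each of the 9 face
#' valences, presented in 6 repetitions, the rating is
#' `round(10 * epsilon(phi; delta, gamma) + noise)` clipped to 1..9.
#' Offer ratings follow the liking regression truth over 100 offers
#' spanning unfair to advantageous splits of the 1000-pence pot.
#'
#' @param delta,gamma True weighting parameters.
#' @param liking True liking coefficients (list with `phi0`, `phi1`,
#'   `phi2`; Likert units, slopes per pence).
#' @param noise_sd Rating noise SD (Likert units), applied to both tasks.
#' @param n_face_reps Repetitions per face (default 6: 54 face rows).
#' @param n_offers Number of rated offers (default 100).
#' @param state_space Task state space supplying the face valences.
#' @param seed Optional seed; same seed gives identical tables.
#' @return A tibble with columns `stimulus_type` (`"face"`/`"offer"`),
#'   `phi`, `R_S`, `R_O`, `repetition`, `likert`.
#' @export
synth_ratings <- function(delta = 1, gamma = 1,
                          liking = list(phi0 = 2, phi1 = 0.01, phi2 = -0.007),
                          noise_sd = 0.5, n_face_reps = 6, n_offers = 100,
                          state_space = ug_state_space(), seed = NULL) {
  gen <- function() {
    phis <- rep(state_space$faces$phi, times = n_face_reps)
    reps <- rep(seq_len(n_face_reps), each = nrow(state_space$faces))
    face_likert <- clip_likert(
      10 * prelec_weight(phis, delta, gamma) + stats::rnorm(length(phis), 0, noise_sd)
    )
    faces <- tibble::tibble(
      stimulus_type = "face", phi = phis, R_S = NA_integer_,
      R_O = NA_integer_, repetition = reps, likert = face_likert
    )
    rs <- sample(seq(50L, 950L, by = 10L), n_offers, replace = TRUE)
    chi <- liking$phi0 + liking$phi1 * rs + liking$phi2 * abs(2 * rs - state_space$pot)
    offers <- tibble::tibble(
      stimulus_type = "offer", phi = NA_real_, R_S = rs,
      R_O = state_space$pot - rs, repetition = 1L,
      likert = clip_likert(chi + stats::rnorm(n_offers, 0, noise_sd))
    )
    dplyr::bind_rows(faces, offers)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Sample a synthetic cohort's ground truth and covariates
#'
#' Draws per-participant true parameters in the identifiable regime in
#' which emotion effects are expressed: weighting parameters
#' `delta ~ U[0.8, 1.6]`, `gamma ~ U[0.5, 1.2]`; decision model 10 with
#' `kappa ~ U[0.5, 2]`, `omega ~ U[-4, -1]` (pound scale) and `beta = 2`
#' with a +/-20% uniform jitter. Covariates mirror the study's second-level
#' design: a composite mood score (independent of the parameters by
#' default), social value orientation (coupled to `omega` through a
#' Gaussian copula, default correlation -0.5: more prosocial participants
#' weigh inequality more negatively), participant sex and opponent type
#' (balanced binaries).
#'
#' @param n Number of participants (default 44).
#' @param model Generative decision model id.
#' @param beta_base Centre of the `beta` jitter.
#' @param svo_r Copula correlation between SVO and `omega`.
#' @param mood_r Copula correlation between the mood composite and `delta`.
#' @param seed Optional master seed.
#' @return A list with `truth` (tibble: `participant`, `model`, `delta`,
#'   `gamma`, `kappa`, `omega`, `beta`) and `covariates` (tibble:
#'   `participant`, `mood`, `svo`, `sex`, `opponent`).
#' @export
synth_cohort <- function(n = 44, model = 10, beta_base = 2,
                         svo_r = -0.5, mood_r = 0, seed = NULL) {
  if (n < 1) stop("cohort must have at least one participant", call. = FALSE)
  stopifnot(abs(svo_r) <= 1, abs(mood_r) <= 1)
  gen <- function() {
    truth <- tibble::tibble(
      participant = seq_len(n),
      model = model,
      delta = stats::runif(n, 0.8, 1.6),
      gamma = stats::runif(n, 0.5, 1.2),
      kappa = stats::runif(n, 0.5, 2),
      omega = stats::runif(n, -4, -1),
      beta = beta_base * stats::runif(n, 0.8, 1.2)
    )
    copula <- function(x, r) {
      z <- stats::qnorm((rank(x) - 0.5) / length(x))
      r * z + sqrt(1 - r^2) * stats::rnorm(length(x))
    }
    covariates <- tibble::tibble(
      participant = seq_len(n),
      mood = copula(truth$delta, mood_r),
      svo = copula(truth$omega, svo_r),
      sex = stats::rbinom(n, 1, 0.5),
      opponent = stats::rbinom(n, 1, 0.5)
    )
    list(truth = truth, covariates = covariates)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate closed-loop sessions for a synthetic cohort
#'
#' Each participant's responder policy draws choices from their true
#' decision model: the acceptance probability is the softmax of the true
#' decision value (with perceived valence from the participant's true
#' weighting parameters), and the choice is a Bernoulli draw. Stimuli
#' evolve through the adaptive sliding-window sampler, closing the loop
#' between the participant's choices and the proposer's behaviour.
#'
#' @param cohort A [synth_cohort()] list (or its `truth` tibble).
#' @param tables,state_space Task configuration.
#' @param n_blocks,trials_per_block Session structure.
#' @param mu Perceptual crossover constant.
#' @param seed Master seed; participant `i` runs under seed `seed + i`.
#' @return A list of session tibbles, one per participant.
#' @export
synth_sessions <- function(cohort, tables = ug_transition_tables(),
                           state_space = ug_state_space(),
                           n_blocks = 6, trials_per_block = 40,
                           mu = 0.4, seed = 1) {
  truth <- if (is.data.frame(cohort)) cohort else cohort$truth
  purrr::map(seq_len(nrow(truth)), function(i) {
    p <- truth[i, ]
    run_session(
      policy_model(p$model, list(kappa = p$kappa, omega = p$omega,
                                 beta = p$beta),
                   delta = p$delta, gamma = p$gamma, mu = mu),
      tables, state_space, n_blocks, trials_per_block,
      seed = seed + i
    )
  })
}

#' Default coefficient time-profiles for the synthetic pupil signal
#'
#' The inequality regressor carries a gamma-shaped response peaking in the
#' first second after offer onset and decaying thereafter (qualitatively
#' matching the observed pupillary inequality response); all other
#' regressors are silent by default.
#'
#' @param peak_s Peak latency (s) of the inequality profile.
#' @param amplitude Peak coefficient value.
#' @return Named list of functions `time_s -> coefficient`.
#' @export
default_pupil_profiles <- function(peak_s = 0.5, amplitude = 0.5) {
  list(
    inequality = function(t) amplitude * (t / peak_s) * exp(1 - t / peak_s)
  )
}

#' Generate a raw synthetic pupil sample stream for a session
#'
#' Builds the continuous 500 Hz pupil trace implied by a trial-wise design
#' and injected coefficient time-profiles: within each trial's response
#' window the signal is the sum over regressors of
#' `profile_k(t) * x_k(trial)` (with the design regressors demeaned, as in
#' the analysis model), on top of stationary AR(1) noise spanning the whole
#' session. Blink artefacts are injected as Poisson-spaced gaps whose
#' samples are zeroed and flagged invalid. Trials are laid out baseline
#' window first, then response window (offer onset at `baseline_s` into
#' the trial), with `trial_start`, `offer_onset`, `decision` and `outcome`
#' events emitted per trial.
#'
#' @param design A [pupil_design()] tibble (trial + regressor columns).
#' @param profiles Named list of functions `time_s -> coefficient`; names
#'   must be design columns. See [default_pupil_profiles()].
#' @param noise_sd Stationary SD of the AR(1) noise (0 for noiseless).
#' @param ar1 AR(1) coefficient of the noise process.
#' @param blink_rate Expected blinks per second (0 for none).
#' @param blink_ms Blink duration range (ms).
#' @param fs Sampling rate (Hz).
#' @param baseline_s,response_s Trial layout (s); trial length is their sum.
#' @param seed Optional seed; same seed gives an identical trace.
#' @return A list with `samples` (tibble `time_ms`, `pupil`, `valid`) and
#'   `events` (tibble `trial`, `event_name`, `time_ms`).
#' @export
synth_pupil <- function(design, profiles = default_pupil_profiles(),
                        noise_sd = 0.1, ar1 = 0.95, blink_rate = 0.1,
                        blink_ms = c(100, 300), fs = 500,
                        baseline_s = 7.5, response_s = 4.5, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      synth_pupil(design, profiles, noise_sd, ar1, blink_rate, blink_ms,
                  fs, baseline_s, response_s, seed = NULL)
    ))
  }
  bad <- setdiff(names(profiles), names(design))
  if (length(bad)) {
    stop("profiles name regressors absent from the design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_trials <- nrow(design)
  trial_s <- baseline_s + response_s
  n_per_trial <- round(trial_s * fs)
  n_resp <- round(response_s * fs)
  n_base <- round(baseline_s * fs)
  n_total <- n_trials * n_per_trial
  step_ms <- 1000 / fs
  time_ms <- (seq_len(n_total) - 1) * step_ms

  t_resp <- (seq_len(n_resp) - 1) / fs
  prof_mat <- vapply(profiles, function(f) f(t_resp), numeric(n_resp))

  signal_trace <- numeric(n_total)
  for (i in seq_len(n_trials)) {
    idx <- (i - 1) * n_per_trial + n_base + seq_len(n_resp)
    contrib <- prof_mat %*% as.numeric(design[i, names(profiles)])
    signal_trace[idx] <- contrib
  }

  noise <- numeric(n_total)
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1^2)
    noise <- as.numeric(stats::filter(stats::rnorm(n_total, 0, innov_sd),
                                      ar1, method = "recursive"))
  }
  pupil <- signal_trace + noise
  valid <- rep(1L, n_total)
  if (blink_rate > 0) {
    n_blinks <- stats::rpois(1, blink_rate * n_total / fs)
    if (n_blinks > 0) {
      starts <- sort(sample.int(n_total, n_blinks))
      durs <- round(stats::runif(n_blinks, blink_ms[1], blink_ms[2]) / step_ms)
      for (b in seq_len(n_blinks)) {
        idx <- starts[b]:min(starts[b] + durs[b] - 1, n_total)
        valid[idx] <- 0L
        pupil[idx] <- 0
      }
    }
  }
  events <- purrr::map_dfr(seq_len(n_trials), function(i) {
    t0 <- (i - 1) * trial_s * 1000
    tibble::tibble(
      trial = design$trial[i],
      event_name = c("trial_start", "offer_onset", "decision", "outcome"),
      time_ms = t0 + c(0, baseline_s, baseline_s + 1.5, baseline_s + 3) * 1000
    )
  })
  list(
    samples = tibble::tibble(time_ms = time_ms, pupil = pupil, valid = valid),
    events = events
  )
}
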