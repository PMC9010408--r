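# Text-format readers/writers and the end-to-end pipeline driver. All
# artefacts are plain CSV/TSV with mandatory headers and validated schemas;
# offers are stored in pence as integers, valence as decimals.

session_cols <- c("trial", "block", "face_index", "phi", "offer_pence",
                  "other_pence", "choice", "outcome_self", "outcome_other",
                  "reaction_face_index", "rt_ms")

#' Read and write session logs
#'
#' One row per trial with the mandatory header
#' `trial,block,face_index,phi,offer_pence,other_pence,choice,outcome_self,
#' outcome_other,reaction_face_index,rt_ms`. Validation on read enforces
#' the schema: binary choices, complementary pence amounts, and outcomes
#' consistent with the choice; violations name the offending row. Missing
#' reaction times are empty fields.
#'
#' @param path File path.
#' @return `read_session()` returns a validated session tibble;
#'   `write_session()` returns `path` invisibly.
#' @export
read_session <- function(path) {
  s <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      trial = "i", block = "i", face_index = "i", phi = "d",
      offer_pence = "i", other_pence = "i", choice = "d",
      outcome_self = "i", outcome_other = "i",
      reaction_face_index = "i", rt_ms = "d"
    )
  )
  missing <- setdiff(session_cols, names(s))
  if (length(missing)) {
    stop("session file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- s[session_cols]
  bad <- which(!(s$choice %in% c(0, 1)))
  if (length(bad)) {
    stop("invalid choice (must be 0/1) at row ", bad[1], call. = FALSE)
  }
  bad <- which(s$offer_pence + s$other_pence !=
                 s$offer_pence[1] + s$other_pence[1])
  if (length(bad)) {
    stop("offer_pence + other_pence is not constant at row ", bad[1],
         call. = FALSE)
  }
  bad <- which(s$outcome_self != s$offer_pence * s$choice |
                 s$outcome_other != s$other_pence * s$choice)
  if (length(bad)) {
    stop("outcomes inconsistent with choice at row ", bad[1], call. = FALSE)
  }
  s
}

#' @rdname read_session
#' @param session Session tibble.
#' @export
write_session <- function(session, path) {
  readr::write_csv(session[session_cols], path, na = "")
  invisible(path)
}

#' Read and write Likert rating tables
#'
#' Schema: `stimulus_type` (`face`/`offer`), `phi`, `R_S`, `R_O`,
#' `repetition`, `likert` (integer 1-9).
#'
#' @param path File path.
#' @return `read_ratings()` returns a validated tibble.
#' @export
read_ratings <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("stimulus_type", "phi", "R_S", "R_O", "repetition", "likert")
  missing <- setdiff(need, names(r))
  if (length(missing)) {
    stop("ratings file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(r$likert %in% 1:9))
  if (length(bad)) {
    stop("likert outside 1..9 at row ", bad[1], call. = FALSE)
  }
  r
}

#' @rdname read_ratings
#' @param ratings Ratings tibble.
#' @export
write_ratings <- function(ratings, path) {
  readr::write_csv(ratings, path, na = "")
  invisible(path)
}

#' Read and write raw pupil sample streams and event tables
#'
#' Samples are TSV with columns `time_ms`, `pupil`, `valid` (0/1); events
#' are CSV with `trial`, `event_name`, `time_ms`.
#'
#' @param path File path.
#' @return Tibbles in the respective schemas.
#' @export
read_pupil_samples <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("time_ms", "pupil", "valid")
  missing <- setdiff(need, names(s))
  if (length(missing)) {
    stop("samples file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s
}

#' @rdname read_pupil_samples
#' @param samples Samples tibble.
#' @export
write_pupil_samples <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname read_pupil_samples
#' @export
read_events <- function(path) {
  e <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("trial", "event_name", "time_ms")
  missing <- setdiff(need, names(e))
  if (length(missing)) {
    stop("events file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e
}

#' @rdname read_pupil_samples
#' @param events Events tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Serialise a model fit to JSON
#'
#' Stores the estimates, fit statistics and (optionally) the joint
#' posterior of a `ug_fit` in a plain JSON file.
#'
#' @param fit A `ug_fit` object.
#' @param path Output path.
#' @param posterior Include the posterior grid table.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, posterior = FALSE) {
  payload <- list(
    model = fit$model, name = fit$name,
    estimates = as.list(fit$estimates),
    logLik = fit$logLik, k = fit$k, n = fit$n,
    bic = fit$bic, accuracy = fit$accuracy
  )
  if (posterior && !is.null(fit$posterior)) {
    payload$posterior <- fit$posterior
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    n_participants = 5,
    n_blocks = 6,
    trials_per_block = 40,
    model = 10,
    fit_models = c(4, 10),
    n_points = 21,
    n_beta = 21,
    rating_noise_sd = 0.5,
    mu = 0.4,
    run_pupil = FALSE,
    pupil_noise_sd = 0.05,
    pupil_blink_rate = 0.05,
    seed = 1
  )
}

#' Run the full synthetic study end-to-end
#'
#' Composes the whole pipeline on a synthetic cohort: draw ground truth and
#' covariates, generate rating tables and fit the perception models,
#' simulate closed-loop sessions, fit the requested decision models by
#' grid Bayes, perform model selection, compute the model-free behavioural
#' statistics, and (optionally) generate and analyse synthetic pupil data
#' for each participant. Fully deterministic given `config$seed`.
#'
#' @param config Named list overriding entries of the default
#'   configuration: `n_participants`, `n_blocks`, `trials_per_block`,
#'   `model` (generative id), `fit_models` (ids to fit and compare),
#'   `n_points`/`n_beta` (grid resolutions), `rating_noise_sd`, `mu`,
#'   `run_pupil`, `pupil_noise_sd`, `pupil_blink_rate`, `seed`. Unknown
#'   keys are rejected.
#' @return A named list (report bundle): `config`, `cohort`, `ratings`,
#'   `perception` (per-participant weighting/liking estimates), `sessions`,
#'   `fits`, `selection`, `acceptance`, `main_effects`, `history`,
#'   `accuracy` (per participant and mean), and `pupil` (when enabled).
#' @export
run_pipeline <- function(config = list()) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$n_participants < 1) {
    stop("config must request at least one participant", call. = FALSE)
  }
  beta_grid <- default_beta_grid(cfg$n_beta)

  cohort <- synth_cohort(cfg$n_participants, model = cfg$model,
                         seed = cfg$seed)
  ratings <- purrr::map(seq_len(cfg$n_participants), function(i) {
    p <- cohort$truth[i, ]
    synth_ratings(p$delta, p$gamma, noise_sd = cfg$rating_noise_sd,
                  seed = cfg$seed + 1000 + i)
  })
  perception <- purrr::map_dfr(seq_len(cfg$n_participants), function(i) {
    faces <- dplyr::filter(ratings[[i]], .data$stimulus_type == "face")
    offers <- dplyr::filter(ratings[[i]], .data$stimulus_type == "offer")
    w <- fit_weighting(faces)
    l <- fit_liking(offers)
    tibble::tibble(participant = i, delta = w$delta, gamma = w$gamma,
                   phi0 = l$phi0, phi1 = l$phi1, phi2 = l$phi2)
  })
  sessions <- synth_sessions(cohort, n_blocks = cfg$n_blocks,
                             trials_per_block = cfg$trials_per_block,
                             mu = cfg$mu, seed = cfg$seed)
  fits <- purrr::map(seq_len(cfg$n_participants), function(i) {
    s <- sessions[[i]]
    eps <- prelec_weight(s$phi, perception$delta[i], perception$gamma[i])
    liking <- as.list(perception[i, c("phi0", "phi1", "phi2")])
    base4 <- fit_model(s, eps, model = 4, n_points = cfg$n_points,
                       beta_grid = beta_grid, mu = cfg$mu,
                       store_posterior = FALSE)
    purrr::map(cfg$fit_models, function(m) {
      if (m == 4) return(base4)
      fit_model(s, eps, model = m, n_points = cfg$n_points,
                beta_grid = beta_grid, mu = cfg$mu, liking = liking,
                base_params = list(kappa = unname(base4$estimates["kappa"]),
                                   omega = unname(base4$estimates["omega"])),
                store_posterior = FALSE)
    })
  })
  selection <- if (length(cfg$fit_models) > 1) {
    select_models(fits, seed = cfg$seed)
  }
  grids <- acceptance_grid(sessions)
  main_effects <- main_effects_ols(grids)
  history <- purrr::map_dfr(seq_along(sessions), function(i) {
    dplyr::mutate(history_logistic(sessions[[i]]), participant = i)
  })
  acc <- purrr::map_dbl(fits, function(f) {
    f[[which(cfg$fit_models == cfg$model)]]$accuracy
  })
  bundle <- list(
    config = cfg, cohort = cohort, ratings = ratings,
    perception = perception, sessions = sessions, fits = fits,
    selection = selection, acceptance = grids,
    main_effects = main_effects, history = history,
    accuracy = list(per_participant = acc, mean = mean(acc))
  )
  if (isTRUE(cfg$run_pupil)) {
    bundle$pupil <- purrr::map(seq_along(sessions), function(i) {
      s <- sessions[[i]]
      idx <- which(cfg$fit_models == cfg$model)
      filt <- session_filter_regressors(s)
      des <- pupil_design(s, fits[[i]][[idx]], filt,
                          epsilons = prelec_weight(s$phi,
                                                   perception$delta[i],
                                                   perception$gamma[i]),
                          mu = cfg$mu)
      raw <- synth_pupil(des, noise_sd = cfg$pupil_noise_sd,
                         blink_rate = cfg$pupil_blink_rate,
                         seed = cfg$seed + 2000 + i)
      ep <- pupil_preprocess(raw$samples, raw$events)
      list(design = des, epochs = ep,
           regression = timepoint_regression(ep, des))
    })
  }
  bundle
}
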