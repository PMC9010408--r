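#' Preprocess a raw pupil trace into per-trial epochs
#'
#' Standard pupillometry preprocessing: samples flagged invalid (blinks,
#' tracker dropouts) are linearly interpolated; the trace is low-pass
#' filtered with a zero-phase (forward-backward) Butterworth filter and
#' z-transformed across the session; per-trial epochs are extracted around
#' offer onset and baseline-corrected by subtracting the mean of the
#' pre-offer baseline window. Trials in which more than half of the
#' outcome-period samples were interpolated are flagged for exclusion.
#'
#' @param samples Tibble with columns `time_ms` (monotone, nominally 2 ms
#'   spacing), `pupil`, `valid` (0/1).
#' @param events Tibble with columns `trial`, `event_name`, `time_ms`;
#'   epoching keys on the `offer_onset` event of each trial.
#' @param fs Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz).
#' @param order Butterworth order (applied forward-backward).
#' @param baseline_s Baseline window length before offer onset (s).
#' @param response_s Response window length after offer onset (s).
#' @param outcome_window Start/end of the outcome period, seconds after
#'   offer onset; the exclusion rule applies to this span.
#' @param exclude_threshold Maximum tolerated interpolated fraction of the
#'   outcome period.
#' @param filter,z_transform Stage toggles, both on by default (the
#'   analysis pipeline). Turning the z-transform off keeps the trace in its
#'   original units, which is what amplitude-exact recovery validation of
#'   injected coefficient profiles requires.
#' @param keep_baseline Also return the baseline-window samples (corrected
#'   by the same per-trial baseline mean) as matrix `baseline`.
#' @return An object of class `pupil_epochs`: list with `response` (matrix
#'   trials x timepoints of baseline-corrected samples), `times_s`
#'   (timepoints relative to offer onset), `info` (per-trial tibble:
#'   `trial`, `interp_frac_outcome`, `included`, `baseline_n`), and the
#'   preprocessing parameters.
#' @export
pupil_preprocess <- function(samples, events, fs = 500, cutoff = 3.75,
                             order = 3, baseline_s = 7.5, response_s = 4.5,
                             outcome_window = c(3.0, 4.5),
                             exclude_threshold = 0.5,
                             filter = TRUE, z_transform = TRUE,
                             keep_baseline = FALSE) {
  stopifnot(all(c("time_ms", "pupil", "valid") %in% names(samples)))
  stopifnot(all(c("trial", "event_name", "time_ms") %in% names(events)))
  tm <- samples$time_ms
  if (is.unsorted(tm, strictly = TRUE)) {
    stop("sample timestamps must be strictly increasing", call. = FALSE)
  }
  x <- samples$pupil
  valid <- samples$valid == 1
  n <- length(x)
  if (mean(!valid) > 0.5) {
    stop("more than 50% of the session is missing (",
         round(100 * mean(!valid), 1), "% invalid samples)", call. = FALSE)
  }
  # linear interpolation over invalid samples (edge values extended)
  if (any(!valid)) {
    x[!valid] <- stats::approx(tm[valid], x[valid], xout = tm[!valid],
                               rule = 2)$y
  }
  # zero-phase low-pass, then session-wide z-transform; a constant trace
  # is left untouched (filter transients would otherwise fabricate signal)
  xf <- x
  if (filter && stats::sd(x) > 0) {
    bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
    xf <- signal::filtfilt(bf, x)
  }
  xz <- xf
  if (z_transform) {
    s <- stats::sd(xf)
    if (s == 0) {
      warning("constant pupil trace; z-transform set to 0", call. = FALSE)
      xz <- rep(0, n)
    } else {
      xz <- (xf - mean(xf)) / s
    }
  }

  offers <- events |>
    dplyr::filter(.data$event_name == "offer_onset") |>
    dplyr::arrange(.data$trial)
  if (nrow(offers) == 0) stop("no offer_onset events", call. = FALSE)
  if (any(offers$time_ms < tm[1] | offers$time_ms > tm[n])) {
    stop("offer_onset events fall outside the sample range", call. = FALSE)
  }
  step_ms <- 1000 / fs
  n_resp <- round(response_s * fs)
  n_base <- round(baseline_s * fs)
  times_s <- (seq_len(n_resp) - 1) / fs

  resp <- matrix(NA_real_, nrow(offers), n_resp)
  base <- if (keep_baseline) matrix(NA_real_, nrow(offers), n_base)
  info <- tibble::tibble(
    trial = offers$trial, interp_frac_outcome = NA_real_,
    included = NA, baseline_n = NA_integer_
  )
  out_idx <- (round(outcome_window[1] * fs) + 1):min(round(outcome_window[2] * fs), n_resp)
  for (i in seq_len(nrow(offers))) {
    i0 <- round((offers$time_ms[i] - tm[1]) / step_ms) + 1
    ridx <- i0:(i0 + n_resp - 1)
    if (max(ridx) > n) {
      stop("response window of trial ", offers$trial[i],
           " extends beyond the recording", call. = FALSE)
    }
    bidx <- max(1, i0 - n_base):(i0 - 1)
    base_mean <- mean(xz[bidx])
    resp[i, ] <- xz[ridx] - base_mean
    if (keep_baseline) {
      base[i, ] <- c(rep(NA_real_, n_base - length(bidx)),
                     xz[bidx] - base_mean)
    }
    frac <- mean(!valid[ridx[out_idx]])
    info$interp_frac_outcome[i] <- frac
    info$included[i] <- frac <= exclude_threshold
    info$baseline_n[i] <- length(bidx)
  }
  structure(
    list(response = resp, baseline = if (keep_baseline) base,
         times_s = times_s, info = info,
         fs = fs, cutoff = cutoff, order = order,
         baseline_s = baseline_s, response_s = response_s,
         outcome_window = outcome_window),
    class = "pupil_epochs"
  )
}

#' @export
print.pupil_epochs <- function(x, ...) {
  cat("Pupil epochs:", nrow(x$response), "trials x", ncol(x$response),
      "timepoints (", x$fs, "Hz );", sum(x$info$included), "included\n")
  invisible(x)
}

#' Trial-wise design matrix for the pupil regression
#'
#' Builds the eleven regressors of the time-resolved pupil model: a
#' constant; the trial index (a fatigue proxy); the subjective self-reward
#' value \eqn{\hat\kappa R_S} under the best-fitting decision model; the
#' emotion-modulated inequality weight \eqn{\hat\omega +
#' (\varepsilon-\mu)^2}; the inequality magnitude \eqn{|R_S - R_O|}; and
#' the surprise, volatility and noise regressors of the Bayesian filter for
#' both the offer and the face stream. All regressors except the constant
#' are demeaned. Monetary terms are on the pound scale of the decision
#' model.
#'
#' @param session Session tibble.
#' @param fit A `ug_fit` of the parabolic inequality-modulation model
#'   (model 10), supplying `kappa` and `omega`.
#' @param filter_regressors Output of [session_filter_regressors()].
#' @param epsilons Per-trial perceived valence (defaults to the true
#'   valence `session$phi`).
#' @param mu Perceptual crossover constant.
#' @return A tibble with `trial` plus the 11 regressor columns `constant`,
#'   `trial_index`, `value_self`, `emo_inequality`, `inequality`,
#'   `surprise_offer`, `surprise_face`, `vol_offer`, `vol_face`,
#'   `noise_offer`, `noise_face`.
#' @export
pupil_design <- function(session, fit, filter_regressors,
                         epsilons = session$phi, mu = 0.4) {
  kappa <- unname(fit$estimates["kappa"])
  omega <- unname(fit$estimates["omega"])
  d <- tibble::tibble(
    trial = session$trial,
    constant = 1,
    trial_index = session$trial,
    value_self = kappa * session$offer_pence / 100,
    emo_inequality = omega + (epsilons - mu)^2,
    inequality = abs(session$offer_pence - session$other_pence) / 100
  ) |>
    dplyr::left_join(
      dplyr::select(filter_regressors, "trial", "surprise_offer",
                    "surprise_face", "vol_offer", "vol_face",
                    "noise_offer", "noise_face"),
      by = "trial"
    )
  d |>
    dplyr::mutate(dplyr::across(-c("trial", "constant"),
                                ~ .x - mean(.x)))
}

#' Time-resolved OLS of pupil size on the trial-wise design
#'
#' Fits the regression separately at every timepoint of the response
#' window, across included trials, exactly as in an event-related
#' fMRI-style analysis: one closed-form normal-equation solve yields the
#' full coefficient-by-timepoint matrix.
#'
#' @param epochs A [pupil_preprocess()] object.
#' @param design A [pupil_design()] tibble (one row per trial of the
#'   session; rows are matched to epochs by `trial`).
#' @param min_trials Minimum included trials; fewer triggers a flag.
#' @return Object of class `pupil_regression`: list with `coefficients`
#'   (matrix terms x timepoints), `times_s`, `terms`, `n_trials`,
#'   `flagged` (`TRUE` when `n_trials < min_trials`). Supports `tidy()`
#'   and `autoplot()`.
#' @export
timepoint_regression <- function(epochs, design, min_trials = 10) {
  keep <- epochs$info$included
  trials <- epochs$info$trial[keep]
  rows <- match(trials, design$trial)
  if (anyNA(rows)) stop("design is missing trials present in the epochs",
                        call. = FALSE)
  X <- as.matrix(design[rows, setdiff(names(design), "trial")])
  Y <- epochs$response[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < ncol(X)) {
    stop("fewer included trials (", n, ") than regressors (", ncol(X), ")",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient pupil design (e.g. a session never visiting ",
            "offers above the even split makes the self-reward and ",
            "inequality regressors collinear); aliased regressors get NA",
            call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  rownames(B) <- colnames(X)
  structure(
    list(coefficients = B, times_s = epochs$times_s, terms = colnames(X),
         n_trials = n, flagged = n < min_trials),
    class = "pupil_regression"
  )
}

#' @export
print.pupil_regression <- function(x, ...) {
  cat("Time-resolved pupil regression:", length(x$terms), "regressors x",
      length(x$times_s), "timepoints,", x$n_trials, "trials",
      if (x$flagged) "(FLAGGED: few trials)" else "", "\n")
  invisible(x)
}

#' @export
tidy.pupil_regression <- function(x, ...) {
  tibble::as_tibble(t(x$coefficients)) |>
    dplyr::mutate(time_s = x$times_s, .before = 1) |>
    tidyr::pivot_longer(-"time_s", names_to = "term", values_to = "estimate")
}

#' Binned group t-tests on pupil coefficient time series
#'
#' Averages each participant's coefficient series within consecutive time
#' bins (default 1 s) after offer onset, then tests each bin's group mean
#' against zero with a one-sample t-test, per regressor. Bins are reported
#' uncorrected with the bin count stated; a single-participant cohort
#' yields undefined t and is flagged.
#'
#' @param regressions List of `pupil_regression` objects (one per
#'   participant), on a common time grid.
#' @param bin_s Bin width in seconds.
#' @return A tibble with `term`, `bin` (index), `bin_start_s`, `mean`,
#'   `t`, `df`, `p_value`, `n_bins`, `flagged`.
#' @export
pupil_binned_ttests <- function(regressions, bin_s = 1) {
  stopifnot(length(regressions) >= 1)
  times <- regressions[[1]]$times_s
  terms <- regressions[[1]]$terms
  bins <- floor(times / bin_s) + 1
  n_bins <- max(bins)
  per_subj <- purrr::map_dfr(seq_along(regressions), function(i) {
    B <- regressions[[i]]$coefficients
    purrr::map_dfr(seq_len(n_bins), function(b) {
      tibble::tibble(
        participant = i, term = terms, bin = b,
        estimate = rowMeans(B[, bins == b, drop = FALSE])
      )
    })
  })
  n_subj <- length(regressions)
  per_subj |>
    dplyr::group_by(.data$term, .data$bin) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sd = stats::sd(.data$estimate),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_start_s = (.data$bin - 1) * bin_s,
      t = dplyr::case_when(
        n_subj <= 1 ~ NA_real_,
        .data$sd > 0 ~ .data$mean / (.data$sd / sqrt(n_subj)),
        .data$mean == 0 ~ 0,
        TRUE ~ sign(.data$mean) * Inf
      ),
      df = n_subj - 1,
      p_value = ifelse(is.na(.data$t), NA_real_,
                       2 * stats::pt(-abs(.data$t), df = n_subj - 1)),
      n_bins = n_bins,
      flagged = n_subj < 2
    )
}
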