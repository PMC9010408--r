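#' Two-parameter probability weighting of facial valence
#'
#' Perceived valence of a displayed face follows the Prelec two-parameter
#' weighting function
#' \deqn{\varepsilon = \exp(-\delta(-\ln \varphi)^{\gamma})}
#' where `phi` is the true valence of the face on a (0, 1) scale. `delta`
#' and `gamma` jointly control the curvature of the mapping and where it
#' crosses the identity diagonal; `delta = gamma = 1` is the identity.
#'
#' @param phi True valence, strictly inside (0, 1). Vectorised.
#' @param delta,gamma Positive curvature parameters.
#' @return Perceived valence in (0, 1).
#' @examples
#' prelec_weight(0.5, 1, 1) # 0.5
#' @export
prelec_weight <- function(phi, delta, gamma) {
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= 1)) {
    stop("phi must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(delta <= 0) || any(gamma <= 0)) {
    stop("delta and gamma must be positive", call. = FALSE)
  }
  exp(-delta * (-log(phi))^gamma)
}

weighting_sse <- function(par, phi, y) {
  sum((prelec_weight(phi, par[1], par[2]) - y)^2)
}

#' Fit the valence weighting function to face ratings
#'
#' Least-squares fit of [prelec_weight()] to Likert ratings of face stimuli.
#' Ratings (1-9) are divided by 10 so that ratings and model predictions
#' share the (0, 1) scale. The objective is minimised by bounded
#' quasi-Newton optimisation from a lattice of log-spaced starting values
#' (best-of-starts), making the fit reproducible.
#'
#' @param ratings A data frame of face ratings with columns `phi` (true
#'   valence) and `likert` (integer 1-9), one row per presentation, e.g.
#'   the face rows of [synth_ratings()].
#' @param bounds Length-2 numeric: lower and upper box bounds for both
#'   `delta` and `gamma`.
#' @param n_starts Starts per parameter; the start lattice is
#'   `n_starts^2` log-spaced points inside `bounds`.
#' @param average_repetitions If `TRUE`, fit the per-`phi` mean rating
#'   instead of all presentations jointly.
#' @return An object of class `weighting_fit`: list with `delta`, `gamma`,
#'   `sse`, `fitted` tibble, `n`, `convergence` and a `degenerate` flag.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_weighting <- function(ratings, bounds = c(0.01, 5), n_starts = 5,
                          average_repetitions = FALSE) {
  stopifnot(all(c("phi", "likert") %in% names(ratings)))
  dat <- tibble::tibble(phi = ratings$phi, y = ratings$likert / 10)
  if (average_repetitions) {
    dat <- dat |>
      dplyr::group_by(.data$phi) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
  }
  if (dplyr::n_distinct(dat$phi) < 2) {
    stop("need ratings at two or more distinct phi values", call. = FALSE)
  }
  degenerate <- stats::sd(dat$y) == 0
  if (degenerate) {
    warning("all ratings identical; weighting fit is degenerate", call. = FALSE)
  }
  starts <- exp(seq(log(bounds[1] * 1.5), log(bounds[2] / 1.5),
                    length.out = n_starts))
  grid <- expand.grid(delta = starts, gamma = starts)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- stats::optim(
      par = as.numeric(grid[i, ]), fn = weighting_sse,
      phi = dat$phi, y = dat$y,
      method = "L-BFGS-B", lower = bounds[1], upper = bounds[2],
      control = list(factr = 1e-9 / .Machine$double.eps, maxit = 500)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(
    list(
      delta = best$par[1], gamma = best$par[2], sse = best$value,
      fitted = tibble::tibble(
        phi = dat$phi, rating = dat$y,
        epsilon = prelec_weight(dat$phi, best$par[1], best$par[2])
      ),
      n = nrow(dat), convergence = best$convergence,
      degenerate = degenerate, bounds = bounds
    ),
    class = "weighting_fit"
  )
}

#' @export
print.weighting_fit <- function(x, ...) {
  cat("Valence weighting fit: delta =", format(x$delta, digits = 4),
      ", gamma =", format(x$gamma, digits = 4),
      " (SSE", format(x$sse, digits = 4), "on", x$n, "ratings)\n")
  invisible(x)
}

#' @export
tidy.weighting_fit <- function(x, ...) {
  tibble::tibble(term = c("delta", "gamma"), estimate = c(x$delta, x$gamma))
}

#' @export
glance.weighting_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, nobs = x$n, degenerate = x$degenerate)
}

#' Fit the liking regression for Ultimatum offers
#'
#' Models Likert liking ratings of offers as a linear function of the
#' self-reward amount and the absolute self-other inequality:
#' \deqn{\chi = \phi_0 + \phi_1 R_S + \phi_2 |R_S - R_O|}
#' The other's amount never enters separately: with a fixed pot all
#' monetary information is carried by the self-reward and the inequality
#' magnitude. Fitted by ordinary least squares.
#'
#' @param ratings Data frame with columns `R_S`, `R_O` (pence) and `likert`.
#' @return An object of class `liking_fit` wrapping the [stats::lm()] fit,
#'   with named coefficients `phi0`, `phi1`, `phi2` (Likert units; per
#'   pence for the slopes). Supports `tidy()`, `glance()` and `predict()`.
#' @export
fit_liking <- function(ratings) {
  stopifnot(all(c("R_S", "R_O", "likert") %in% names(ratings)))
  dat <- tibble::tibble(
    likert = ratings$likert,
    R_S = ratings$R_S,
    inequality = abs(ratings$R_S - ratings$R_O)
  )
  X <- cbind(1, dat$R_S, dat$inequality)
  if (qr(X)$rank < 3 && stats::sd(dat$likert) > 0) {
    stop("rank-deficient design: need variation in both R_S and |R_S - R_O|",
         call. = FALSE)
  }
  fit <- stats::lm(likert ~ R_S + inequality, data = dat)
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  structure(
    list(phi0 = unname(co[1]), phi1 = unname(co[2]), phi2 = unname(co[3]),
         lm = fit, n = nrow(dat)),
    class = "liking_fit"
  )
}

#' @export
print.liking_fit <- function(x, ...) {
  cat("Offer liking fit: chi = ", format(x$phi0, digits = 4), " + ",
      format(x$phi1, digits = 4), " R_S + ",
      format(x$phi2, digits = 4), " |R_S - R_O|  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.liking_fit <- function(x, ...) {
  out <- generics::tidy(x$lm, ...)
  out$term <- c("phi0", "phi1", "phi2")[seq_len(nrow(out))]
  out
}

#' @export
glance.liking_fit <- function(x, ...) generics::glance(x$lm, ...)

#' @export
predict.liking_fit <- function(object, R_S, R_O, ...) {
  object$phi0 + object$phi1 * R_S + object$phi2 * abs(R_S - R_O)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
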