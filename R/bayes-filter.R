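#' Gaussian surprise of an observation
#'
#' Surprise is the negative log probability of the observation under a
#' Gaussian predictive distribution:
#' \eqn{-\ln \mathcal N(y;\, \mu, \sigma)}. Observations that violate the
#' observer's expectations yield larger surprise.
#'
#' @param observation Observed value(s).
#' @param mean,sd Predictive mean and standard deviation.
#' @return Surprise (nats).
#' @export
gaussian_surprise <- function(observation, mean, sd) {
  -stats::dnorm(observation, mean, sd, log = TRUE)
}

# Column-stochastic random-walk transition matrix on the mean grid for one
# volatility node: T[i, j] = P(m_t = node_i | m_{t-1} = node_j).
diffusion_matrix <- function(mean_nodes, vol) {
  Tm <- outer(mean_nodes, mean_nodes,
              function(to, from) stats::dnorm(to, from, vol))
  sweep(Tm, 2, colSums(Tm), `/`)
}

#' Recursive Bayesian filter over a stimulus stream
#'
#' Tracks the hidden generative statistics of a scalar observation stream
#' with a grid-based Bayesian observer: a latent mean that diffuses between
#' trials with standard deviation equal to the (unknown, static)
#' environmental volatility, observed through Gaussian noise of unknown
#' standard deviation. The joint posterior over (latent mean, volatility,
#' noise) is propagated on a fixed 3-D grid by exact predict-update cycles.
#' Each trial yields the posterior-mean volatility and noise and the
#' surprise, i.e. the negative log of the grid-marginal predictive density
#' of the observation (a mixture over all nodes, not a single-node
#' plug-in).
#'
#' @param observations Finite numeric vector (e.g. offers in pounds or
#'   face valences).
#' @param n_mean,n_vol,n_noise Grid sizes. The mean axis spans the
#'   observation range widened by 20% on each side; volatility and noise
#'   axes are log-spaced between 1% and 100% of the mean-axis span.
#' @param mean_nodes,vol_nodes,noise_nodes Explicit grid nodes, overriding
#'   the automatic axes (used for small-grid oracle checks).
#' @param keep_posterior If `TRUE`, attach the per-trial posterior arrays
#'   (`dim = c(n_mean, n_vol, n_noise)`) as attribute `"posteriors"`.
#' @return A tibble with one row per trial: `trial`, `observation`,
#'   `pred_mean`, `pred_sd` (moments of the predictive distribution of the
#'   observation), `surprise`, `vol`, `noise` (posterior means).
#' @examples
#' f <- filter_stream(c(5, 5, 5, 9))
#' f$surprise[4] > f$surprise[3] # the jump is surprising
#' @export
filter_stream <- function(observations, n_mean = 61, n_vol = 21, n_noise = 21,
                          mean_nodes = NULL, vol_nodes = NULL,
                          noise_nodes = NULL, keep_posterior = FALSE) {
  if (length(observations) < 1 || any(!is.finite(observations))) {
    stop("observations must be a non-empty finite numeric vector", call. = FALSE)
  }
  rng <- range(observations)
  span <- max(diff(rng), 1e-3)
  if (is.null(mean_nodes)) {
    mean_nodes <- seq(rng[1] - 0.2 * span, rng[2] + 0.2 * span,
                      length.out = n_mean)
  }
  grid_span <- max(diff(range(mean_nodes)), 1e-3)
  if (is.null(vol_nodes)) {
    vol_nodes <- exp(seq(log(0.01 * grid_span), log(grid_span),
                         length.out = n_vol))
  }
  if (is.null(noise_nodes)) {
    noise_nodes <- exp(seq(log(0.01 * grid_span), log(grid_span),
                           length.out = n_noise))
  }
  n_m <- length(mean_nodes)
  n_v <- length(vol_nodes)
  n_n <- length(noise_nodes)

  Tv <- lapply(vol_nodes, function(v) diffusion_matrix(mean_nodes, v))
  post <- array(1 / (n_m * n_v * n_n), dim = c(n_m, n_v, n_n))
  posteriors <- if (keep_posterior) vector("list", length(observations))

  n_t <- length(observations)
  out <- tibble::tibble(
    trial = seq_len(n_t), observation = observations,
    pred_mean = NA_real_, pred_sd = NA_real_, surprise = NA_real_,
    vol = NA_real_, noise = NA_real_
  )
  for (t in seq_len(n_t)) {
    # predict: diffuse the latent mean (no diffusion before the first obs)
    pred <- post
    if (t > 1) {
      for (v in seq_len(n_v)) {
        pred[, v, ] <- Tv[[v]] %*% matrix(post[, v, ], n_m, n_n)
      }
    }
    y <- observations[t]
    # observation likelihood, shared across volatility nodes
    Lmn <- outer(mean_nodes, noise_nodes, function(m, s) stats::dnorm(y, m, s))
    L <- aperm(array(Lmn, dim = c(n_m, n_n, n_v)), c(1, 3, 2))

    # predictive moments and surprise from the grid-marginal mixture
    w_m <- apply(pred, 1, sum)
    ey <- sum(w_m * mean_nodes)
    w_n <- apply(pred, 3, sum)
    vy <- sum(w_m * mean_nodes^2) - ey^2 + sum(w_n * noise_nodes^2)
    dens <- sum(pred * L)
    out$pred_mean[t] <- ey
    out$pred_sd[t] <- sqrt(vy)
    out$surprise[t] <- -log(dens)

    # update
    post <- pred * L
    post <- post / sum(post)
    out$vol[t] <- sum(apply(post, 2, sum) * vol_nodes)
    out$noise[t] <- sum(apply(post, 3, sum) * noise_nodes)
    if (keep_posterior) posteriors[[t]] <- post
  }
  if (keep_posterior) attr(out, "posteriors") <- posteriors
  out
}

#' Trial-wise filter regressors for a session
#'
#' Runs [filter_stream()] independently on the offer stream (rescaled to
#' pounds) and on the face-valence stream of a session, returning the six
#' regressors used by the time-resolved pupil model: surprise, volatility
#' and noise for each stream.
#'
#' @param session A session tibble.
#' @param ... Passed to [filter_stream()] (grid sizes).
#' @return A tibble with `trial`, `surprise_offer`, `surprise_face`,
#'   `vol_offer`, `vol_face`, `noise_offer`, `noise_face`.
#' @export
session_filter_regressors <- function(session, ...) {
  f_offer <- filter_stream(session$offer_pence / 100, ...)
  f_face <- filter_stream(session$phi, ...)
  tibble::tibble(
    trial = session$trial,
    surprise_offer = f_offer$surprise,
    surprise_face = f_face$surprise,
    vol_offer = f_offer$vol,
    vol_face = f_face$vol,
    noise_offer = f_offer$noise,
    noise_face = f_face$noise
  )
}
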