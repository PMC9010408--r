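#' Define the joint face-by-offer stimulus space
#'
#' The iterative Ultimatum Game presents a proposer face drawn from an
#' ordered set of emotional expressions together with an offer splitting a
#' fixed pot. Faces carry a true valence `phi` on a probability-like scale;
#' offers are pence amounts on a regular grid. The default space has 9 faces
#' (valence 0.1 to 0.9 in steps of 0.1) and 19 offers (50 to 950 pence in
#' steps of 50 out of a 1000 pence pot), giving 171 joint stimulus states.
#'
#' @param n_faces Number of face levels; valences are placed uniformly on
#'   `(0, 1)` at `k / (n_faces + 1)`.
#' @param offer_min,offer_max,offer_step Offer grid in pence.
#' @param pot Total amount to be split, in pence.
#'
#' @return An object of class `ug_state_space`: a list with `faces` (tibble
#'   of `face_index`, `phi`), `offers` (integer vector of pence amounts),
#'   `pot`, and `n_states`. Enumeration order of the joint space is
#'   face-major: state `(f, o)` has linear index `(f - 1) * n_offers + o`.
#' @examples
#' sp <- ug_state_space()
#' sp$n_states # 171
#' @export
ug_state_space <- function(n_faces = 9, offer_min = 50, offer_max = 950,
                           offer_step = 50, pot = 1000) {
  stopifnot(n_faces >= 1, offer_step > 0)
  if (offer_max > pot) {
    stop("offer_max (", offer_max, ") exceeds the pot (", pot, ")", call. = FALSE)
  }
  if (offer_min <= 0 || offer_min > offer_max) {
    stop("offer grid must satisfy 0 < offer_min <= offer_max", call. = FALSE)
  }
  if ((offer_max - offer_min) %% offer_step != 0) {
    stop("offer_step must divide offer_max - offer_min", call. = FALSE)
  }
  offers <- as.integer(seq(offer_min, offer_max, by = offer_step))
  faces <- tibble::tibble(
    face_index = seq_len(n_faces),
    phi = seq_len(n_faces) / (n_faces + 1)
  )
  structure(
    list(
      faces = faces,
      offers = offers,
      pot = as.integer(pot),
      n_states = n_faces * length(offers)
    ),
    class = "ug_state_space"
  )
}

#' @export
print.ug_state_space <- function(x, ...) {
  cat("Ultimatum Game state space:", nrow(x$faces), "faces x",
      length(x$offers), "offers =", x$n_states, "joint states\n")
  cat("  face valence:", format(min(x$faces$phi)), "..", format(max(x$faces$phi)), "\n")
  cat("  offers (pence):", min(x$offers), "..", max(x$offers),
      "step", diff(x$offers[1:2]), "; pot", x$pot, "\n")
  invisible(x)
}

validate_move_row <- function(row, what) {
  if (!is.numeric(row) || length(row) != 3L || anyNA(row)) {
    stop(what, " row must be 3 numeric probabilities (step -1, stay, step +1)",
         call. = FALSE)
  }
  if (any(row < 0)) stop(what, " row has negative mass", call. = FALSE)
  if (abs(sum(row) - 1) > 1e-12) {
    stop(what, " row must sum to 1 (got ", format(sum(row), digits = 15), ")",
         call. = FALSE)
  }
  invisible(row)
}

#' Response-conditioned sliding-window transition tables
#'
#' The proposer strategy revises the displayed face and the offer in single
#' steps on their respective grids, with move probabilities conditioned on
#' the participant's last response. The defaults encode the qualitative
#' strategy of the task: after an accept the face tends to step towards more
#' positive valence while the offer drifts down (probing the acceptance
#' threshold from above); after a reject the face tends to step negative
#' while the offer drifts up.
#'
#' Each row is a probability triple over moves `(step -1, stay, step +1)`.
#'
#' @param accept_face,accept_offer,reject_face,reject_offer Numeric
#'   probability triples over `(-1, 0, +1)` moves, each summing to 1.
#' @return An object of class `ug_transition_tables`: a nested list
#'   `tables$accept$face`, `tables$accept$offer`, `tables$reject$face`,
#'   `tables$reject$offer`.
#' @export
ug_transition_tables <- function(accept_face = c(0.10, 0.30, 0.60),
                                 accept_offer = c(0.50, 0.35, 0.15),
                                 reject_face = c(0.60, 0.30, 0.10),
                                 reject_offer = c(0.15, 0.35, 0.50)) {
  validate_move_row(accept_face, "accept/face")
  validate_move_row(accept_offer, "accept/offer")
  validate_move_row(reject_face, "reject/face")
  validate_move_row(reject_offer, "reject/offer")
  structure(
    list(
      accept = list(face = unname(accept_face), offer = unname(accept_offer)),
      reject = list(face = unname(reject_face), offer = unname(reject_offer))
    ),
    class = "ug_transition_tables"
  )
}

#' Read / write transition tables as a plain-text config
#'
#' Tables are stored as a small YAML document with keys
#' `accept_face`, `accept_offer`, `reject_face`, `reject_offer`, each a
#' 3-vector of move probabilities. Validated on load.
#'
#' @param path File path.
#' @return `read_transition_tables()` returns a `ug_transition_tables`
#'   object; `write_transition_tables()` returns `path` invisibly.
#' @export
read_transition_tables <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("accept_face", "accept_offer", "reject_face", "reject_offer")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("transition config missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ug_transition_tables(
    accept_face = as.numeric(cfg$accept_face),
    accept_offer = as.numeric(cfg$accept_offer),
    reject_face = as.numeric(cfg$reject_face),
    reject_offer = as.numeric(cfg$reject_offer)
  )
}

#' @rdname read_transition_tables
#' @param tables A `ug_transition_tables` object.
#' @export
write_transition_tables <- function(tables, path) {
  stopifnot(inherits(tables, "ug_transition_tables"))
  yaml::write_yaml(
    list(
      accept_face = tables$accept$face,
      accept_offer = tables$accept$offer,
      reject_face = tables$reject$face,
      reject_offer = tables$reject$offer
    ),
    path
  )
  invisible(path)
}

# Draw a neighbour move on an index grid 1..n with clamp-and-renormalise
# boundary handling: out-of-range move mass is dropped and the remaining
# probabilities rescaled, preserving relative stay/step odds.
sample_neighbour <- function(current, row, n) {
  validate_move_row(row, "transition")
  moves <- c(-1L, 0L, 1L)
  ok <- current + moves >= 1L & current + moves <= n
  p <- row * ok
  p <- p / sum(p)
  current + sample(moves, 1L, prob = p)
}

#' Sample the next face or offer under the sliding-window strategy
#'
#' Draws the proposer's next stimulus level given the current level and the
#' participant's response, using the response-conditioned move row. Moves
#' are restricted to the immediate neighbours; at the grid boundary the
#' out-of-range move mass is dropped and the row renormalised.
#'
#' Draws consume the current R random number stream; seed with
#' [set.seed()] or wrap in [withr::with_seed()] for reproducibility.
#'
#' @param current Current face index (1-based) or offer in pence.
#' @param choice Participant response: 1 = accept, 0 = reject.
#' @param tables A [ug_transition_tables()] object.
#' @param state_space A [ug_state_space()] object.
#' @return The next face index / offer amount.
#' @export
sample_next_face <- function(current, choice, tables = ug_transition_tables(),
                             state_space = ug_state_space()) {
  n <- nrow(state_space$faces)
  stopifnot(current >= 1, current <= n)
  row <- if (choice == 1) tables$accept$face else tables$reject$face
  sample_neighbour(as.integer(current), row, n)
}

#' @rdname sample_next_face
#' @export
sample_next_offer <- function(current, choice, tables = ug_transition_tables(),
                              state_space = ug_state_space()) {
  offers <- state_space$offers
  idx <- match(current, offers)
  if (is.na(idx)) {
    stop("offer ", current, " is not on the offer grid", call. = FALSE)
  }
  row <- if (choice == 1) tables$accept$offer else tables$reject$offer
  offers[sample_neighbour(idx, row, length(offers))]
}

check_choice <- function(choice) {
  if (!is.numeric(choice) && !is.logical(choice)) {
    stop("policy must return 0 (reject) or 1 (accept)", call. = FALSE)
  }
  choice <- as.numeric(choice)
  if (length(choice) != 1L || is.na(choice) || !choice %in% c(0, 1)) {
    stop("policy must return 0 (reject) or 1 (accept)", call. = FALSE)
  }
  choice
}

#' Simulate one closed-loop Ultimatum Game session
#'
#' Runs the full iterative task: blocks restart at the neutral face and the
#' fair 500/500 split; within a block the proposer's reaction face after the
#' participant's decision becomes the face shown at the start of the next
#' trial, and the offer is revised by the sliding-window sampler. Accepted
#' offers pay out as proposed; rejections pay nothing to either side.
#'
#' @param policy A function `(phi, offer, history) -> 0/1` giving the
#'   responder's choice; `history` is the tibble of trials completed so far
#'   (possibly zero rows).
#' @param tables A [ug_transition_tables()] object.
#' @param state_space A [ug_state_space()] object. Block starts use the
#'   middle face (neutral) and the offer closest to half the pot.
#' @param n_blocks,trials_per_block Session structure (defaults 6 x 40).
#' @param seed Optional integer; when supplied the session is generated
#'   under [withr::with_seed()] and is byte-identical across runs.
#'
#' @return A tibble with one row per trial: `trial`, `block`, `face_index`,
#'   `phi`, `offer_pence`, `other_pence`, `choice`, `outcome_self`,
#'   `outcome_other`, `reaction_face_index`, `rt_ms`.
#' @examples
#' s <- run_session(policy_threshold(300), seed = 1)
#' nrow(s) # 240
#' @export
run_session <- function(policy, tables = ug_transition_tables(),
                        state_space = ug_state_space(),
                        n_blocks = 6, trials_per_block = 40, seed = NULL) {
  stopifnot(is.function(policy))
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      run_session(policy, tables, state_space, n_blocks, trials_per_block,
                  seed = NULL)
    ))
  }
  faces <- state_space$faces
  offers <- state_space$offers
  pot <- state_space$pot
  neutral_face <- (nrow(faces) + 1L) %/% 2L
  start_offer <- offers[which.min(abs(offers - pot / 2))]

  n_trials <- n_blocks * trials_per_block
  col <- list(
    trial = integer(n_trials), block = integer(n_trials),
    face_index = integer(n_trials), phi = numeric(n_trials),
    offer_pence = integer(n_trials), other_pence = integer(n_trials),
    choice = numeric(n_trials), outcome_self = integer(n_trials),
    outcome_other = integer(n_trials),
    reaction_face_index = integer(n_trials), rt_ms = rep(NA_real_, n_trials)
  )
  slice_history <- function(k) {
    if (k == 0L) return(NULL)
    tibble::as_tibble(lapply(col, function(x) x[seq_len(k)]))
  }
  t_global <- 0L
  for (b in seq_len(n_blocks)) {
    face <- neutral_face
    offer <- start_offer
    for (t in seq_len(trials_per_block)) {
      t_global <- t_global + 1L
      phi <- faces$phi[face]
      choice <- check_choice(policy(phi, offer, slice_history(t_global - 1L)))
      reaction <- sample_next_face(face, choice, tables, state_space)
      col$trial[t_global] <- t_global
      col$block[t_global] <- b
      col$face_index[t_global] <- face
      col$phi[t_global] <- phi
      col$offer_pence[t_global] <- as.integer(offer)
      col$other_pence[t_global] <- as.integer(pot - offer)
      col$choice[t_global] <- choice
      col$outcome_self[t_global] <- as.integer(offer * choice)
      col$outcome_other[t_global] <- as.integer((pot - offer) * choice)
      col$reaction_face_index[t_global] <- reaction
      face <- reaction
      offer <- sample_next_offer(offer, choice, tables, state_space)
    }
  }
  tibble::as_tibble(col)
}

#' Built-in responder policies
#'
#' Convenience policies for simulation and testing: accept everything,
#' reject everything, accept offers at or above a fixed threshold, and a
#' stochastic model-based responder that accepts with the softmax
#' probability of a decision-value model (see [decision_value()]).
#'
#' @param threshold Offer threshold in pence.
#' @return A policy function `(phi, offer, history) -> 0/1`.
#' @export
policy_accept_all <- function() function(phi, offer, history) 1

#' @rdname policy_accept_all
#' @export
policy_reject_all <- function() function(phi, offer, history) 0

#' @rdname policy_accept_all
#' @export
policy_threshold <- function(threshold = 500) {
  force(threshold)
  function(phi, offer, history) as.numeric(offer >= threshold)
}

#' @rdname policy_accept_all
#' @param model Model id (1-11), see [model_registry()].
#' @param params Named list/vector of the model's parameters (pound scale),
#'   including `beta`.
#' @param delta,gamma Prelec weighting parameters mapping true valence
#'   `phi` to perceived valence `epsilon`.
#' @param mu Perceptual crossover constant.
#' @param deterministic If `TRUE`, choose accept iff the acceptance
#'   probability is at least 0.5 instead of sampling.
#' @export
policy_model <- function(model, params, delta = 1, gamma = 1, mu = 0.4,
                         deterministic = FALSE) {
  force(params)
  function(phi, offer, history) {
    eps <- prelec_weight(phi, delta, gamma)
    v <- decision_value(model, params,
                        R_S = offer / 100, R_O = (1000 - offer) / 100,
                        epsilon = eps, mu = mu)
    q <- accept_probability(v, params[["beta"]])
    if (deterministic) as.numeric(q >= 0.5) else stats::rbinom(1L, 1L, q)
  }
}

#' Randomly select the trials that are paid out
#'
#' At the end of the session a fixed number of trials (default 20) is drawn
#' uniformly without replacement, irrespective of the participant's choices,
#' and the participant is paid the summed self-outcome over those trials.
#'
#' @param session A session tibble from [run_session()].
#' @param n Number of payout trials.
#' @param seed Optional seed for reproducible selection.
#' @return A list with `trials` (sorted selected trial indices) and
#'   `payout_pence` (total self-outcome over them).
#' @export
select_payout_trials <- function(session, n = 20, seed = NULL) {
  if (nrow(session) < n) {
    stop("session has fewer than ", n, " trials", call. = FALSE)
  }
  draw <- function() sort(sample(session$trial, n))
  trials <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(
    trials = trials,
    payout_pence = sum(session$outcome_self[match(trials, session$trial)])
  )
}
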