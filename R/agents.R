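#' Hybrid reinforcement-learning agent parameters
#'
#' Parameters of the hybrid model-based/model-free agent for the two-stage
#' task: a SARSA(lambda) model-free branch, a Bellman model-based branch
#' computed from the known transition probabilities, a softmax mixture
#' weighted by `w`, and a perseveration bonus `pi_persev` (value units) for
#' repeating the previous first-stage choice.
#'
#' @param alpha1,alpha2 Stage-1 and stage-2 learning rates in \[0, 1\].
#' @param beta1,beta2 Stage-1 and stage-2 inverse temperatures (>= 0).
#' @param lam Eligibility-trace parameter in \[0, 1\].
#' @param w Model-based weight in \[0, 1\].
#' @param pi_persev Perseveration weight (unbounded; positive = sticky).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha1 = 0.5, alpha2 = 0.5, beta1 = 4, beta2 = 4,
                         lam = 1, w = 0.5, pi_persev = 0) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            lam = lam, w = w, pi_persev = pi_persev)
  stopifnot(all(vapply(p, is.finite, logical(1))),
            alpha1 >= 0, alpha1 <= 1, alpha2 >= 0, alpha2 <= 1,
            beta1 >= 0, beta2 >= 0, lam >= 0, lam <= 1, w >= 0, w <= 1)
  structure(p, class = "agent_params")
}

#' Fresh agent learning state
#'
#' @return List with zeroed stage-1 model-free values (`q_mf_s1`, length 2),
#'   zeroed second-stage values (`q_s2`, 2x2), and no previous choice.
#' @export
agent_state <- function() {
  list(q_mf_s1 = c(0, 0), q_s2 = matrix(0, 2, 2), prev_s1_choice = NA_integer_)
}

#' Stage-1 choice probabilities of the hybrid agent
#'
#' Model-based values are recomputed each trial from the current
#' second-stage values and the transition structure:
#' `Q_mb(a) = p_common * max Q2(common(a), .) + (1 - p_common) * max Q2(rare(a), .)`.
#' The net value `w * Q_mb + (1 - w) * Q_mf` plus the perseveration bonus
#' enters a softmax with inverse temperature `beta1`.
#'
#' @param state Agent state from [agent_state()] / [agent_update()].
#' @param params An [agent_params()].
#' @param p_common Transition probability assumed by the agent (default 0.7,
#'   the true task value).
#' @return Numeric length-2 vector of probabilities (sums to 1).
#' @export
stage1_choice_probs <- function(state, params, p_common = 0.7) {
  if (!all(is.finite(state$q_mf_s1)) || !all(is.finite(state$q_s2))) {
    stop("agent state contains non-finite values", call. = FALSE)
  }
  best <- apply(state$q_s2, 1, max)  # best attainable value in each state
  q_mb <- vapply(0:1, function(a) {
    p_common * best[a + 1L] + (1 - p_common) * best[2L - a]
  }, numeric(1))
  q_net <- params$w * q_mb + (1 - params$w) * state$q_mf_s1
  rep_bonus <- if (is.na(state$prev_s1_choice)) c(0, 0) else {
    as.numeric(0:1 == state$prev_s1_choice)
  }
  softmax2(params$beta1 * (q_net + params$pi_persev * rep_bonus))
}

softmax2 <- function(v) {
  v <- v - max(v)
  e <- exp(v)
  e / sum(e)
}

#' Update the agent state after a trial
#'
#' SARSA(lambda) model-free updates: the stage-1 prediction error uses the
#' chosen second-stage value, the stage-2 prediction error uses the reward,
#' and the stage-2 error is passed back to stage 1 with weight
#' `alpha1 * lam`. Incomplete trials update only the previous-choice memory,
#' which is cleared (so the next trial carries no perseveration bonus),
#' mirroring the removal of incomplete trials from analysis.
#'
#' @inheritParams stage1_choice_probs
#' @param trial A list or one-row data frame with `s1_choice`, `s2_state`,
#'   `s2_choice`, `reward`.
#' @return The updated agent state.
#' @export
agent_update <- function(state, params, trial) {
  if (is.na(trial$s1_choice) || is.na(trial$s2_choice) ||
      is.na(trial$reward)) {
    state$prev_s1_choice <- NA_integer_
    return(state)
  }
  if (!trial$reward %in% c(0L, 1L)) {
    stop("reward must be 0 or 1", call. = FALSE)
  }
  a1 <- trial$s1_choice + 1L
  s2 <- trial$s2_state + 1L
  a2 <- trial$s2_choice + 1L
  delta1 <- state$q_s2[s2, a2] - state$q_mf_s1[a1]
  state$q_mf_s1[a1] <- state$q_mf_s1[a1] + params$alpha1 * delta1
  delta2 <- trial$reward - state$q_s2[s2, a2]
  state$q_s2[s2, a2] <- state$q_s2[s2, a2] + params$alpha2 * delta2
  state$q_mf_s1[a1] <- state$q_mf_s1[a1] + params$alpha1 * params$lam * delta2
  state$prev_s1_choice <- as.integer(trial$s1_choice)
  state
}

#' Session log-likelihood of the hybrid agent
#'
#' Sums, over completed trials, the log probability of the observed stage-1
#' choice under [stage1_choice_probs()] and of the stage-2 choice under a
#' softmax with inverse temperature `beta2` over the current second-stage
#' values; the agent state is updated trial by trial. Incomplete trials
#' contribute 0 and clear the perseveration memory.
#'
#' @param params An [agent_params()].
#' @param records A session tibble from [simulate_session()].
#' @param p_common Transition probability assumed by the agent.
#' @return Scalar log-likelihood.
#' @export
session_loglik <- function(params, records, p_common = 0.7) {
  if (nrow(records) == 0) stop("empty session", call. = FALSE)
  na_i <- -1L
  enc <- function(x) {
    x <- as.integer(x)
    x[is.na(x)] <- na_i
    x
  }
  hybrid_loglik_cpp(
    enc(records$s1_choice), enc(records$s2_state), enc(records$s2_choice),
    enc(records$reward),
    params$alpha1, params$alpha2, params$beta1, params$beta2,
    params$lam, params$w, params$pi_persev, p_common
  )
}

#' Wrap agent parameters into a simulator policy
#'
#' @param params An [agent_params()].
#' @param p_common Transition probability assumed by the agent.
#' @return A policy object for [simulate_session()]: softmax choices at both
#'   stages, learning via [agent_update()].
#' @export
make_policy <- function(params, p_common = 0.7) {
  state <- agent_state()
  list(
    choose1 = function() {
      p <- stage1_choice_probs(state, params, p_common)
      as.integer(stats::runif(1) < p[2])
    },
    choose2 = function(s2_state) {
      p <- softmax2(params$beta2 * state$q_s2[s2_state + 1L, ])
      as.integer(stats::runif(1) < p[2])
    },
    observe = function(trial) {
      state <<- agent_update(state, params, trial)
      invisible(NULL)
    }
  )
}

#' Model variants of the hybrid agent family
#'
#' Three nested variants are fitted to choice data:
#' * `hybrid4`: ties `alpha1 = alpha2` and `beta1 = beta2`, fixes `lam = 1`;
#'   free parameters `alpha`, `beta`, `w`, `pi_persev`.
#' * `hybrid6`: additionally frees `lam` and unties the learning rates;
#'   free parameters `alpha1`, `alpha2`, `beta`, `lam`, `w`, `pi_persev`.
#' * `hybrid7`: all seven parameters free.
#'
#' @param name One of `"hybrid4"`, `"hybrid6"`, `"hybrid7"`.
#' @return List with the variant `name`, the `free` parameter names (on the
#'   reduced parameterization) and `n_free`.
#' @export
model_variant <- function(name = c("hybrid7", "hybrid6", "hybrid4")) {
  name <- match.arg(name)
  free <- switch(name,
    hybrid4 = c("alpha", "beta", "w", "pi_persev"),
    hybrid6 = c("alpha1", "alpha2", "beta", "lam", "w", "pi_persev"),
    hybrid7 = c("alpha1", "alpha2", "beta1", "beta2", "lam", "w", "pi_persev")
  )
  list(name = name, free = free, n_free = length(free))
}

# expand a named vector on a variant's reduced parameterization to the full
# seven-parameter agent_params
variant_params <- function(theta, variant) {
  v <- variant$name
  if (v == "hybrid4") {
    agent_params(alpha1 = theta[["alpha"]], alpha2 = theta[["alpha"]],
                 beta1 = theta[["beta"]], beta2 = theta[["beta"]],
                 lam = 1, w = theta[["w"]], pi_persev = theta[["pi_persev"]])
  } else if (v == "hybrid6") {
    agent_params(alpha1 = theta[["alpha1"]], alpha2 = theta[["alpha2"]],
                 beta1 = theta[["beta"]], beta2 = theta[["beta"]],
                 lam = theta[["lam"]], w = theta[["w"]],
                 pi_persev = theta[["pi_persev"]])
  } else {
    agent_params(alpha1 = theta[["alpha1"]], alpha2 = theta[["alpha2"]],
                 beta1 = theta[["beta1"]], beta2 = theta[["beta2"]],
                 lam = theta[["lam"]], w = theta[["w"]],
                 pi_persev = theta[["pi_persev"]])
  }
}
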