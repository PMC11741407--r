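# Pure-R reference implementation of the session log-likelihood, built from
# the exported single-step functions (stage1_choice_probs / agent_update).
# Serves as the independent oracle for the compiled incremental likelihood.
loglik_reference <- function(params, records, p_common = 0.7) {
  state <- agent_state()
  ll <- 0
  for (t in seq_len(nrow(records))) {
    tr <- as.list(records[t, ])
    if (is.na(tr$s1_choice) || is.na(tr$s2_choice) || is.na(tr$reward)) {
      state <- agent_update(state, params, tr)
      next
    }
    p1 <- stage1_choice_probs(state, params, p_common)
    ll <- ll + log(p1[tr$s1_choice + 1L])
    q2 <- state$q_s2[tr$s2_state + 1L, ]
    p2 <- exp(params$beta2 * q2 - max(params$beta2 * q2))
    p2 <- p2 / sum(p2)
    ll <- ll + log(p2[tr$s2_choice + 1L])
    state <- agent_update(state, params, tr)
  }
  ll
}

# minimal hand-built session tibble from explicit vectors
make_session <- function(s1, s2s, s2c, rew, trans = NULL,
                         subject = "s001", visit = 1L) {
  n <- length(s1)
  if (is.null(trans)) {
    trans <- ifelse(is.na(s1) | is.na(s2s), NA_character_,
                    ifelse(s1 == s2s, "common", "rare"))
  }
  tibble::tibble(
    subject = subject, visit = visit,
    session = paste0(subject, "_v", visit),
    trial = seq_len(n), block = 1L,
    s1_choice = as.integer(s1), transition = trans,
    s2_state = as.integer(s2s), s2_choice = as.integer(s2c),
    reward = as.integer(rew), rt1 = 0.5, rt2 = 0.5
  )
}

# simulate a cohort of sessions from one agent parameterization
sim_cohort <- function(n_sessions, params, seed = 1, n_trials = 200,
                       pi_sd = 0) {
  cfg <- task_config(n_trials = n_trials)
  set.seed(seed)
  pis <- stats::rnorm(n_sessions, params$pi_persev, pi_sd)
  seeds <- sample.int(1e6, n_sessions)
  out <- purrr::map_dfr(seq_len(n_sessions), function(i) {
    set.seed(seeds[i])
    p <- params
    p$pi_persev <- pis[i]
    pol <- make_policy(p)
    simulate_session(pol, cfg) |>
      dplyr::mutate(subject = sprintf("s%03d", i), visit = 1L,
                    session = sprintf("s%03d_v1", i), .before = 1)
  })
  attr(out, "pi_true") <- pis
  out
}

# empirical stay probabilities conditioned on the previous trial's
# reward x transition cell -- brute-force check of agent signatures
stay_prob_by_condition <- function(trials) {
  build_stay_table(trials) |>
    dplyr::group_by(.data$prev_reward, .data$prev_transition) |>
    dplyr::summarise(p_stay = mean(.data$stay), .groups = "drop")
}
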