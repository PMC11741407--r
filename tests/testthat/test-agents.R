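test_that("stage-1 choice probabilities match hand-computed softmax", {
  st <- agent_state()
  # flat softmax at zero temperature
  p <- stage1_choice_probs(st, agent_params(beta1 = 0))
  expect_equal(p, c(0.5, 0.5))

  # overwhelming perseveration pins the previous choice
  st$prev_s1_choice <- 0L
  p <- stage1_choice_probs(st, agent_params(beta1 = 5, pi_persev = 50))
  expect_gt(p[1], 1 - 1e-10)

  # hand-set tables, w = 0.5: exact arithmetic oracle
  st <- agent_state()
  st$q_s2 <- matrix(c(0.8, 0.1, 0.3, 0.6), 2, 2)  # [state, alien]
  st$q_mf_s1 <- c(0.2, 0.5)
  st$prev_s1_choice <- 1L
  pars <- agent_params(beta1 = 2, w = 0.5, pi_persev = 0.3)
  best <- apply(st$q_s2, 1, max)
  q_mb <- c(0.7 * best[1] + 0.3 * best[2], 0.7 * best[2] + 0.3 * best[1])
  v <- 0.5 * q_mb + 0.5 * st$q_mf_s1 + c(0, 0.3)
  expected <- exp(2 * v) / sum(exp(2 * v))
  expect_equal(stage1_choice_probs(st, pars), expected, tolerance = 1e-12)

  st$q_s2[1, 1] <- Inf
  expect_error(stage1_choice_probs(st, pars), "non-finite")

  # probabilities normalize and stay strictly positive
  set.seed(3)
  for (i in 1:20) {
    st <- agent_state()
    st$q_s2 <- matrix(runif(4), 2, 2)
    st$q_mf_s1 <- runif(2)
    pars <- agent_params(beta1 = runif(1, 0, 10), w = runif(1),
                         pi_persev = rnorm(1))
    p <- stage1_choice_probs(st, pars)
    expect_equal(sum(p), 1)
    expect_true(all(p > 0))
  }
})

test_that("SARSA(lambda) updates follow the stated recursions", {
  pars <- agent_params(alpha1 = 0.5, alpha2 = 0.5, lam = 1)
  st <- agent_update(agent_state(), pars,
                     list(s1_choice = 0L, s2_state = 0L, s2_choice = 1L,
                          reward = 1L))
  expect_equal(st$q_s2[1, 2], 0.5)
  # delta2 = 1 is evaluated before the stage-2 value update, so the
  # eligibility pass-back adds alpha1 * lam * delta2 = 0.5
  expect_equal(st$q_mf_s1[1], 0.5)
  expect_equal(st$prev_s1_choice, 0L)

  # zero learning rates: values untouched, memory updated
  st0 <- agent_update(agent_state(), agent_params(alpha1 = 0, alpha2 = 0),
                      list(s1_choice = 1L, s2_state = 1L, s2_choice = 0L,
                           reward = 1L))
  expect_equal(st0$q_s2, matrix(0, 2, 2))
  expect_equal(st0$prev_s1_choice, 1L)

  # repeated rewarded trials drive the chosen value monotonically to 1
  st <- agent_state()
  prev <- 0
  for (i in 1:50) {
    st <- agent_update(st, pars, list(s1_choice = 0L, s2_state = 0L,
                                      s2_choice = 0L, reward = 1L))
    expect_gt(st$q_s2[1, 1], prev)
    prev <- st$q_s2[1, 1]
  }
  expect_equal(st$q_s2[1, 1], 1, tolerance = 1e-10)

  # missing trials clear the perseveration memory only
  stm <- agent_update(st, pars, list(s1_choice = NA, s2_state = NA,
                                     s2_choice = NA, reward = NA))
  expect_identical(stm$q_s2, st$q_s2)
  expect_true(is.na(stm$prev_s1_choice))

  expect_error(
    agent_update(agent_state(), pars,
                 list(s1_choice = 0L, s2_state = 0L, s2_choice = 0L,
                      reward = 2L)),
    "reward")
})

test_that("session log-likelihood matches closed form and the R oracle", {
  set.seed(21)
  s <- simulate_session(random_policy(), task_config())
  # uniform policy: exactly 2 * n_trials * log(1/2)
  expect_equal(session_loglik(agent_params(beta1 = 0, beta2 = 0), s),
               400 * log(0.5), tolerance = 1e-10)
  expect_error(session_loglik(agent_params(), s[0, ]), "empty")

  # compiled incremental likelihood vs naive R recomputation, with and
  # without missing trials
  set.seed(22)
  pars <- agent_params(alpha1 = 0.3, alpha2 = 0.6, beta1 = 3, beta2 = 2,
                       lam = 0.5, w = 0.7, pi_persev = 0.4)
  pol <- make_policy(pars)
  s2 <- simulate_session(pol, task_config(omission_rate = 0.1))
  expect_equal(session_loglik(pars, s2), loglik_reference(pars, s2),
               tolerance = 1e-10)
  set.seed(23)
  s3 <- simulate_session(make_policy(pars), task_config())
  expect_equal(session_loglik(pars, s3), loglik_reference(pars, s3),
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant to joint relabeling of choices/states", {
  set.seed(31)
  pars <- agent_params(alpha1 = 0.4, alpha2 = 0.4, beta1 = 3, beta2 = 3,
                       lam = 1, w = 0.6, pi_persev = 0.2)
  s <- simulate_session(make_policy(pars), task_config())
  flipped <- s
  flipped$s1_choice <- 1L - s$s1_choice
  flipped$s2_state <- 1L - s$s2_state
  flipped$s2_choice <- 1L - s$s2_choice
  expect_equal(session_loglik(pars, flipped), session_loglik(pars, s),
               tolerance = 1e-10)
})

test_that("generated data is more likely under its own parameters", {
  pars <- agent_params(alpha1 = 0.5, alpha2 = 0.5, beta1 = 4, beta2 = 4,
                       lam = 1, w = 0.5, pi_persev = 0.3)
  perturbed <- agent_params(alpha1 = 0.9, alpha2 = 0.1, beta1 = 1,
                            beta2 = 8, lam = 0.2, w = 0.9, pi_persev = -0.5)
  trials <- sim_cohort(40, pars, seed = 41)
  ll <- vapply(split(trials, trials$session), function(s) {
    c(session_loglik(pars, s), session_loglik(perturbed, s))
  }, numeric(2))
  expect_gt(mean(ll[1, ]), mean(ll[2, ]))
})

test_that("agent policies reproduce the canonical strategy signatures", {
  # pure model-based: stay more after rewarded-common than rewarded-rare
  mb <- sim_cohort(60, agent_params(beta1 = 5, beta2 = 5, w = 1,
                                    pi_persev = 0), seed = 51)
  tab <- stay_prob_by_condition(mb)
  p_rc <- tab$p_stay[tab$prev_reward == 1 & tab$prev_transition == 1]
  p_rr <- tab$p_stay[tab$prev_reward == 1 & tab$prev_transition == -1]
  expect_gt(p_rc, p_rr + 0.03)

  # pure model-free: reward raises staying regardless of transition
  mf <- sim_cohort(60, agent_params(beta1 = 5, beta2 = 5, w = 0,
                                    pi_persev = 0), seed = 52)
  tabf <- stay_prob_by_condition(mf)
  for (tr in c(-1, 1)) {
    p_r <- tabf$p_stay[tabf$prev_reward == 1 & tabf$prev_transition == tr]
    p_n <- tabf$p_stay[tabf$prev_reward == -1 & tabf$prev_transition == tr]
    expect_gt(p_r, p_n + 0.03)
  }
})
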