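test_that("stay table coding matches the worked example", {
  s <- make_session(c(0, 0, 1, 1), c(0, 1, 1, 1), c(0, 1, 0, 1),
                    c(1, 0, 1, 0),
                    trans = c("common", "rare", "common", "common"))
  tab <- build_stay_table(s)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$stay, c(1L, 0L, 1L))
  expect_equal(tab$prev_reward, c(1L, -1L, 1L))
  expect_equal(tab$prev_transition, c(1L, -1L, 1L))
})

test_that("missing responses remove the trial and its successor", {
  s1 <- c(0, 0, 0, 0, 0)
  s2c <- c(1, 1, NA, 1, 1)
  s <- make_session(s1, rep(0, 5), s2c, ifelse(is.na(s2c), NA, 1))
  tab <- build_stay_table(s)
  expect_setequal(tab$trial, c(2L, 5L))

  # a complete 200-trial session yields 199 rows across blocks
  set.seed(61)
  full <- sim_cohort(1, agent_params(), seed = 61)
  expect_equal(nrow(build_stay_table(full)), 199)

  # sessions with < 2 complete trials yield zero rows with a warning
  tiny <- make_session(c(0, NA), c(0, NA), c(1, NA), c(1, NA))
  expect_warning(tab0 <- build_stay_table(tiny), "no analyzable")
  expect_equal(nrow(tab0), 0)
})

test_that("null stay data yields null fixed effects", {
  set.seed(71)
  tab <- purrr::map_dfr(1:60, function(i) {
    tibble::tibble(
      subject = sprintf("s%02d", i), visit = 1L,
      session = sprintf("s%02d_v1", i), trial = 2:200,
      stay = rbinom(199, 1, 0.5),
      prev_reward = sample(c(-1L, 1L), 199, TRUE),
      prev_transition = sample(c(-1L, 1L), 199, TRUE)
    )
  })
  fit <- fit_stay_mlm(tab)
  expect_s3_class(fit, "stay_fit")
  # every fixed effect within 3 SE of zero
  expect_true(all(abs(fit$fixed) < 3 * fit$fixed_se))
  expect_true(isSymmetric(fit$ranef_cov))
  expect_true(all(eigen(fit$ranef_cov, only.values = TRUE)$values > -1e-8))
  expect_equal(nrow(fit$blups), 60)

  # flipping the transition coding flips transition and interaction only
  tab2 <- dplyr::mutate(tab, prev_transition = -prev_transition)
  fit2 <- fit_stay_mlm(tab2)
  # optimizer paths differ slightly between the recoded fits
  expect_lt(abs(fit2$fixed[["reward"]] - fit$fixed[["reward"]]), 0.005)
  expect_lt(abs(fit2$fixed[["transition"]] + fit$fixed[["transition"]]),
            0.005)
  expect_lt(abs(fit2$fixed[["interaction"]] + fit$fixed[["interaction"]]),
            0.005)
})

test_that("cohort signatures appear in the fitted stay model", {
  mf <- sim_cohort(50, agent_params(beta1 = 5, beta2 = 5, w = 0,
                                    alpha1 = 0.5, alpha2 = 0.5,
                                    pi_persev = 0), seed = 81)
  fit_mf <- fit_stay_mlm(build_stay_table(mf))
  expect_gt(fit_mf$fixed[["reward"]] / fit_mf$fixed_se[["reward"]], 3)
  expect_lt(abs(fit_mf$fixed[["interaction"]] /
                  fit_mf$fixed_se[["interaction"]]), 3)

  mb <- sim_cohort(50, agent_params(beta1 = 5, beta2 = 5, w = 1,
                                    pi_persev = 0), seed = 82)
  fit_mb <- fit_stay_mlm(build_stay_table(mb))
  expect_gt(fit_mb$fixed[["interaction"]] /
              fit_mb$fixed_se[["interaction"]], 3)
})

test_that("index assembly is the definitional sum of fixed and random parts", {
  set.seed(91)
  trials <- sim_cohort(30, agent_params(pi_persev = 0.3), seed = 91,
                       pi_sd = 0.25)
  fit <- fit_stay_mlm(build_stay_table(trials))
  idx <- extract_indices(fit)
  expect_equal(idx$mb,
               fit$fixed[["interaction"]] + fit$blups$interaction)
  expect_equal(idx$mf, fit$fixed[["reward"]] + fit$blups$reward)
  expect_equal(idx$fss, fit$fixed[["intercept"]] + fit$blups$intercept)
  expect_true(all(c("subject", "visit") %in% names(idx)))

  # fss equals predicted stay log-odds at the centered predictor point:
  # intercept-only contribution of the session
  eta <- fit$fixed[["intercept"]] + fit$blups$intercept
  expect_equal(idx$fss, eta)
})

test_that("fss tracks generative perseveration across a heterogeneous cohort", {
  trials <- sim_cohort(60, agent_params(pi_persev = 0.3), seed = 101,
                       pi_sd = 0.2)
  pis <- attr(trials, "pi_true")
  idx <- extract_indices(fit_stay_mlm(build_stay_table(trials)))
  m <- dplyr::inner_join(
    idx, tibble::tibble(session = sprintf("s%03d_v1", seq_along(pis)),
                        pi_true = pis), by = "session")
  expect_gte(cor(m$fss, m$pi_true, method = "spearman"), 0.7)
})

test_that("blups approach per-session ML estimates with long sessions", {
  trials <- sim_cohort(25, agent_params(pi_persev = 0.2), seed = 111,
                       pi_sd = 0.4, n_trials = 2000)
  tab <- build_stay_table(trials)
  fit <- fit_stay_mlm(tab)
  idx <- extract_indices(fit)
  # independent per-session logistic fits
  solo <- purrr::map_dfr(split(tab, tab$session), function(d) {
    g <- stats::glm(stay ~ prev_reward * prev_transition, data = d,
                    family = binomial())
    tibble::tibble(session = d$session[1],
                   fss_ml = coef(g)[["(Intercept)"]])
  })
  m <- dplyr::inner_join(idx, solo, by = "session")
  expect_gt(cor(m$fss, m$fss_ml), 0.95)
  expect_lt(mean(abs(m$fss - m$fss_ml)), 0.1)
})

test_that("supplementary models recover planted age and RT effects", {
  set.seed(121)
  n_sessions <- 60
  trials <- sim_cohort(n_sessions, agent_params(), seed = 121)
  ages <- tibble::tibble(session = sprintf("s%03d_v1", 1:n_sessions),
                         age = runif(n_sessions, 10, 33))
  # plant a +50 ms RT shift after rare transitions
  rt_table <- trials |>
    dplyr::filter(!is.na(rt2)) |>
    dplyr::mutate(rt2 = rt2 + ifelse(transition == "rare", 0.05, 0))
  res <- fit_supplementary_mlms(build_stay_table(trials), rt_table, ages)
  rare_row <- res$rt_by_transition[res$rt_by_transition$term == "rare", ]
  expect_gt(rare_row$estimate, 0)
  expect_lt(rare_row$p_value, 0.05)
  expect_true(all(c("estimate", "p_value") %in% names(res$stay_by_age)))

  # zero planted shift: coefficient within 3 SEs of zero
  res0 <- fit_supplementary_mlms(build_stay_table(trials),
                                 dplyr::filter(trials, !is.na(rt2)), ages)
  rare0 <- res0$rt_by_transition[res0$rt_by_transition$term == "rare", ]
  expect_lt(abs(rare0$estimate / rare0$std_error), 3)
})

test_that("tidy and glance methods summarize stay fits", {
  trials <- sim_cohort(20, agent_params(), seed = 131)
  fit <- fit_stay_mlm(build_stay_table(trials))
  td <- tidy(fit)
  expect_equal(td$term,
               c("intercept", "reward", "transition", "interaction"))
  gl <- glance(fit)
  expect_equal(gl$n_sessions, 20)
  expect_true(gl$n_obs > 0)
})
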