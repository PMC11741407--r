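test_that("spline basis has linear null space and centered columns", {
  set.seed(181)
  x <- runif(100, 10, 33)
  b <- build_basis(x, k = 3)
  expect_true(all(abs(colMeans(b$X)) < 1e-10))
  expect_true(isSymmetric(b$S))
  expect_true(all(eigen(b$S, only.values = TRUE)$values > -1e-10))

  # coefficients reproducing a linear function incur zero penalty
  xc <- x - mean(x)
  beta_lin <- qr.solve(b$X, xc)
  expect_lt(max(abs(b$X %*% beta_lin - xc)), 1e-8)  # linear is representable
  expect_lt(drop(t(beta_lin) %*% b$S %*% beta_lin), 1e-10)

  # prediction at knots matches spline interpolation of the basis functions
  X_knots <- eval_basis(b, b$knots)
  for (j in seq_len(ncol(b$X))) {
    sp <- stats::splinefun(b$knots, X_knots[, j], method = "natural")
    expect_equal(sp(x), b$X[, j], tolerance = 1e-8)
  }

  expect_error(build_basis(c(1, 1, 2), k = 3), "distinct")
})

test_that("penalized fit matches OLS in the linear limit and shrinks under null", {
  set.seed(191)
  n <- 400
  d <- data.frame(age = runif(n, 10, 33))
  d$y <- 2 + 0.5 * d$age + rnorm(n, 0, 1e-5)
  f <- fit_gamm(d, "y", linear = NULL, random = NULL)
  ols <- lm(y ~ age, data = d)
  expect_lt(sqrt(mean((fitted(f$gam) - fitted(ols))^2)), 1e-3)

  # unrelated smooth: edf ~ 1, p > 0.05, intercept recovered
  d0 <- data.frame(age = runif(n, 10, 33))
  d0$y <- 3 + rnorm(n)
  f0 <- fit_gamm(d0, "y", linear = NULL, random = NULL)
  s <- smooth_significance(f0, "age")
  expect_lte(s$edf, 2)
  expect_gt(s$p_value, 0.05)
  b0 <- summary(f0$gam)$p.table
  expect_lt(abs(b0["(Intercept)", 1] - 3) / b0["(Intercept)", 2], 3)

  # strong sinusoidal signal is detected decisively
  ds <- data.frame(age = runif(n, 10, 33))
  ds$y <- sin(ds$age / 2) + rnorm(n, 0, 0.3)
  fs <- fit_gamm(ds, "y", linear = NULL, random = NULL, k = 10)
  expect_lt(smooth_significance(fs, "age")$p_value, 1e-6)

  expect_error(smooth_significance(f0, "nope"), "no smooth term")
})

test_that("random intercepts recover known subject offsets", {
  set.seed(201)
  n_rep <- 40
  d <- data.frame(
    subject = rep(c("a", "b"), each = n_rep),
    age = runif(2 * n_rep, 10, 33)
  )
  d$y <- 0.1 * d$age + ifelse(d$subject == "a", 1, -1) +
    rnorm(2 * n_rep, 0, 0.3)
  f <- fit_gamm(d, "y", linear = NULL, random = "subject")
  gl <- glance(f)
  expect_gt(gl$ranef_var, 0)
  # predicted offsets close to +/-1
  co <- coef(f$gam)
  re <- co[grep("s\\(subject\\)", names(co))]
  expect_equal(unname(re[1]), 1, tolerance = 0.2)
  expect_equal(unname(re[2]), -1, tolerance = 0.2)
})

test_that("age residualization is exact orthogonalization", {
  set.seed(211)
  age <- runif(200, 10, 33)
  expect_equal(residualize_age(2 * age, age), rep(0, 200),
               tolerance = 1e-10, ignore_attr = TRUE)
  y <- 0.5 * age + rnorm(200)
  r <- residualize_age(y, age)
  expect_lt(abs(cor(r, age)), 1e-10)
  expect_lt(abs(mean(r)), 1e-10)
  expect_error(residualize_age(y, rep(5, 200)), "constant")
  # the internal regression recovers the planted slope
  sl <- coef(lm(y ~ age))[["age"]]
  se <- summary(lm(y ~ age))$coefficients["age", 2]
  expect_lt(abs(sl - 0.5) / se, 3)
})

test_that("bonferroni thresholds match the reported family sizes", {
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(round(bonferroni(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0))
})

test_that("varying-coefficient fits recover constant and null couplings", {
  set.seed(221)
  n <- 500
  d <- data.frame(subject = sprintf("s%03d", rep(1:250, each = 2)),
                  age = runif(n, 10, 33), sex = rbinom(n, 1, 0.5),
                  visit = rep(1:2, 250))
  d$beh <- rnorm(n)
  d$y <- 0.05 * d$age + 0.4 * d$beh + rnorm(n, 0, 0.3)
  f <- fit_varying_coefficient(d, "y", "beh")
  w <- derivative_windows(f, n_sims = 2000, seed = 1)
  # fitted beta(age) within 0.1 of the constant truth across the grid
  expect_true(all(abs(w$grid$estimate - 0.4) < 0.1))
  # constant truth: derivative-mode windows should be (nearly) absent
  wd <- derivative_windows(f, mode = "derivative", n_sims = 2000, seed = 1)
  expect_lt(sum(wd$grid$significant) / nrow(wd$grid), 0.05)

  # all-zero behavior: varying-coefficient block is inert
  d0 <- d
  d0$beh <- 0
  expect_warning(f0 <- fit_varying_coefficient(d0, "y", "beh"),
                 "constant")
  f1 <- fit_gamm(d0, "y")
  expect_equal(fitted(f0$gam), fitted(f1$gam), tolerance = 1e-6)
})

test_that("derivative windows detect a decreasing coupling", {
  set.seed(231)
  n <- 500
  d <- data.frame(subject = sprintf("s%03d", 1:n),
                  age = runif(n, 10, 33), sex = rbinom(n, 1, 0.5),
                  visit = 1L)
  d$beh <- rnorm(n)
  beta_age <- 1.5 - 0.06 * d$age            # strong linear decrease
  d$y <- 0.05 * d$age + beta_age * d$beh + rnorm(n, 0, 0.2)
  f <- fit_varying_coefficient(d, "y", "beh", random = NULL)
  wd <- derivative_windows(f, mode = "derivative", n_sims = 2000, seed = 2)
  covered <- sum(wd$grid$significant) / nrow(wd$grid)
  expect_gte(covered, 0.8)
  # the derivative estimate has the right sign where significant
  expect_true(all(wd$grid$estimate[wd$grid$significant] < 0))
  expect_error(derivative_windows(f, n_sims = 50), "at least 100")
})

test_that("windows are disjoint, sorted, and inside the age range", {
  set.seed(241)
  n <- 300
  d <- data.frame(subject = sprintf("s%03d", 1:n),
                  age = runif(n, 10, 33), sex = rbinom(n, 1, 0.5),
                  visit = 1L, beh = rnorm(n))
  d$y <- coupling_beta(d$age, -0.5, 14, 23) * d$beh + rnorm(n, 0, 0.2)
  f <- fit_varying_coefficient(d, "y", "beh", random = NULL)
  w <- derivative_windows(f, n_sims = 2000, seed = 3)
  if (nrow(w$windows) > 1) {
    expect_true(all(diff(w$windows$start) > 0))
    expect_true(all(w$windows$end[-nrow(w$windows)] <
                      w$windows$start[-1]))
  }
  expect_true(all(w$windows$start >= min(d$age) &
                    w$windows$end <= max(d$age)))
  # simultaneous band is wider than pointwise
  ws <- derivative_windows(f, n_sims = 2000, simultaneous = TRUE, seed = 3)
  expect_true(all(ws$grid$hi - ws$grid$lo >= w$grid$hi - w$grid$lo - 1e-9))
})

test_that("marginal trajectories are linear in the behavior level", {
  set.seed(251)
  n <- 300
  d <- data.frame(subject = sprintf("s%03d", 1:n),
                  age = runif(n, 10, 33), sex = rbinom(n, 1, 0.5),
                  visit = 1L, beh = rnorm(n))
  d$y <- -0.03 * d$age + 0.3 * d$beh + rnorm(n, 0, 0.2)
  f <- fit_varying_coefficient(d, "y", "beh", random = NULL)
  mt <- marginal_trajectories(f, levels = c(-1, 0, 1), grid_n = 50)
  m <- tidyr::pivot_wider(mt[, c("age", "level_sd", "estimate")],
                          names_from = "level_sd",
                          values_from = "estimate")
  # mirror symmetry about the level-0 curve
  expect_equal(m$`1` - m$`0`, m$`0` - m$`-1`, tolerance = 1e-8)

  # brute-force oracle from the assembled design matrix
  lv <- mt[mt$level_sd == 1, ]
  nd <- d[rep(1, 50), ]
  nd$age <- lv$age
  nd$beh <- lv$behavior_value[1]
  nd$sex <- mean(d$sex)
  nd$visit <- mean(d$visit)
  Xp <- predict(f$gam, newdata = nd, type = "lpmatrix")
  expect_equal(lv$estimate, as.numeric(Xp %*% coef(f$gam)),
               tolerance = 1e-10)
})

test_that("the conjunctive ladder rule retains the generating model", {
  # Model-3-style truth: fss and mb couplings present
  cfg3 <- cohort_config(
    n_subjects = 217,
    couplings = tibble::tibble(region = "putamen",
                               index = c("fss", "mb"),
                               amplitude = c(-0.4, 0.35),
                               a0 = Inf, a1 = Inf))
  ch3 <- generate_cohort(cfg3, seed = 261, simulate_trials = FALSE)
  d3 <- habitiron:::assemble_index_analysis(ch3)
  lad3 <- compare_model_ladder(d3, "putamen")
  expect_equal(lad3$retained, 3L)
  expect_equal(nrow(lad3$models), 4)
  expect_true(all(lad3$models$AIC > 0 | lad3$models$AIC < 0))  # finite
  expect_s3_class(lad3$tests, "tbl_df")

  # null truth: no behavior coupling anywhere
  cfg1 <- cohort_config(n_subjects = 150,
                        couplings = default_couplings()[0, ])
  ch1 <- generate_cohort(cfg1, seed = 262, simulate_trials = FALSE)
  d1 <- habitiron:::assemble_index_analysis(ch1)
  lad1 <- compare_model_ladder(d1, "putamen")
  expect_equal(lad1$retained, 1L)
})

test_that("edf never exceeds the k = 3 basis bound", {
  set.seed(271)
  for (i in 1:5) {
    d <- data.frame(age = runif(300, 10, 33))
    d$y <- 0.1 * d$age + rnorm(300, 0, 0.5)
    f <- fit_gamm(d, "y", linear = NULL, random = NULL)
    expect_lte(smooth_significance(f, "age")$edf, 2 + 1e-6)
  }
})
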