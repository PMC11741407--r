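#' Default weakly-informative priors for MAP fitting
#'
#' Beta(2, 2) on learning rates, the eligibility trace and the model-based
#' weight; Gamma(shape 1, rate 0.2) on inverse temperatures (mean 5, mode
#' 0, so a flat likelihood yields a zero temperature and the uniform-policy
#' log-likelihood); Normal(0, 1) on the perseveration weight. Densities are
#' evaluated on the natural parameter scale.
#'
#' @return Named list of log-prior functions keyed by parameter name.
#' @export
default_priors <- function() {
  rate_prior <- function(x) stats::dbeta(x, 2, 2, log = TRUE)
  temp_prior <- function(x) stats::dgamma(x, shape = 1, rate = 0.2, log = TRUE)
  list(
    alpha = rate_prior, alpha1 = rate_prior, alpha2 = rate_prior,
    beta = temp_prior, beta1 = temp_prior, beta2 = temp_prior,
    lam = rate_prior, w = rate_prior,
    pi_persev = function(x) stats::dnorm(x, 0, 1, log = TRUE)
  )
}

# transform free parameters between the unconstrained optimizer scale and
# the natural scale: logit for rates/lam/w, log for temperatures, identity
# for the perseveration weight
par_kind <- function(name) {
  if (grepl("^alpha|^lam$|^w$", name)) "unit"
  else if (grepl("^beta", name)) "pos"
  else "real"
}

to_natural <- function(z, names) {
  vapply(seq_along(z), function(i) {
    switch(par_kind(names[i]),
           unit = stats::plogis(z[i]),
           pos = exp(z[i]),
           real = z[i])
  }, numeric(1)) |> stats::setNames(names)
}

to_unconstrained <- function(theta, names) {
  vapply(seq_along(theta), function(i) {
    switch(par_kind(names[i]),
           unit = stats::qlogis(min(max(theta[i], 1e-6), 1 - 1e-6)),
           pos = log(max(theta[i], 1e-8)),
           real = theta[i])
  }, numeric(1)) |> stats::setNames(names)
}

#' Fit a hybrid RL variant to one session by MAP
#'
#' Maximizes the session log-likelihood plus log-prior over a transformed
#' (unconstrained) parameterization — logit scale for rates and the
#' model-based weight, log scale for inverse temperatures — by BFGS from
#' `n_restarts` Latin-hypercube start points. Deterministic given `seed`.
#'
#' @param records A session tibble (see [simulate_session()]).
#' @param variant Variant name or [model_variant()] object.
#' @param priors Named list of log-prior functions, as [default_priors()].
#' @param n_restarts Number of optimizer restarts (default 10).
#' @param seed Integer seed for the start points.
#' @param p_common Transition probability assumed by the agent.
#' @return An object of class `rl_fit`: list with `variant`, `params_hat`
#'   (named natural-scale estimates), full `agent_params`, `loglik` (pure
#'   log-likelihood at the MAP), `logpost`, `aic`, `bic`, `n_restarts`,
#'   `converged`, and `se` (standard errors on the transformed scale, from
#'   the numerical Hessian when available).
#' @export
fit_map <- function(records, variant = "hybrid7", priors = default_priors(),
                    n_restarts = 10, seed = 1, p_common = 0.7) {
  if (is.character(variant)) variant <- model_variant(variant)
  free <- variant$free
  k <- variant$n_free
  n_complete <- sum(trial_complete(records))
  if (n_complete == 0) stop("session has no complete trials", call. = FALSE)

  neg_logpost <- function(z) {
    theta <- to_natural(z, free)
    p <- variant_params(theta, variant)
    lp <- sum(vapply(free, function(nm) priors[[nm]](theta[[nm]]),
                     numeric(1)))
    val <- -(session_loglik(p, records, p_common) + lp)
    if (!is.finite(val)) 1e10 else val
  }

  # Latin-hypercube starts on the unconstrained scale
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  set.seed(seed)
  grid <- lhs::randomLHS(max(n_restarts, 1L), k)
  starts <- grid * 4 - 2  # uniform on [-2, 2] per dimension
  results <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(starts[i, ], neg_logpost, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  results <- Filter(Negate(is.null), results)
  if (length(results) == 0) {
    return(structure(list(variant = variant$name, params_hat = NULL,
                          converged = FALSE), class = "rl_fit"))
  }
  best <- results[[which.min(vapply(results, `[[`, numeric(1), "value"))]]
  z_hat <- stats::setNames(best$par, free)
  theta_hat <- to_natural(z_hat, free)
  p_hat <- variant_params(theta_hat, variant)
  ll <- session_loglik(p_hat, records, p_common)
  se <- tryCatch({
    H <- stats::optimHess(best$par, neg_logpost)
    s <- suppressWarnings(sqrt(diag(solve(H))))
    stats::setNames(s, free)
  }, error = function(e) stats::setNames(rep(NA_real_, k), free))

  structure(
    list(variant = variant$name, params_hat = theta_hat, params = p_hat,
         loglik = ll, logpost = -best$value,
         aic = 2 * k - 2 * ll, bic = k * log(n_complete) - 2 * ll,
         n_free = k, n_trials = n_complete, n_restarts = n_restarts,
         converged = best$convergence == 0, se = se, seed = seed),
    class = "rl_fit"
  )
}

#' @method print rl_fit
#' @export
print.rl_fit <- function(x, ...) {
  cat("MAP fit,", x$variant, "- loglik", round(x$loglik, 2),
      "AIC", round(x$aic, 2), "\n")
  if (!is.null(x$params_hat)) print(round(x$params_hat, 4))
  invisible(x)
}

#' Tidy an RL MAP fit
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, and the transformed-scale
#'   `std_error`.
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params_hat),
                 estimate = unname(x$params_hat),
                 std_error = unname(x$se[names(x$params_hat)]))
}

#' One-row summary of an RL MAP fit
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return Tibble with variant, log-likelihood, AIC/BIC, counts and flags.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, logLik = x$loglik, AIC = x$aic,
                 BIC = x$bic, n_free = x$n_free, n_trials = x$n_trials,
                 converged = x$converged)
}

#' Fit one or more variants to every session of a cohort
#'
#' @param sessions Trial tibble for several sessions (column `session`).
#' @param variants Character vector of variant names.
#' @param ... Passed to [fit_map()].
#' @return Tibble with one row per session x variant: fit summaries and a
#'   list-column `fit` of the `rl_fit` objects.
#' @export
fit_map_cohort <- function(sessions, variants = "hybrid7", ...) {
  split_sessions <- split(sessions, sessions$session)
  purrr::map_dfr(names(split_sessions), function(sid) {
    purrr::map_dfr(variants, function(v) {
      f <- fit_map(split_sessions[[sid]], variant = v, ...)
      dplyr::bind_cols(tibble::tibble(session = sid), glance(f),
                       tibble::tibble(fit = list(f)))
    })
  })
}

#' Compare RL variants across sessions
#'
#' Summed and per-session AIC/BIC, the winning variant per session, and
#' generalized likelihood-ratio statistics for the nested chain
#' hybrid4 < hybrid6 < hybrid7 where the relevant variants are present.
#'
#' @param fits A tibble from [fit_map_cohort()] covering >= 1 variant.
#' @return List with `by_session` (winner per session), `totals` (summed
#'   AIC/BIC and winner counts per variant), and `glrt` (nested deviance
#'   statistics, when computable).
#' @export
compare_variants <- function(fits) {
  complete_sessions <- fits |>
    dplyr::count(.data$session) |>
    dplyr::filter(.data$n == dplyr::n_distinct(fits$variant)) |>
    dplyr::pull(.data$session)
  dropped <- setdiff(unique(fits$session), complete_sessions)
  if (length(dropped) > 0) {
    warning(length(dropped), " session(s) missing a variant were excluded",
            call. = FALSE)
  }
  fits <- dplyr::filter(fits, .data$session %in% complete_sessions)
  by_session <- fits |>
    dplyr::group_by(.data$session) |>
    dplyr::slice_min(.data$AIC, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("session", winner = "variant", "AIC")
  totals <- fits |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(sum_AIC = sum(.data$AIC), sum_BIC = sum(.data$BIC),
                     sum_loglik = sum(.data$logLik),
                     n_free = .data$n_free[1], .groups = "drop") |>
    dplyr::left_join(dplyr::count(by_session, .data$winner, name = "n_wins"),
                     by = c(variant = "winner")) |>
    dplyr::mutate(n_wins = dplyr::coalesce(.data$n_wins, 0L))
  nested <- list(c("hybrid4", "hybrid6"), c("hybrid6", "hybrid7"),
                 c("hybrid4", "hybrid7"))
  glrt <- purrr::map_dfr(nested, function(pair) {
    if (!all(pair %in% totals$variant)) return(tibble::tibble())
    t0 <- totals[totals$variant == pair[1], ]
    t1 <- totals[totals$variant == pair[2], ]
    stat <- 2 * (t1$sum_loglik - t0$sum_loglik)
    df <- (t1$n_free - t0$n_free) * length(complete_sessions)
    tibble::tibble(null = pair[1], alt = pair[2], statistic = stat, df = df,
                   p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  })
  list(by_session = by_session, totals = totals, glrt = glrt)
}

#' Validate the first-stage-stay index against the perseveration parameter
#'
#' Across a cohort of sessions, computes the first-stage-stay (fss) index
#' from the hierarchical stay model and the MAP-estimated perseveration
#' weight from the RL fit, and reports their Pearson and Spearman
#' correlations with a bootstrap confidence interval. If the index truly
#' tracks habitual (outcome-insensitive) responding, the two should be
#' strongly correlated.
#'
#' @param sessions Trial tibble with `subject`, `visit`, `session` columns.
#' @param variant RL variant to fit (default `"hybrid7"`).
#' @param n_boot Bootstrap replicates for the CI (default 500).
#' @param seed Seed for fitting and the bootstrap.
#' @param ... Passed to [fit_map()].
#' @return List with `pearson`, `spearman`, `ci` (95% percentile bootstrap
#'   for Pearson), `degenerate` flag, and the per-session table `data`.
#' @export
validate_fss_vs_perseveration <- function(sessions, variant = "hybrid7",
                                          n_boot = 500, seed = 1, ...) {
  n_sessions <- dplyr::n_distinct(sessions$session)
  if (n_sessions < 10) stop("need at least 10 sessions", call. = FALSE)
  idx <- sessions |>
    build_stay_table() |>
    fit_stay_mlm() |>
    extract_indices()
  fits <- fit_map_cohort(sessions, variants = variant, seed = seed, ...)
  pi_hat <- fits |>
    dplyr::mutate(pi_persev = purrr::map_dbl(
      .data$fit, ~ .x$params_hat[["pi_persev"]])) |>
    dplyr::select("session", "pi_persev")
  df <- dplyr::inner_join(
    dplyr::mutate(idx, session = as.character(.data$session)),
    pi_hat, by = "session")
  degenerate <- stats::sd(df$pi_persev) < 1e-8 || stats::sd(df$fss) < 1e-8
  if (degenerate) {
    return(list(pearson = NA_real_, spearman = NA_real_,
                ci = c(NA_real_, NA_real_), degenerate = TRUE, data = df))
  }
  r_p <- stats::cor(df$fss, df$pi_persev)
  r_s <- stats::cor(df$fss, df$pi_persev, method = "spearman")
  set.seed(seed)
  boot <- replicate(n_boot, {
    i <- sample.int(nrow(df), replace = TRUE)
    stats::cor(df$fss[i], df$pi_persev[i])
  })
  list(pearson = r_p, spearman = r_s,
       ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       degenerate = FALSE, data = df)
}
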