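#' Build the lagged stay-probability table
#'
#' For every analyzable trial, codes the first-stage choice as stay (1) or
#' switch (0) relative to the previous trial, together with the previous
#' trial's reward (rewarded = +1, not rewarded = -1) and transition type
#' (common = +1, rare = -1). A row exists only when both the current and the
#' previous trial are complete; trials with a missed first- or second-stage
#' response are removed, as is the trial following them (its lag is
#' undefined).
#'
#' @param sessions A tibble of trials across sessions with columns
#'   `subject`, `visit`, `session`, `trial`, `block`, `s1_choice`,
#'   `transition`, `s2_choice`, `reward` (one session = one subject-visit).
#' @param reset_blocks Reset the lag at block boundaries? Default `FALSE`
#'   (the stay regressor crosses block breaks).
#' @return A tibble with columns `subject`, `visit`, `session`, `trial`,
#'   `stay` (0/1), `prev_reward` (-1/+1), `prev_transition` (-1/+1).
#'   Sessions with fewer than two complete trials contribute zero rows (with
#'   a warning).
#' @export
build_stay_table <- function(sessions, reset_blocks = FALSE) {
  stopifnot(all(c("subject", "visit", "session", "trial", "s1_choice",
                  "transition", "s2_choice", "reward") %in% names(sessions)))
  out <- sessions |>
    dplyr::group_by(.data$subject, .data$visit, .data$session) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      .complete = trial_complete(dplyr::pick(dplyr::everything())),
      stay = stay_indicator(dplyr::pick(dplyr::everything()),
                            reset_blocks = reset_blocks),
      prev_reward = 2L * dplyr::lag(.data$reward) - 1L,
      prev_transition = ifelse(dplyr::lag(.data$transition) == "common",
                               1L, -1L)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$stay), !is.na(.data$prev_reward),
                  !is.na(.data$prev_transition)) |>
    dplyr::select("subject", "visit", "session", "trial", "stay",
                  "prev_reward", "prev_transition")
  empty <- setdiff(unique(sessions$session), unique(out$session))
  if (length(empty) > 0) {
    warning(length(empty), " session(s) contributed no analyzable trials",
            call. = FALSE)
  }
  out
}

#' Fit the hierarchical logistic stay-probability model
#'
#' Multilevel logistic regression of stay/switch on previous reward,
#' previous transition type, and their interaction, with a random effect for
#' the intercept and every predictor grouped by session (subject-visit).
#' Fitted by Laplace-approximate maximum likelihood via [lme4::glmer()].
#'
#' @param table A stay table from [build_stay_table()].
#' @param re_structure `"full"` for an unstructured 4x4 random-effect
#'   covariance, `"diagonal"` for independent random effects, or `"auto"`
#'   (default): full when the table has at least 30 sessions, else diagonal.
#' @param group Grouping column for the random effects (default
#'   `"session"`, i.e. one effect vector per subject-visit).
#' @return An object of class `stay_fit`: list with the `lme4` fit (`fit`),
#'   `fixed` (named length-4 vector), `fixed_se`, `ranef_cov` (4x4),
#'   `blups` (tibble: one row per session with the four predicted random
#'   effects), `converged`, and `messages`.
#' @export
fit_stay_mlm <- function(table, re_structure = c("auto", "full", "diagonal"),
                         group = "session") {
  re_structure <- match.arg(re_structure)
  n_sessions <- dplyr::n_distinct(table[[group]])
  if (n_sessions < 2) stop("need at least 2 sessions", call. = FALSE)
  if (re_structure == "auto") {
    re_structure <- if (n_sessions >= 30) "full" else "diagonal"
  }
  re_term <- if (re_structure == "full") {
    sprintf("(1 + prev_reward * prev_transition | %s)", group)
  } else {
    sprintf("(1 + prev_reward * prev_transition || %s)", group)
  }
  form <- stats::as.formula(
    paste("stay ~ prev_reward * prev_transition +", re_term))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = table, family = stats::binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  converged <- length(fit@optinfo$conv$lme4$messages) == 0
  fx <- lme4::fixef(fit)
  names(fx) <- c("intercept", "reward", "transition", "interaction")
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- names(fx)
  re <- lme4::ranef(fit)[[group]]
  blups <- tibble::tibble(
    !!group := rownames(re),
    intercept = re[["(Intercept)"]],
    reward = re[["prev_reward"]],
    transition = re[["prev_transition"]],
    interaction = re[["prev_reward:prev_transition"]]
  )
  vc <- lme4::VarCorr(fit)
  if (re_structure == "full") {
    rc <- as.matrix(vc[[group]])
  } else {
    rc <- diag(vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1)))
  }
  dimnames(rc) <- list(names(fx), names(fx))
  meta <- if (all(c("subject", "visit") %in% names(table)) &&
              group == "session") {
    dplyr::distinct(table, .data$subject, .data$visit, .data$session) |>
      dplyr::mutate(session = as.character(.data$session))
  } else {
    NULL
  }
  structure(
    list(fit = fit, fixed = fx, fixed_se = se, ranef_cov = rc, blups = blups,
         converged = converged, messages = msgs, group = group, meta = meta),
    class = "stay_fit"
  )
}

#' Assemble the behavioral indices from a stay-model fit
#'
#' Per session: the model-based index (`mb`) is the fixed reward-by-
#' transition interaction plus the session's interaction random effect; the
#' model-free index (`mf`) is the fixed reward effect plus the session's
#' reward random effect; the first-stage-stay index (`fss`) — the habit /
#' perseveration measure — is the fixed intercept plus the session's random
#' intercept. With the ±1 predictor codings, `fss` is the session's
#' predicted stay log-odds at the average of all previous-outcome
#' conditions.
#'
#' @param fit A [fit_stay_mlm()] result.
#' @return Tibble with one row per session: `session` (plus `subject` and
#'   `visit` when available), `mb`, `mf`, `fss`.
#' @export
extract_indices <- function(fit) {
  stopifnot(inherits(fit, "stay_fit"))
  out <- fit$blups |>
    dplyr::transmute(
      session = .data[[fit$group]],
      mb = fit$fixed[["interaction"]] + .data$interaction,
      mf = fit$fixed[["reward"]] + .data$reward,
      fss = fit$fixed[["intercept"]] + .data$intercept
    )
  if (!is.null(fit$meta)) {
    out <- dplyr::left_join(fit$meta, out, by = "session")
  }
  out
}

#' Supplementary multilevel models: age moderation and transition RTs
#'
#' Two models reported alongside the main indices: (a) the stay model
#' augmented with a standardized-age main effect and all two- and three-way
#' interactions with previous reward and transition; (b) a linear
#' mixed model of second-stage response time on transition type (rare vs
#' common) and its interaction with age, with session random intercepts —
#' slower responding after rare transitions indicates awareness of the task
#' transition structure.
#'
#' @param table A stay table from [build_stay_table()].
#' @param rt_table Tibble with columns `session`, `transition`, `rt2` (one
#'   row per completed trial).
#' @param ages Tibble with columns `session`, `age`.
#' @return List of two tidy coefficient tables (`stay_by_age`,
#'   `rt_by_transition`) with estimates, standard errors, statistics and
#'   p-values.
#' @export
fit_supplementary_mlms <- function(table, rt_table, ages) {
  ages <- dplyr::mutate(ages, session = as.character(.data$session),
                        age_z = as.numeric(scale(.data$age)))
  tab <- table |>
    dplyr::mutate(session = as.character(.data$session)) |>
    dplyr::left_join(dplyr::select(ages, "session", "age_z"), by = "session")
  stay_fit <- lme4::glmer(
    stay ~ prev_reward * prev_transition * age_z +
      (1 + prev_reward * prev_transition || session),
    data = tab, family = stats::binomial(),
    control = lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE))
  sco <- stats::coef(summary(stay_fit))
  stay_tidy <- tibble::tibble(
    term = rownames(sco), estimate = sco[, 1], std_error = sco[, 2],
    statistic = sco[, 3], p_value = sco[, 4]
  )

  rt <- rt_table |>
    dplyr::mutate(session = as.character(.data$session),
                  rare = as.integer(.data$transition == "rare")) |>
    dplyr::filter(!is.na(.data$rt2)) |>
    dplyr::left_join(dplyr::select(ages, "session", "age_z"), by = "session")
  use_age <- !all(is.na(rt$age_z)) && stats::sd(rt$age_z, na.rm = TRUE) > 0
  form <- if (use_age) rt2 ~ rare * age_z + (1 | session) else
    rt2 ~ rare + (1 | session)
  rt_fit <- lme4::lmer(form, data = rt, REML = TRUE)
  rco <- stats::coef(summary(rt_fit))
  rt_tidy <- tibble::tibble(
    term = rownames(rco), estimate = rco[, 1], std_error = rco[, 2],
    statistic = rco[, 3],
    p_value = 2 * stats::pnorm(-abs(rco[, 3]))  # Wald normal approximation
  )
  list(stay_by_age = stay_tidy, rt_by_transition = rt_tidy)
}

#' @method print stay_fit
#' @export
print.stay_fit <- function(x, ...) {
  cat("Hierarchical logistic stay-probability model\n")
  cat("  sessions:", nrow(x$blups), " converged:", x$converged, "\n")
  cat("  fixed effects (log-odds):\n")
  print(round(rbind(estimate = x$fixed, se = x$fixed_se), 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a stay-model fit
#'
#' @param x A `stay_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.stay_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$fixed),
    estimate = unname(x$fixed),
    std_error = unname(x$fixed_se),
    statistic = unname(x$fixed / x$fixed_se),
    p_value = 2 * stats::pnorm(-abs(unname(x$fixed / x$fixed_se)))
  )
}

#' One-row summary of a stay-model fit
#'
#' @param x A `stay_fit` object.
#' @param ... Unused.
#' @return Tibble with session/row counts, log-likelihood, AIC and a
#'   convergence flag.
#' @export
glance.stay_fit <- function(x, ...) {
  ll <- as.numeric(stats::logLik(x$fit))
  tibble::tibble(
    n_sessions = nrow(x$blups),
    n_obs = stats::nobs(x$fit),
    logLik = ll,
    AIC = stats::AIC(x$fit),
    converged = x$converged
  )
}
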