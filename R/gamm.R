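#' Penalized cubic-regression-spline basis
#'
#' Builds a low-rank cubic regression spline basis of dimension `k` with
#' knots at quantiles of `x`, centered (sum-to-zero over the data) for
#' identifiability, together with its second-derivative penalty matrix. The
#' penalty's null space is the space of linear functions: an exactly linear
#' fitted function incurs zero penalty.
#'
#' @param x Covariate values (>= `k` distinct values required).
#' @param k Basis dimension before the centering constraint (default 3, the
#'   package-wide default for age smooths).
#' @return List of class `spline_basis` with `X` (n x (k-1) design after
#'   centering), `S` (penalty matrix), `knots`, `k`, and the underlying
#'   smooth construction object `sm` used for prediction.
#' @export
build_basis <- function(x, k = 3) {
  stopifnot(k >= 3)
  if (length(unique(x)) < k) {
    stop("need at least ", k, " distinct covariate values", call. = FALSE)
  }
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k), data = dat,
                        absorb.cons = TRUE)[[1]]
  structure(
    list(X = sm$X, S = sm$S[[1]], knots = sm$xp, k = k, sm = sm),
    class = "spline_basis"
  )
}

#' Evaluate a spline basis at new covariate values
#'
#' @param basis A [build_basis()] result.
#' @param x_new New covariate values.
#' @return Design matrix at `x_new` under the same centering constraint.
#' @export
eval_basis <- function(basis, x_new) {
  mgcv::PredictMat(basis$sm, data.frame(x = x_new))
}

#' Fit a penalized-spline mixed model (GAMM)
#'
#' Gaussian additive model for a response measured per subject-visit:
#' linear covariates (by default sex and visit number), penalized
#' cubic-regression-spline smooths (by default a smooth of age with basis
#' dimension `k = 3`), optional varying-coefficient terms (a covariate's
#' linear effect changing smoothly with age), and a subject random
#' intercept absorbed as a ridge-penalized smooth. Fitting, smoothing-
#' parameter selection and the Bayesian coefficient covariance come from
#' [mgcv::gam()].
#'
#' @param data Data frame with the response and all covariates; `subject`
#'   must be a factor (coerced) when `random = "subject"`.
#' @param response Response column name (e.g. an ROI's nT2*w or a
#'   behavioral index).
#' @param smooths Character vector of covariates receiving a smooth
#'   (default `"age"`).
#' @param by_smooths Named character vector: varying-coefficient terms,
#'   names = smoothing covariate, values = the covariate whose linear
#'   coefficient varies (e.g. `c(age = "fss_resid")`).
#' @param linear Character vector of linear covariates (default
#'   `c("sex", "visit")`).
#' @param random Grouping column for the random intercept, or `NULL`.
#' @param k Basis dimension for all smooths (default 3).
#' @param method Smoothing-parameter criterion: `"REML"` (default, for
#'   single-model summaries) or `"ML"` (required whenever models are
#'   compared).
#' @return Object of class `gamm_fit` wrapping the `gam` fit with the model
#'   specification; `edf` per smooth, the random-intercept variance and the
#'   coefficient covariance are available through the methods below.
#' @export
fit_gamm <- function(data, response, smooths = "age", by_smooths = NULL,
                     linear = c("sex", "visit"), random = "subject",
                     k = 3, method = c("REML", "ML")) {
  method <- match.arg(method)
  need <- c(response, smooths, unname(by_smooths), names(by_smooths),
            linear, random)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)
  if (!is.null(random)) data[[random]] <- factor(data[[random]])
  if (length(by_smooths) > 0) {
    # a zero-variance by-covariate makes the term inert and the penalized
    # fit degenerate; drop it explicitly
    keep <- vapply(unname(by_smooths),
                   function(v) stats::sd(data[[v]]) > 0, logical(1))
    if (any(!keep)) {
      warning("dropping varying-coefficient term(s) with constant ",
              "covariate: ", paste(by_smooths[!keep], collapse = ", "),
              call. = FALSE)
      by_smooths <- by_smooths[keep]
    }
  }
  terms <- c(
    linear,
    sprintf("s(%s, bs = 'cr', k = %d)", smooths, k),
    if (length(by_smooths) > 0) {
      sprintf("s(%s, by = %s, bs = 'cr', k = %d)", names(by_smooths),
              unname(by_smooths), k)
    },
    if (!is.null(random)) sprintf("s(%s, bs = 're')", random)
  )
  form <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = data, method = method)
  if (!fit$converged) warning("GAMM did not converge", call. = FALSE)
  structure(
    list(gam = fit, response = response, smooths = smooths,
         by_smooths = by_smooths, linear = linear, random = random, k = k,
         method = method, data = data, converged = fit$converged),
    class = "gamm_fit"
  )
}

# label of the smooth for a variable (optionally a by= term)
smooth_label <- function(fit, variable, by = NULL) {
  labs <- vapply(fit$gam$smooth, `[[`, character(1), "label")
  target <- if (is.null(by)) sprintf("s(%s)", variable) else
    sprintf("s(%s):%s", variable, by)
  i <- match(target, labs)
  if (is.na(i)) {
    stop("no smooth term '", target, "' in the model; available: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  i
}

#' Significance of a fitted smooth
#'
#' Wald-type test of a smooth term against zero using the Bayesian
#' coefficient covariance, reported in the (edf, F, p) format used for
#' developmental-trajectory summaries.
#'
#' @param fit A [fit_gamm()] result.
#' @param variable The smooth's covariate (e.g. `"age"`).
#' @param by Optional `by` covariate identifying a varying-coefficient term.
#' @return Tibble with `term`, `edf`, `F`, `p_value`.
#' @export
smooth_significance <- function(fit, variable = "age", by = NULL) {
  i <- smooth_label(fit, variable, by)
  st <- summary(fit$gam)$s.table
  lab <- fit$gam$smooth[[i]]$label
  row <- st[rownames(st) == lab, , drop = FALSE]
  tibble::tibble(term = lab, edf = row[1, "edf"], F = row[1, "F"],
                 p_value = row[1, "p-value"])
}

#' Residualize a variable on age
#'
#' Simple linear regression of `values` on `ages`; returns the residuals,
#' which are exactly orthogonal to age and to the constant. Used to
#' orthogonalize behavioral indices against the age smooth before entering
#' them into tissue-iron models (avoiding concurvity between the age smooth
#' and behavior smooths, since all indices increase with age).
#'
#' @param values Numeric vector.
#' @param ages Numeric vector of the same length.
#' @return Numeric vector of residuals.
#' @export
residualize_age <- function(values, ages) {
  stopifnot(length(values) == length(ages))
  if (stats::sd(ages) == 0) stop("age vector is constant", call. = FALSE)
  stats::resid(stats::lm(values ~ ages))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Number of comparisons (>= 1). With the four basal-ganglia ROIs
#'   this gives 0.0125; with the three behavioral indices, 0.0167.
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Compare the nested four-model ladder for one response
#'
#' Fits the sequence: Model 1 = age smooth only; Model 2 = + smooth of the
#' first behavior; Model 3 = + smooth of the second; Model 4 = + smooth of
#' the third (behaviors are age-residualized indices, entered in the order
#' first-stage stay, model-based, model-free). All models are fit by
#' maximum likelihood, and compared on the marginal (mixed-model)
#' likelihood in which the penalized coefficients and the subject random
#' intercepts are integrated out — the conditional likelihood of a fit
#' with hundreds of random-intercept degrees of freedom is not comparable
#' across models. Adjacent models are compared with analysis-of-deviance
#' (likelihood-ratio) tests, with degrees of freedom equal to the added
#' smooth's basis dimension (an approximation, documented), and with AIC
#' on the same marginal likelihood; a more complex model is retained only
#' when BOTH the deviance test (at `alpha`) and the AIC favor it.
#'
#' @param data Data frame with response, `age`, the behavior columns,
#'   linear covariates and `subject`.
#' @param response Response column name.
#' @param behaviors Character vector (length <= 3) of behavior columns, in
#'   inclusion order.
#' @param alpha Deviance-test level for advancing (default 0.05).
#' @inheritParams fit_gamm
#' @return Object of class `ladder_result`: list with `models` (tibble of
#'   per-model AIC, deviance, edf), `tests` (adjacent deviance tests),
#'   `retained` (model number) and the fitted `gamm_fit` objects.
#' @export
compare_model_ladder <- function(data, response,
                                 behaviors = c("fss_resid", "mb_resid",
                                               "mf_resid"),
                                 linear = c("sex", "visit"),
                                 random = "subject", k = 3, alpha = 0.05) {
  stopifnot(length(behaviors) >= 1, length(behaviors) <= 3)
  fits <- lapply(0:length(behaviors), function(j) {
    fit_gamm(data, response, smooths = c("age", behaviors[seq_len(j)]),
             linear = linear, random = random, k = k, method = "ML")
  })
  model_tbl <- purrr::map_dfr(seq_along(fits), function(j) {
    g <- fits[[j]]$gam
    # marginal log-likelihood: gam's ML criterion is its negative
    ll_m <- -as.numeric(g$gcv.ubre)
    # parameter count: unpenalized coefficients, spline coefficients of
    # non-random-effect smooths, smoothing/variance parameters, residual
    # variance (random-intercept levels count via their variance parameter)
    n_coef_smooth <- sum(vapply(
      g$smooth, function(s) as.numeric(s$last.para - s$first.para + 1),
      numeric(1)))
    n_spline <- sum(vapply(g$smooth, function(s) {
      if (inherits(s, "random.effect")) 0 else as.numeric(s$bs.dim - 1)
    }, numeric(1)))
    n_par <- length(stats::coef(g)) - n_coef_smooth + n_spline +
      length(g$sp) + 1L
    tibble::tibble(model = j, logLik_marginal = ll_m,
                   AIC = -2 * ll_m + 2 * n_par, n_par = n_par,
                   deviance = stats::deviance(g), edf = sum(g$edf))
  })
  tests <- purrr::map_dfr(seq_len(length(fits) - 1), function(j) {
    # likelihood-ratio (analysis of deviance) on the marginal likelihood;
    # df = basis dimension of the added behavior smooth
    added <- fits[[j + 1]]$gam$smooth[[j + 1]]
    df <- as.numeric(added$bs.dim - 1)
    stat <- 2 * (model_tbl$logLik_marginal[j + 1] -
                   model_tbl$logLik_marginal[j])
    tibble::tibble(null_model = j, alt_model = j + 1, statistic = stat,
                   df = df,
                   p_value = stats::pchisq(pmax(stat, 0), df,
                                           lower.tail = FALSE))
  })
  retained <- 1L
  for (j in seq_len(nrow(tests))) {
    p_ok <- !is.na(tests$p_value[j]) && tests$p_value[j] < alpha
    aic_ok <- model_tbl$AIC[j + 1] < model_tbl$AIC[j]
    if (p_ok && aic_ok && retained == j) retained <- j + 1L else break
  }
  structure(
    list(models = model_tbl, tests = tests, retained = retained,
         fits = fits, response = response, behaviors = behaviors),
    class = "ladder_result"
  )
}

#' @method print ladder_result
#' @export
print.ladder_result <- function(x, ...) {
  cat("Model ladder for", x$response, "- retained: Model", x$retained, "\n")
  print(as.data.frame(x$models), row.names = FALSE)
  invisible(x)
}

#' Fit a varying-coefficient (time-varying) model
#'
#' Extends the age-trajectory model with a term `f(age) * behavior` that
#' lets the linear association between a behavioral index and the response
#' vary smoothly with age.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param behavior Column whose coefficient varies with age (typically an
#'   age-residualized index).
#' @inheritParams fit_gamm
#' @return A `gamm_fit` whose `by_smooths` records the term.
#' @export
fit_varying_coefficient <- function(data, response, behavior,
                                    linear = c("sex", "visit"),
                                    random = "subject", k = 3,
                                    method = c("REML", "ML")) {
  fit_gamm(data, response, smooths = "age",
           by_smooths = stats::setNames(behavior, "age"),
           linear = linear, random = random, k = k,
           method = match.arg(method))
}

# prediction matrix restricted to one smooth term's columns, on an age grid
term_lpmatrix <- function(fit, variable, by, grid_n) {
  g <- fit$gam
  i <- smooth_label(fit, variable, by)
  sm <- g$smooth[[i]]
  ages <- fit$data[[variable]]
  grid <- seq(min(ages), max(ages), length.out = grid_n)
  nd <- fit$data[rep(1L, grid_n), , drop = FALSE]
  nd[[variable]] <- grid
  if (!is.null(by)) nd[[by]] <- 1  # evaluate beta(age) per unit of behavior
  Xp <- stats::predict(g, newdata = nd, type = "lpmatrix")
  idx <- sm$first.para:sm$last.para
  list(grid = grid, X = Xp[, idx, drop = FALSE], idx = idx)
}

#' Windows of significance for a smooth or varying-coefficient term
#'
#' Draws `n_sims` coefficient vectors from the Gaussian approximation to
#' the coefficient posterior (mean = estimates, covariance = Bayesian
#' covariance), evaluates the term — or its first derivative via central
#' finite differences with step equal to the grid spacing — on an evenly
#' spaced age grid, and returns the maximal age intervals where the
#' pointwise (default) or simultaneous 95% interval excludes zero. For a
#' varying-coefficient term the monitored quantity is the age-varying
#' coefficient beta(age) per unit of the behavior covariate.
#'
#' @param fit A [fit_gamm()] / [fit_varying_coefficient()] result.
#' @param variable Covariate of the smooth (default `"age"`).
#' @param by Optional `by` covariate naming a varying-coefficient term;
#'   defaults to the fit's varying-coefficient term when one exists.
#' @param mode `"coefficient"` monitors the term itself (where is the
#'   association non-zero); `"derivative"` monitors its first derivative
#'   (where is the association changing).
#' @param n_sims Posterior simulations (default 10000; minimum 100).
#' @param grid_n Age-grid size (default 200).
#' @param level Interval level (default 0.95).
#' @param simultaneous Use a simultaneous (max-t) band instead of pointwise
#'   intervals? Default `FALSE`.
#' @param seed Seed for the posterior simulation.
#' @return Object of class `window_result`: list with `grid` (tibble: age,
#'   estimate, lo, hi), `windows` (tibble of disjoint sorted intervals
#'   `start`/`end`), `mode`, `level`, `term`, `simultaneous`.
#' @export
derivative_windows <- function(fit, variable = "age", by = NULL,
                               mode = c("coefficient", "derivative"),
                               n_sims = 10000, grid_n = 200, level = 0.95,
                               simultaneous = FALSE, seed = 1) {
  mode <- match.arg(mode)
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  if (is.null(by) && length(fit$by_smooths) > 0) {
    by <- unname(fit$by_smooths[1])
  }
  tl <- term_lpmatrix(fit, variable, by, grid_n)
  g <- fit$gam
  mu <- stats::coef(g)[tl$idx]
  V <- g$Vp[tl$idx, tl$idx, drop = FALSE]
  set.seed(seed)
  draws <- MASS::mvrnorm(n_sims, mu, V)          # n_sims x p
  curves <- tl$X %*% t(draws)                    # grid_n x n_sims
  est <- as.numeric(tl$X %*% mu)
  if (mode == "derivative") {
    h <- tl$grid[2] - tl$grid[1]
    cdiff <- function(m) {
      d <- m
      n <- nrow(m)
      d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                           m[1:(n - 2), , drop = FALSE]) / (2 * h)
      d[1, ] <- (m[2, ] - m[1, ]) / h
      d[n, ] <- (m[n, ] - m[n - 1, ]) / h
      d
    }
    curves <- cdiff(curves)
    est <- as.numeric(cdiff(cbind(est)))
  }
  a <- (1 - level) / 2
  if (simultaneous) {
    se_g <- apply(curves, 1, stats::sd)
    se_g[se_g == 0] <- 1e-12
    zmax <- apply(abs(sweep(curves - est, 1, se_g, `/`)), 2, max)
    crit <- stats::quantile(zmax, level)
    lo <- est - crit * se_g
    hi <- est + crit * se_g
  } else {
    lo <- apply(curves, 1, stats::quantile, probs = a)
    hi <- apply(curves, 1, stats::quantile, probs = 1 - a)
  }
  sig <- lo > 0 | hi < 0
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  windows <- tibble::tibble(
    start = tl$grid[starts[runs$values]],
    end = tl$grid[ends[runs$values]]
  ) |> dplyr::arrange(.data$start)
  structure(
    list(grid = tibble::tibble(age = tl$grid, estimate = est, lo = lo,
                               hi = hi, significant = sig),
         windows = windows, mode = mode, level = level,
         term = if (is.null(by)) sprintf("s(%s)", variable) else
           sprintf("s(%s):%s", variable, by),
         simultaneous = simultaneous),
    class = "window_result"
  )
}

#' @method print window_result
#' @export
print.window_result <- function(x, ...) {
  cat("Windows of significance (", x$mode, ", ",
      if (x$simultaneous) "simultaneous" else "pointwise", " ",
      round(100 * x$level), "% CI) for ", x$term, ":\n", sep = "")
  if (nrow(x$windows) == 0) cat("  none\n") else
    print(as.data.frame(round(x$windows, 2)), row.names = FALSE)
  invisible(x)
}

#' Marginal response-by-age trajectories at fixed behavior levels
#'
#' Predicted response-versus-age curves from a varying-coefficient fit with
#' the behavior covariate held at its mean and at ±1 and ±2 SD (computed
#' from the fitting data), with pointwise confidence intervals. Subject
#' random effects are excluded; sex and visit are held at reference values.
#'
#' @param fit A [fit_varying_coefficient()] result.
#' @param levels Behavior levels in SD units (default `c(-2, -1, 0, 1, 2)`).
#' @param grid_n Age-grid size.
#' @param level CI level.
#' @return Tibble of class `marginal_trajectories` with `age`, `level_sd`,
#'   `behavior_value`, `estimate`, `lo`, `hi`.
#' @export
marginal_trajectories <- function(fit, levels = c(-2, -1, 0, 1, 2),
                                  grid_n = 200, level = 0.95) {
  if (length(fit$by_smooths) == 0) {
    stop("fit has no varying-coefficient term", call. = FALSE)
  }
  beh <- unname(fit$by_smooths[1])
  b_vals <- fit$data[[beh]]
  b_mean <- mean(b_vals)
  b_sd <- stats::sd(b_vals)
  out_range <- levels[abs(b_mean + levels * b_sd - b_mean) >
                        max(abs(b_vals - b_mean))]
  if (length(out_range) > 0) {
    warning("levels beyond the data-supported behavior range: ",
            paste(out_range, collapse = ", "), call. = FALSE)
  }
  ages <- fit$data$age
  grid <- seq(min(ages), max(ages), length.out = grid_n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  re_label <- if (!is.null(fit$random)) {
    sprintf("s(%s)", fit$random)
  } else NULL
  purrr::map_dfr(levels, function(l) {
    nd <- fit$data[rep(1L, grid_n), , drop = FALSE]
    nd$age <- grid
    nd[[beh]] <- b_mean + l * b_sd
    for (v in fit$linear) nd[[v]] <- if (is.numeric(fit$data[[v]]))
      mean(fit$data[[v]]) else fit$data[[v]][1]
    pr <- stats::predict(fit$gam, newdata = nd, se.fit = TRUE,
                         exclude = re_label)
    tibble::tibble(age = grid, level_sd = l,
                   behavior_value = b_mean + l * b_sd,
                   estimate = as.numeric(pr$fit),
                   lo = as.numeric(pr$fit) - z * as.numeric(pr$se.fit),
                   hi = as.numeric(pr$fit) + z * as.numeric(pr$se.fit))
  }) |>
    structure(class = c("marginal_trajectories", "tbl_df", "tbl", "data.frame"))
}

#' Tidy a GAMM fit
#'
#' @param x A `gamm_fit` object.
#' @param ... Unused.
#' @return Tibble with the parametric coefficients and the smooth-term
#'   (edf, F, p) rows.
#' @export
tidy.gamm_fit <- function(x, ...) {
  s <- summary(x$gam)
  pt <- s$p.table
  para <- tibble::tibble(term = rownames(pt), type = "parametric",
                         estimate = pt[, 1], std_error = pt[, 2],
                         statistic = pt[, 3], p_value = pt[, 4],
                         edf = NA_real_)
  st <- s$s.table
  sm <- tibble::tibble(term = rownames(st), type = "smooth",
                       estimate = NA_real_, std_error = NA_real_,
                       statistic = st[, "F"], p_value = st[, "p-value"],
                       edf = st[, "edf"])
  dplyr::bind_rows(para, sm)
}

#' One-row summary of a GAMM fit
#'
#' @param x A `gamm_fit` object.
#' @param ... Unused.
#' @return Tibble with n, criterion value and method, AIC, residual and
#'   random-intercept variances, and R-squared.
#' @export
glance.gamm_fit <- function(x, ...) {
  g <- x$gam
  re_var <- if (!is.null(x$random)) {
    vc <- mgcv::gam.vcomp(g, rescale = TRUE)
    lbl <- sprintf("s(%s)", x$random)
    if (lbl %in% rownames(vc)) vc[lbl, 1]^2 else NA_real_
  } else NA_real_
  tibble::tibble(
    n = stats::nobs(g), method = x$method,
    criterion = as.numeric(g$gcv.ubre), AIC = stats::AIC(g),
    sigma2 = g$sig2, ranef_var = re_var,
    r_squared = summary(g)$r.sq, converged = x$converged
  )
}

#' @method print gamm_fit
#' @export
print.gamm_fit <- function(x, ...) {
  cat("Penalized-spline mixed model:", x$response, "(", x$method, ")\n")
  print(tidy(x), n = Inf)
  invisible(x)
}
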