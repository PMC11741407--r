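#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the analysis sequence end to end: cohort generation, behavioral
#' index estimation (hierarchical stay model, or latent indices when
#' `simulate_trials = FALSE`), batch harmonization of ROI nT2*w, per-ROI and
#' per-behavior age-trajectory models with Bonferroni-adjusted summaries,
#' age-residualization of the indices, the nested four-model ladder per ROI,
#' varying-coefficient fits with windows of significance and marginal
#' trajectories for ROIs that retain a behavioral model, and (optionally)
#' MAP RL fits on a session subsample with the fss-vs-perseveration
#' validation. Idempotent given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed governing every stage.
#' @param simulate_trials Passed to [generate_cohort()].
#' @param rois ROIs to analyze (default: the four primary basal-ganglia
#'   ROIs plus the four putamen subdivisions).
#' @param behaviors Behavioral indices to consider, in ladder inclusion
#'   order (default `c("fss", "mb", "mf")`).
#' @param fit_rl Run the MAP RL validation stage? Default `FALSE` (the
#'   slowest stage; validation-only).
#' @param rl_subsample Number of sessions for the RL stage (default 50).
#' @param window_mode Monitored quantity for windows (default
#'   `"coefficient"`).
#' @param n_sims Posterior simulations for windows (default 10000).
#' @param out_dir Optional directory; when given, report tables are written
#'   as CSV.
#' @return Object of class `pipeline_report`: list with `design`,
#'   `indices`, `analysis` (wide per-session analysis table),
#'   `descriptives`, `roi_trajectories`, `behavior_trajectories`, `ladder`
#'   (per-ROI retained models), `windows`, `marginals`, `rl_validation`,
#'   and `seed`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = config$seed,
                         simulate_trials = TRUE,
                         rois = NULL, behaviors = c("fss", "mb", "mf"),
                         fit_rl = FALSE, rl_subsample = 50,
                         window_mode = c("coefficient", "derivative"),
                         n_sims = 10000, out_dir = NULL) {
  window_mode <- match.arg(window_mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("generate", generate_cohort(config, seed = seed,
                                              simulate_trials = simulate_trials))
  if (is.null(rois)) rois <- unique(cohort$iron$region)

  indices <- stage("indices", {
    if (simulate_trials) {
      cohort$trials |>
        build_stay_table() |>
        fit_stay_mlm() |>
        extract_indices() |>
        dplyr::mutate(session = as.character(.data$session))
    } else {
      dplyr::select(cohort$indices, "subject", "visit", "session",
                    "fss", "mb", "mf")
    }
  })

  iron <- stage("harmonize", {
    harmonize_batches(cohort$iron, value = "nT2w", batch = "batch",
                      covariates = c("age", "sex"))
  })

  analysis <- stage("assemble", {
    iron |>
      dplyr::select("session", "region", "nT2w") |>
      tidyr::pivot_wider(names_from = "region", values_from = "nT2w") |>
      dplyr::inner_join(cohort$design, by = "session") |>
      dplyr::inner_join(dplyr::select(indices, "session", "fss", "mb",
                                      "mf"),
                        by = "session")
  })

  descriptives <- stage("descriptives", {
    summarize_descriptives(analysis,
                           vars = c("age", behaviors, rois))
  })

  alpha_roi <- bonferroni(0.05, 4)       # four primary basal-ganglia ROIs
  alpha_beh <- bonferroni(0.05, length(behaviors))

  roi_traj <- stage("roi_trajectories", {
    purrr::map_dfr(rois, function(r) {
      f <- fit_gamm(analysis, r, method = "REML")
      smooth_significance(f, "age") |>
        dplyr::mutate(response = r, alpha = alpha_roi,
                      significant = .data$p_value < alpha_roi, .before = 1)
    })
  })

  beh_traj <- stage("behavior_trajectories", {
    purrr::map_dfr(behaviors, function(b) {
      f <- fit_gamm(analysis, b, method = "REML")
      smooth_significance(f, "age") |>
        dplyr::mutate(response = b, alpha = alpha_beh,
                      significant = .data$p_value < alpha_beh, .before = 1)
    })
  })

  analysis <- stage("residualize", {
    dplyr::mutate(analysis, dplyr::across(
      dplyr::all_of(behaviors), ~ residualize_age(.x, analysis$age),
      .names = "{.col}_resid"))
  })

  ladder <- stage("ladder", {
    res <- lapply(rois, function(r) {
      compare_model_ladder(analysis, r,
                           behaviors = paste0(behaviors, "_resid"))
    })
    names(res) <- rois
    res
  })
  ladder_tbl <- purrr::map_dfr(rois, function(r) {
    tibble::tibble(region = r, retained = ladder[[r]]$retained)
  })

  windows <- list()
  marginals <- list()
  for (r in rois) {
    keep <- ladder_tbl$retained[ladder_tbl$region == r]
    if (keep < 2) next
    for (b in behaviors[seq_len(min(keep - 1, length(behaviors)))]) {
      vc <- stage(paste0("varying_", r, "_", b), {
        fit_varying_coefficient(analysis, r, paste0(b, "_resid"),
                                method = "REML")
      })
      key <- paste(r, b, sep = ".")
      windows[[key]] <- derivative_windows(
        vc, mode = window_mode, n_sims = n_sims, seed = seed)
      marginals[[key]] <- marginal_trajectories(vc)
    }
  }

  rl_validation <- NULL
  if (fit_rl && simulate_trials) {
    rl_validation <- stage("rl_validation", {
      sess <- unique(cohort$trials$session)
      set.seed(seed)
      pick <- sample(sess, min(rl_subsample, length(sess)))
      sub <- dplyr::filter(cohort$trials, .data$session %in% pick)
      validate_fss_vs_perseveration(sub, seed = seed)
    })
  }

  report <- structure(
    list(design = cohort$design, indices = indices, analysis = analysis,
         descriptives = descriptives, roi_trajectories = roi_traj,
         behavior_trajectories = beh_traj, ladder = ladder_tbl,
         ladder_detail = ladder, windows = windows, marginals = marginals,
         rl_validation = rl_validation, seed = seed,
         truth = cohort$truth),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$analysis,
                     file.path(out_dir, "analysis_table.csv"),
                     row.names = FALSE)
    utils::write.csv(report$roi_trajectories,
                     file.path(out_dir, "roi_trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(report$behavior_trajectories,
                     file.path(out_dir, "behavior_trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(report$ladder, file.path(out_dir, "ladder.csv"),
                     row.names = FALSE)
    win_tbl <- purrr::imap_dfr(report$windows, function(w, key) {
      if (nrow(w$windows) == 0) return(tibble::tibble())
      dplyr::mutate(w$windows, term = key, .before = 1)
    })
    utils::write.csv(win_tbl, file.path(out_dir, "windows.csv"),
                     row.names = FALSE)
  }
  report
}

#' @method print pipeline_report
#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  cat("  sessions:", nrow(x$design), "\n")
  cat("  ladder retained models:\n")
  print(as.data.frame(x$ladder), row.names = FALSE)
  if (length(x$windows) > 0) {
    cat("  significance windows:\n")
    for (k in names(x$windows)) {
      w <- x$windows[[k]]$windows
      cat("   ", k, ":",
          if (nrow(w) == 0) "none" else
            paste(sprintf("[%.2f, %.2f]", w$start, w$end), collapse = " "),
          "\n")
    }
  }
  invisible(x)
}

#' Descriptive statistics and zero-order correlations
#'
#' Pairwise Pearson correlations plus mean and SD for a set of variables,
#' in the conventional correlation-table layout (one row per variable,
#' correlation columns followed by mean and SD).
#'
#' @param data Data frame.
#' @param vars Variable names (numeric columns of `data`).
#' @return Tibble with `variable`, one correlation column per variable,
#'   `mean`, `sd` — dimensions `length(vars)` x `(length(vars) + 3)`
#'   including the name column.
#' @export
summarize_descriptives <- function(data, vars) {
  vars <- intersect(vars, names(data))
  m <- as.matrix(data[, vars])
  cc <- stats::cor(m, use = "pairwise.complete.obs")
  out <- tibble::as_tibble(cc, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(variable = vars), out) |>
    dplyr::mutate(mean = colMeans(m, na.rm = TRUE),
                  sd = apply(m, 2, stats::sd, na.rm = TRUE))
}
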