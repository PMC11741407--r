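#' Default ROI trajectory parameters
#'
#' Exponential-approach trajectories `nT2w(age) = asymptote +
#' amplitude * exp(-rate * (age - 10))`: nT2*w decreases (iron accumulates)
#' with age, fastest early and flattening into adulthood. The caudate is
#' given a weak, shallow trajectory, emulating its weak age association.
#'
#' @return Tibble with `region`, `asymptote`, `amplitude`, `rate`.
#' @export
default_roi_params <- function() {
  tibble::tribble(
    ~region,                      ~asymptote, ~amplitude, ~rate,
    "caudate",                        -0.35,       0.30,  0.05,
    "putamen",                        -0.90,       0.90,  0.10,
    "globus_pallidus",                -1.10,       1.00,  0.12,
    "nucleus_accumbens",              -0.60,       0.55,  0.08,
    "anterior_dorsal_putamen",        -0.85,       0.85,  0.10,
    "anterior_ventral_putamen",       -0.80,       0.80,  0.09,
    "posterior_dorsal_putamen",       -0.95,       0.95,  0.11,
    "posterior_ventral_putamen",      -0.92,       0.90,  0.10
  )
}

#' Default behavior-to-iron coupling specification
#'
#' One row per (region, index) coupling. The age-varying coupling
#' `beta(age)` is `amplitude` below `a0`, ramps linearly to 0 at `a1`, and
#' is 0 above; `a0 = Inf` makes it constant at `amplitude`. The default
#' couples the subject's perseveration residual (the driver of the
#' first-stage-stay index) to the putamen and its posterior subdivisions:
#' negative amplitude, so more perseveration for one's age means lower
#' nT2*w (more tissue iron), active in adolescence and fading by the
#' mid-twenties.
#'
#' @param amplitude Coupling amplitude (nT2*w units per unit of index
#'   residual; default -0.4).
#' @param a0,a1 Ramp onset and cutoff ages (defaults 14 and 23).
#' @return Tibble with `region`, `index`, `amplitude`, `a0`, `a1`.
#' @export
default_couplings <- function(amplitude = -0.4, a0 = 14, a1 = 23) {
  tibble::tibble(
    region = c("putamen", "posterior_dorsal_putamen",
               "posterior_ventral_putamen"),
    index = "fss", amplitude = amplitude, a0 = a0, a1 = a1
  )
}

#' Configuration of the synthetic accelerated-longitudinal cohort
#'
#' Defaults emulate the study design: 217 subjects in two scanner batches
#' (156 in batch A with 1-3 visits about 1.5 years apart, 61 in batch B
#' with a single visit, about 320 sessions in total), ages 10.17-33.22,
#' 53% female. Agent parameters vary with age through logistic maps (the
#' model-based weight and the perseveration weight both increase with age)
#' plus stable subject deviations; ROI nT2*w follows decreasing
#' exponential-approach trajectories with subject random intercepts, batch
#' location/scale effects, and a configurable age-varying coupling between
#' behavior residuals and iron.
#'
#' @param n_subjects Number of subjects (default 217).
#' @param batch_a_frac Fraction of subjects in batch A (default 156/217).
#' @param visit_probs_a Distribution of visits per batch-A subject over
#'   1/2/3 visits (default `c(0.45, 0.44, 0.11)`, giving about 320 total
#'   sessions); batch-B subjects always have one visit.
#' @param age_range Observed age range in years (default
#'   `c(10.17, 33.22)`).
#' @param sex_ratio Probability a subject is female (default 0.53).
#' @param gap_mean,gap_sd Inter-visit gap mean and SD in years (defaults
#'   1.5 and 0.2); visits running past the age range are dropped.
#' @param task A [task_config()] for the simulated sessions.
#' @param agent Named list of agent-parameter map settings (logistic age
#'   maps for `w` and `pi_persev`, subject-deviation SDs, learning-rate and
#'   temperature distributions); see the source for the fields.
#' @param index Named list mapping latent agent parameters to index-scale
#'   values plus measurement noise, used when `simulate_trials = FALSE`.
#' @param rois ROI trajectory tibble, as [default_roi_params()].
#' @param iron Named list: `subject_sd` (random-intercept SD), `resid_sd`,
#'   `batch_offsets` and `batch_scales` (named by batch).
#' @param couplings Coupling tibble, as [default_couplings()]; use
#'   `couplings[0, ]` for a zero-coupling cohort.
#' @param seed Default seed for [generate_cohort()].
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 217, batch_a_frac = 156 / 217,
                          visit_probs_a = c(0.45, 0.44, 0.11),
                          age_range = c(10.17, 33.22), sex_ratio = 0.53,
                          gap_mean = 1.5, gap_sd = 0.2,
                          task = task_config(),
                          agent = list(), index = list(), rois = default_roi_params(),
                          iron = list(), couplings = default_couplings(),
                          seed = 1) {
  agent_defaults <- list(
    w_base = 0.25, w_gain = 0.5, w_mid = 16, w_slope = 3, w_dev_sd = 0.12,
    pi_base = 0.05, pi_gain = 0.4, pi_mid = 16, pi_slope = 3,
    pi_dev_sd = 0.2, alpha_mean = 0.5, alpha_sd = 0.1,
    beta_meanlog = log(4), beta_sdlog = 0.2, lam = 0.6
  )
  index_defaults <- list(
    fss_intercept = 0.1, fss_slope = 2.0,
    mb_intercept = -0.3, mb_slope = 1.8,
    mf_base = 0.6, mf_age_slope = 0.01, mf_dev_sd = 0.25,
    noise_sd = 0.25
  )
  iron_defaults <- list(
    subject_sd = 0.12, resid_sd = 0.10,
    batch_offsets = c(A = 0, B = 0.05), batch_scales = c(A = 1, B = 1.1)
  )
  cfg <- list(
    n_subjects = as.integer(n_subjects), batch_a_frac = batch_a_frac,
    visit_probs_a = visit_probs_a / sum(visit_probs_a),
    age_range = age_range, sex_ratio = sex_ratio,
    gap_mean = gap_mean, gap_sd = gap_sd, task = task,
    agent = utils::modifyList(agent_defaults, agent),
    index = utils::modifyList(index_defaults, index),
    rois = rois,
    iron = utils::modifyList(iron_defaults, iron),
    couplings = couplings, seed = seed
  )
  stopifnot(cfg$n_subjects >= 1, age_range[1] < age_range[2],
            sex_ratio >= 0, sex_ratio <= 1,
            cfg$iron$subject_sd >= 0, cfg$iron$resid_sd >= 0,
            all(cfg$visit_probs_a >= 0))
  structure(cfg, class = "cohort_config")
}

#' Age-varying coupling between a behavior residual and nT2*w
#'
#' Piecewise-linear ramp: `amplitude` at and below `a0`, linearly shrinking
#' to 0 at `a1`, 0 at and above `a1`.
#'
#' @param age Age(s) in years.
#' @param amplitude Plateau value.
#' @param a0,a1 Ramp onset and cutoff ages (`a0 <= a1`).
#' @return Numeric vector of coupling values.
#' @export
coupling_beta <- function(age, amplitude, a0 = 14, a1 = 23) {
  stopifnot(a0 <= a1)
  ifelse(age <= a0, amplitude,
         ifelse(age >= a1, 0, amplitude * (a1 - age) / (a1 - a0)))
}

logistic_map <- function(age, base, gain, mid, slope) {
  base + gain * stats::plogis((age - mid) / slope)
}

#' Generate a synthetic accelerated-longitudinal cohort with ground truth
#'
#' Samples the design (subjects, visits, ages, sex, batches), subject-level
#' agent parameters from the age maps, per-session task data (via
#' [simulate_session()] with hybrid-agent policies), and per-session ROI
#' nT2*w values from the trajectory + subject intercept + batch effect +
#' coupling x (behavior residual) + noise model. Fully reproducible from
#' the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (default `config$seed`).
#' @param simulate_trials Simulate trial-level task data (default `TRUE`)?
#'   With `FALSE`, behavioral indices are instead drawn directly from the
#'   latent index maps plus measurement noise (returned in `$indices`) —
#'   appropriate for experiments that only exercise the index-to-iron
#'   stages.
#' @return List of class `cohort_data` with `design` (subject-visit
#'   tibble), `trials` (trial tibble or `NULL`), `indices` (session index
#'   tibble or `NULL`), `iron` (long ROI tibble), and `truth` (list:
#'   per-subject and per-session generative parameters, config, seed).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            simulate_trials = TRUE) {
  set.seed(seed)
  n <- config$n_subjects
  n_a <- round(n * config$batch_a_frac)
  subjects <- tibble::tibble(
    subject = sprintf("sub%03d", seq_len(n)),
    batch = c(rep("A", n_a), rep("B", n - n_a)),
    sex = stats::rbinom(n, 1, config$sex_ratio),  # 1 = female
    n_visits = ifelse(
      c(rep(TRUE, n_a), rep(FALSE, n - n_a)),
      sample(1:3, n, replace = TRUE, prob = config$visit_probs_a), 1L)
  )
  lo <- config$age_range[1]
  hi <- config$age_range[2]
  design <- subjects |>
    dplyr::mutate(age0 = stats::runif(n, lo, hi)) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      subject = .data$subject, batch = .data$batch, sex = .data$sex,
      visit = seq_len(.data$n_visits),
      age = .data$age0 + cumsum(c(0, pmax(
        stats::rnorm(.data$n_visits - 1, config$gap_mean, config$gap_sd),
        0.5)))[seq_len(.data$n_visits)]
    ) |>
    dplyr::filter(.data$age <= hi) |>
    dplyr::mutate(session = sprintf("%s_v%d", .data$subject, .data$visit)) |>
    dplyr::select("subject", "visit", "session", "age", "sex", "batch")

  ag <- config$agent
  subj_truth <- subjects |>
    dplyr::select("subject", "batch", "sex") |>
    dplyr::mutate(
      alpha = pmin(pmax(stats::rnorm(n, ag$alpha_mean, ag$alpha_sd),
                        0.05), 0.95),
      beta = stats::rlnorm(n, ag$beta_meanlog, ag$beta_sdlog),
      w_dev = stats::rnorm(n, 0, ag$w_dev_sd),
      pi_dev = stats::rnorm(n, 0, ag$pi_dev_sd),
      mf_dev = stats::rnorm(n, 0, config$index$mf_dev_sd)
    )

  ix <- config$index
  session_truth <- design |>
    dplyr::left_join(subj_truth |>
                       dplyr::select(-"batch", -"sex"), by = "subject") |>
    dplyr::mutate(
      w_true = pmin(pmax(logistic_map(.data$age, ag$w_base, ag$w_gain,
                                      ag$w_mid, ag$w_slope) + .data$w_dev,
                         0), 1),
      pi_true = logistic_map(.data$age, ag$pi_base, ag$pi_gain, ag$pi_mid,
                             ag$pi_slope) + .data$pi_dev,
      fss_latent = ix$fss_intercept + ix$fss_slope * .data$pi_true,
      mb_latent = ix$mb_intercept + ix$mb_slope * .data$w_true,
      mf_latent = ix$mf_base + ix$mf_age_slope * (.data$age - 20) +
        .data$mf_dev
    )

  trials <- NULL
  indices <- NULL
  if (simulate_trials) {
    session_seeds <- sample.int(.Machine$integer.max - 1L,
                                nrow(session_truth))
    trials <- purrr::map_dfr(seq_len(nrow(session_truth)), function(i) {
      st <- session_truth[i, ]
      set.seed(session_seeds[i])
      pol <- make_policy(agent_params(
        alpha1 = st$alpha, alpha2 = st$alpha, beta1 = st$beta,
        beta2 = st$beta, lam = ag$lam, w = st$w_true,
        pi_persev = st$pi_true), p_common = config$task$p_common)
      simulate_session(pol, config$task) |>
        dplyr::mutate(subject = st$subject, visit = st$visit,
                      session = st$session, .before = 1)
    })
  } else {
    indices <- session_truth |>
      dplyr::transmute(
        .data$subject, .data$visit, .data$session, .data$age,
        fss = .data$fss_latent + stats::rnorm(dplyr::n(), 0, ix$noise_sd),
        mb = .data$mb_latent + stats::rnorm(dplyr::n(), 0, ix$noise_sd),
        mf = .data$mf_latent + stats::rnorm(dplyr::n(), 0, ix$noise_sd)
      )
  }

  # subject random intercepts per region
  regions <- config$rois$region
  subj_int <- matrix(stats::rnorm(n * length(regions), 0,
                                  config$iron$subject_sd),
                     nrow = n, dimnames = list(subjects$subject, regions))

  iron <- purrr::map_dfr(seq_len(nrow(config$rois)), function(r) {
    rp <- config$rois[r, ]
    cpl <- config$couplings[config$couplings$region == rp$region, ,
                            drop = FALSE]
    st <- session_truth
    coupling <- rep(0, nrow(st))
    if (nrow(cpl) > 0) {
      for (j in seq_len(nrow(cpl))) {
        dev <- switch(cpl$index[j],
                      fss = st$pi_dev * ix$fss_slope,
                      mb = st$w_dev * ix$mb_slope,
                      mf = st$mf_dev)
        coupling <- coupling +
          coupling_beta(st$age, cpl$amplitude[j], cpl$a0[j], cpl$a1[j]) * dev
      }
    }
    traj <- rp$asymptote + rp$amplitude * exp(-rp$rate * (st$age - 10))
    eps <- stats::rnorm(nrow(st), 0, config$iron$resid_sd)
    scale_b <- unname(config$iron$batch_scales[st$batch])
    offset_b <- unname(config$iron$batch_offsets[st$batch])
    tibble::tibble(
      subject = st$subject, visit = st$visit, session = st$session,
      age = st$age, sex = st$sex, batch = st$batch, region = rp$region,
      nT2w = traj + subj_int[cbind(st$subject, rp$region)] + coupling +
        offset_b + scale_b * eps
    )
  })

  structure(
    list(design = design, trials = trials, indices = indices, iron = iron,
         truth = list(subjects = subj_truth, sessions = session_truth,
                      subject_intercepts = subj_int,
                      couplings = config$couplings, config = config,
                      seed = seed)),
    class = "cohort_data"
  )
}

#' @method print cohort_data
#' @export
print.cohort_data <- function(x, ...) {
  cat("Synthetic cohort:", dplyr::n_distinct(x$design$subject), "subjects,",
      nrow(x$design), "sessions, ages",
      round(min(x$design$age), 2), "-", round(max(x$design$age), 2), "\n")
  invisible(x)
}

#' Build 4D volume phantoms for testing the nT2*w pipeline
#'
#' For a small subset of sessions, constructs a synthetic echo-planar-like
#' 4D series on a block atlas whose region-wise planted z-levels equal the
#' session's generated ROI nT2*w values: after coverage-map z-normalization
#' and voxelwise median aggregation, ROI extraction recovers the planted
#' values. Each region has two "hemispheric" labels to exercise pooling.
#' Volumes carry per-volume positive-affine intensity drift, and a
#' configurable fraction are high-motion junk volumes (FD 0.5 mm,
#' scrambled content) that censoring must remove.
#'
#' @param cohort A [generate_cohort()] result.
#' @param n_sessions Number of sessions to build (max 10).
#' @param dims 3D grid dimensions (default `c(12, 12, 8)`).
#' @param n_volumes Volumes per series (default 20).
#' @param high_fd_frac Fraction of junk high-motion volumes (default 0.3).
#' @param drift Apply per-volume positive-affine intensity drift?
#' @param seed Seed for the construction.
#' @return List with `series` (list of [volume_series()]), `atlas` (3D
#'   label array), `regions` (name -> labels mapping), and `truth` (tibble
#'   of planted per-session region values).
#' @export
make_volume_phantoms <- function(cohort, n_sessions = 3,
                                 dims = c(12, 12, 8), n_volumes = 20,
                                 high_fd_frac = 0.3, drift = TRUE,
                                 seed = 1) {
  stopifnot(n_sessions <= 10)
  set.seed(seed)
  region_names <- unique(cohort$iron$region)
  n_r <- length(region_names)
  n_vox <- prod(dims)
  # block atlas: per region, two hemispheric labels over a contiguous slab
  atlas <- array(0L, dims)
  slab <- max(4L, 2L * ceiling(n_vox / (4 * n_r)))
  pos <- 1L
  regions <- list()
  for (r in seq_len(n_r)) {
    vox <- pos:min(pos + slab - 1L, n_vox %/% 2)
    half <- length(vox) %/% 2
    atlas[vox[seq_len(half)]] <- r * 10L + 1L          # "left"
    atlas[vox[(half + 1L):length(vox)]] <- r * 10L + 2L # "right"
    regions[[region_names[r]]] <- c(r * 10L + 1L, r * 10L + 2L)
    pos <- pos + slab
  }

  sess <- utils::head(unique(cohort$iron$session), n_sessions)
  background <- stats::rnorm(sum(atlas == 0))
  truth <- dplyr::filter(cohort$iron, .data$session %in% sess)

  series <- lapply(sess, function(sid) {
    vals <- truth[truth$session == sid, ]
    targets <- stats::setNames(vals$nT2w, vals$region)[region_names]
    # fixed-point construction: raw ROI value m + t * s reproduces target t
    # after z-scoring over the full mask
    m <- 0; s <- 1
    base <- array(0, dims)
    base[atlas == 0] <- background
    for (it in 1:200) {
      for (r in seq_len(n_r)) {
        base[atlas %in% regions[[region_names[r]]]] <- m + targets[r] * s
      }
      m_new <- mean(base)
      s_new <- stats::sd(base)
      if (abs(m_new - m) < 1e-14 && abs(s_new - s) < 1e-14) break
      m <- m_new; s <- s_new
    }
    base <- base + 100  # keep every voxel non-zero for the coverage map
    junk <- stats::runif(n_volumes) < high_fd_frac
    if (all(junk)) junk[1] <- FALSE
    fd <- ifelse(junk, 0.5, stats::runif(n_volumes, 0, 0.25))
    vols <- array(0, c(dims, n_volumes))
    for (t in seq_len(n_volumes)) {
      a <- if (drift) stats::runif(1, 0.8, 1.5) else 1
      b <- if (drift) stats::runif(1, -20, 20) else 0
      v <- if (junk[t]) array(sample(base), dims) else base
      vols[, , , t] <- a * v + b + 1e3 * junk[t]
    }
    batch <- vals$batch[1]
    volume_series(vols, fd, session = sid, batch = batch)
  })
  list(series = series, atlas = atlas, regions = regions, truth = truth)
}
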