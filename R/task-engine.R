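#' Configuration for the two-stage sequential decision-making task
#'
#' The task has two stages: a first-stage choice between two options
#' ("spaceships") leading probabilistically (common/rare transition) to one of
#' two second-stage states ("planets"), where a second choice between two
#' options ("aliens") is rewarded according to slowly drifting probabilities.
#' Reward probabilities follow independent bounded Gaussian random walks.
#'
#' @param n_trials Number of trials per session (default 200).
#' @param n_blocks Number of contiguous, near-equal blocks the session is
#'   divided into (default 3).
#' @param p_common Probability of the common transition (default 0.7). Must
#'   exceed 0.5 so "common" is meaningful.
#' @param walk_sd Standard deviation of the per-trial Gaussian increment of
#'   each reward probability (default 0.025).
#' @param walk_bounds Length-2 numeric, lower and upper bounds of the reward
#'   walks (default `c(0.25, 0.75)`; some task dialects use `c(0.2, 0.8)`).
#' @param walk_boundary Either `"reflect"` (default) or `"clamp"`: how a
#'   proposed step outside `walk_bounds` is handled.
#' @param choice_deadline Response deadline in seconds (default 3).
#' @param omission_rate Probability that a response is missed at each stage
#'   (default 0). A missed first-stage response voids the whole trial.
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters (seconds).
#' @param rt_rare_shift Additive shift (seconds) of second-stage response
#'   times following rare transitions (default 0); used by the synthetic
#'   cohort to plant the awareness-of-structure signature.
#'
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_trials = 200L, n_blocks = 3L, p_common = 0.7,
                        walk_sd = 0.025, walk_bounds = c(0.25, 0.75),
                        walk_boundary = c("reflect", "clamp"),
                        choice_deadline = 3, omission_rate = 0,
                        rt_meanlog = log(0.7), rt_sdlog = 0.3,
                        rt_rare_shift = 0) {
  walk_boundary <- match.arg(walk_boundary)
  stopifnot(
    n_trials >= 1, n_blocks >= 1, n_blocks <= n_trials,
    p_common > 0.5, p_common <= 1,
    walk_sd >= 0,
    length(walk_bounds) == 2, walk_bounds[1] >= 0, walk_bounds[2] <= 1,
    walk_bounds[1] < walk_bounds[2],
    omission_rate >= 0, omission_rate <= 1
  )
  structure(
    list(
      n_trials = as.integer(n_trials), n_blocks = as.integer(n_blocks),
      p_common = p_common, walk_sd = walk_sd, walk_bounds = walk_bounds,
      walk_boundary = walk_boundary, choice_deadline = choice_deadline,
      omission_rate = omission_rate, rt_meanlog = rt_meanlog,
      rt_sdlog = rt_sdlog, rt_rare_shift = rt_rare_shift
    ),
    class = "task_config"
  )
}

#' Create a reward-probability walk state
#'
#' @param p 2x2 matrix of reward probabilities indexed by
#'   (second-stage state, second-stage option); defaults to all 0.5.
#' @return A 2x2 numeric matrix of class `reward_walk`.
#' @export
reward_walk <- function(p = matrix(0.5, 2, 2)) {
  p <- as.matrix(p)
  stopifnot(identical(dim(p), c(2L, 2L)), all(is.finite(p)),
            all(p >= 0), all(p <= 1))
  structure(p, class = c("reward_walk", "matrix", "array"))
}

# reflect x into [lo, hi]; multiple reflections handled for large steps
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  lo + y
}

#' Advance the reward walk by one trial
#'
#' Each of the four reward probabilities is independently perturbed by a
#' zero-mean Gaussian increment of SD `config$walk_sd` and then constrained
#' to `config$walk_bounds`, by reflection at the bounds (default) or by
#' clamping. Uses the current R random-number stream.
#'
#' @param walk A [reward_walk()] state.
#' @param config A [task_config()].
#' @return The updated `reward_walk`.
#' @export
step_reward_walk <- function(walk, config = task_config()) {
  if (!all(is.finite(walk))) {
    stop("reward walk contains non-finite probabilities", call. = FALSE)
  }
  lo <- config$walk_bounds[1]
  hi <- config$walk_bounds[2]
  prop <- unclass(walk) + stats::rnorm(4L, 0, config$walk_sd)
  out <- if (config$walk_boundary == "reflect") {
    reflect_into(prop, lo, hi)
  } else {
    pmin(pmax(prop, lo), hi)
  }
  reward_walk(matrix(out, 2, 2))
}

#' Draw a second-stage state given a first-stage choice
#'
#' Choice `i` transitions to state `i` with probability `p_common` (the
#' common transition) and to the other state otherwise (rare). The mapping
#' choice 0 -> state 0 common is a fixed labelling convention.
#'
#' @param s1_choice First-stage choice, 0 or 1.
#' @param config A [task_config()].
#' @return List with `s2_state` (0/1) and `transition` ("common"/"rare").
#' @export
draw_transition <- function(s1_choice, config = task_config()) {
  stopifnot(s1_choice %in% c(0L, 1L))
  common <- stats::runif(1) < config$p_common
  s2 <- if (common) as.integer(s1_choice) else 1L - as.integer(s1_choice)
  list(s2_state = s2, transition = if (common) "common" else "rare")
}

#' Simulate one session of the two-stage task
#'
#' Runs `config$n_trials` trials of the task under an arbitrary agent policy.
#' The reward walk is stepped once per trial; rewards are Bernoulli draws
#' from the current walk entry. Missed responses (simulated at rate
#' `config$omission_rate` per stage) void the trial from the first missed
#' stage onward. All randomness comes from the current R random-number
#' stream, so `set.seed()` before the call makes the session reproducible.
#'
#' @param policy A policy object as returned by [make_policy()] or
#'   [random_policy()]: a list with functions `choose1()`,
#'   `choose2(s2_state)` (each returning 0 or 1) and `observe(trial)` called
#'   with the completed trial record for learning.
#' @param config A [task_config()].
#' @param walk Initial [reward_walk()]; defaults to all probabilities 0.5.
#' @return A tibble with one row per trial (columns `trial`, `block`,
#'   `s1_choice`, `transition`, `s2_state`, `s2_choice`, `reward`, `rt1`,
#'   `rt2`), with the final walk state attached as attribute `final_walk`.
#' @export
simulate_session <- function(policy, config = task_config(),
                             walk = reward_walk()) {
  n <- config$n_trials
  block_of <- rep(seq_len(config$n_blocks),
                  diff(floor(seq(0, n, length.out = config$n_blocks + 1L))))
  s1 <- s2s <- s2c <- rew <- rep(NA_integer_, n)
  trans <- rep(NA_character_, n)
  rt1 <- rt2 <- rep(NA_real_, n)

  check_choice <- function(ch) {
    if (!(length(ch) == 1L && ch %in% c(0L, 1L))) {
      stop("policy returned an out-of-range choice: ", ch, call. = FALSE)
    }
    as.integer(ch)
  }
  draw_rt <- function(shift = 0) {
    min(stats::rlnorm(1, config$rt_meanlog, config$rt_sdlog) + shift,
        config$choice_deadline)
  }

  for (t in seq_len(n)) {
    omit1 <- config$omission_rate > 0 && stats::runif(1) < config$omission_rate
    if (!omit1) {
      s1[t] <- check_choice(policy$choose1())
      rt1[t] <- draw_rt()
      tr <- draw_transition(s1[t], config)
      s2s[t] <- tr$s2_state
      trans[t] <- tr$transition
      omit2 <- config$omission_rate > 0 &&
        stats::runif(1) < config$omission_rate
      if (!omit2) {
        s2c[t] <- check_choice(policy$choose2(s2s[t]))
        rt2[t] <- draw_rt(if (trans[t] == "rare") config$rt_rare_shift else 0)
        rew[t] <- as.integer(stats::runif(1) < walk[s2s[t] + 1L, s2c[t] + 1L])
      }
    }
    policy$observe(list(s1_choice = s1[t], transition = trans[t],
                        s2_state = s2s[t], s2_choice = s2c[t],
                        reward = rew[t]))
    walk <- step_reward_walk(walk, config)
  }

  out <- tibble::tibble(
    trial = seq_len(n),
    block = as.integer(block_of),
    s1_choice = s1, transition = trans, s2_state = s2s,
    s2_choice = s2c, reward = rew, rt1 = rt1, rt2 = rt2
  )
  attr(out, "final_walk") <- walk
  out
}

#' A reward-blind, transition-blind uniform-choice policy
#'
#' @return A policy object choosing uniformly at every stage.
#' @export
random_policy <- function() {
  list(
    choose1 = function() as.integer(stats::runif(1) < 0.5),
    choose2 = function(s2_state) as.integer(stats::runif(1) < 0.5),
    observe = function(trial) invisible(NULL)
  )
}

#' First-stage stay indicator per trial
#'
#' Trial `t` is coded 1 if its first-stage choice repeats the previous
#' trial's, 0 if both are present and differ, and `NA` if either trial is
#' incomplete (any missing field voids the lag) or `t` has no analyzable
#' predecessor. By default the lag crosses block breaks; with
#' `reset_blocks = TRUE` the first trial of each block is `NA`.
#'
#' @param records A session tibble from [simulate_session()].
#' @param reset_blocks Reset the lag at block boundaries? Default `FALSE`.
#' @return Integer vector (0/1/`NA`) of length `nrow(records)`.
#' @export
stay_indicator <- function(records, reset_blocks = FALSE) {
  complete <- trial_complete(records)
  ch <- ifelse(complete, records$s1_choice, NA_integer_)
  prev <- dplyr::lag(ch)
  stay <- as.integer(ch == prev)
  stay[1L] <- NA_integer_
  if (reset_blocks && "block" %in% names(records)) {
    stay[records$block != dplyr::lag(records$block)] <- NA_integer_
    stay[1L] <- NA_integer_
  }
  stay
}

# a trial is complete when both stages were responded to
trial_complete <- function(records) {
  !is.na(records$s1_choice) & !is.na(records$s2_choice) &
    !is.na(records$reward)
}
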