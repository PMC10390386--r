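#' Task configuration for a reversal-learning session
#'
#' Describes one block of the two-alternative guessing game: the correct side
#' follows the hidden preferred side with probability `p_reward`, and the
#' preferred side reverses either after eight consecutive preferred choices
#' (response-contingent rule) or independently with a fixed per-trial
#' probability (stochastic rule).
#'
#' @param n_trials number of trials (>= 1).
#' @param p_reward probability that the correct side equals the preferred
#'   side; the study conditions use 0.75, 0.85 and 0.65. Must be in (0.5, 1].
#' @param reversal_rule `"response_contingent"` or `"stochastic"`.
#' @param k_consecutive consecutive preferred choices triggering a reversal
#'   under the response-contingent rule (default 8).
#' @param h per-trial switch probability under the stochastic rule
#'   (default 0.06).
#' @param start_points starting score (default 100).
#' @param timing list of phase durations in seconds: `fixation` and `wait`
#'   ranges (uniform draws), `rt` range for the simulated response time,
#'   `feedback` total feedback duration. Only used to produce feedback onset
#'   timestamps for the pupil generator.
#' @return an object of class `task_config`.
#' @export
#' @examples
#' task_config(100, 0.85, "stochastic")
task_config <- function(n_trials, p_reward,
                        reversal_rule = c("response_contingent", "stochastic"),
                        k_consecutive = 8L, h = 0.06, start_points = 100L,
                        timing = list(fixation = c(1.5, 2), rt = c(0.4, 1.5),
                                      wait = c(1.5, 2), feedback = 3)) {
  reversal_rule <- match.arg(reversal_rule)
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (!(p_reward > 0.5 && p_reward <= 1)) {
    stop("`p_reward` must be in (0.5, 1]")
  }
  if (h < 0 || h >= 1) stop("`h` must be in [0, 1)")
  if (k_consecutive < 1) stop("`k_consecutive` must be >= 1")
  structure(list(n_trials = as.integer(n_trials), p_reward = p_reward,
                 reversal_rule = reversal_rule,
                 k_consecutive = as.integer(k_consecutive), h = h,
                 start_points = as.integer(start_points), timing = timing),
            class = "task_config")
}

#' Named study conditions
#'
#' Returns the [task_config()] of one of the three experimental conditions:
#' `exp1` (150 trials, 0.75/0.25 contingency, response-contingent reversals
#' after 8 consecutive preferred choices), `exp2a` (100 trials, 0.85/0.15,
#' stochastic 0.06/trial) and `exp2b` (100 trials, 0.65/0.35, stochastic
#' 0.06/trial).
#'
#' @param condition one of `"exp1"`, `"exp2a"`, `"exp2b"`.
#' @return a `task_config`.
#' @export
condition_config <- function(condition = c("exp1", "exp2a", "exp2b")) {
  switch(match.arg(condition),
    exp1 = task_config(150, 0.75, "response_contingent"),
    exp2a = task_config(100, 0.85, "stochastic"),
    exp2b = task_config(100, 0.65, "stochastic"))
}

#' Specify a choice agent
#'
#' @param kind `"bayes_hmm"` (softmax over the HMM one-step predictive;
#'   params `alpha_p`, `beta_p`, `alpha_a`, `beta_a`, `beta`, optional
#'   `n_particles`), `"rescorla_wagner"` (delta rule; params `alpha`, `beta`),
#'   `"no_reversal"` (hyperbolic learning-rate beta-Bernoulli predictive;
#'   params `alpha_sum`, `beta`) or `"scripted"` (fixed choice sequence).
#' @param params named numeric vector/list of parameters for the kind.
#' @param script integer vector of choices for scripted agents; must be at
#'   least as long as the session.
#' @return an object of class `agent_spec`.
#' @export
#' @examples
#' agent_spec("rescorla_wagner", c(alpha = 0.3, beta = 8))
agent_spec <- function(kind = c("bayes_hmm", "rescorla_wagner", "no_reversal",
                                "scripted"),
                       params = NULL, script = NULL) {
  kind <- match.arg(kind)
  params <- as.list(params)
  need <- switch(kind,
    bayes_hmm = c("alpha_p", "beta_p", "alpha_a", "beta_a", "beta"),
    rescorla_wagner = c("alpha", "beta"),
    no_reversal = c("alpha_sum", "beta"),
    scripted = character())
  if (!all(need %in% names(params))) {
    stop(sprintf("agent kind '%s' needs parameters: %s", kind,
                 paste(need, collapse = ", ")))
  }
  if (kind == "scripted" && is.null(script)) {
    stop("scripted agents need a `script`")
  }
  structure(list(kind = kind, params = params, script = script),
            class = "agent_spec")
}

# internal stepping interface: returns list(state) with
#   $prob1(state, t): probability of choosing side 1 at trial t
#   $update(state, y, x, reward01, t): incorporate feedback
.agent_runtime <- function(agent, n_trials) {
  p <- agent$params
  switch(agent$kind,
    scripted = {
      if (length(agent$script) < n_trials) {
        stop("script shorter than the session")
      }
      list(state = NULL,
           prob1 = function(state, t) as.numeric(agent$script[t] == 1L),
           update = function(state, y, x, rwd, t) state)
    },
    rescorla_wagner = {
      list(state = c(0.5, 0.5),
           prob1 = function(state, t) {
             softmax_choice(state, p$beta)[2]
           },
           update = function(state, y, x, rwd, t) {
             state[y + 1] <- state[y + 1] + p$alpha * (rwd - state[y + 1])
             state
           })
    },
    no_reversal = {
      list(state = 0.5, # P(x_t = 1 | x_{1:t-1})
           prob1 = function(state, t) {
             softmax_choice(c(1 - state, state), p$beta)[2]
           },
           update = function(state, y, x, rwd, t) {
             state + (x - state) / (p$alpha_sum + t)
           })
    },
    bayes_hmm = {
      np <- if (!is.null(p$n_particles)) p$n_particles else 2000L
      hp <- hmm_params(p$alpha_p, p$beta_p, p$alpha_a, p$beta_a)
      c0 <- c0_correction(hp)
      list(state = integer(0), # observed x history
           prob1 = function(state, t) {
             pred1 <- if (length(state) == 0L) 0.5 else {
               hmm_filter_cpp(state, hp$alpha_p, hp$beta_p, hp$alpha_a,
                              hp$beta_a, c0, as.integer(np),
                              0L)$next_predictive_x1
             }
             softmax_choice(c(1 - pred1, pred1), p$beta)[2]
           },
           update = function(state, y, x, rwd, t) c(state, x))
    })
}

#' Simulate one reversal-learning session
#'
#' Draws the hidden preferred side, the correct (stone) side, the agent's
#' choices and the resulting rewards for `n_trials` trials. Under the
#' response-contingent rule the preferred side switches on the trial following
#' the eighth consecutive preferred choice, regardless of reward; choosing the
#' nonpreferred side resets the streak. Under the stochastic rule the side
#' switches independently with probability `h` between consecutive trials.
#'
#' @param config a [task_config()].
#' @param agent an [agent_spec()].
#' @param seed integer RNG seed; identical seeds reproduce sessions
#'   bit-for-bit.
#' @param z1 optional forced initial preferred side (0/1); default random.
#' @return a data frame of class `session_record` with one row per trial:
#'   `trial`, `z` (preferred side), `x` (correct side), `y` (choice, `NA` if
#'   missed), `reward` (+1/-1 points, 0 if missed), `reversal` (logical),
#'   `feedback_onset_s`, `score`.
#' @export
#' @examples
#' s <- generate_session(condition_config("exp2a"),
#'                       agent_spec("rescorla_wagner",
#'                                  c(alpha = 0.3, beta = 8)), seed = 1)
#' head(s)
generate_session <- function(config, agent, seed, z1 = NULL) {
  n <- config$n_trials
  rt <- .agent_runtime(agent, n)
  with_seed(seed, {
    z <- x <- y <- integer(n)
    reward <- numeric(n)
    revflag <- logical(n)
    onset <- numeric(n)
    score <- integer(n)
    st <- rt$state
    cur_z <- if (is.null(z1)) as.integer(runif(1) < 0.5) else as.integer(z1)
    streak <- 0L
    pts <- config$start_points
    tm <- config$timing
    clock <- 0
    for (t in seq_len(n)) {
      z[t] <- cur_z
      revflag[t] <- if (t == 1L) FALSE else z[t] != z[t - 1L]
      x[t] <- if (runif(1) < config$p_reward) cur_z else 1L - cur_z
      p1 <- rt$prob1(st, t)
      y[t] <- as.integer(runif(1) < p1)
      rwd01 <- as.numeric(y[t] == x[t])
      reward[t] <- if (rwd01 == 1) 1 else -1
      pts <- pts + reward[t]
      score[t] <- pts
      clock <- clock + runif(1, tm$fixation[1], tm$fixation[2]) +
        runif(1, tm$rt[1], tm$rt[2]) + runif(1, tm$wait[1], tm$wait[2])
      onset[t] <- clock
      clock <- clock + tm$feedback
      st <- rt$update(st, y[t], x[t], rwd01, t)
      if (config$reversal_rule == "response_contingent") {
        streak <- if (y[t] == cur_z) streak + 1L else 0L
        if (streak >= config$k_consecutive) {
          cur_z <- 1L - cur_z
          streak <- 0L
        }
      } else if (runif(1) < config$h) {
        cur_z <- 1L - cur_z
      }
    }
    out <- data.frame(trial = seq_len(n), z = z, x = x, y = y,
                      reward = reward, reversal = revflag,
                      feedback_onset_s = onset, score = score)
    class(out) <- c("session_record", "data.frame")
    out
  })
}

#' Behavioral summary of one session
#'
#' @param session a `session_record`.
#' @return named numeric vector, in percent: `preferred_pct` (choice equals
#'   the hidden preferred side), `rewarded_pct` (choice equals the correct
#'   side), `switch_pct` (choice differs from the previous responded trial's
#'   choice).
#' @export
summarize_behavior <- function(session) {
  ok <- !is.na(session$y)
  if (sum(ok) < 2) stop("need at least two responded trials")
  y <- session$y[ok]
  c(preferred_pct = 100 * mean(y == session$z[ok]),
    rewarded_pct = 100 * mean(y == session$x[ok]),
    switch_pct = 100 * mean(y[-1] != y[-length(y)]))
}

#' Reversal-aligned behavioral curves
#'
#' Pools all reversal events across sessions and averages the three
#' behavioral measures at each trial offset relative to the reversal (offset 0
#' is the first trial governed by the new preferred side).
#'
#' @param sessions a `session_record` or list of them.
#' @param window integer trial offsets, e.g. `-2:3`.
#' @return data frame: `offset`, `preferred_pct`, `rewarded_pct`,
#'   `switch_pct`, `n_events` (events contributing at that offset; offsets
#'   with no data carry `NA` means).
#' @export
reversal_aligned_curves <- function(sessions, window = -2:3) {
  if (length(window) == 0) stop("empty window")
  if (is.data.frame(sessions)) sessions <- list(sessions)
  acc <- matrix(0, nrow = length(window), ncol = 4,
                dimnames = list(NULL, c("pref", "rew", "sw", "n")))
  n_events <- 0L
  for (s in sessions) {
    revs <- which(s$reversal)
    n_events <- n_events + length(revs)
    for (t0 in revs) {
      for (k in seq_along(window)) {
        t <- t0 + window[k]
        if (t < 1 || t > nrow(s) || is.na(s$y[t])) next
        acc[k, "pref"] <- acc[k, "pref"] + (s$y[t] == s$z[t])
        acc[k, "rew"] <- acc[k, "rew"] + (s$y[t] == s$x[t])
        if (t > 1 && !is.na(s$y[t - 1])) {
          acc[k, "sw"] <- acc[k, "sw"] + (s$y[t] != s$y[t - 1])
        }
        acc[k, "n"] <- acc[k, "n"] + 1
      }
    }
  }
  if (n_events == 0L) stop("no reversal events in the supplied sessions")
  n <- ifelse(acc[, "n"] > 0, acc[, "n"], NA_real_)
  data.frame(offset = window,
             preferred_pct = 100 * acc[, "pref"] / n,
             rewarded_pct = 100 * acc[, "rew"] / n,
             switch_pct = 100 * acc[, "sw"] / n,
             n_events = acc[, "n"])
}
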