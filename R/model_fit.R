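#' Softmax choice rule
#'
#' `P(choice = k) = exp(beta * v_k) / sum_j exp(beta * v_j)`. For the HMM
#' model the values are the one-step predictive probabilities of each side
#' being correct; for the Rescorla-Wagner model they are the Q values. `beta`
#' is the inverse temperature: 0 gives random choice, infinity always selects
#' the higher value.
#'
#' @param values numeric vector of side values.
#' @param beta inverse temperature (>= 0).
#' @return choice probabilities summing to 1 (overflow-safe).
#' @export
#' @examples
#' softmax_choice(c(0.6, 0.4), 5)
softmax_choice <- function(values, beta) {
  if (!is.finite(beta)) {
    if (beta < 0) stop("`beta` must be >= 0")
    p <- as.numeric(values == max(values))
    return(p / sum(p))
  }
  if (beta < 0) stop("`beta` must be >= 0")
  e <- exp(beta * (values - max(values)))
  e / sum(e)
}

#' Rescorla-Wagner value update
#'
#' Delta rule for the chosen side only: `Q_y <- Q_y + alpha (R - Q_y)` with
#' binary reward `R` in `{0, 1}`; the reward coding keeps Q on the same
#' `[0, 1]` scale as the HMM predictive probabilities entering the shared
#' softmax (the symmetric start `Q = (0.5, 0.5)` presumes this).
#'
#' @param q numeric length-2 vector of Q values (sides 0 and 1).
#' @param y chosen side (0/1).
#' @param r binary reward (0/1).
#' @param alpha learning rate in `[0, 1]`.
#' @return updated Q vector.
#' @export
rw_update <- function(q, y, r, alpha) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  q[y + 1] <- q[y + 1] + alpha * (r - q[y + 1])
  q
}

#' Closed-form predictive of the no-reversal model
#'
#' With zero reversal probability the model reduces to a beta-Bernoulli
#' predictive on the correct side: `P(x_{t+1} = 1 | x_{1:t}) = P_t + (x_t -
#' P_t) / (alpha_sum + t)` starting at 0.5 -- a reinforcement learning rule
#' with hyperbolically decreasing learning rate, parameterized only by
#' `alpha_sum = alpha_p + beta_p`.
#'
#' @param alpha_sum positive prior strength.
#' @param x integer vector of observed correct sides.
#' @return numeric vector of length `length(x)` where entry `t` is
#'   `P(x_t = 1 | x_{1:t-1})` (entry 1 is 0.5).
#' @export
#' @examples
#' no_reversal_predictive(2, c(1, 1, 0))
no_reversal_predictive <- function(alpha_sum, x) {
  if (alpha_sum <= 0) stop("`alpha_sum` must be > 0")
  pred <- numeric(length(x))
  p <- 0.5
  for (t in seq_along(x)) {
    pred[t] <- p
    p <- p + (x[t] - p) / (alpha_sum + t)
  }
  pred
}

# per-trial P(y_t = 1 | x_{1:t-1}; theta) for each model; missed trials get
# NA but their observations still advance the model state
.choice_prob1 <- function(model, theta, session, n_particles = 2000,
                          seed = 1L) {
  x <- as.integer(session$x)
  y <- session$y
  n <- length(x)
  switch(model,
    hmm = {
      hp <- hmm_params(theta[["alpha_p"]], theta[["beta_p"]],
                       theta[["alpha_a"]], theta[["beta_a"]])
      est <- run_filter(hp, session, n_particles = n_particles, seed = seed)
      # predictive for trial t uses x_{1:t-1} only (pre-observation branch);
      # binary softmax reduces to a logistic in the value difference
      stats::plogis(theta[["beta"]] * (2 * est$predictive_x1 - 1))
    },
    rescorla_wagner = {
      q <- c(0.5, 0.5)
      out <- numeric(n)
      for (t in seq_len(n)) {
        out[t] <- softmax_choice(q, theta[["beta"]])[2]
        if (!is.na(y[t])) {
          q <- rw_update(q, y[t], as.numeric(y[t] == x[t]), theta[["alpha"]])
        }
      }
      out
    },
    no_reversal = {
      pred <- no_reversal_predictive(theta[["alpha_sum"]], x)
      stats::plogis(theta[["beta"]] * (2 * pred - 1))
    },
    stop("unknown model: ", model))
}

#' Negative log-likelihood of a choice model on a session
#'
#' `-sum_t log P(y_t | x_{1:t-1}; theta)` over responded trials; missed
#' trials contribute nothing but their observations still advance the model
#' state. Choice probabilities are floored at `prob_floor` inside the log.
#'
#' @param model `"hmm"`, `"rescorla_wagner"` or `"no_reversal"`.
#' @param theta named parameter vector (see [fit_spec()]).
#' @param session a `session_record`.
#' @param n_particles particles for the HMM filter.
#' @param seed filter seed; keep fixed across evaluations within one fit so
#'   the objective is deterministic for the optimizer.
#' @param prob_floor lower bound applied inside the log (default 1e-12).
#' @return the negative log-likelihood (scalar).
#' @export
session_nll <- function(model, theta, session, n_particles = 2000, seed = 1L,
                        prob_floor = 1e-12) {
  ok <- !is.na(session$y)
  if (!any(ok)) stop("session has no responded trials")
  p1 <- .choice_prob1(model, theta, session, n_particles, seed)
  py <- ifelse(session$y == 1L, p1, 1 - p1)[ok]
  -sum(log(pmax(py, prob_floor)))
}

#' Fit specification for maximum-likelihood estimation
#'
#' @param model `"hmm"` (5 parameters: `alpha_p`, `beta_p`, `alpha_a`,
#'   `beta_a`, `beta`), `"rescorla_wagner"` (2: `alpha`, `beta`) or
#'   `"no_reversal"` (2: `alpha_sum`, `beta`).
#' @param n_starts random multistart count (default 10).
#' @param n_particles particles per HMM likelihood evaluation.
#' @param bounds optional named list overriding default box bounds
#'   (shapes and `alpha_sum` in `[1e-3, 1e3]`, `beta` in `[0, 1e3]`,
#'   `alpha` in `[0, 1]`).
#' @param seed seed controlling the random starts and the fixed filter seed.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(model = c("hmm", "rescorla_wagner", "no_reversal"),
                     n_starts = 10L, n_particles = 2000L, bounds = NULL,
                     seed = 1L) {
  model <- match.arg(model)
  def <- switch(model,
    hmm = list(alpha_p = c(1e-3, 1e3), beta_p = c(1e-3, 1e3),
               alpha_a = c(1e-3, 1e3), beta_a = c(1e-3, 1e3),
               beta = c(0, 1e3)),
    rescorla_wagner = list(alpha = c(0, 1), beta = c(0, 1e3)),
    no_reversal = list(alpha_sum = c(1e-3, 1e3), beta = c(0, 1e3)))
  if (!is.null(bounds)) def <- modifyList(def, bounds)
  structure(list(model = model, n_starts = as.integer(n_starts),
                 n_particles = as.integer(n_particles), bounds = def,
                 seed = as.integer(seed)),
            class = "fit_spec")
}

# random start within bounds: log-uniform for scale params, uniform for alpha
.draw_start <- function(bounds) {
  vapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    if (nm == "alpha") {
      runif(1, b[1], b[2])
    } else {
      lo <- max(b[1], 1e-3)
      exp(runif(1, log(lo), log(b[2])))
    }
  }, numeric(1))
}

#' Maximum-likelihood fit of a choice model to one session
#'
#' Best-of-`n_starts` constrained minimization of [session_nll()]. The smooth
#' 2-parameter models use L-BFGS-B on the natural scale; the 5-parameter HMM,
#' whose particle-filter likelihood is only piecewise smooth, uses Nelder-Mead
#' on a log-transformed scale with a fixed filter seed per evaluation so the
#' objective is deterministic. AIC and BIC use the number of responded trials
#' as the sample size.
#'
#' @param spec a [fit_spec()].
#' @param session a `session_record`.
#' @return an object of class `fit_result`: list with `model`, `theta`
#'   (named vector), `nll`, `k`, `n_obs`, `aic`, `bic`, `convergence`
#'   (per-start codes), `starts` (per-start NLLs).
#' @export
fit_mle <- function(spec, session) {
  bounds <- spec$bounds
  nms <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  filter_seed <- derive_seed(spec$seed, "filter")
  obj_nat <- function(th) {
    th <- setNames(pmin(pmax(th, lower), upper), nms)
    val <- try(session_nll(spec$model, th, session,
                           n_particles = spec$n_particles,
                           seed = filter_seed), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e10 else val
  }
  best <- NULL
  conv <- integer(spec$n_starts)
  start_nll <- numeric(spec$n_starts)
  with_seed(derive_seed(spec$seed, "starts"), {
    for (s in seq_len(spec$n_starts)) {
      th0 <- .draw_start(bounds)
      fit <- if (spec$model == "hmm") {
        # log scale keeps parameters positive; box enforced by clamping
        tr <- function(u) setNames(exp(u), nms)
        o <- optim(log(pmax(th0, 1e-6)), function(u) obj_nat(tr(u)),
                   method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-6))
        list(par = pmin(pmax(tr(o$par), lower), upper), value = o$value,
             convergence = o$convergence)
      } else {
        o <- optim(th0, obj_nat, method = "L-BFGS-B",
                   lower = lower + 1e-9, upper = upper,
                   control = list(maxit = 200))
        list(par = setNames(o$par, nms), value = o$value,
             convergence = o$convergence)
      }
      conv[s] <- fit$convergence
      start_nll[s] <- fit$value
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    stop("no optimization start converged to a finite objective")
  }
  n_obs <- sum(!is.na(session$y))
  k <- length(nms)
  structure(list(model = spec$model, theta = best$theta %||% best$par,
                 nll = best$value, k = k, n_obs = n_obs,
                 aic = 2 * k + 2 * best$value,
                 bic = k * log(n_obs) + 2 * best$value,
                 convergence = conv, starts = start_nll),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: nll = %.3f, AIC = %.2f, BIC = %.2f (n = %d)\n",
              x$model, x$nll, x$aic, x$bic, x$n_obs))
  print(round(x$theta, 4))
  invisible(x)
}

# agent corresponding to a fitted/pooled parameter vector
.agent_from_theta <- function(model, theta) {
  switch(model,
    hmm = agent_spec("bayes_hmm", theta),
    rescorla_wagner = agent_spec("rescorla_wagner", theta),
    no_reversal = agent_spec("no_reversal", theta))
}

#' Model recovery on simulated data
#'
#' For each generating model, simulates sessions from a pool of parameter
#' vectors, fits each candidate model to each dataset, and tabulates mean AIC
#' and BIC per generating x fitting model with paired t-tests between fitting
#' models on the same datasets. This checks that the information criteria can
#' identify the data-generating model at the study's design and sample sizes.
#'
#' @param config a [task_config()] shared by all simulated sessions.
#' @param param_pool named list: for each generating model, a list of named
#'   parameter vectors (one session is simulated per vector).
#' @param fit_models character vector of models to fit to every dataset.
#' @param seed master seed.
#' @param n_starts,n_particles forwarded to [fit_spec()] (scaled down by
#'   default for tractability of the full recovery table).
#' @return list with `fits` (long data frame: generator, dataset, fit_model,
#'   nll, aic, bic), `aic_table`, `bic_table` (mean criteria matrices) and
#'   `paired` (data frame of paired t-tests on per-dataset AIC).
#' @export
model_recovery <- function(config, param_pool,
                           fit_models = names(param_pool), seed = 1L,
                           n_starts = 3L, n_particles = 1000L) {
  if (length(param_pool) == 0) stop("empty parameter pool")
  rows <- list()
  for (gen in names(param_pool)) {
    pool <- param_pool[[gen]]
    for (d in seq_along(pool)) {
      sess <- generate_session(config, .agent_from_theta(gen, pool[[d]]),
                               seed = derive_seed(seed, "sess", gen, d))
      for (fm in fit_models) {
        fit <- try(fit_mle(fit_spec(fm, n_starts = n_starts,
                                    n_particles = n_particles,
                                    seed = derive_seed(seed, "fit", gen, d,
                                                       fm)),
                           sess), silent = TRUE)
        rows[[length(rows) + 1L]] <- if (inherits(fit, "try-error")) {
          data.frame(generator = gen, dataset = d, fit_model = fm,
                     nll = NA_real_, aic = NA_real_, bic = NA_real_)
        } else {
          data.frame(generator = gen, dataset = d, fit_model = fm,
                     nll = fit$nll, aic = fit$aic, bic = fit$bic)
        }
      }
    }
  }
  fits <- do.call(rbind, rows)
  mk_table <- function(col) {
    tab <- tapply(fits[[col]], list(fits$generator, fits$fit_model), mean,
                  na.rm = TRUE)
    tab[names(param_pool), fit_models, drop = FALSE]
  }
  paired <- list()
  for (gen in names(param_pool)) {
    sub <- fits[fits$generator == gen, ]
    cmb <- utils::combn(fit_models, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- sub$aic[sub$fit_model == cmb[1, j]]
      b <- sub$aic[sub$fit_model == cmb[2, j]]
      keep <- is.finite(a) & is.finite(b)
      tt <- if (sum(keep) >= 2 && sd(a[keep] - b[keep]) > 0) {
        t.test(a[keep], b[keep], paired = TRUE)
      } else {
        list(statistic = NA_real_, p.value = NA_real_)
      }
      paired[[length(paired) + 1L]] <- data.frame(
        generator = gen, model_a = cmb[1, j], model_b = cmb[2, j],
        mean_diff_aic = mean(a[keep] - b[keep]),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  list(fits = fits, aic_table = mk_table("aic"), bic_table = mk_table("bic"),
       paired = do.call(rbind, paired))
}

#' Generative performance check of fitted models
#'
#' Simulates `n_per_fit` independent sessions for each fitted parameter
#' vector (treated as simulated participants) and returns the behavioral
#' summary distribution and reversal-aligned curves for comparison with
#' observed behavior.
#'
#' @param model generating model name.
#' @param theta_pool list of named parameter vectors (e.g. per-participant
#'   fits).
#' @param config a [task_config()].
#' @param n_per_fit sessions per parameter vector (default 10).
#' @param window offsets for [reversal_aligned_curves()].
#' @param seed master seed.
#' @return list with `summaries` (data frame, one row per simulated session)
#'   and `curves` (pooled reversal-aligned data frame, `NULL` if no reversals
#'   occurred).
#' @export
generative_check <- function(model, theta_pool, config, n_per_fit = 10L,
                             window = -2:3, seed = 1L) {
  if (length(theta_pool) == 0 || n_per_fit == 0) {
    return(list(summaries = data.frame(), curves = NULL))
  }
  sessions <- list()
  rows <- list()
  for (i in seq_along(theta_pool)) {
    ag <- .agent_from_theta(model, theta_pool[[i]])
    for (j in seq_len(n_per_fit)) {
      s <- generate_session(config, ag, seed = derive_seed(seed, i, j))
      sessions[[length(sessions) + 1L]] <- s
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, rep = j, t(summarize_behavior(s)))
    }
  }
  curves <- try(reversal_aligned_curves(sessions, window), silent = TRUE)
  list(summaries = do.call(rbind, rows),
       curves = if (inherits(curves, "try-error")) NULL else curves)
}
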