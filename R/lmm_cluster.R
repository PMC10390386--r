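# Mass-univariate per-bin random-intercept mixed models with LRTs and
# cluster-based permutation correction. The outcome at each of the 350 bins
# is regressed on the pre-feedback baseline (nuisance, always included) plus
# the predictors of interest, with a participant random intercept; full vs
# reduced models are compared by a likelihood-ratio test (models fitted by
# ML, not REML, because the fixed-effect structures differ).

#' Fit a single random-intercept linear mixed model by ML
#'
#' Profiled maximum likelihood for `y = X beta + (1|group) + e` (see
#' `src/lmm.cpp`); verified against `lme4::lmer(REML = FALSE)` in the test
#' suite. Used for every bin-wise fit, including all permutations.
#'
#' @param X design matrix (including intercept column).
#' @param y outcome vector.
#' @param group factor-like grouping (participant identity).
#' @return list: `logLik`, `beta`, `sigma2`, `sigma2_b`, `ok`.
#' @export
lmm_ml <- function(X, y, group) {
  g <- as.integer(factor(group)) - 1L
  res <- lmm_ml_cpp(as.matrix(X), as.numeric(y), g, max(g) + 1L)
  if (!isTRUE(res$ok)) {
    return(list(ok = FALSE, logLik = NA_real_))
  }
  list(ok = TRUE, logLik = res$logLik, beta = drop(res$beta),
       sigma2 = res$sigma2, sigma2_b = res$sigma2_b)
}

#' Specify the per-bin model
#'
#' @param predictors character vector of trial-level predictor columns of
#'   interest (tested jointly by one LRT). The baseline nuisance and the
#'   participant random intercept are always included; the reduced model drops
#'   exactly the predictors of interest.
#' @param alpha per-bin significance level for cluster formation
#'   (default 0.05).
#' @return object of class `bin_model_spec`.
#' @export
bin_model_spec <- function(predictors, alpha = 0.05) {
  if (length(predictors) == 0) stop("need at least one predictor of interest")
  structure(list(predictors = predictors, alpha = alpha),
            class = "bin_model_spec")
}

# reshape a long epochs table into the per-trial design pieces used by the
# C++ bin engine: Y (trials x bins), trial-level covariate data frame, group
.bin_data <- function(epochs) {
  need <- c("participant", "trial", "bin", "value", "baseline")
  if (!all(need %in% names(epochs))) {
    stop("epochs table needs columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(epochs$participant, epochs$trial, drop = TRUE)
  ord <- order(key, epochs$bin)
  epochs <- epochs[ord, ]
  key <- key[ord]
  bins <- sort(unique(epochs$bin))
  nb <- length(bins)
  ids <- !duplicated(key)
  n <- sum(ids)
  if (nrow(epochs) != n * nb) {
    stop("every (participant, trial) must contribute every bin")
  }
  Y <- matrix(epochs$value, nrow = nb)[order(bins), , drop = FALSE]
  trialcols <- setdiff(names(epochs), c("bin", "time_s", "value"))
  list(Y = t(Y), trials = epochs[ids, trialcols, drop = FALSE], bins = bins)
}

.design <- function(trials, cols) {
  X <- cbind(1, trials$baseline)
  colnames(X) <- c("(Intercept)", "baseline")
  for (cl in cols) {
    if (!cl %in% names(trials)) stop("missing predictor column: ", cl)
    v <- trials[[cl]]
    if (is.logical(v) || is.factor(v)) v <- as.numeric(v) # 0/1 coding
    if (sd(v) == 0) stop("predictor '", cl, "' is constant across trials")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cl
  }
  X
}

.lrt_from_ll <- function(ll_full, ll_red, df) {
  stat <- 2 * (ll_full - ll_red)
  stat[!is.na(stat) & stat < 0] <- 0
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  data.frame(stat = stat, df = df, p = p,
             singular = is.na(ll_full) | is.na(ll_red))
}

# threshold from the permutation null: per-permutation maxima ("max",
# family-wise calibrated) or all cluster lengths pooled ("all"). For "max"
# the threshold is the ceiling((B+1)p)-th order statistic of the B maxima --
# the permutation convention that counts the observed series as the (B+1)-th
# member, giving exceedance probability <= 1 - p exactly.
.null_threshold <- function(null_lengths, null_max, null_pool,
                            threshold_prob) {
  if (null_pool == "max") {
    b <- length(null_max)
    k <- min(b, ceiling(threshold_prob * (b + 1)))
    as.numeric(sort(null_max)[k])
  } else if (length(null_lengths)) {
    as.numeric(quantile(null_lengths, threshold_prob))
  } else {
    0
  }
}

# runs of consecutive TRUE; returns integer lengths (possibly empty)
.cluster_lengths <- function(sig) {
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  r$lengths[r$values]
}

.cluster_table <- function(sig) {
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Per-bin likelihood-ratio test series
#'
#' For each time bin, fits the full model (baseline + predictors of interest
#' + participant random intercept) and the reduced model (baseline +
#' intercept only) by ML and computes the LRT. Bins where either fit fails
#' are flagged singular and treated as non-significant downstream.
#'
#' @param epochs long epochs table: `participant`, `trial`, `bin`, `value`,
#'   `baseline` plus one column per predictor of interest (the preprocessing
#'   output joined with trial-level estimates).
#' @param spec a [bin_model_spec()].
#' @return data frame: `bin`, `stat`, `df`, `p`, `singular`, `significant`.
#' @export
fit_bin_series <- function(epochs, spec) {
  bd <- .bin_data(epochs)
  Xf <- .design(bd$trials, spec$predictors)
  Xr <- .design(bd$trials, character())
  g <- as.integer(factor(bd$trials$participant)) - 1L
  ll <- lmm_ml_bins_cpp(bd$Y, list(Xf, Xr), g, max(g) + 1L)
  res <- .lrt_from_ll(ll[, 1], ll[, 2], df = length(spec$predictors))
  data.frame(bin = bd$bins, res,
             significant = !res$singular & res$p < spec$alpha)
}

# permute the given trial-level columns within participant; `source_col`
# allows derived columns (entropy basis) to be recomputed from the permuted q
.permute_trials <- function(trials, cols, group) {
  for (gid in unique(group)) {
    rows <- which(group == gid)
    perm <- rows[sample.int(length(rows))]
    trials[rows, cols] <- trials[perm, cols, drop = FALSE]
  }
  trials
}

#' Cluster-based permutation test for one predictor set
#'
#' Computes the observed per-bin LRT series, then re-runs it `n_perm` times
#' with the predictors of interest randomly permuted across trials within
#' participant (baseline and outcomes untouched). Lengths of all runs of
#' consecutive significant bins across all permutations form the null
#' cluster-size distribution; observed clusters whose length strictly exceeds
#' its 95th percentile survive.
#'
#' @param epochs long epochs table (see [fit_bin_series()]).
#' @param spec a [bin_model_spec()].
#' @param n_perm number of permutations (500 in the emulated design).
#' @param seed RNG seed.
#' @param threshold_prob quantile of the null cluster-length distribution
#'   (default 0.95).
#' @param null_pool `"max"` (default) thresholds against the per-permutation
#'   maximum cluster length, which controls the family-wise error at
#'   `1 - threshold_prob`; `"all"` pools every null cluster length across
#'   permutations (a variant seen in the pupillometry literature,
#'   anticonservative when several clusters arise per series).
#' @return object of class `cluster_result`: list with `series` (observed
#'   per-bin table), `clusters` (observed clusters with `surviving` flag),
#'   `null_lengths`, `threshold`, `n_perm`.
#' @export
cluster_permutation <- function(epochs, spec, n_perm = 500L, seed = 1L,
                                threshold_prob = 0.95,
                                null_pool = c("max", "all")) {
  null_pool <- match.arg(null_pool)
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  bd <- .bin_data(epochs)
  g <- as.integer(factor(bd$trials$participant)) - 1L
  G <- max(g) + 1L
  Xr <- .design(bd$trials, character())
  Xf <- .design(bd$trials, spec$predictors)
  df <- length(spec$predictors)

  ll <- lmm_ml_bins_cpp(bd$Y, list(Xf, Xr), g, G)
  obs <- .lrt_from_ll(ll[, 1], ll[, 2], df)
  obs_sig <- !obs$singular & obs$p < spec$alpha
  ll_red <- ll[, 2] # reduced model has no permuted columns: fit once

  null_lengths <- integer(0)
  null_max <- integer(n_perm)
  with_seed(seed, for (b in seq_len(n_perm)) {
    tr <- .permute_trials(bd$trials, spec$predictors, bd$trials$participant)
    Xp <- .design(tr, spec$predictors)
    llp <- lmm_ml_bins_cpp(bd$Y, list(Xp), g, G)
    pr <- .lrt_from_ll(llp[, 1], ll_red, df)
    lens <- .cluster_lengths(!pr$singular & pr$p < spec$alpha)
    null_lengths <- c(null_lengths, lens)
    null_max[b] <- if (length(lens)) max(lens) else 0L
  })

  threshold <- .null_threshold(null_lengths, null_max, null_pool,
                               threshold_prob)
  clusters <- .cluster_table(obs_sig)
  clusters$surviving <- clusters$length > threshold
  structure(list(series = data.frame(bin = bd$bins, obs,
                                     significant = obs_sig),
                 clusters = clusters, null_lengths = null_lengths,
                 threshold = threshold, n_perm = n_perm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster permutation: %d permutations, 95th pct null length = %.1f\n",
    x$n_perm, x$threshold))
  surv <- x$clusters[x$clusters$surviving, , drop = FALSE]
  if (nrow(surv) == 0) {
    cat("no surviving clusters\n")
  } else {
    cat(sprintf("%d surviving cluster(s): bins %s\n", nrow(surv),
                paste(sprintf("%d-%d", surv$start, surv$end),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Dual-basis-function analysis of state change probability
#'
#' The full model contains both basis functions of state change probability
#' `q`: the identity basis `q` and the entropy basis `H(q)` (binary entropy,
#' implemented by [binary_entropy()] with positive sign so a positive
#' coefficient means larger responses at higher uncertainty). Each basis is
#' tested by an LRT against the model with only that basis removed, with a
#' separate permutation correction per basis; permutations shuffle `q` within
#' participant and recompute both bases from the permuted values.
#'
#' @param epochs long epochs table containing a `state_change_probability`
#'   column.
#' @param n_perm permutations per basis.
#' @param alpha cluster-forming significance level.
#' @param seed RNG seed.
#' @param threshold_prob null-distribution quantile (default 0.95).
#' @param null_pool `"max"` or `"all"` (see [cluster_permutation()]).
#' @return named list of two `cluster_result`s: `linear` and `entropy`, each
#'   additionally carrying per-bin coefficients of its basis (`coef`).
#' @export
dual_basis_model <- function(epochs, n_perm = 500L, alpha = 0.05, seed = 1L,
                             threshold_prob = 0.95,
                             null_pool = c("max", "all")) {
  null_pool <- match.arg(null_pool)
  if (!"state_change_probability" %in% names(epochs)) {
    stop("epochs must carry `state_change_probability`")
  }
  epochs$entropy_basis <- binary_entropy(epochs$state_change_probability)
  if (sd(epochs$state_change_probability) == 0) {
    stop("state change probability is constant; bases are collinear")
  }
  bd <- .bin_data(epochs)
  g <- as.integer(factor(bd$trials$participant)) - 1L
  G <- max(g) + 1L
  both <- c("state_change_probability", "entropy_basis")
  Xf <- .design(bd$trials, both)
  X_no_lin <- .design(bd$trials, "entropy_basis")
  X_no_ent <- .design(bd$trials, "state_change_probability")

  ll <- lmm_ml_bins_cpp(bd$Y, list(Xf, X_no_lin, X_no_ent), g, G)
  obs_lin <- .lrt_from_ll(ll[, 1], ll[, 2], 1L)
  obs_ent <- .lrt_from_ll(ll[, 1], ll[, 3], 1L)

  # per-bin coefficients of the full model for reporting
  coefs <- t(vapply(seq_len(nrow(obs_lin)), function(b) {
    f <- lmm_ml(Xf, bd$Y[, b], bd$trials$participant)
    if (f$ok) f$beta[3:4] else c(NA_real_, NA_real_)
  }, numeric(2)))

  null_lin <- null_ent <- integer(0)
  max_lin <- max_ent <- integer(n_perm)
  with_seed(seed, for (b in seq_len(n_perm)) {
    tr <- .permute_trials(bd$trials, "state_change_probability",
                          bd$trials$participant)
    tr$entropy_basis <- binary_entropy(tr$state_change_probability)
    Xp <- .design(tr, both)
    Xp_nl <- .design(tr, "entropy_basis")
    Xp_ne <- .design(tr, "state_change_probability")
    llp <- lmm_ml_bins_cpp(bd$Y, list(Xp, Xp_nl, Xp_ne), g, G)
    pl <- .lrt_from_ll(llp[, 1], llp[, 2], 1L)
    pe <- .lrt_from_ll(llp[, 1], llp[, 3], 1L)
    ll_ <- .cluster_lengths(!pl$singular & pl$p < alpha)
    le_ <- .cluster_lengths(!pe$singular & pe$p < alpha)
    null_lin <- c(null_lin, ll_)
    null_ent <- c(null_ent, le_)
    max_lin[b] <- if (length(ll_)) max(ll_) else 0L
    max_ent[b] <- if (length(le_)) max(le_) else 0L
  })

  wrap <- function(obs, nulls, maxes, coef) {
    sig <- !obs$singular & obs$p < alpha
    thr <- .null_threshold(nulls, maxes, null_pool, threshold_prob)
    cl <- .cluster_table(sig)
    cl$surviving <- cl$length > thr
    structure(list(series = data.frame(bin = bd$bins, obs,
                                       significant = sig, coef = coef),
                   clusters = cl, null_lengths = nulls, threshold = thr,
                   n_perm = n_perm),
              class = "cluster_result")
  }
  list(linear = wrap(obs_lin, null_lin, max_lin, coefs[, 1]),
       entropy = wrap(obs_ent, null_ent, max_ent, coefs[, 2]))
}

#' Interaction of state change probability with its dichotomization at 0.5
#'
#' Tests whether the slope of state change probability on the pupil response
#' differs between trials below and above `q = 0.5` (the signature of an
#' entropy-like, sign-flipping effect). The full model contains `q`, the
#' indicator `1{q > 0.5}` and their interaction; the reduced model drops the
#' interaction; the LRT on the interaction term is permutation-corrected.
#'
#' @inheritParams dual_basis_model
#' @return a `cluster_result` for the interaction term.
#' @export
dichotomized_interaction <- function(epochs, n_perm = 500L, alpha = 0.05,
                                     seed = 1L, threshold_prob = 0.95,
                                     null_pool = c("max", "all")) {
  null_pool <- match.arg(null_pool)
  q <- epochs$state_change_probability
  if (is.null(q)) stop("epochs must carry `state_change_probability`")
  if (all(q <= 0.5) || all(q > 0.5)) {
    stop("need trials on both sides of q = 0.5")
  }
  epochs$above_half <- as.numeric(q > 0.5)
  epochs$q_x_above <- q * epochs$above_half
  bd <- .bin_data(epochs)
  g <- as.integer(factor(bd$trials$participant)) - 1L
  G <- max(g) + 1L
  full_cols <- c("state_change_probability", "above_half", "q_x_above")
  red_cols <- c("state_change_probability", "above_half")
  Xf <- .design(bd$trials, full_cols)
  Xr <- .design(bd$trials, red_cols)
  ll <- lmm_ml_bins_cpp(bd$Y, list(Xf, Xr), g, G)
  obs <- .lrt_from_ll(ll[, 1], ll[, 2], 1L)
  obs_sig <- !obs$singular & obs$p < alpha

  null_lengths <- integer(0)
  null_max <- integer(n_perm)
  with_seed(seed, for (b in seq_len(n_perm)) {
    tr <- .permute_trials(bd$trials, "state_change_probability",
                          bd$trials$participant)
    tr$above_half <- as.numeric(tr$state_change_probability > 0.5)
    tr$q_x_above <- tr$state_change_probability * tr$above_half
    llp <- lmm_ml_bins_cpp(bd$Y, list(.design(tr, full_cols),
                                      .design(tr, red_cols)), g, G)
    pr <- .lrt_from_ll(llp[, 1], llp[, 2], 1L)
    lens <- .cluster_lengths(!pr$singular & pr$p < alpha)
    null_lengths <- c(null_lengths, lens)
    null_max[b] <- if (length(lens)) max(lens) else 0L
  })
  threshold <- .null_threshold(null_lengths, null_max, null_pool,
                               threshold_prob)
  clusters <- .cluster_table(obs_sig)
  clusters$surviving <- clusters$length > threshold
  structure(list(series = data.frame(bin = bd$bins, obs,
                                     significant = obs_sig),
                 clusters = clusters, null_lengths = null_lengths,
                 threshold = threshold, n_perm = n_perm),
            class = "cluster_result")
}
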