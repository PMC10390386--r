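#' Study configuration for an end-to-end synthetic run
#'
#' Bundles everything [run_study()] needs: a named experimental condition, a
#' cohort size, the generating agent, the pupil generator settings, the
#' statistical analysis settings, and a master seed from which all
#' per-participant, per-stage streams are derived (so enlarging the cohort
#' never perturbs existing participants).
#'
#' @param condition `"exp1"`, `"exp2a"` or `"exp2b"` (see
#'   [condition_config()]).
#' @param n_participants cohort size.
#' @param agent an [agent_spec()] generating the behavior (default: a
#'   Bayesian HMM agent with weakly informative priors).
#' @param hmm an [hmm_params()] used for the uncertainty estimates.
#' @param pupil a [pupil_gen_spec()] or `NULL` to run the behavioral-only
#'   pipeline (stages sessions/fits/estimates).
#' @param analysis list: `predictors`, `n_perm`, `alpha` for the cluster
#'   statistics stage.
#' @param fit_models character vector of models to fit per participant
#'   (empty to skip fitting).
#' @param n_particles particles for the estimate stage.
#' @param seed master seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(condition = c("exp1", "exp2a", "exp2b"),
                         n_participants = 10L,
                         agent = agent_spec("bayes_hmm",
                                            c(alpha_p = 1, beta_p = 1,
                                              alpha_a = 1, beta_a = 12,
                                              beta = 8)),
                         hmm = hmm_params(1, 1, 1, 12),
                         pupil = pupil_gen_spec(),
                         analysis = list(predictors = "state_entropy",
                                         n_perm = 100L, alpha = 0.05),
                         fit_models = character(),
                         n_particles = 2000L, seed = 1L) {
  condition <- match.arg(condition)
  structure(list(condition = condition,
                 n_participants = as.integer(n_participants), agent = agent,
                 hmm = hmm, pupil = pupil, analysis = analysis,
                 fit_models = fit_models,
                 n_particles = as.integer(n_particles),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from a JSON file
#'
#' Keys mirror the [study_config()] arguments; `agent` is given as
#' `{"kind": ..., "params": {...}}`, `hmm` as a 4-element object, `pupil` as
#' an object of [pupil_gen_spec()] overrides or `null` for behavioral-only.
#'
#' @param path JSON file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (k in c("condition", "n_participants", "seed", "n_particles",
              "fit_models")) {
    if (!is.null(j[[k]])) args[[k]] <- j[[k]]
  }
  if (!is.null(j$agent)) {
    args$agent <- agent_spec(j$agent$kind, unlist(j$agent$params))
  }
  if (!is.null(j$hmm)) args$hmm <- do.call(hmm_params, as.list(j$hmm))
  if ("pupil" %in% names(j)) {
    # assigning NULL would drop the element; keep it to force behavioral-only
    args["pupil"] <- if (is.null(j$pupil)) list(NULL) else {
      list(do.call(pupil_gen_spec, as.list(j$pupil)))
    }
  }
  if (!is.null(j$analysis)) args$analysis <- as.list(j$analysis)
  do.call(study_config, args)
}

#' Run the full synthetic study
#'
#' Executes, in order: session simulation for every participant; optional
#' per-participant model fits; particle-filter estimates; synthetic pupil
#' recordings; preprocessing to epochs; cluster statistics. All outputs are
#' plain-text files in `out_dir` plus a JSON manifest recording the
#' configuration, seeds and package version. Completed stages are detected by
#' their marker files, so an interrupted run resumes where it stopped.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the per-stage in-memory results
#'   (`sessions`, `fits`, `estimates`, `reports`, `epochs`, `stats`).
#' @export
run_study <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tcfg <- condition_config(config$condition)
  np <- config$n_participants
  done <- function(stage) file.exists(file.path(out_dir, paste0(
    ".done_", stage)))
  mark <- function(stage) file.create(file.path(out_dir, paste0(
    ".done_", stage)))

  say("stage 1/6: simulating %d sessions (%s)", np, config$condition)
  sessions <- lapply(seq_len(np), function(i) {
    generate_session(tcfg, config$agent,
                     seed = derive_seed(config$seed, "session", i))
  })
  if (!done("sessions")) {
    for (i in seq_len(np)) {
      write_session_tsv(sessions[[i]],
                        file.path(out_dir, sprintf("session_%02d.tsv", i)))
    }
    mark("sessions")
  }

  fits <- NULL
  if (length(config$fit_models) > 0) {
    say("stage 2/6: fitting models (%s)",
        paste(config$fit_models, collapse = ", "))
    rows <- list()
    for (i in seq_len(np)) {
      for (fm in config$fit_models) {
        f <- fit_mle(fit_spec(fm, n_starts = 3L,
                              n_particles = config$n_particles,
                              seed = derive_seed(config$seed, "fit", i, fm)),
                     sessions[[i]])
        rows[[length(rows) + 1L]] <- data.frame(
          participant = i, model = fm, k = f$k, nll = f$nll, aic = f$aic,
          bic = f$bic, theta = paste(sprintf("%s=%.6g", names(f$theta),
                                             f$theta), collapse = ";"))
      }
    }
    fits <- do.call(rbind, rows)
    if (!done("fits")) {
      write.table(fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      mark("fits")
    }
  } else {
    say("stage 2/6: model fitting skipped")
  }

  say("stage 3/6: particle-filter estimates")
  estimates <- lapply(seq_len(np), function(i) {
    run_filter(config$hmm, sessions[[i]], n_particles = config$n_particles,
               seed = derive_seed(config$seed, "filter", i))
  })
  if (!done("estimates")) {
    for (i in seq_len(np)) {
      write_estimates_tsv(estimates[[i]],
                          file.path(out_dir,
                                    sprintf("estimates_%02d.tsv", i)))
    }
    mark("estimates")
  }

  if (is.null(config$pupil)) {
    say("stages 4-6 skipped (behavioral-only pipeline: no pupil spec)")
    manifest(config, out_dir, pupil = FALSE)
    return(invisible(list(sessions = sessions, fits = fits,
                          estimates = estimates)))
  }

  say("stage 4/6: synthesizing pupil recordings")
  recordings <- lapply(seq_len(np), function(i) {
    generate_recording(config$pupil, sessions[[i]], estimates[[i]],
                       seed = derive_seed(config$seed, "pupil", i))
  })

  say("stage 5/6: preprocessing")
  reports <- numeric(np)
  epochs_list <- vector("list", np)
  for (i in seq_len(np)) {
    cl <- clean_series(recordings[[i]])
    reports[i] <- cl$interpolated_pct
    ep <- epoch_and_baseline(cl, recordings[[i]]$events)
    e <- ep$epochs
    e$participant <- i
    est <- estimates[[i]]
    e$state_change_probability <-
      est$state_change_probability[match(e$trial, est$trial)]
    e$state_entropy <- est$state_entropy[match(e$trial, est$trial)]
    e$feedback_negative <-
      as.numeric(sessions[[i]]$reward[match(e$trial, sessions[[i]]$trial)] < 0)
    epochs_list[[i]] <- e
  }
  excl <- if (np >= 2) participant_exclusion(reports) else rep(FALSE, np)
  epochs <- do.call(rbind, epochs_list[!excl])
  if (!done("epochs")) {
    write.table(epochs, file.path(out_dir, "epochs.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(participant = seq_len(np),
                           interpolated_pct = reports, excluded = excl),
                file.path(out_dir, "preprocess_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mark("epochs")
  }

  say("stage 6/6: cluster statistics (%s)",
      paste(config$analysis$predictors, collapse = ", "))
  stats_res <- cluster_permutation(
    epochs, bin_model_spec(config$analysis$predictors,
                           alpha = config$analysis$alpha %||% 0.05),
    n_perm = config$analysis$n_perm %||% 100L,
    seed = derive_seed(config$seed, "stats"))
  if (!done("stats")) {
    write.table(stats_res$series, file.path(out_dir, "bin_stats.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(threshold = stats_res$threshold, n_perm = stats_res$n_perm,
           clusters = stats_res$clusters),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    mark("stats")
  }
  manifest(config, out_dir, pupil = TRUE)
  invisible(list(sessions = sessions, fits = fits, estimates = estimates,
                 reports = reports, excluded = excl, epochs = epochs,
                 stats = stats_res))
}

manifest <- function(config, out_dir, pupil) {
  jsonlite::write_json(
    list(condition = config$condition,
         n_participants = config$n_participants, seed = config$seed,
         n_particles = config$n_particles, pupil_stage = pupil,
         package_version = as.character(utils::packageVersion("revlearn")),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
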