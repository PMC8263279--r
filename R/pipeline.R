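paradigm_tasks <- function(paradigm) {
  # paradigm: "ME" (execution) or "MI" (imagery); left task first (class 0)
  paste0(c("L", "R"), "-FE_", paradigm)
}

#' Build one subject's train/test sample matrices for one paradigm
#'
#' Band-pass filters each session, extracts 0-8 s task epochs, keeps the two
#' tasks of the requested paradigm, fits the per-channel min-max scaler on
#' the training sessions only (sessions 1..K-1), applies it to train and
#' test, and flattens into sample matrices. The held-out last session never
#' influences the scaler.
#'
#' @param subject one element of [simulate_study()] output (or a list with
#'   `sessions` of `session_recording`s).
#' @param paradigm `"ME"` or `"MI"`.
#' @param bandpass [bandpass_spec()].
#' @return list with `train`, `test` (sample matrices) and `scaler`.
#' @export
build_subject_samples <- function(subject, paradigm = c("MI", "ME"),
                                  bandpass = bandpass_spec()) {
  paradigm <- match.arg(paradigm)
  tasks <- paradigm_tasks(paradigm)
  sess <- subject$sessions
  n_se <- length(sess)
  if (n_se < 2) stop("need at least two sessions (train + test)")
  epochs <- lapply(sess, function(rec) {
    rec$hbo <- bandpass_filter(rec$hbo, rec$sampling_rate, bandpass)
    extract_epochs(rec)
  })
  train_ep <- lapply(epochs[seq_len(n_se - 1)], epochs_subset, tasks = tasks)
  test_ep <- epochs_subset(epochs[[n_se]], tasks)
  scaler <- fit_scaler(train_ep)
  train_ep <- lapply(train_ep, function(e) apply_scaler(scaler, e))
  test_ep <- apply_scaler(scaler, test_ep)
  train <- assemble_samples(lapply(train_ep, epochs_subset, tasks = tasks[1]),
                            lapply(train_ep, epochs_subset, tasks = tasks[2]))
  test <- assemble_samples(epochs_subset(test_ep, tasks[1]),
                           epochs_subset(test_ep, tasks[2]))
  list(train = train, test = test, scaler = scaler)
}

#' Run the full study pipeline
#'
#' Simulates the study, then for every subject and both paradigms trains a
#' DBN on sessions 1..K-1 and scores the held-out last session; finally
#' evaluates the cross-subject transfer grid on the imagery problem. Writes
#' per-subject accuracy tables (execution and imagery columns), the transfer
#' grid, and the configuration snapshot to `outdir` as delimited text.
#'
#' @param cfg [run_config()].
#' @param outdir output directory (created if needed); NULL to skip writing.
#' @param paradigms which problems to train (default both).
#' @param verbose print progress.
#' @return list with `accuracy` (data.frame), `transfer`
#'   (`transfer_matrix` or NULL if imagery was not run), `models`,
#'   `histories`, `reports`.
#' @export
run_pipeline <- function(cfg = run_config(), outdir = NULL,
                         paradigms = c("ME", "MI"), verbose = FALSE) {
  study <- simulate_study(cfg$sim)
  subs <- vapply(study, function(s) s$profile$subject_id, "")
  models <- list(); reports <- list(); histories <- list()
  test_sets <- list()
  for (pd in paradigms) {
    models[[pd]] <- list(); reports[[pd]] <- list()
    histories[[pd]] <- list(); test_sets[[pd]] <- list()
    for (k in seq_along(study)) {
      ds <- build_subject_samples(study[[k]], pd, cfg$bandpass)
      cd_k <- cfg$cd; cd_k$seed <- derive_seed(cfg$cd$seed, k,
                                               match(pd, c("ME", "MI")))
      fit <- train_dbn(ds$train, cfg$grid, cd_k, cfg$ft)
      rep_k <- score_model(fit$model, ds$test)
      models[[pd]][[subs[k]]] <- fit$model
      histories[[pd]][[subs[k]]] <- fit$history
      reports[[pd]][[subs[k]]] <- rep_k
      test_sets[[pd]][[subs[k]]] <- ds$test
      if (verbose)
        message(sprintf("%s %s: (h1,h2)=(%d,%d) test sample acc %.2f%%",
                        subs[k], pd, fit$history$h1, fit$history$h2,
                        rep_k$sample_accuracy))
    }
  }
  acc <- data.frame(subject = subs, stringsAsFactors = FALSE)
  for (pd in paradigms) {
    acc[[paste0(ifelse(pd == "ME", "movement", "imagery"), "_sample")]] <-
      vapply(reports[[pd]], `[[`, 0, "sample_accuracy")
    acc[[paste0(ifelse(pd == "ME", "movement", "imagery"), "_trial")]] <-
      vapply(reports[[pd]], `[[`, 0, "trial_accuracy")
  }
  transfer <- NULL
  if ("MI" %in% paradigms) {
    arch <- data.frame(
      subject = subs,
      h1 = vapply(histories[["MI"]], `[[`, 0L, "h1"),
      h2 = vapply(histories[["MI"]], `[[`, 0L, "h2"))
    transfer <- transfer_evaluate(models[["MI"]], test_sets[["MI"]], arch)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    acc_out <- acc
    num <- vapply(acc_out, is.numeric, TRUE)
    acc_out[num] <- lapply(acc_out[num], function(v) sprintf("%.2f", v))
    utils::write.csv(acc_out, file.path(outdir, "accuracy_by_subject.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(transfer)) {
      tm <- format(round(transfer$accuracy, 2), nsmall = 2, trim = TRUE)
      tab <- data.frame(model = paste0("DBN_", rownames(transfer$accuracy)),
                        h1 = transfer$arch$h1, h2 = transfer$arch$h2, tm,
                        check.names = FALSE)
      utils::write.csv(tab, file.path(outdir, "transfer_imagery.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(config_snapshot(cfg),
                         file.path(outdir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(accuracy = acc, transfer = transfer, models = models,
       histories = histories, reports = reports)
}

# plain-list view of a run_config for serialization
config_snapshot <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}
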