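# Step 3 — train the deep belief networks.
#
# For every subject and both binary problems (executed and imagined
# flexion/extension, left vs right arm): select the hidden-layer sizes by
# trial-blocked 2-fold cross-validation over the 5x5 grid, greedily pretrain
# the two RBMs by CD-1, fine-tune in two phases, and score the held-out
# session. Model containers go to scratch/models (not part of the
# repository); the accuracy table goes to results/.

source("analysis/_settings.R")

cfg <- study_config()
study <- simulate_study(cfg$sim)

rows <- list()
for (k in seq_along(study)) {
  sid <- study[[k]]$profile$subject_id
  for (pd in c("ME", "MI")) {
    ds <- build_subject_samples(study[[k]], pd, cfg$bandpass)
    cd_k <- cfg$cd
    cd_k$seed <- derive_seed(cfg$cd$seed, k, match(pd, c("ME", "MI")))
    fit <- train_dbn(ds$train, cfg$grid, cd_k, cfg$ft)
    rep_k <- score_model(fit$model, ds$test)
    save_model(fit$model, ds$scaler, config = list(seed = cfg$seed,
                                                   paradigm = pd),
               path = file.path(scratch_dir, "models",
                                sprintf("%s_%s.json", sid, pd)),
               history = fit$history)
    rows[[length(rows) + 1]] <- data.frame(
      subject = sid, paradigm = pd,
      h1 = fit$history$h1, h2 = fit$history$h2,
      sample_accuracy = round(rep_k$sample_accuracy, 2),
      trial_accuracy = round(rep_k$trial_accuracy, 2))
    cat(sprintf("%s %s: (h1,h2)=(%d,%d) sample %.2f%% trial %.2f%%\n",
                sid, pd, fit$history$h1, fit$history$h2,
                rep_k$sample_accuracy, rep_k$trial_accuracy))
  }
}
acc <- do.call(rbind, rows)
write.csv(acc, file.path(results_dir, "03_accuracies.csv"), row.names = FALSE)
cat("wrote", file.path(results_dir, "03_accuracies.csv"), "\n")
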