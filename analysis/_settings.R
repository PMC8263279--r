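# Shared settings for the numbered analysis drivers.
#
# The distributed configuration runs the emulated study at a reduced scale
# (10 subjects, 10 trials per task per session instead of the protocol's 30)
# so the whole workflow completes in minutes on one CPU; set FULL_PROTOCOL
# to TRUE to reproduce the full 19200x16 / 9600x16 dataset geometry.

library(fnirsdbn)

FULL_PROTOCOL <- FALSE
STUDY_SEED <- 1L

study_config <- function() {
  run_config(
    seed = STUDY_SEED,
    sim = sim_config(
      n_subjects = 10,
      trials_per_task_per_session = if (FULL_PROTOCOL) 30L else 10L))
}

results_dir <- "results"
scratch_dir <- "scratch"
dir.create(results_dir, showWarnings = FALSE)
dir.create(file.path(scratch_dir, "models"), recursive = TRUE,
           showWarnings = FALSE)
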