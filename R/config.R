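#' @keywords internal
"_PACKAGE"

# Canonical task labels: arm (L/R) x paradigm (ME = motor execution,
# MI = motor imagery). The left/right *arm* is the class; execution and
# imagery are always trained as two separate binary problems.
TASK_SET <- c("L-FE_ME", "R-FE_ME", "L-FE_MI", "R-FE_MI")

task_arm <- function(task) substr(task, 1L, 1L)
task_paradigm <- function(task) substr(task, nchar(task) - 1L, nchar(task))

#' Deterministically derive a child seed
#'
#' Mixes a base seed with up to two stream identifiers so that every
#' subject/session/stage gets its own reproducible stream. Result is always a
#' valid 32-bit seed.
#'
#' @param seed base integer seed.
#' @param a,b integer stream identifiers.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, a = 0L, b = 0L) {
  s <- (as.double(seed) %% 1e6) * 10007 + as.double(a) * 1009 + as.double(b) * 101
  as.integer(s %% 2147483629)
}

#' Simulation configuration
#'
#' Describes the experimental protocol being emulated: 4 tasks (left/right arm
#' flexion-extension, executed and imagined), 3 sessions of 30 trials per task,
#' 16 channels at 20 Hz, each trial being 2 s cue + 8 s task + 1 s test cue +
#' 17 s rest. Amplitude parameters express the hemodynamic contrast the
#' classifier is expected to exploit: contralateral channels respond more
#' strongly than ipsilateral ones and imagery responds more weakly than
#' execution.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_sessions sessions per subject.
#' @param trials_per_task_per_session trials of *each* task in one session.
#' @param sampling_rate sampling rate in Hz.
#' @param cue_s,task_s,rest_s,test_cue_s trial phase durations in seconds.
#' @param n_channels number of measurement channels.
#' @param left_channels indices of left-hemisphere channels (the rest are
#'   right-hemisphere).
#' @param exec_amplitude peak HbO response (z-units) of an executed movement on
#'   an ipsilateral channel with unit gain.
#' @param imagery_amplitude_ratio multiplicative amplitude of imagery relative
#'   to execution, in (0,1).
#' @param contralateral_ratio contralateral/ipsilateral peak ratio, > 1.
#' @param hbr_ratio HbR amplitude relative to HbO (negative: HbR falls while
#'   HbO rises).
#' @param hrf_params double-gamma kernel parameters, see
#'   [hemodynamic_kernel()].
#' @param noise_spec physiological noise description: `frequencies` (Hz) and
#'   `amplitudes` of sinusoidal components (cardiac, respiratory, Mayer waves)
#'   plus `white_sigma`, the white-noise standard deviation.
#' @param subject_variability inter-subject idiosyncrasy parameters, see
#'   [default_subject_variability()] and [subject_profile()].
#' @param seed base seed; all per-subject/per-session streams derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10L,
                       n_sessions = 3L,
                       trials_per_task_per_session = 30L,
                       sampling_rate = 20,
                       cue_s = 2, task_s = 8, rest_s = 17, test_cue_s = 1,
                       n_channels = 16L,
                       left_channels = 1:8,
                       exec_amplitude = 1.0,
                       imagery_amplitude_ratio = 0.6,
                       contralateral_ratio = 1.5,
                       hbr_ratio = -0.3,
                       hrf_params = default_hrf_params(),
                       noise_spec = default_noise_spec(),
                       subject_variability = default_subject_variability(),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, trials_per_task_per_session >= 1)
  # strict inequalities describe physiology; equality is allowed so that
  # degenerate (symmetry-testing) configurations remain expressible
  if (imagery_amplitude_ratio <= 0 || imagery_amplitude_ratio > 1)
    stop("imagery_amplitude_ratio must lie in (0, 1]")
  if (contralateral_ratio < 1)
    stop("contralateral_ratio must be at least 1")
  if (any(noise_spec$frequencies >= sampling_rate / 2))
    stop("all noise frequencies must be below the Nyquist frequency")
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    trials_per_task_per_session = as.integer(trials_per_task_per_session),
    task_set = TASK_SET,
    sampling_rate = sampling_rate,
    cue_s = cue_s, task_s = task_s, rest_s = rest_s, test_cue_s = test_cue_s,
    n_channels = as.integer(n_channels),
    left_channels = as.integer(left_channels),
    exec_amplitude = exec_amplitude,
    imagery_amplitude_ratio = imagery_amplitude_ratio,
    contralateral_ratio = contralateral_ratio,
    hbr_ratio = hbr_ratio,
    hrf_params = hrf_params,
    noise_spec = noise_spec,
    subject_variability = subject_variability,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default double-gamma response parameters
#'
#' The peak lobe is a gamma density with mode `peak_delay_s`; the optional
#' undershoot is a second gamma density subtracted with weight
#' `undershoot_ratio`. Defaults place the peak of the 8-s-task-convolved
#' response at ~17 s after task onset, within the 16-20 s window seen in
#' event-averaged motor-cortex HbO.
#'
#' @return list of kernel parameters.
#' @export
default_hrf_params <- function() {
  list(peak_delay_s = 14, peak_shape = 3,
       undershoot_delay_s = 22, undershoot_shape = 8,
       undershoot_ratio = 0.3)
}

#' Default physiological noise specification
#'
#' Cardiac (~1.1 Hz), respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz)
#' sinusoids plus white noise, amplitudes in the same z-units as the unit
#' execution response peak. Only the Mayer component survives the 0.01-0.2 Hz
#' band-pass, so it sets the in-band noise floor; its default amplitude is
#' calibrated so the early-window lateralization signal is decodable at
#' roughly the per-sample accuracy the emulated protocol is known to support
#' (see the methods vignette).
#'
#' @return list with `frequencies`, `amplitudes`, `white_sigma`.
#' @export
default_noise_spec <- function() {
  list(frequencies = c(cardiac = 1.1, respiratory = 0.25, mayer = 0.1),
       amplitudes  = c(cardiac = 0.4, respiratory = 0.2, mayer = 0.03),
       white_sigma = 0.15)
}

#' Default inter-subject variability parameters
#'
#' Controls the subject idiosyncrasy model of [subject_profile()]: focal
#' activation topography (how many channels per hemisphere respond, how
#' strongly the rest are attenuated, and the lognormal spread of the active
#' gains), per-channel noise-scale spread, and tight global amplitude and
#' HRF-delay jitters. Defaults are calibrated so a population of synthetic
#' subjects supports subject-specific classifiers whose cross-subject
#' transfer grid is diagonal-dominant while per-subject decodability stays
#' near the levels the emulated protocol is known to support (see the
#' methods vignette).
#'
#' @return list of variability parameters.
#' @export
default_subject_variability <- function() {
  list(active_channels_per_hemisphere = 3L,
       inactive_gain = 0.02,
       gain_sdlog = 0.5,
       noise_sdlog = 0.5,
       amplitude_sdlog = 0.03,
       hrf_jitter_sdlog = 0.02)
}

# samples in one full trial (cue + task + test cue + rest)
trial_samples <- function(config) {
  as.integer(round((config$cue_s + config$task_s + config$rest_s +
                      config$test_cue_s) * config$sampling_rate))
}

#' Band-pass filter specification
#'
#' @param low_cut,high_cut band edges in Hz.
#' @param order Butterworth order.
#' @param zero_phase apply the filter forward and backward (no phase shift).
#' @return a `bandpass_spec` list.
#' @export
bandpass_spec <- function(low_cut = 0.01, high_cut = 0.2, order = 3,
                          zero_phase = TRUE) {
  if (low_cut <= 0 || low_cut >= high_cut)
    stop("need 0 < low_cut < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 zero_phase = zero_phase),
            class = "bandpass_spec")
}

#' Contrastive-divergence training configuration
#'
#' @param epochs full passes over the training data (pretraining run length).
#' @param learning_rate step size for weights and offsets.
#' @param momentum velocity blending coefficient in `[0, 1)`.
#' @param cd_steps Gibbs half-step pairs per update (CD-k).
#' @param batch_size mini-batch rows.
#' @param init_sigma sd of the Gaussian weight initialization.
#' @param seed RNG seed for initialization, shuffling and hidden sampling.
#' @return a `cd_config` list.
#' @export
cd_config <- function(epochs = 10L, learning_rate = 0.1, momentum = 0.5,
                      cd_steps = 1L, batch_size = 100L, init_sigma = 0.01,
                      seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, cd_steps >= 1,
            epochs >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, cd_steps = as.integer(cd_steps),
                 batch_size = as.integer(batch_size), init_sigma = init_sigma,
                 seed = as.integer(seed)),
            class = "cd_config")
}

#' Fine-tuning configuration
#'
#' Phase 1 adjusts only the softmax output weights on frozen features; phase 2
#' backpropagates through the whole network. Both phases use Polak-Ribiere
#' conjugate-gradient steps with a backtracking (Armijo) line search and
#' momentum blending of the previous accepted step. `cv_*` fields give the
#' shortened schedule used during architecture selection only.
#'
#' @param phase1_iters,phase2_iters CG iterations per phase.
#' @param learning_rate initial line-search step scale.
#' @param momentum blending coefficient for the previous accepted step.
#' @param cg_line_searches accepted-step-size growth tries per iteration.
#' @param cv_phase1_iters,cv_phase2_iters schedule used in cross-validated
#'   architecture selection.
#' @param seed RNG seed (fine-tuning itself is deterministic; kept for
#'   bookkeeping).
#' @return a `finetune_config` list.
#' @export
finetune_config <- function(phase1_iters = 30L, phase2_iters = 30L,
                            learning_rate = 0.1, momentum = 0.5,
                            cg_line_searches = 3L,
                            cv_phase1_iters = 30L, cv_phase2_iters = 0L,
                            seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1)
  structure(list(phase1_iters = as.integer(phase1_iters),
                 phase2_iters = as.integer(phase2_iters),
                 learning_rate = learning_rate, momentum = momentum,
                 cg_line_searches = as.integer(cg_line_searches),
                 cv_phase1_iters = as.integer(cv_phase1_iters),
                 cv_phase2_iters = as.integer(cv_phase2_iters),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

#' Hidden-layer architecture grid
#'
#' @param candidates candidate unit counts for each hidden layer; all
#'   `(h1, h2)` pairs of the Cartesian product are evaluated.
#' @param n_folds cross-validation folds (trial-blocked).
#' @return an `arch_grid` list.
#' @export
arch_grid <- function(candidates = c(10L, 20L, 30L, 40L, 50L), n_folds = 2L) {
  stopifnot(all(candidates >= 1), n_folds >= 2)
  structure(list(candidates = as.integer(candidates),
                 n_folds = as.integer(n_folds)),
            class = "arch_grid")
}

#' Full pipeline run configuration
#'
#' Bundles every stage's configuration under one global seed. Stage seeds are
#' derived deterministically from `seed` so a run is reproducible from this
#' object alone.
#'
#' @param seed global seed.
#' @param sim [sim_config()]; its seed is overridden by a derived seed.
#' @param bandpass [bandpass_spec()].
#' @param cd [cd_config()].
#' @param ft [finetune_config()].
#' @param grid [arch_grid()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(),
                       bandpass = bandpass_spec(),
                       cd = cd_config(),
                       ft = finetune_config(),
                       grid = arch_grid()) {
  sim$seed <- derive_seed(seed, 1L)
  cd$seed <- derive_seed(seed, 2L)
  ft$seed <- derive_seed(seed, 3L)
  structure(list(seed = as.integer(seed), sim = sim, bandpass = bandpass,
                 cd = cd, ft = ft, grid = grid),
            class = "run_config")
}
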