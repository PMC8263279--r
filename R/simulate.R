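#' Double-gamma hemodynamic impulse response
#'
#' Canonical-style kernel: a gamma-density main lobe minus a delayed,
#' down-weighted gamma undershoot, normalized to unit peak. The gamma lobes
#' are parameterized by their mode (`*_delay_s`) and shape; the scale is
#' `delay / (shape - 1)`, so the density is exactly 0 at t = 0 for shapes > 1.
#'
#' @param hrf_params list with `peak_delay_s`, `peak_shape`,
#'   `undershoot_delay_s`, `undershoot_shape`, `undershoot_ratio`
#'   (see [default_hrf_params()]).
#' @param sampling_rate sampling rate in Hz.
#' @param duration_s kernel support in seconds (>= 30).
#' @return numeric vector of length `duration_s * sampling_rate`, starting at
#'   t = 0, unit peak.
#' @export
hemodynamic_kernel <- function(hrf_params = default_hrf_params(),
                               sampling_rate = 20, duration_s = 40) {
  if (sampling_rate <= 0 || duration_s <= 0)
    stop("sampling_rate and duration_s must be positive")
  if (duration_s < 30)
    stop("duration_s must be at least 30 s to contain the response")
  p <- hrf_params
  n <- as.integer(round(duration_s * sampling_rate))
  t <- (seq_len(n) - 1) / sampling_rate
  main <- stats::dgamma(t, shape = p$peak_shape,
                        scale = p$peak_delay_s / (p$peak_shape - 1))
  k <- main
  if (p$undershoot_ratio > 0) {
    under <- stats::dgamma(t, shape = p$undershoot_shape,
                           scale = p$undershoot_delay_s / (p$undershoot_shape - 1))
    # undershoot_ratio is relative to the (unit) peak of the main lobe
    k <- main - p$undershoot_ratio * max(main) / max(under) * under
  }
  k / max(k)
}

#' Subject-specific generative profile
#'
#' Inter-subject variability, a deterministic function of
#' `(config$seed, subject_id)`:
#'
#' * focal activation topography — in each hemisphere only
#'   `active_channels_per_hemisphere` channels carry a full-strength task
#'   response (lognormal gains, sdlog `gain_sdlog`); the remaining channels
#'   are attenuated by `inactive_gain`. Gains are normalized per hemisphere
#'   to constant root-mean-square, so subjects differ in *where* they
#'   activate much more than in how decodable they are. This mirrors the
#'   focal arm-area activation that a fixed 16-channel montage samples
#'   differently across heads.
#' * per-channel physiological-noise scales (lognormal, sdlog
#'   `noise_sdlog`, hemisphere-RMS-normalized) — scalp coupling and
#'   superficial vasculature differ per channel per subject.
#' * a global `amplitude_scale` and a jittered HRF peak delay (both tight,
#'   sdlog `amplitude_sdlog` / `hrf_jitter_sdlog`).
#'
#' @param config [sim_config()].
#' @param subject_id integer subject index (1-based).
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(config, subject_id) {
  stopifnot(subject_id >= 1)
  sv <- config$subject_variability
  seed <- derive_seed(config$seed, as.integer(subject_id), 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_ch <- config$n_channels
  hemis <- list(config$left_channels,
                setdiff(seq_len(n_ch), config$left_channels))
  gains <- exp(stats::rnorm(n_ch, 0, sv$gain_sdlog))
  for (hemi in hemis) {
    active <- sample(hemi, min(sv$active_channels_per_hemisphere,
                               length(hemi)))
    gains[setdiff(hemi, active)] <-
      gains[setdiff(hemi, active)] * sv$inactive_gain
    gains[hemi] <- gains[hemi] / sqrt(mean(gains[hemi]^2))
  }
  noise_scale <- exp(stats::rnorm(n_ch, 0, sv$noise_sdlog))
  for (hemi in hemis)
    noise_scale[hemi] <- noise_scale[hemi] / sqrt(mean(noise_scale[hemi]^2))
  prof <- list(
    subject_id = sprintf("S%d", as.integer(subject_id)),
    subject_index = as.integer(subject_id),
    channel_gains = gains,
    channel_noise_scale = noise_scale,
    amplitude_scale = exp(stats::rnorm(1, 0, sv$amplitude_sdlog)),
    hrf_params = local({
      p <- config$hrf_params
      p$peak_delay_s <- p$peak_delay_s *
        exp(stats::rnorm(1, 0, sv$hrf_jitter_sdlog))
      p
    }),
    seed_offset = as.integer(subject_id)
  )
  class(prof) <- "subject_profile"
  prof
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Noise-free single-trial HbO response of one channel
#'
#' An 8-s boxcar convolved with the hemodynamic kernel, normalized to unit
#' peak, then scaled by the execution amplitude, the imagery attenuation (for
#' MI tasks), the contralateral gain (when the channel's hemisphere is
#' opposite the task's arm) and the subject's channel gain and amplitude
#' scale.
#'
#' @param task task label from the configured task set.
#' @param channel channel index in `1:n_channels`.
#' @param profile [subject_profile()].
#' @param config [sim_config()].
#' @return numeric vector (HbO, starting at task onset); the HbR companion is
#'   `config$hbr_ratio` times this trace.
#' @export
trial_response <- function(task, channel, profile, config) {
  if (!task %in% config$task_set)
    stop("unknown task label: ", task)
  if (channel < 1 || channel > config$n_channels)
    stop("channel out of range")
  fs <- config$sampling_rate
  kern <- hemodynamic_kernel(profile$hrf_params, fs)
  box <- rep(1, as.integer(round(config$task_s * fs)))
  shape <- full_convolve(box, kern)
  shape <- shape / max(shape)
  amp <- config$exec_amplitude * profile$amplitude_scale *
    profile$channel_gains[channel]
  if (task_paradigm(task) == "MI")
    amp <- amp * config$imagery_amplitude_ratio
  is_left_channel <- channel %in% config$left_channels
  contra <- (task_arm(task) == "L" && !is_left_channel) ||
    (task_arm(task) == "R" && is_left_channel)
  if (contra)
    amp <- amp * config$contralateral_ratio
  amp * shape
}

# plain full linear convolution (lengths add)
full_convolve <- function(x, y) {
  n <- length(x) + length(y) - 1L
  xp <- c(x, rep(0, n - length(x)))
  yp <- c(y, rep(0, n - length(y)))
  Re(stats::fft(stats::fft(xp) * stats::fft(yp), inverse = TRUE)) / n
}

#' Physiological noise series
#'
#' Sum of sinusoids at the specified frequencies, each with an amplitude from
#' the spec and a phase drawn uniformly from the current RNG stream, plus
#' Gaussian white noise. Zero mean in expectation.
#'
#' @param n_samples series length.
#' @param sampling_rate Hz.
#' @param noise_spec see [default_noise_spec()].
#' @return numeric vector of length `n_samples`.
#' @export
physiological_noise <- function(n_samples, sampling_rate,
                                noise_spec = default_noise_spec()) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (any(noise_spec$frequencies >= sampling_rate / 2))
    stop("noise frequency at or above Nyquist")
  t <- (seq_len(n_samples) - 1) / sampling_rate
  out <- numeric(n_samples)
  for (i in seq_along(noise_spec$frequencies)) {
    phase <- stats::runif(1, 0, 2 * pi)
    out <- out + noise_spec$amplitudes[[i]] *
      sin(2 * pi * noise_spec$frequencies[[i]] * t + phase)
  }
  if (noise_spec$white_sigma > 0)
    out <- out + stats::rnorm(n_samples, 0, noise_spec$white_sigma)
  out
}

#' Simulate one recording session
#'
#' Generates `trials_per_task_per_session` trials of each task in a shuffled
#' order, superposes the per-trial hemodynamic responses at the task onsets
#' (responses may outlast a trial and overlap the next), and adds independent
#' physiological noise per channel. Fully reproducible given
#' `(config$seed, profile, session_index)`.
#'
#' @param config [sim_config()].
#' @param profile [subject_profile()].
#' @param session_index 1-based session number.
#' @return a `session_recording`: list with `hbo`/`hbr`
#'   (`n_channels x T` matrices), `sampling_rate`, `events` (data.frame with
#'   0-based `onset_sample` and `task`), `task_s`, `subject_id`,
#'   `session_index`.
#' @export
simulate_session <- function(config, profile, session_index) {
  fs <- config$sampling_rate
  tps <- trial_samples(config)
  n_tasks <- length(config$task_set)
  n_trials <- config$trials_per_task_per_session * n_tasks
  T_len <- n_trials * tps

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, profile$seed_offset, as.integer(session_index)))

  # rng draw order is fixed by purpose: (1) trial order, (2) per-channel noise
  tasks <- sample(rep(config$task_set, each = config$trials_per_task_per_session))
  onsets <- (seq_len(n_trials) - 1L) * tps +
    as.integer(round(config$cue_s * fs))

  # response shape is shared within (task, channel); compute each once
  hbo <- matrix(0, config$n_channels, T_len)
  resp <- lapply(config$task_set, function(tk)
    lapply(seq_len(config$n_channels), function(ch)
      trial_response(tk, ch, profile, config)))
  names(resp) <- config$task_set
  rl <- length(resp[[1]][[1]])
  for (i in seq_len(n_trials)) {
    idx <- onsets[i] + seq_len(rl)          # 1-based placement
    keep <- idx <= T_len
    for (ch in seq_len(config$n_channels)) {
      r <- resp[[tasks[i]]][[ch]]
      hbo[ch, idx[keep]] <- hbo[ch, idx[keep]] + r[keep]
    }
  }
  nsc <- profile$channel_noise_scale
  if (is.null(nsc)) nsc <- rep(1, config$n_channels)
  for (ch in seq_len(config$n_channels))
    hbo[ch, ] <- hbo[ch, ] +
      nsc[ch] * physiological_noise(T_len, fs, config$noise_spec)

  rec <- list(
    hbo = hbo,
    hbr = config$hbr_ratio * hbo,
    sampling_rate = fs,
    events = data.frame(onset_sample = onsets, task = tasks,
                        stringsAsFactors = FALSE),
    task_s = config$task_s,
    subject_id = profile$subject_id,
    session_index = as.integer(session_index)
  )
  class(rec) <- "session_recording"
  rec
}

#' Simulate a full multi-subject study
#'
#' @param config [sim_config()].
#' @return list with one element per subject, each a list of `profile` and
#'   `sessions` (a list of [simulate_session()] recordings).
#' @export
simulate_study <- function(config) {
  stopifnot(config$n_subjects >= 1)
  lapply(seq_len(config$n_subjects), function(s) {
    prof <- subject_profile(config, s)
    list(profile = prof,
         sessions = lapply(seq_len(config$n_sessions), function(k)
           simulate_session(config, prof, k)))
  })
}
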