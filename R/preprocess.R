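#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared magnitude response of a Butterworth band-pass of the
#' requested order — i.e. the filter run forward and backward, which has no
#' phase shift — to the series. The gain is evaluated in closed form from the
#' bilinear-prewarped analog prototype and applied in the frequency domain:
#' at a 0.01 Hz edge on 20 Hz data the direct-form recursion of the digital
#' filter loses about six significant digits, while the closed-form gain is
#' exact (DC is removed exactly, and filtering is linear to machine
#' precision). Slow hemodynamics (0.01-0.2 Hz by default) are kept; cardiac
#' and respiratory oscillations are rejected. With `zero_phase = FALSE` the
#' causal digital filter is applied once via `signal::filter`.
#'
#' @param series numeric vector, or a channels-by-time matrix filtered row-wise.
#' @param sampling_rate Hz.
#' @param spec [bandpass_spec()].
#' @return filtered series, same shape as the input.
#' @export
bandpass_filter <- function(series, sampling_rate, spec = bandpass_spec()) {
  if (spec$high_cut >= sampling_rate / 2)
    stop("high_cut must be below the Nyquist frequency")
  if (is.matrix(series)) {
    out <- series
    for (i in seq_len(nrow(series)))
      out[i, ] <- bandpass_filter(series[i, ], sampling_rate, spec)
    return(out)
  }
  if (length(series) <= 3 * (2 * spec$order))
    stop("series too short for the requested filter order")
  if (!spec$zero_phase) {
    flt <- signal::butter(spec$order,
                          c(spec$low_cut, spec$high_cut) / (sampling_rate / 2),
                          type = "pass")
    return(as.numeric(signal::filter(flt, series)))
  }
  n <- length(series)
  k <- 0:(n - 1)
  w <- 2 * pi * pmin(k, n - k) / n            # digital frequency per FFT bin
  g <- butter_bp_gain(w, spec, sampling_rate)
  Re(stats::fft(stats::fft(series) * g, inverse = TRUE)) / n
}

# closed-form magnitude gain of the zero-phase (forward-backward) Butterworth
# band-pass at digital frequencies w (radians/sample), via the
# bilinear-transform prewarped analog prototype:
#   |H(w)|^2 = 1 / (1 + ((O^2 - O0^2) / (B O))^(2 * order)),  O = tan(w / 2)
butter_bp_gain <- function(w, spec, sampling_rate) {
  o1 <- tan(pi * spec$low_cut / sampling_rate)
  o2 <- tan(pi * spec$high_cut / sampling_rate)
  o0sq <- o1 * o2
  bw <- o2 - o1
  o <- tan(w / 2)
  x <- (o^2 - o0sq) / (bw * o)
  g2 <- 1 / (1 + x^(2 * spec$order))
  g2[!is.finite(x)] <- 0                       # DC (w = 0) and Nyquist
  g2
}

#' Designed filter gain at a frequency
#'
#' Magnitude response of the band-pass, squared when the filter is applied
#' zero-phase (forward and backward). Used as the independent check of what
#' [bandpass_filter()] passes and rejects.
#'
#' @param freq_hz frequency of interest.
#' @param sampling_rate Hz.
#' @param spec [bandpass_spec()].
#' @return scalar gain.
#' @export
bandpass_gain <- function(freq_hz, sampling_rate, spec = bandpass_spec()) {
  g2 <- butter_bp_gain(2 * pi * freq_hz / sampling_rate, spec, sampling_rate)
  if (spec$zero_phase) g2 else sqrt(g2)
}

#' Extract task-locked epochs
#'
#' Slices the HbO matrix into `[onset, onset + task_s)` windows (half-open,
#' onset sample included), one per trial event.
#'
#' @param recording a `session_recording`.
#' @param window_s two-element window in seconds relative to task onset;
#'   defaults to the full task period `c(0, task_s)`.
#' @return an `epoch_set`: list with `data`
#'   (trials x channels x window-samples array), `labels`, `sampling_rate`,
#'   `window_s`, `subject_id`, `session_index`.
#' @export
extract_epochs <- function(recording, window_s = NULL) {
  if (is.null(window_s)) window_s <- c(0, recording$task_s)
  fs <- recording$sampling_rate
  w0 <- as.integer(round(window_s[1] * fs))
  n_win <- as.integer(round((window_s[2] - window_s[1]) * fs))
  T_len <- ncol(recording$hbo)
  n_ch <- nrow(recording$hbo)
  ev <- recording$events
  ends <- ev$onset_sample + w0 + n_win     # 0-based, exclusive
  if (any(ends > T_len)) {
    bad <- which(ends > T_len)[1]
    stop(sprintf("epoch window of trial %d (onset sample %d) overruns the recording",
                 bad, ev$onset_sample[bad]))
  }
  dat <- array(0, dim = c(nrow(ev), n_ch, n_win))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$onset_sample[i] + w0 + seq_len(n_win)   # 1-based slice
    dat[i, , ] <- recording$hbo[, idx]
  }
  structure(list(data = dat, labels = ev$task, sampling_rate = fs,
                 window_s = window_s, subject_id = recording$subject_id,
                 session_index = recording$session_index),
            class = "epoch_set")
}

#' Subset an epoch set by task label
#'
#' @param epochs an `epoch_set`.
#' @param tasks labels to keep.
#' @return an `epoch_set` with only the matching trials.
#' @export
epochs_subset <- function(epochs, tasks) {
  keep <- epochs$labels %in% tasks
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$labels <- epochs$labels[keep]
  epochs
}

# concatenate epoch sets (same channel/window geometry) along trials
epochs_bind <- function(sets) {
  if (inherits(sets, "epoch_set")) return(sets)
  dat <- do.call(abind3, lapply(sets, `[[`, "data"))
  out <- sets[[1]]
  out$data <- dat
  out$labels <- unlist(lapply(sets, `[[`, "labels"), use.names = FALSE)
  out$session_index <- NA_integer_
  out
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Fit a per-channel min-max scaler
#'
#' Computes each channel's minimum and range over all training epochs. The
#' linear map `(x - min) / range` sends the training data to `[0, 1]`, the
#' range the Bernoulli visible units of the Boltzmann machine expect. A
#' zero-range (constant) channel is flagged degenerate and maps to 0.5.
#'
#' @param train_epochs an `epoch_set` or list of them (training sessions
#'   only; never fit on test data).
#' @return a `channel_scaler` with `offset`, `scale`, `degenerate` per channel.
#' @export
fit_scaler <- function(train_epochs) {
  ep <- epochs_bind(train_epochs)
  if (dim(ep$data)[1] == 0) stop("empty epoch set")
  n_ch <- dim(ep$data)[2]
  mins <- apply(ep$data, 2, min)
  maxs <- apply(ep$data, 2, max)
  structure(list(offset = mins, scale = maxs - mins,
                 degenerate = (maxs - mins) <= 0, n_channels = n_ch),
            class = "channel_scaler")
}

#' Apply a fitted scaler
#'
#' Applies the training-data linear map and clips to `[0, 1]`, so test values
#' outside the training range saturate rather than leaving the unit interval.
#'
#' @param scaler a `channel_scaler`.
#' @param epochs an `epoch_set`.
#' @return the normalized `epoch_set`.
#' @export
apply_scaler <- function(scaler, epochs) {
  if (dim(epochs$data)[2] != scaler$n_channels)
    stop("channel count does not match the fitted scaler")
  dat <- epochs$data
  for (ch in seq_len(scaler$n_channels)) {
    if (scaler$degenerate[ch]) {
      dat[, ch, ] <- 0.5
    } else {
      v <- (dat[, ch, ] - scaler$offset[ch]) / scaler$scale[ch]
      dat[, ch, ] <- pmin(1, pmax(0, v))
    }
  }
  epochs$data <- dat
  epochs
}

#' Assemble a two-class sample matrix
#'
#' Flattens normalized epochs of a left-arm task and a right-arm task of the
#' same paradigm into the classifier's currency: every time point of every
#' trial is one 16-dimensional sample. Left-arm tasks are labelled 0,
#' right-arm tasks 1. Rows of one trial stay contiguous and carry a trial
#' index so trial-level (majority-vote) scoring and trial-blocked
#' cross-validation remain possible.
#'
#' @param epochs_a,epochs_b `epoch_set`s (or lists of them) holding the two
#'   classes; each must contain exactly one task, both from the same paradigm
#'   (both execution or both imagery).
#' @return a `sample_matrix`: list with `x` (N x channels, in `[0,1]`),
#'   `y` (0/1), `trial_index`, `trial_labels`, `samples_per_trial`.
#' @export
assemble_samples <- function(epochs_a, epochs_b) {
  a <- epochs_bind(epochs_a)
  b <- epochs_bind(epochs_b)
  ta <- unique(a$labels); tb <- unique(b$labels)
  if (length(ta) != 1 || length(tb) != 1)
    stop("each input must contain exactly one task")
  if (task_paradigm(ta) != task_paradigm(tb))
    stop("cannot mix execution and imagery tasks in one problem")
  if (identical(sort(c(task_arm(ta), task_arm(tb))), c("L", "R")) == FALSE)
    stop("need one left-arm and one right-arm task")
  sets <- if (task_arm(ta) == "L") list(a, b) else list(b, a)
  xs <- list(); ys <- list(); tis <- list(); tls <- character(0)
  spt <- dim(a$data)[3]
  trial_at <- 0L
  for (ci in 1:2) {
    ep <- sets[[ci]]
    n_tr <- dim(ep$data)[1]
    # rows: time within trial, trials consecutive -> (n_tr*spt) x channels
    x <- matrix(aperm(ep$data, c(3, 1, 2)), nrow = n_tr * spt)
    xs[[ci]] <- x
    ys[[ci]] <- rep(ci - 1L, n_tr * spt)
    tis[[ci]] <- rep(trial_at + seq_len(n_tr), each = spt)
    tls <- c(tls, ep$labels)
    trial_at <- trial_at + n_tr
  }
  structure(list(x = do.call(rbind, xs),
                 y = unlist(ys, use.names = FALSE),
                 trial_index = unlist(tis, use.names = FALSE),
                 trial_labels = tls,
                 samples_per_trial = spt),
            class = "sample_matrix")
}
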