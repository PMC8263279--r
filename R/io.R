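#' Write a session recording to delimited text
#'
#' The channel file is a CSV with one row per time sample: 16 HbO columns
#' (`ch01_hbo`...) then 16 HbR columns. The events file is tab-separated with
#' `onset_seconds`, `duration_seconds`, `task_label`.
#'
#' @param recording a `session_recording`.
#' @param channel_file,events_file output paths.
#' @return invisibly, the two paths.
#' @export
write_recording <- function(recording, channel_file, events_file) {
  n_ch <- nrow(recording$hbo)
  mat <- cbind(t(recording$hbo), t(recording$hbr))
  colnames(mat) <- c(sprintf("ch%02d_hbo", seq_len(n_ch)),
                     sprintf("ch%02d_hbr", seq_len(n_ch)))
  utils::write.csv(as.data.frame(mat), channel_file, row.names = FALSE)
  ev <- data.frame(
    onset_seconds = recording$events$onset_sample / recording$sampling_rate,
    duration_seconds = recording$task_s,
    task_label = recording$events$task
  )
  utils::write.table(ev, events_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(channel_file, events_file))
}

#' Read a session recording from delimited text
#'
#' Inverse of [write_recording()]. Onset seconds are converted to 0-based
#' samples by rounding to the nearest sample. Validates monotone onsets, the
#' absence of non-finite values, and that every task window fits in the
#' recording.
#'
#' @param channel_file,events_file paths written by [write_recording()].
#' @param sampling_rate Hz.
#' @param subject_id,session_index optional metadata to attach.
#' @return a `session_recording`.
#' @export
read_recording <- function(channel_file, events_file, sampling_rate = 20,
                           subject_id = NA_character_,
                           session_index = NA_integer_) {
  mat <- as.matrix(utils::read.csv(channel_file))
  cn <- colnames(mat)
  hbo_cols <- grep("_hbo$", cn)
  hbr_cols <- grep("_hbr$", cn)
  if (length(hbo_cols) == 0)
    stop("channel file has no *_hbo columns")
  if (any(!is.finite(mat))) {
    bad <- which(rowSums(!is.finite(mat)) > 0)[1]
    stop(sprintf("non-finite value in channel file at row %d", bad))
  }
  ev <- utils::read.delim(events_file, stringsAsFactors = FALSE)
  need <- c("onset_seconds", "duration_seconds", "task_label")
  if (!all(need %in% names(ev)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  onset <- as.integer(round(ev$onset_seconds * sampling_rate))
  if (any(diff(onset) <= 0)) {
    bad <- which(diff(onset) <= 0)[1] + 1L
    stop(sprintf("event onsets not strictly increasing at row %d", bad))
  }
  task_s <- ev$duration_seconds[1]
  ends <- onset + as.integer(round(task_s * sampling_rate))
  if (any(ends > nrow(mat))) {
    bad <- which(ends > nrow(mat))[1]
    stop(sprintf("trial %d overruns the recording", bad))
  }
  rec <- list(hbo = t(mat[, hbo_cols, drop = FALSE]),
              hbr = t(mat[, hbr_cols, drop = FALSE]),
              sampling_rate = sampling_rate,
              events = data.frame(onset_sample = onset,
                                  task = ev$task_label,
                                  stringsAsFactors = FALSE),
              task_s = task_s,
              subject_id = subject_id,
              session_index = session_index)
  class(rec) <- "session_recording"
  rec
}

MODEL_CONTAINER_VERSION <- "fnirsdbn-model-1"

# doubles as decimal strings with 17 significant digits: guaranteed to parse
# back to the identical IEEE-754 value (JSON number emitters round)
num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(s) as.numeric(unlist(s))

#' Save a trained model to a self-describing JSON container
#'
#' Stores all DBN arrays, layer shapes, class labels, the scaler, the
#' configuration snapshot and the selected architecture at full floating
#' point precision, so a reloaded model reproduces predictions bitwise.
#'
#' @param model `dbn_model`.
#' @param scaler `channel_scaler` (or NULL).
#' @param config configuration snapshot to embed (any list; or NULL).
#' @param path output file.
#' @param history optional training history (selected sizes, seeds).
#' @return invisibly, `path`.
#' @export
save_model <- function(model, scaler = NULL, config = NULL, path,
                       history = NULL) {
  payload <- list(
    version = MODEL_CONTAINER_VERSION,
    class_labels = model$class_labels,
    shapes = list(m = nrow(model$rbm1$W), h1 = ncol(model$rbm1$W),
                  h2 = ncol(model$rbm2$W), c = nrow(model$softmax_w)),
    rbm1 = list(W = num_out(model$rbm1$W), a = num_out(model$rbm1$a),
                b = num_out(model$rbm1$b)),
    rbm2 = list(W = num_out(model$rbm2$W), a = num_out(model$rbm2$a),
                b = num_out(model$rbm2$b)),
    softmax_w = num_out(model$softmax_w),
    scaler = if (!is.null(scaler))
      list(offset = num_out(scaler$offset), scale = num_out(scaler$scale),
           degenerate = scaler$degenerate, n_channels = scaler$n_channels),
    config = config,
    selected = if (!is.null(history)) list(h1 = history$h1, h2 = history$h2),
    seeds = if (!is.null(history)) as.list(history$seeds)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a model container
#'
#' @param path file written by [save_model()].
#' @return list with `model`, `scaler`, `config`, `selected`, `seeds`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("cannot parse model container: ",
                             conditionMessage(e)))
  if (is.null(payload$version) ||
      !identical(payload$version, MODEL_CONTAINER_VERSION))
    stop("model container version mismatch: found ",
         if (is.null(payload$version)) "<none>" else payload$version,
         ", expected ", MODEL_CONTAINER_VERSION)
  sh <- payload$shapes
  as_mat <- function(x, nr, nc) matrix(num_in(x), nr, nc)
  rbm1 <- structure(list(W = as_mat(payload$rbm1$W, sh$m, sh$h1),
                         a = num_in(payload$rbm1$a),
                         b = num_in(payload$rbm1$b)),
                    class = "rbm_params")
  rbm2 <- structure(list(W = as_mat(payload$rbm2$W, sh$h1, sh$h2),
                         a = num_in(payload$rbm2$a),
                         b = num_in(payload$rbm2$b)),
                    class = "rbm_params")
  model <- dbn_model(rbm1, rbm2,
                     softmax_w = as_mat(payload$softmax_w, sh$c, sh$h2 + 1),
                     class_labels = as.character(payload$class_labels))
  scaler <- NULL
  if (!is.null(payload$scaler)) {
    scaler <- structure(list(offset = num_in(payload$scaler$offset),
                             scale = num_in(payload$scaler$scale),
                             degenerate = as.logical(payload$scaler$degenerate),
                             n_channels = as.integer(payload$scaler$n_channels)),
                        class = "channel_scaler")
  }
  list(model = model, scaler = scaler, config = payload$config,
       selected = payload$selected, seeds = payload$seeds)
}
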