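#' Score a model on labelled samples
#'
#' Argmax-class predictions at sample level, plus a trial-level accuracy by
#' majority vote over each trial's rows (ties go to class 0, the left-arm
#' class).
#'
#' @param model `dbn_model`.
#' @param samples a `sample_matrix`, or an N x m matrix (then `labels` and
#'   `trial_index` must be given).
#' @param labels,trial_index used when `samples` is a plain matrix.
#' @return an `accuracy_report`: list with `sample_accuracy` and
#'   `trial_accuracy` (percent), `n_samples`, `n_trials`, and a 2 x 2
#'   `confusion` matrix (true x predicted sample counts).
#' @export
score_model <- function(model, samples, labels = NULL, trial_index = NULL) {
  if (inherits(samples, "sample_matrix")) {
    x <- samples$x; y <- samples$y; ti <- samples$trial_index
  } else {
    x <- samples; y <- labels; ti <- trial_index
  }
  if (length(y) != nrow(x))
    stop("labels and samples are misaligned")
  if (!is.null(ti) && length(ti) != nrow(x))
    stop("trial_index and samples are misaligned")
  pred <- max.col(dbn_forward(model, x), ties.method = "first") - 1L
  sample_acc <- 100 * mean(pred == y)
  confusion <- table(factor(y, levels = 0:1), factor(pred, levels = 0:1))
  trial_acc <- NA_real_
  n_trials <- NA_integer_
  if (!is.null(ti)) {
    votes <- tapply(pred, ti, function(p) as.integer(mean(p) > 0.5))
    truth <- tapply(y, ti, function(v) v[1])
    trial_acc <- 100 * mean(votes == truth)
    n_trials <- length(votes)
  }
  structure(list(sample_accuracy = sample_acc, trial_accuracy = trial_acc,
                 n_samples = nrow(x), n_trials = n_trials,
                 confusion = unclass(confusion)),
            class = "accuracy_report")
}

#' Mean and population standard deviation of accuracies
#'
#' Aggregates per-subject accuracies the way published group tables are
#' formed: arithmetic mean and the divide-by-N (population) standard
#' deviation.
#'
#' @param values numeric accuracies (percent).
#' @return list with `mean` and `sd_pop`.
#' @export
accuracy_summary <- function(values) {
  if (length(values) < 1) stop("no values to summarize")
  m <- mean(values)
  list(mean = m, sd_pop = sqrt(mean((values - m)^2)))
}

#' Cross-subject transfer evaluation
#'
#' Applies every subject's trained model to every subject's held-out-session
#' test samples (each already normalized with its own subject's
#' training-data scaler) and records the sample-accuracy grid. Entry `[i, j]`
#' is the model of subject i scored on subject j's test set; the diagonal is
#' each subject's own result.
#'
#' @param models_by_subject named list of `dbn_model`s.
#' @param test_by_subject named list of `sample_matrix` test sets, same
#'   names/order.
#' @param arch optional data.frame with `h1`, `h2` per model (row
#'   annotation).
#' @return a `transfer_matrix`: list with `accuracy` (S x S matrix, percent)
#'   and `arch`.
#' @export
transfer_evaluate <- function(models_by_subject, test_by_subject,
                              arch = NULL) {
  subs <- names(models_by_subject)
  if (is.null(subs) || !identical(subs, names(test_by_subject)))
    stop("models and test sets must be named identically per subject")
  S <- length(subs)
  acc <- matrix(NA_real_, S, S, dimnames = list(model = subs, test = subs))
  for (i in seq_len(S))
    for (j in seq_len(S))
      acc[i, j] <- score_model(models_by_subject[[i]],
                               test_by_subject[[j]])$sample_accuracy
  structure(list(accuracy = acc, arch = arch), class = "transfer_matrix")
}

#' Published per-subject reference accuracies
#'
#' The per-subject classification accuracies (percent) reported by the
#' original 10-subject fNIRS arm-movement/imagery study, shipped as plain
#' text. Used to reproduce the group mean and population standard deviation.
#' Note the movement column's published mean (84.35) does not equal the mean
#' of its own ten entries (83.35); the imagery column is internally
#' consistent.
#'
#' @return data.frame with `subject`, `movement`, `imagery`.
#' @export
reference_accuracies <- function() {
  path <- system.file("extdata", "reference_accuracies.csv",
                      package = "fnirsdbn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
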