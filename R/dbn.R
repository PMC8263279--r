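#' Construct a DBN model container
#'
#' Two stacked RBMs (16 -> h1 -> h2) plus a softmax output layer whose weight
#' matrix carries an extra offset column.
#'
#' @param rbm1,rbm2 `rbm_params`.
#' @param softmax_w c x (h2 + 1) matrix (last column is the offset), or NULL
#'   for zeros.
#' @param class_labels ordered class labels (length c = 2).
#' @return a `dbn_model`.
#' @export
dbn_model <- function(rbm1, rbm2, softmax_w = NULL,
                      class_labels = c("0", "1")) {
  h2 <- ncol(rbm2$W)
  if (ncol(rbm1$W) != nrow(rbm2$W))
    stop("rbm1 hidden size must equal rbm2 visible size")
  if (is.null(softmax_w))
    softmax_w <- matrix(0, length(class_labels), h2 + 1)
  stopifnot(ncol(softmax_w) == h2 + 1)
  structure(list(rbm1 = rbm1, rbm2 = rbm2, softmax_w = softmax_w,
                 class_labels = class_labels),
            class = "dbn_model")
}

softmax_rows <- function(scores) {
  m <- scores[, 1]
  for (j in seq_len(ncol(scores))[-1]) m <- pmax(m, scores[, j])
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Deterministic forward pass
#'
#' Mean-field propagation: each layer passes its activation probabilities (no
#' sampling) to the next, and the top hidden vector (augmented with a
#' constant 1) feeds the softmax.
#'
#' @param model `dbn_model`.
#' @param x `[0,1]` feature vector, or an N x m matrix of rows.
#' @return N x c matrix of class probabilities (rows sum to 1).
#' @export
dbn_forward <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model$rbm1$W))
    stop("input dimension does not match the first layer")
  h1 <- hidden_probs(x, model$rbm1)
  h2 <- hidden_probs(h1, model$rbm2)
  p <- softmax_rows(tcrossprod(cbind(h2, 1), model$softmax_w))
  colnames(p) <- model$class_labels
  p
}

#' Softmax cross-entropy loss
#'
#' `J = -(1/M) sum_i log p_i(y_i)`. Probabilities below 1e-12 are clamped
#' (with a warning) so the loss stays finite.
#'
#' @param probabilities N x c matrix, rows summing to 1.
#' @param labels integer class indices in `0:(c-1)` (or a factor).
#' @return scalar loss.
#' @export
softmax_loss <- function(probabilities, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  idx <- cbind(seq_len(nrow(probabilities)), labels + 1L)
  p <- probabilities[idx]
  if (any(p < 1e-12)) {
    warning("probabilities at true labels clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

#' Greedy layer-wise pretraining
#'
#' Trains the first RBM on the raw samples and the second on the first's
#' hidden activation probabilities; labels are never seen.
#'
#' @param x N x m matrix in `[0, 1]`.
#' @param h1,h2 hidden layer sizes.
#' @param cd_config [cd_config()]; layer 2 uses a derived seed.
#' @return list with `rbm1`, `rbm2`, `history` (per-layer reconstruction
#'   error by epoch).
#' @export
pretrain_dbn <- function(x, h1, h2, cd_config = fnirsdbn::cd_config()) {
  r1 <- train_rbm(x, h1, cd_config)
  cfg2 <- cd_config
  cfg2$seed <- derive_seed(cd_config$seed, 7L)
  act1 <- hidden_probs(x, r1$params)
  r2 <- train_rbm(act1, h2, cfg2)
  list(rbm1 = r1$params, rbm2 = r2$params,
       history = list(layer1 = r1$history, layer2 = r2$history))
}

# ---- parameter flattening for fine-tuning -------------------------------

flatten_model <- function(model) {
  c(as.numeric(model$rbm1$W), model$rbm1$b,
    as.numeric(model$rbm2$W), model$rbm2$b,
    as.numeric(model$softmax_w))
}

unflatten_model <- function(theta, model) {
  m <- nrow(model$rbm1$W); n1 <- ncol(model$rbm1$W)
  n2 <- ncol(model$rbm2$W); cc <- nrow(model$softmax_w)
  at <- 0L
  take <- function(k) {
    out <- theta[at + seq_len(k)]; at <<- at + k; out
  }
  model$rbm1$W <- matrix(take(m * n1), m, n1)
  model$rbm1$b <- take(n1)
  model$rbm2$W <- matrix(take(n1 * n2), n1, n2)
  model$rbm2$b <- take(n2)
  model$softmax_w <- matrix(take(cc * (n2 + 1)), cc, n2 + 1)
  model
}

# loss and gradient of the full network on (x, y01)
dbn_loss_grad <- function(model, x, y01, want_grad = TRUE) {
  N <- nrow(x)
  h1 <- hidden_probs(x, model$rbm1)
  h2 <- hidden_probs(h1, model$rbm2)
  ha <- cbind(h2, 1)
  p <- softmax_rows(tcrossprod(ha, model$softmax_w))
  idx <- cbind(seq_len(N), y01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  if (!want_grad) return(list(loss = loss))
  Y <- matrix(0, N, ncol(p)); Y[idx] <- 1
  dz <- (p - Y) / N                               # N x c
  g_ws <- crossprod(dz, ha)                       # c x (h2+1)
  dh2 <- dz %*% model$softmax_w[, seq_len(ncol(h2)), drop = FALSE]
  da2 <- dh2 * h2 * (1 - h2)
  g_w2 <- crossprod(h1, da2)
  g_b2 <- colSums(da2)
  dh1 <- tcrossprod(da2, model$rbm2$W)
  da1 <- dh1 * h1 * (1 - h1)
  g_w1 <- crossprod(x, da1)
  g_b1 <- colSums(da1)
  list(loss = loss,
       grad = c(as.numeric(g_w1), g_b1, as.numeric(g_w2), g_b2,
                as.numeric(g_ws)))
}

#' Loss and analytic gradient of the fine-tuning objective
#'
#' Exposed for gradient verification: returns the softmax cross-entropy and
#' its exact gradient with respect to every fine-tuned parameter
#' (both sigmoid layers' weights/offsets and the softmax matrix), in
#' flattened order.
#'
#' @param model `dbn_model`.
#' @param x N x m matrix.
#' @param y01 integer labels 0/1.
#' @return list with `loss`, `grad`, and `theta` (the flattened parameters).
#' @export
finetune_objective <- function(model, x, y01) {
  r <- dbn_loss_grad(model, x, y01, want_grad = TRUE)
  r$theta <- flatten_model(model)
  r
}

# Polak-Ribiere conjugate gradient descent with backtracking line search and
# momentum blending of the accepted step; monotone by construction.
cg_descent <- function(theta, fn, gr, iters, momentum, init_step,
                       growth_tries = 3L) {
  if (iters <= 0) return(list(theta = theta, history = numeric(0)))
  f <- fn(theta)
  g <- gr(theta)
  d <- -g
  vel <- numeric(length(theta))
  t_prev <- init_step
  history <- numeric(iters)
  for (it in seq_len(iters)) {
    gd <- sum(g * d)
    if (!is.finite(gd) || gd >= 0) { d <- -g; gd <- -sum(g * g) }
    if (gd == 0) { history[it:iters] <- f; break }
    # backtracking Armijo search, starting just above the last accepted step
    t <- t_prev * 2
    f_new <- Inf
    for (ls in 1:30) {
      f_new <- fn(theta + t * d)
      if (is.finite(f_new) && f_new <= f + 1e-4 * t * gd) break
      t <- t / 2
    }
    if (!is.finite(f_new) || f_new > f + 1e-4 * t * gd) {
      history[it:iters] <- f
      break
    }
    # probe a few larger steps while they keep improving
    for (probe in seq_len(growth_tries)) {
      f_try <- fn(theta + 2 * t * d)
      if (is.finite(f_try) && f_try < f_new) {
        t <- 2 * t; f_new <- f_try
      } else break
    }
    step <- t * d
    blended <- momentum * vel + step
    f_bl <- fn(theta + blended)
    if (is.finite(f_bl) && f_bl <= f_new) {
      theta <- theta + blended; vel <- blended; f <- f_bl
    } else {
      theta <- theta + step; vel <- step; f <- f_new
    }
    t_prev <- t
    g_new <- gr(theta)
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    d <- -g_new + beta * d
    g <- g_new
    history[it] <- f
  }
  list(theta = theta, history = history)
}

#' Two-phase supervised fine-tuning
#'
#' Phase 1 minimizes the softmax cross-entropy over the output weights only,
#' with the pretrained features frozen (the RBM layers are untouched,
#' bitwise). Phase 2 backpropagates through both sigmoid layers and updates
#' every parameter. Both phases use Polak-Ribiere conjugate gradients with a
#' backtracking line search; the previous accepted step is momentum-blended
#' into each candidate step and kept only when it does not increase the
#' training loss, so the recorded loss history never rises.
#'
#' @param model pretrained `dbn_model`.
#' @param samples a `sample_matrix`, or an N x m matrix (then `labels` must
#'   be given).
#' @param labels integer 0/1 labels (ignored when `samples` is a
#'   `sample_matrix`).
#' @param config [finetune_config()].
#' @param phase1_iters,phase2_iters optional overrides of the configured
#'   schedule (used by cross-validated selection).
#' @return list with the fine-tuned `model` and `history`
#'   (`phase1`/`phase2` loss per iteration).
#' @export
finetune_dbn <- function(model, samples, labels = NULL,
                         config = finetune_config(),
                         phase1_iters = NULL, phase2_iters = NULL) {
  if (inherits(samples, "sample_matrix")) {
    x <- samples$x; y01 <- samples$y
  } else {
    x <- samples; y01 <- labels
  }
  if (is.null(y01)) stop("labels are required")
  if (!all(y01 %in% c(0L, 1L))) stop("unknown label; expected 0/1")
  p1 <- if (is.null(phase1_iters)) config$phase1_iters else phase1_iters
  p2 <- if (is.null(phase2_iters)) config$phase2_iters else phase2_iters

  # phase 1: softmax weights only, features precomputed once
  h1 <- hidden_probs(x, model$rbm1)
  h2 <- hidden_probs(h1, model$rbm2)
  ha <- cbind(h2, 1)
  cc <- nrow(model$softmax_w); hw <- ncol(model$softmax_w)
  idx <- cbind(seq_len(nrow(x)), y01 + 1L)
  fn1 <- function(w) {
    p <- softmax_rows(tcrossprod(ha, matrix(w, cc, hw)))
    -mean(log(pmax(p[idx], 1e-12)))
  }
  gr1 <- function(w) {
    p <- softmax_rows(tcrossprod(ha, matrix(w, cc, hw)))
    Y <- matrix(0, nrow(x), cc); Y[idx] <- 1
    as.numeric(crossprod((p - Y) / nrow(x), ha))
  }
  r1 <- cg_descent(as.numeric(model$softmax_w), fn1, gr1, p1,
                   config$momentum, config$learning_rate,
                   config$cg_line_searches)
  model$softmax_w <- matrix(r1$theta, cc, hw)

  # phase 2: the whole network
  hist2 <- numeric(0)
  if (p2 > 0) {
    fn2 <- function(th) dbn_loss_grad(unflatten_model(th, model), x, y01,
                                      want_grad = FALSE)$loss
    gr2 <- function(th) dbn_loss_grad(unflatten_model(th, model), x, y01,
                                      want_grad = TRUE)$grad
    r2 <- cg_descent(flatten_model(model), fn2, gr2, p2,
                     config$momentum, config$learning_rate,
                     config$cg_line_searches)
    model <- unflatten_model(r2$theta, model)
    hist2 <- r2$history
  }
  list(model = model, history = list(phase1 = r1$history, phase2 = hist2))
}

# deterministic trial-blocked fold assignment, stratified by class:
# within each class, trials alternate folds in order of appearance
trial_folds <- function(trial_index, y, n_folds) {
  trials <- unique(trial_index)
  t_y <- y[match(trials, trial_index)]
  fold <- integer(length(trials))
  for (cl in unique(t_y)) {
    rows <- which(t_y == cl)
    fold[rows] <- ((seq_along(rows) - 1L) %% n_folds) + 1L
  }
  fold[match(trial_index, trials)]
}

#' Cross-validated hidden-layer size selection
#'
#' Evaluates every `(h1, h2)` pair of the grid by trial-blocked k-fold
#' cross-validation on the training set (all 160 rows of a trial stay in one
#' fold). To keep selection affordable the folds use a shortened schedule
#' (`cv_*` iterations of [finetune_config()], 5 pretraining epochs), and the
#' first-layer RBM is shared across pairs with equal `h1` within a fold.
#' Ties are broken toward the smaller `h1 + h2`, then the smaller `h1`.
#'
#' @param samples a `sample_matrix` (training data only).
#' @param grid [arch_grid()].
#' @param cd_cfg [cd_config()].
#' @param ft_cfg [finetune_config()].
#' @return list with `h1`, `h2` and `cv_table`
#'   (data.frame h1, h2, accuracy).
#' @export
select_architecture <- function(samples, grid = arch_grid(),
                                cd_cfg = cd_config(),
                                ft_cfg = finetune_config()) {
  x <- samples$x; y <- samples$y
  n_trials <- length(unique(samples$trial_index))
  if (n_trials < grid$n_folds)
    stop("fewer trials than folds")
  if (min(table(y[!duplicated(samples$trial_index)])) < 1)
    stop("need at least one trial per class")
  fold_of <- trial_folds(samples$trial_index, y, grid$n_folds)
  pairs <- expand.grid(h1 = grid$candidates, h2 = grid$candidates)
  acc <- matrix(0, nrow(pairs), grid$n_folds)
  cv_cd <- cd_cfg
  cv_cd$epochs <- min(cd_cfg$epochs, 5L)
  for (f in seq_len(grid$n_folds)) {
    tr <- fold_of != f
    x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
    x_va <- x[!tr, , drop = FALSE]; y_va <- y[!tr]
    # first-layer RBMs depend only on h1: train each once per fold
    rbm1_by_h1 <- list()
    for (h1 in unique(grid$candidates)) {
      cfg <- cv_cd; cfg$seed <- derive_seed(cd_cfg$seed, h1, f)
      r1 <- train_rbm(x_tr, h1, cfg)
      rbm1_by_h1[[as.character(h1)]] <-
        list(params = r1$params, act = hidden_probs(x_tr, r1$params))
    }
    for (pi in seq_len(nrow(pairs))) {
      h1 <- pairs$h1[pi]; h2 <- pairs$h2[pi]
      l1 <- rbm1_by_h1[[as.character(h1)]]
      cfg2 <- cv_cd; cfg2$seed <- derive_seed(cd_cfg$seed, h1 * 100L + h2, f)
      r2 <- train_rbm(l1$act, h2, cfg2)
      mdl <- dbn_model(l1$params, r2$params)
      ft <- finetune_dbn(mdl, x_tr, y_tr, ft_cfg,
                         phase1_iters = ft_cfg$cv_phase1_iters,
                         phase2_iters = ft_cfg$cv_phase2_iters)
      pred <- max.col(dbn_forward(ft$model, x_va), ties.method = "first") - 1L
      acc[pi, f] <- mean(pred == y_va)
    }
  }
  cv_table <- data.frame(h1 = pairs$h1, h2 = pairs$h2,
                         accuracy = rowMeans(acc))
  ord <- order(-cv_table$accuracy, cv_table$h1 + cv_table$h2, cv_table$h1)
  list(h1 = cv_table$h1[ord[1]], h2 = cv_table$h2[ord[1]],
       cv_table = cv_table)
}

#' Full DBN training: selection, pretraining, fine-tuning
#'
#' Selects `(h1, h2)` by [select_architecture()], greedily pretrains both
#' RBMs on the full training set, then fine-tunes in two phases. All seeds
#' derive from `cd_cfg$seed` and are recorded in the history.
#'
#' @param samples a `sample_matrix` (training data).
#' @param grid [arch_grid()]; pass a single-pair grid to skip searching.
#' @param cd_cfg [cd_config()].
#' @param ft_cfg [finetune_config()].
#' @param class_labels labels attached to the softmax outputs, in the order
#'   (left = 0, right = 1).
#' @return list with `model` (a `dbn_model`) and `history` (selected sizes,
#'   cv table, pretraining errors, fine-tuning loss, seeds).
#' @export
train_dbn <- function(samples, grid = arch_grid(), cd_cfg = cd_config(),
                      ft_cfg = finetune_config(),
                      class_labels = c("left", "right")) {
  sel <- if (length(grid$candidates) > 1)
    select_architecture(samples, grid, cd_cfg, ft_cfg)
  else
    list(h1 = grid$candidates[1], h2 = grid$candidates[1], cv_table = NULL)
  pre <- pretrain_dbn(samples$x, sel$h1, sel$h2, cd_cfg)
  model <- dbn_model(pre$rbm1, pre$rbm2, class_labels = class_labels)
  ft <- finetune_dbn(model, samples, config = ft_cfg)
  list(model = ft$model,
       history = list(h1 = sel$h1, h2 = sel$h2, cv_table = sel$cv_table,
                      pretrain = pre$history, finetune = ft$history,
                      seeds = c(cd = cd_cfg$seed, ft = ft_cfg$seed)))
}
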