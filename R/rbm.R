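#' Initialize RBM parameters
#'
#' Weights drawn from N(0, init_sigma^2), offsets zero.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param init_sigma sd of the weight initialization.
#' @param seed RNG seed.
#' @return an `rbm_params` list with `W` (m x n), `a` (m), `b` (n).
#' @export
rbm_params <- function(n_visible, n_hidden, init_sigma = 0.01, seed = 1L) {
  stopifnot(n_visible >= 1, n_hidden >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structure(list(W = matrix(stats::rnorm(n_visible * n_hidden, 0, init_sigma),
                            n_visible, n_hidden),
                 a = numeric(n_visible),
                 b = numeric(n_hidden)),
            class = "rbm_params")
}

#' RBM energy
#'
#' `E(v, h) = -a'v - b'h - v'Wh`, the energy whose Boltzmann distribution the
#' machine defines.
#'
#' @param v visible vector (length m).
#' @param h hidden vector (length n).
#' @param params `rbm_params`.
#' @return scalar energy.
#' @export
rbm_energy <- function(v, h, params) {
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W))
    stop("v/h lengths do not match the parameter shapes")
  -sum(params$a * v) - sum(params$b * h) - drop(v %*% params$W %*% h)
}

#' Hidden-unit activation probabilities
#'
#' `P(h_j = 1 | v) = sigmoid(b_j + v'W[, j])`; conditionally independent
#' across hidden units given the visible state.
#'
#' @param v visible vector, or an N x m matrix of rows.
#' @param params `rbm_params`.
#' @return vector of n probabilities, or an N x n matrix.
#' @export
hidden_probs <- function(v, params) {
  if (is.matrix(v)) {
    z <- v %*% params$W
    sigmoid(z + rep(params$b, each = nrow(z)))
  } else {
    sigmoid(params$b + drop(v %*% params$W))
  }
}

# logistic function on the log-odds scale; plain form is faster than plogis
# and exp() underflow at large |x| saturates to exactly 0/1, which is fine
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Visible-unit activation probabilities
#'
#' `P(v_i = 1 | h) = sigmoid(a_i + W[i, ]'h)`, the mirror of [hidden_probs()]
#' under the bipartite symmetry of the machine.
#'
#' @param h hidden vector, or an N x n matrix of rows.
#' @param params `rbm_params`.
#' @return vector of m probabilities, or an N x m matrix.
#' @export
visible_probs <- function(h, params) {
  if (is.matrix(h)) {
    z <- tcrossprod(h, params$W)
    sigmoid(z + rep(params$a, each = nrow(z)))
  } else {
    sigmoid(params$a + drop(params$W %*% h))
  }
}

# all binary vectors of length m as a (2^m) x m matrix
enumerate_states <- function(m) {
  if (m == 0) return(matrix(0, 1, 0))
  g <- as.matrix(expand.grid(rep(list(0:1), m)))
  dimnames(g) <- NULL
  g
}

#' Exact marginal distribution over visible states
#'
#' Product-of-experts form: `P(v) = exp(a'v) prod_j (1 + exp(b_j + v'W[, j])) / Z`
#' with the partition function computed by full enumeration. Only feasible for
#' tiny models; used as an oracle for the sampling-based training.
#'
#' @param params `rbm_params` with `m + n <= 16`.
#' @return list with `states` (2^m x m matrix) and `prob` (vector summing
#'   to 1).
#' @export
exact_marginal <- function(params) {
  m <- nrow(params$W); n <- ncol(params$W)
  if (m + n > 16) stop("model too large for exact enumeration (m + n > 16)")
  V <- enumerate_states(m)
  act <- sweep(V %*% params$W, 2, params$b, `+`)     # 2^m x n
  # stable log(1 + exp(act))
  softplus <- pmax(act, 0) + log1p(exp(-abs(act)))
  logp <- drop(V %*% params$a) + rowSums(softplus)
  logZ <- log(sum(exp(logp - max(logp)))) + max(logp)
  list(states = V, prob = exp(logp - logZ))
}

# zero velocity container matching params
zero_velocities <- function(params) {
  list(W = params$W * 0, a = params$a * 0, b = params$b * 0)
}

#' One contrastive-divergence (CD-k) parameter update
#'
#' Positive statistics use the hidden activation probabilities of the data;
#' the negative (reconstruction) chain starts from a binary sample of those
#' probabilities and runs k Gibbs half-step pairs, with reconstruction
#' statistics taken on probabilities. Updates are
#' `dW = eps * (<v h>_data - <v h>_recon)` (and the analogous offset rules),
#' blended through momentum velocities. Batch rows are put in a canonical
#' (lexicographic) order before any sampling, so the update does not depend
#' on row order within the batch.
#'
#' @param batch B x m matrix of rows in `[0, 1]`.
#' @param params `rbm_params`.
#' @param velocities momentum state (as returned, or NULL to start at zero).
#' @param config [cd_config()].
#' @return list with updated `params`, `velocities`, and the batch mean
#'   squared `recon_error`.
#' @export
cd_step <- function(batch, params, velocities = NULL, config = cd_config()) {
  if (!is.matrix(batch) || nrow(batch) == 0) stop("empty batch")
  if (is.null(velocities)) velocities <- zero_velocities(params)
  B <- nrow(batch)
  ord <- do.call(order, lapply(seq_len(ncol(batch)), function(j) batch[, j]))
  batch <- batch[ord, , drop = FALSE]

  ph_data <- hidden_probs(batch, params)
  h_cur <- (matrix(stats::runif(length(ph_data)), nrow(ph_data)) < ph_data) * 1
  for (step in seq_len(config$cd_steps)) {
    v_prob <- visible_probs(h_cur, params)
    ph_cur <- hidden_probs(v_prob, params)
    if (step < config$cd_steps)
      h_cur <- (matrix(stats::runif(length(ph_cur)), nrow(ph_cur)) < ph_cur) * 1
  }

  eps <- config$learning_rate
  dW <- eps * (crossprod(batch, ph_data) - crossprod(v_prob, ph_cur)) / B
  da <- eps * (colMeans(batch) - colMeans(v_prob))
  db <- eps * (colMeans(ph_data) - colMeans(ph_cur))

  velocities$W <- config$momentum * velocities$W + dW
  velocities$a <- config$momentum * velocities$a + da
  velocities$b <- config$momentum * velocities$b + db
  params$W <- params$W + velocities$W
  params$a <- params$a + velocities$a
  params$b <- params$b + velocities$b

  list(params = params, velocities = velocities,
       recon_error = mean((batch - v_prob)^2))
}

#' Train one RBM by CD
#'
#' Runs `config$epochs` full passes in shuffled mini-batches, deterministic
#' given `config$seed`. With `batch_size >= N` the single batch makes the
#' result independent of sample order.
#'
#' @param data N x m matrix in `[0, 1]`.
#' @param n_hidden hidden layer size.
#' @param config [cd_config()].
#' @return list with `params` and `history` (mean reconstruction error per
#'   epoch).
#' @export
train_rbm <- function(data, n_hidden, config = cd_config()) {
  if (n_hidden < 1) stop("n_hidden must be at least 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- list(W = matrix(stats::rnorm(ncol(data) * n_hidden, 0,
                                         config$init_sigma),
                            ncol(data), n_hidden),
                 a = numeric(ncol(data)),
                 b = numeric(n_hidden))
  class(params) <- "rbm_params"
  vel <- zero_velocities(params)
  N <- nrow(data)
  history <- numeric(config$epochs)
  full_batch <- config$batch_size >= N
  for (ep in seq_len(config$epochs)) {
    idx <- if (full_batch) seq_len(N) else sample(N)
    starts <- seq(1, N, by = config$batch_size)
    errs <- numeric(length(starts))
    for (k in seq_along(starts)) {
      rows <- idx[starts[k]:min(starts[k] + config$batch_size - 1L, N)]
      res <- cd_step(data[rows, , drop = FALSE], params, vel, config)
      params <- res$params; vel <- res$velocities
      errs[k] <- res$recon_error
    }
    history[ep] <- mean(errs)
  }
  list(params = params, history = history)
}
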