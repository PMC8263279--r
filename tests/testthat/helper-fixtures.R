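# Small fixtures shared across test files. Everything is generated in code.

# a uniform-gain subject profile for symmetry checks
flat_profile <- function(config, peak_jitter = 1) {
  p <- subject_profile(config, 1)
  p$channel_gains[] <- 1
  p$amplitude_scale <- 1
  p$hrf_params <- config$hrf_params
  p
}

# tiny simulation config: quick sessions, deterministic
tiny_sim <- function(..., trials = 2L, sessions = 2L, seed = 42L) {
  sim_config(n_subjects = 1, n_sessions = sessions,
             trials_per_task_per_session = trials, seed = seed, ...)
}

noise_off <- function() {
  ns <- default_noise_spec()
  ns$amplitudes[] <- 0
  ns$white_sigma <- 0
  ns
}

# epoch_set built directly from an array (bypasses simulation)
make_epochs <- function(data, labels, fs = 20) {
  structure(list(data = data, labels = labels, sampling_rate = fs,
                 window_s = c(0, dim(data)[3] / fs), subject_id = "S1",
                 session_index = 1L),
            class = "epoch_set")
}

# sample_matrix with n_tr trials per class of spt rows each, given a
# deterministic class offset on the first feature
toy_samples <- function(n_tr = 4, spt = 10, m = 16, sep = 1, seed = 7) {
  set.seed(seed)
  n <- 2 * n_tr * spt
  x <- matrix(runif(n * m), n, m)
  y <- rep(c(0L, 1L), each = n_tr * spt)
  x[, 1] <- pmin(1, pmax(0, 0.5 + (y - 0.5) * sep + rnorm(n, 0, 0.05)))
  structure(list(x = x, y = y,
                 trial_index = rep(seq_len(2 * n_tr), each = spt),
                 trial_labels = rep(c("L-FE_MI", "R-FE_MI"), each = n_tr),
                 samples_per_trial = spt),
            class = "sample_matrix")
}

# random tiny RBM for enumeration oracles
random_rbm <- function(m, n, sd = 0.8, seed = 1) {
  set.seed(seed)
  structure(list(W = matrix(rnorm(m * n, 0, sd), m, n),
                 a = rnorm(m, 0, sd), b = rnorm(n, 0, sd)),
            class = "rbm_params")
}

# brute-force joint distribution over (v, h) from the energy function
brute_force_joint <- function(params) {
  m <- nrow(params$W); n <- ncol(params$W)
  V <- as.matrix(expand.grid(rep(list(0:1), m)))
  H <- as.matrix(expand.grid(rep(list(0:1), n)))
  E <- matrix(0, nrow(V), nrow(H))
  for (i in seq_len(nrow(V)))
    for (j in seq_len(nrow(H)))
      E[i, j] <- rbm_energy(V[i, ], H[j, ], params)
  P <- exp(-E)
  list(V = V, H = H, prob = P / sum(P))
}

# exact log-likelihood gradient of a batch under the tiny-model marginal
exact_loglik_grad <- function(batch, params) {
  marg <- exact_marginal(params)
  ph_data <- hidden_probs(batch, params)
  pos_W <- crossprod(batch, ph_data) / nrow(batch)
  pos_a <- colMeans(batch)
  pos_b <- colMeans(ph_data)
  ph_all <- hidden_probs(marg$states, params)
  w <- marg$prob
  neg_W <- crossprod(marg$states * w, ph_all)
  neg_a <- colSums(marg$states * w)
  neg_b <- colSums(ph_all * w)
  list(W = pos_W - neg_W, a = pos_a - neg_a, b = pos_b - neg_b)
}

# rebuild a model from a flattened parameter vector (internal layout)
unflatten_for_test <- function(theta, model) {
  fnirsdbn:::unflatten_model(theta, model)
}
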