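test_that("forward pass is a valid distribution with softmax invariances", {
  m <- dbn_model(random_rbm(16, 3, seed = 1), random_rbm(3, 2, seed = 2),
                 softmax_w = matrix(rnorm(6), 2, 3))
  X <- matrix(runif(5 * 16), 5, 16)
  p <- dbn_forward(m, X)
  expect_equal(rowSums(p), rep(1, 5))
  expect_true(all(p >= 0 & p <= 1))
  # all-zero parameters -> uniform output
  m0 <- dbn_model(structure(list(W = matrix(0, 16, 3), a = numeric(16),
                                 b = numeric(3)), class = "rbm_params"),
                  structure(list(W = matrix(0, 3, 2), a = numeric(3),
                                 b = numeric(2)), class = "rbm_params"))
  expect_equal(unname(dbn_forward(m0, X[1, ])), matrix(0.5, 1, 2))
  # shifting every softmax row by a constant vector changes nothing
  m2 <- m
  m2$softmax_w <- m$softmax_w + matrix(rep(c(3.2, -1.1, 0.7), each = 2), 2, 3)
  expect_equal(dbn_forward(m2, X), dbn_forward(m, X))
  # hand-set tiny chain against scalar arithmetic
  mh <- dbn_model(
    structure(list(W = matrix(c(0.5, -0.2), 1, 2), a = 0,
                   b = c(0.1, -0.3)), class = "rbm_params"),
    structure(list(W = matrix(c(1, -1, 0.5, 0.25), 2, 2), a = numeric(2),
                   b = c(0, 0.2)), class = "rbm_params"),
    softmax_w = matrix(c(0.3, -0.3, 1, 0, 0.1, -0.1), 2, 3))
  x <- 0.8
  h1 <- 1 / (1 + exp(-(mh$rbm1$b + x * c(0.5, -0.2))))
  h2 <- 1 / (1 + exp(-(mh$rbm2$b + drop(h1 %*% mh$rbm2$W))))
  z <- drop(mh$softmax_w %*% c(h2, 1))
  expect_equal(unname(dbn_forward(mh, x)[1, ]), exp(z) / sum(exp(z)))
  expect_error(dbn_forward(m, matrix(0, 1, 4)), "dimension")
})

test_that("softmax loss matches hand-computed cross-entropies", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(softmax_loss(perfect, c(0L, 1L)), 0)
  unif <- matrix(0.5, 4, 2)
  expect_equal(softmax_loss(unif, c(0L, 1L, 0L, 1L)), log(2))
  p <- rbind(c(0.9, 0.1), c(0.3, 0.7), c(0.6, 0.4))
  y <- c(0L, 1L, 1L)
  expect_equal(softmax_loss(p, y), -(log(0.9) + log(0.7) + log(0.4)) / 3)
  expect_warning(softmax_loss(rbind(c(1, 0)), 1L), "clamped")
})

test_that("greedy pretraining stacks on first-layer activations without label access", {
  s <- toy_samples(n_tr = 3, spt = 8)
  cfg <- cd_config(epochs = 3, seed = 5)
  pre <- pretrain_dbn(s$x, 4, 3, cfg)
  expect_equal(dim(pre$rbm1$W), c(16, 4))
  expect_equal(dim(pre$rbm2$W), c(4, 3))
  expect_length(pre$history$layer1, 3)
  # oracle: retrain layer 2 on recomputed layer-1 activations -> identical
  act <- hidden_probs(s$x, pre$rbm1)
  cfg2 <- cfg; cfg2$seed <- derive_seed(cfg$seed, 7L)
  r2 <- train_rbm(act, 3, cfg2)
  expect_identical(pre$rbm2$W, r2$params$W)
  expect_identical(pre$rbm2$b, r2$params$b)
  # degenerate 16 -> 1 -> 1 stack still runs
  pre1 <- pretrain_dbn(s$x, 1, 1, cfg)
  expect_equal(dim(pre1$rbm2$W), c(1, 1))
  # full-batch pretraining ignores row order (unsupervised; no label input)
  cfgf <- cd_config(epochs = 2, batch_size = nrow(s$x), seed = 5)
  a <- pretrain_dbn(s$x, 3, 2, cfgf)
  b <- pretrain_dbn(s$x[rev(seq_len(nrow(s$x))), ], 3, 2, cfgf)
  expect_identical(a$rbm1$W, b$rbm1$W)
  expect_identical(a$rbm2$W, b$rbm2$W)
})

test_that("phase-1 fine-tuning touches only the softmax layer and reduces the loss", {
  s <- toy_samples(n_tr = 4, spt = 10, sep = 0.6)
  pre <- pretrain_dbn(s$x, 4, 3, cd_config(epochs = 2, seed = 3))
  model <- dbn_model(pre$rbm1, pre$rbm2)
  ft <- finetune_dbn(model, s, config = finetune_config(phase1_iters = 10,
                                                        phase2_iters = 0))
  expect_identical(ft$model$rbm1, model$rbm1)   # bitwise
  expect_identical(ft$model$rbm2, model$rbm2)
  expect_false(identical(ft$model$softmax_w, model$softmax_w))
  h <- ft$history$phase1
  expect_lte(h[length(h)], log(2) + 1e-12)      # from the 0-parameter start
  expect_true(all(diff(h) <= 1e-12))            # non-increasing
  expect_error(finetune_dbn(model, s$x, c(s$y[-1], 7L)), "label")
})

test_that("analytic fine-tuning gradient matches central finite differences", {
  set.seed(11)
  x <- matrix(runif(30 * 5), 30, 5)
  y <- rep(c(0L, 1L), 15)
  r1 <- random_rbm(5, 4, sd = 0.4, seed = 12)
  r2 <- random_rbm(4, 3, sd = 0.4, seed = 13)
  model <- dbn_model(r1, r2, softmax_w = matrix(rnorm(8, 0, 0.3), 2, 4))
  obj <- finetune_objective(model, x, y)
  eps <- 1e-5
  num <- vapply(seq_along(obj$theta), function(i) {
    tp <- obj$theta; tp[i] <- tp[i] + eps
    tm <- obj$theta; tm[i] <- tm[i] - eps
    fp <- finetune_objective(unflatten_for_test(tp, model), x, y)$loss
    fm <- finetune_objective(unflatten_for_test(tm, model), x, y)$loss
    (fp - fm) / (2 * eps)
  }, 0)
  rel <- sqrt(sum((num - obj$grad)^2)) / sqrt(sum(num^2))
  expect_lt(rel, 1e-5)
})

test_that("full fine-tuning separates a linearly separable toy problem", {
  s <- toy_samples(n_tr = 4, spt = 12, sep = 0.9, seed = 21)
  pre <- pretrain_dbn(s$x, 6, 4, cd_config(epochs = 5, seed = 9))
  model <- dbn_model(pre$rbm1, pre$rbm2)
  ft <- finetune_dbn(model, s, config = finetune_config(phase1_iters = 20,
                                                        phase2_iters = 40))
  pred <- max.col(dbn_forward(ft$model, s$x), ties.method = "first") - 1L
  expect_equal(mean(pred == s$y), 1)            # 100% training accuracy
  # J_final <= J_initial on training data
  all_h <- c(ft$history$phase1, ft$history$phase2)
  expect_lte(all_h[length(all_h)], log(2))
  expect_true(all(diff(ft$history$phase2) <= 1e-12))
})

test_that("class relabeling with swapped softmax rows yields mirrored predictions", {
  s <- toy_samples(n_tr = 3, spt = 8, sep = 0.5, seed = 31)
  pre <- pretrain_dbn(s$x, 3, 3, cd_config(epochs = 2, seed = 2))
  model <- dbn_model(pre$rbm1, pre$rbm2,
                     softmax_w = matrix(rnorm(8), 2, 4))
  swapped <- model
  swapped$softmax_w <- model$softmax_w[2:1, ]
  p1 <- dbn_forward(model, s$x)
  p2 <- dbn_forward(swapped, s$x)
  expect_equal(unname(p1), unname(p2[, 2:1]))
})

test_that("architecture selection searches the grid with stable tie-breaking", {
  s <- toy_samples(n_tr = 6, spt = 10, sep = 0.7, seed = 41)
  cd <- cd_config(epochs = 2, seed = 4)
  ft <- finetune_config(cv_phase1_iters = 10, cv_phase2_iters = 0)
  g <- arch_grid(candidates = c(2L, 4L))
  sel <- select_architecture(s, g, cd, ft)
  expect_equal(nrow(sel$cv_table), 4)           # Cartesian product
  expect_true(sel$h1 %in% c(2, 4) && sel$h2 %in% c(2, 4))
  # duplicating the winning candidate does not change the selection
  g2 <- arch_grid(candidates = c(2L, 4L, sel$h1))
  sel2 <- select_architecture(s, g2, cd, ft)
  expect_equal(c(sel2$h1, sel2$h2), c(sel$h1, sel$h2))
  # fewer trials than folds errors
  s1 <- toy_samples(n_tr = 1, spt = 4)
  s1$trial_index <- rep(1L, nrow(s1$x))
  expect_error(select_architecture(s1, g, cd, ft), "folds")
})

test_that("train_dbn is deterministic and beats chance on separable data", {
  s <- toy_samples(n_tr = 5, spt = 10, sep = 0.8, seed = 51)
  cd <- cd_config(epochs = 3, seed = 6)
  ftc <- finetune_config(phase1_iters = 10, phase2_iters = 10,
                         cv_phase1_iters = 5)
  g <- arch_grid(candidates = c(3L, 5L))
  f1 <- train_dbn(s, g, cd, ftc)
  f2 <- train_dbn(s, g, cd, ftc)
  expect_identical(f1$model$rbm1$W, f2$model$rbm1$W)
  expect_identical(f1$model$softmax_w, f2$model$softmax_w)
  expect_equal(f1$history$h1, f2$history$h1)
  # history bookkeeping: epochs entries per pretrained layer
  expect_length(f1$history$pretrain$layer1, cd$epochs)
  expect_length(f1$history$pretrain$layer2, cd$epochs)
  # training accuracy above 50% + 3 binomial sigmas
  pred <- max.col(dbn_forward(f1$model, s$x), ties.method = "first") - 1L
  n <- length(pred)
  expect_gt(mean(pred == s$y), 0.5 + 3 * sqrt(0.25 / n))
})
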