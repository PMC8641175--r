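# Small architecture used where full-size encoders would be wasteful.
toy_model_config <- function()
  model_config(m = 16, n = 6, T_steps = 3, conv_filters = c(4, 6, 8, 8, 10, 12),
               se_reduction = 2, lstm_units = 4, dense_sizes = c(6, 4),
               dropout_rate = 0)

test_that("configs validate their fields", {
  expect_equal(model_config()$F, 160L)
  expect_equal(model_config()$m, 200L)
  expect_equal(model_config()$n, 18L)
  expect_equal(model_config()$T_steps, 100L)
  expect_error(model_config(dropout_rate = 1), "dropout")
  expect_error(model_config(conv_filters = c(8, 16)), "conv_filters")
  expect_equal(training_config()$patience, 10L)
  expect_equal(training_config()$loss_a, 0.001)
  expect_equal(training_config()$learning_rate, 0.001)
  expect_error(training_config(loss_a = 0), "loss_a")
})

test_that("encoder maps a window to an F-length vector; zeros stay zero", {
  model <- init_model(model_config(), seed = 1)
  v <- encode_window(model, matrix(0L, 18, 200))
  expect_length(v, 160L)
  expect_true(all(v == 0))   # conv/pool of zeros with zero bias, ReLU(0)=0
  set.seed(2)
  v2 <- encode_window(model, matrix(rbinom(3600, 1, 0.2), 18, 200))
  expect_true(any(v2 != 0))
  expect_error(encode_window(model, matrix(0, 5, 200)), "shape")
})

test_that("3x3 convolution computes sliding weighted sums with zero padding", {
  # single channel, kernel of ones: interior output = sum of 3x3 patch
  h <- 4; w <- 5
  set.seed(3)
  X <- matrix(rnorm(h * w), h, w)
  W <- matrix(1, 9, 1)
  y <- conv3_fwd_cpp(matrix(as.vector(X), ncol = 1), h, w, 1L, W, 0)
  ymat <- matrix(y, h, w)
  Xp <- rbind(0, cbind(0, X, 0), 0)
  for (i in 1:h) for (j in 1:w)
    expect_equal(ymat[i, j], sum(Xp[i:(i + 2), j:(j + 2)]), tolerance = 1e-12)
})

test_that("classifier outputs are probabilities and deterministic in inference", {
  cfg <- toy_model_config()
  model <- init_model(cfg, seed = 5)
  set.seed(6)
  X3 <- array(rbinom(cfg$n * cfg$m * cfg$T_steps, 1, 0.2),
              c(cfg$n, cfg$m, cfg$T_steps))
  p1 <- classify_batch(model, X3)
  p2 <- classify_batch(model, X3)
  expect_length(p1, cfg$T_steps)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  expect_error(classify_batch(model, X3[, , 1:2]), "expects")
})

test_that("the recurrent core is live in both directions", {
  cfg <- toy_model_config()
  model <- init_model(cfg, seed = 7)
  set.seed(8)
  X3 <- array(rnorm(cfg$n * cfg$m * cfg$T_steps), c(cfg$n, cfg$m, cfg$T_steps))
  fwd <- classify_batch(model, X3)
  rev_order <- classify_batch(model, X3[, , cfg$T_steps:1])
  expect_false(isTRUE(all.equal(fwd, rev(rev_order))))
})

test_that("one LSTM step matches the gate recursion evaluated directly", {
  set.seed(9)
  D <- 5; H <- 3; B <- 2
  Wx <- matrix(rnorm(D * 4 * H, sd = 0.3), D, 4 * H)
  Wh <- matrix(rnorm(H * 4 * H, sd = 0.3), H, 4 * H)
  b <- rnorm(4 * H, sd = 0.2)
  x1 <- matrix(rnorm(B * D), B, D)
  x2 <- matrix(rnorm(B * D), B, D)
  out <- delnet:::lstm_fwd(list(x1, x2), Wx, Wh, b)

  sig <- function(z) 1 / (1 + exp(-z))
  idx <- function(g) (g - 1) * H + seq_len(H)
  h_prev <- matrix(0, B, H); c_prev <- matrix(0, B, H)
  for (t in 1:2) {
    x_t <- if (t == 1) x1 else x2
    I_t <- sig(x_t %*% Wx[, idx(1)] + h_prev %*% Wh[, idx(1)] +
                 rep(b[idx(1)], each = B))
    F_t <- sig(x_t %*% Wx[, idx(2)] + h_prev %*% Wh[, idx(2)] +
                 rep(b[idx(2)], each = B))
    O_t <- sig(x_t %*% Wx[, idx(3)] + h_prev %*% Wh[, idx(3)] +
                 rep(b[idx(3)], each = B))
    C_tilde <- tanh(x_t %*% Wx[, idx(4)] + h_prev %*% Wh[, idx(4)] +
                      rep(b[idx(4)], each = B))
    c_prev <- F_t * c_prev + I_t * C_tilde
    h_prev <- O_t * tanh(c_prev)
    expect_true(all(I_t > 0 & I_t < 1))
    expect_true(all(h_prev > -1 & h_prev < 1))
    expect_equal(out$h[[t]], h_prev, tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- toy_model_config()
  model <- init_model(cfg, seed = 5)
  B <- 2
  set.seed(11)
  X3 <- array(rnorm(cfg$n * cfg$m * B * cfg$T_steps),
              c(cfg$n, cfg$m, B * cfg$T_steps))
  # guard against the degenerate all-dead-ReLU configuration, where the
  # finite-difference probe itself sits on the kink
  expect_gt(sum(abs(delnet:::encoder_fwd(X3, model$params, cfg,
                                         keep_cache = FALSE)$E)), 0)
  y <- matrix(rbinom(B * cfg$T_steps, 1, 0.5), B, cfg$T_steps)
  lossf <- function(params) {
    f <- delnet:::model_fwd(X3, B, params, cfg)
    mean(custom_loss(f$probs, y, 0.001))
  }
  f <- delnet:::model_fwd(X3, B, model$params, cfg, train = TRUE)
  dp <- delnet:::custom_loss_grad(f$probs, y, 0.001) / length(y)
  g <- delnet:::model_bwd(dp, f, model$params, cfg)
  eps <- 1e-5
  set.seed(12)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- model$params
      pp[[nm]][i] <- p[i] + eps; f1 <- lossf(pp)
      pp[[nm]][i] <- p[i] - eps; f0 <- lossf(pp)
      num <- (f1 - f0) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-4, abs(num) + abs(g[[nm]][i])),
                1e-4)
    }
  }
})

test_that("the asymmetric log loss matches its analytic form", {
  expect_equal(custom_loss(1, 1, 0.001), log(1.001)^2, tolerance = 1e-12)
  expect_equal(custom_loss(0, 1, 0.001), log(0.001)^2, tolerance = 1e-12)
  expect_equal(custom_loss(1, 0, 0.001), log(2.001)^2, tolerance = 1e-12)
  # missed deletions cost far more than unconfirmed predictions
  for (a in c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2))
    expect_gt(custom_loss(0, 1, a), custom_loss(1, 0, a))
  # gradient signs by finite differences: pulls up for positives, down for
  # negatives
  eps <- 1e-7
  for (p in c(0.1, 0.5, 0.9)) {
    expect_lt((custom_loss(p + eps, 1) - custom_loss(p - eps, 1)) / (2 * eps), 0)
    expect_gt((custom_loss(p + eps, 0) - custom_loss(p - eps, 0)) / (2 * eps), 0)
    expect_equal((custom_loss(p + eps, 1) - custom_loss(p - eps, 1)) / (2 * eps),
                 delnet:::custom_loss_grad(p, 1), tolerance = 1e-5)
  }
  expect_error(custom_loss(0.5, 1, a = 0), "a > 0")
})

test_that("early stopping keeps the best epoch and stops after patience", {
  # monitored sequence .5 .6 .6 .6 with patience 2: stop after epoch 4,
  # epoch-2 weights kept
  st <- es_init(2)
  for (m in c(0.5, 0.6, 0.6, 0.6)) st <- es_update(st, m)
  expect_true(st$stop)
  expect_equal(st$epoch, 4L)
  expect_equal(st$best_epoch, 2L)

  st2 <- es_init(3)
  for (m in c(0.5, 0.6, 0.55, 0.7)) st2 <- es_update(st2, m)
  expect_false(st2$stop)
  expect_equal(st2$best_epoch, 4L)
})

test_that("training refuses all-negative data and learns under a fixed seed", {
  cfg <- toy_model_config()
  set.seed(20)
  n_win <- 24L
  win <- partition_reference(c(c1 = n_win * cfg$m), cfg$m)
  arr <- array(0L, c(cfg$n, cfg$m, n_win))
  labels <- integer(n_win)
  pos <- c(3L, 9L, 15L, 21L)
  labels[pos] <- 1L
  for (p in pos) arr[1:4, 4:13, p] <- 1L
  fs <- structure(list(windows = win, array = arr, p = rep(5L, n_win),
                       m = cfg$m, n = cfg$n, orientation = "rows=reads;cols=positions"),
                  class = "feature_set")
  batches <- make_batches(fs, cfg$T_steps)
  dat <- list(featset = fs, batches = batches, labels = labels)

  expect_error(
    train(init_model(cfg, 1), list(featset = fs, batches = batches,
                                   labels = integer(n_win)), dat,
          training_config(max_epochs = 1)),
    "positive")

  tcfg <- training_config(max_epochs = 15, batch_size = 24 * cfg$T_steps,
                          shuffle_seed = 4)
  m1 <- train(init_model(cfg, 1), dat, dat, tcfg)
  expect_true(max(m1$history$val_auc) > 0.9)
  expect_equal(m1$best_epoch, which.max(m1$history$val_auc))
  # seeded reproducibility
  m2 <- train(init_model(cfg, 1), dat, dat, tcfg)
  expect_equal(m1$history$val_auc, m2$history$val_auc, tolerance = 1e-10)
})

test_that("window scoring strips padding and re-attaches coordinates", {
  cfg <- toy_model_config()
  model <- init_model(cfg, seed = 3)
  n_win <- 8L   # 3 batches of T=3, last padded with 1
  win <- partition_reference(c(c1 = n_win * cfg$m), cfg$m)
  set.seed(21)
  fs <- structure(list(windows = win,
                       array = array(rbinom(cfg$n * cfg$m * n_win, 1, .1),
                                     c(cfg$n, cfg$m, n_win)),
                       p = rep(3L, n_win), m = cfg$m, n = cfg$n,
                       orientation = "rows=reads;cols=positions"),
                  class = "feature_set")
  sc <- predict_windows(model, fs)
  expect_equal(nrow(sc), n_win)
  expect_equal(sc$index, 0:(n_win - 1L))
  expect_true(all(sc$prob > 0 & sc$prob < 1))

  bad <- fs; bad$m <- 100L
  expect_error(predict_windows(model, bad), "incompatible")
})

test_that("models round-trip through checkpoint files", {
  cfg <- toy_model_config()
  model <- init_model(cfg, seed = 13)
  stem <- file.path(tempdir(), "ckpt")
  save_model(model, stem)
  back <- load_model(stem)
  expect_equal(back$cfg$conv_filters, cfg$conv_filters)
  expect_equal(back$params, model$params, tolerance = 1e-15)
  set.seed(14)
  X3 <- array(rbinom(cfg$n * cfg$m * cfg$T_steps, 1, .2),
              c(cfg$n, cfg$m, cfg$T_steps))
  expect_identical(classify_batch(model, X3), classify_batch(back, X3))
})
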