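#' Model architecture configuration
#'
#' Collects every architecture hyperparameter in one validated place. The
#' defaults follow the method's published architecture: 200-bp windows
#' (`m`), 18 matrix rows (`n`), sequences of `T = 100` windows, an initial
#' 1x2 average pooling, six conv/SE/max-pool blocks whose final filter count
#' fixes the encoder width at `F = 160`, two bidirectional LSTM layers of 64
#' units, and a two-layer fully connected head with dropout 0.4 ahead of a
#' sigmoid output. Per-block filter counts, kernel size, SE reduction and
#' head widths are not pinned down by the published description; the
#' defaults here keep the model under one million parameters.
#'
#' @param m Window length in bp.
#' @param n Feature-matrix rows.
#' @param T_steps Windows per recurrent sample.
#' @param conv_filters Integer vector of six per-block filter counts; the
#'   last one is the encoder output dimension `F`.
#' @param se_reduction Channel-reduction ratio of the squeeze-and-excitation
#'   bottleneck.
#' @param lstm_units LSTM units per direction per layer.
#' @param dense_sizes Widths of the two fully connected head layers.
#' @param dropout_rate Dropout probability after each fully connected layer.
#' @return A validated `model_config` list; `$F` is the encoder width.
#' @export
model_config <- function(m = 200L, n = 18L, T_steps = 100L,
                         conv_filters = c(4L, 8L, 16L, 32L, 64L, 160L),
                         se_reduction = 4L, lstm_units = 64L,
                         dense_sizes = c(64L, 32L), dropout_rate = 0.4) {
  stopifnot(m >= 2, n >= 1, T_steps >= 1,
            length(conv_filters) == 6L, all(conv_filters >= 1),
            se_reduction >= 1, lstm_units >= 1,
            length(dense_sizes) == 2L, all(dense_sizes >= 1),
            dropout_rate >= 0, dropout_rate < 1)
  cfg <- list(m = as.integer(m), n = as.integer(n),
              T_steps = as.integer(T_steps),
              conv_filters = as.integer(conv_filters),
              se_reduction = as.integer(se_reduction),
              lstm_units = as.integer(lstm_units),
              dense_sizes = as.integer(dense_sizes),
              dropout_rate = dropout_rate,
              F = as.integer(conv_filters[6L]))
  # spatial trace through the encoder: initial 1x2 average pool, then one
  # max pool per block (2x2 where the dimension allows, else 1x2 / 1x1)
  h <- cfg$n; w <- cfg$m %/% 2L
  trace <- list()
  for (k in 1:6) {
    ph <- min(2L, h); pw <- min(2L, w)
    trace[[k]] <- c(h = h, w = w, ph = ph, pw = pw,
                    h2 = h %/% ph, w2 = w %/% pw)
    h <- h %/% ph; w <- w %/% pw
    if (h < 1L || w < 1L)
      stop("encoder spatial dimensions collapse below 1x1; ",
           "reduce pooling or enlarge m/n", call. = FALSE)
  }
  cfg$trace <- trace
  structure(cfg, class = "model_config")
}

#' Training configuration
#'
#' @param loss_a Offset `a` of the class-asymmetric log loss (default 0.001).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Gradient-step size in windows (default 512; with
#'   `T = 100` this is about five window sequences per step — a deliberately
#'   large batch so that the rare positive windows are seen at every step).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param max_epochs Hard epoch cap.
#' @param shuffle_seed Seed for per-epoch shuffling, dropout and weight
#'   initialisation.
#' @param stop_loss Optional epoch-mean training-loss floor; training also
#'   stops once the loss drops below it (0 disables, the default).
#' @return A validated `training_config` list.
#' @export
training_config <- function(loss_a = 0.001, learning_rate = 0.001,
                            batch_size = 512L, patience = 10L,
                            max_epochs = 40L, shuffle_seed = 1L,
                            stop_loss = 0) {
  stopifnot(loss_a > 0, learning_rate > 0, batch_size >= 1, patience >= 1,
            max_epochs >= 1, stop_loss >= 0)
  structure(list(loss_a = loss_a, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 shuffle_seed = as.integer(shuffle_seed),
                 stop_loss = stop_loss),
            class = "training_config")
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# He-uniform for ReLU layers: keeps activation magnitude stable through the
# six-block encoder, where Glorot + ReLU + SE gating otherwise shrinks
# activations toward the dead-ReLU regime.
he_uniform <- function(fan_in, dims) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Initialise an untrained model
#'
#' Glorot-uniform weights (forget-gate biases set to 1) drawn under `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for reproducible initialisation.
#' @return A `del_model`: list with `cfg` and named parameter list `params`.
#' @export
init_model <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  p <- list()
  cin <- 1L
  for (k in 1:6) {
    cout <- cfg$conv_filters[k]
    p[[paste0("conv", k, "_W")]] <- he_uniform(9 * cin, c(9 * cin, cout))
    p[[paste0("conv", k, "_b")]] <- numeric(cout)
    cse <- max(1L, cout %/% cfg$se_reduction)
    p[[paste0("se", k, "_W1")]] <- he_uniform(cout, c(cout, cse))
    p[[paste0("se", k, "_b1")]] <- numeric(cse)
    p[[paste0("se", k, "_W2")]] <- glorot(cse, cout, c(cse, cout))
    # start the SE gates nearly open so early training is not attenuated
    p[[paste0("se", k, "_b2")]] <- rep(2, cout)
    cin <- cout
  }
  H <- cfg$lstm_units
  d_in <- cfg$F
  for (l in 1:2) {
    for (dir in c("f", "r")) {
      p[[paste0("lstm", l, dir, "_Wx")]] <- glorot(d_in, 4 * H, c(d_in, 4 * H))
      p[[paste0("lstm", l, dir, "_Wh")]] <- glorot(H, 4 * H, c(H, 4 * H))
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1      # forget-gate bias
      p[[paste0("lstm", l, dir, "_b")]] <- b
    }
    d_in <- 2L * H
  }
  d1 <- cfg$dense_sizes[1L]; d2 <- cfg$dense_sizes[2L]
  p$dense1_W <- he_uniform(2 * H, c(2 * H, d1)); p$dense1_b <- numeric(d1)
  p$dense2_W <- he_uniform(d1, c(d1, d2)); p$dense2_b <- numeric(d2)
  p$out_W <- glorot(d2, 1, c(d2, 1)); p$out_b <- numeric(1)
  structure(list(cfg = cfg, params = p), class = "del_model")
}

# ---- encoder --------------------------------------------------------------

# Initial fixed 1x2 average pool along the window-position axis.
avgpool_1x2 <- function(X3) {
  m <- dim(X3)[2L]
  w <- m %/% 2L
  (X3[, 2 * seq_len(w) - 1L, , drop = FALSE] +
     X3[, 2 * seq_len(w), , drop = FALSE]) / 2
}

# Parameter order and layer geometry handed to the C++ encoder.
enc_param_names <- function() {
  unlist(lapply(1:6, function(k)
    paste0(c("conv", "conv", "se", "se", "se", "se"), k,
           c("_W", "_b", "_W1", "_b1", "_W2", "_b2"))))
}

enc_trace_mat <- function(cfg)
  do.call(rbind, lapply(cfg$trace, function(tr)
    as.integer(tr[c("h", "w", "ph", "pw", "h2", "w2")])))

# Forward pass of the time-distributed encoder over N windows.
# X3: n x m x N array. Returns F-vectors (N x F); the layer activations
# needed for backprop stay in native memory behind `cache_ptr`.
encoder_fwd <- function(X3, params, cfg, keep_cache = TRUE) {
  N <- dim(X3)[3L]
  r <- encoder_fwd_cpp(X3, cfg$n, cfg$m, N, params[enc_param_names()],
                       enc_trace_mat(cfg), keep_cache)
  list(E = r$E, cache_ptr = r$cache, N = N)
}

encoder_bwd <- function(dE, fwd, params, cfg) {
  nms <- enc_param_names()
  g <- encoder_bwd_cpp(fwd$cache_ptr, dE, params[nms], enc_trace_mat(cfg))
  stats::setNames(g, nms)
}

#' Encode one feature matrix into its F-dimensional representation
#'
#' Applies the convolutional encoder (1x2 average pool, six
#' conv/ReLU/SE/max-pool blocks, global average pool) to a single window.
#'
#' @param model A `del_model`.
#' @param mat An n x m feature matrix (or a `feature_matrix` object).
#' @return Numeric vector of length `model$cfg$F`.
#' @export
encode_window <- function(model, mat) {
  if (inherits(mat, "feature_matrix")) mat <- mat$mat
  if (!all(dim(mat) == c(model$cfg$n, model$cfg$m)))
    stop("matrix shape ", paste(dim(mat), collapse = "x"),
         " does not match model config ", model$cfg$n, "x", model$cfg$m,
         call. = FALSE)
  X3 <- array(as.numeric(mat), c(model$cfg$n, model$cfg$m, 1L))
  drop(encoder_fwd(X3, model$params, model$cfg, keep_cache = FALSE)$E)
}

# ---- full model -----------------------------------------------------------

# Forward pass over B samples of T windows. X3: n x m x (B*T) array with
# window slices in t-major order (slice index = b + (t-1)*B). Returns
# probabilities as a B x T matrix plus caches when training.
model_fwd <- function(X3, B, params, cfg, train = FALSE, keep_cache = train) {
  NT <- dim(X3)[3L]
  T_len <- NT / B
  stopifnot(T_len == as.integer(T_len))
  enc <- encoder_fwd(X3, params, cfg, keep_cache = keep_cache)
  Xt <- lapply(seq_len(T_len), function(t)
    enc$E[(t - 1L) * B + seq_len(B), , drop = FALSE])
  l1f <- lstm_fwd(Xt, params$lstm1f_Wx, params$lstm1f_Wh, params$lstm1f_b)
  l1r <- lstm_fwd(Xt, params$lstm1r_Wx, params$lstm1r_Wh, params$lstm1r_b,
                  reverse = TRUE)
  H1 <- lapply(seq_len(T_len), function(t) cbind(l1f$h[[t]], l1r$h[[t]]))
  l2f <- lstm_fwd(H1, params$lstm2f_Wx, params$lstm2f_Wh, params$lstm2f_b)
  l2r <- lstm_fwd(H1, params$lstm2r_Wx, params$lstm2r_Wh, params$lstm2r_b,
                  reverse = TRUE)
  Hflat <- do.call(rbind, lapply(seq_len(T_len), function(t)
    cbind(l2f$h[[t]], l2r$h[[t]])))           # (B*T) x 2H, t-major
  z1 <- dense_fwd(Hflat, params$dense1_W, params$dense1_b)
  a1 <- pmax(z1, 0)
  dp1 <- dropout_fwd(a1, cfg$dropout_rate, train)
  z2 <- dense_fwd(dp1$y, params$dense2_W, params$dense2_b)
  a2 <- pmax(z2, 0)
  dp2 <- dropout_fwd(a2, cfg$dropout_rate, train)
  logits <- dense_fwd(dp2$y, params$out_W, params$out_b)
  probs <- sigmoid(drop(logits))
  out <- list(probs = matrix(probs, B, T_len), B = B, T_len = T_len)
  if (keep_cache)
    out$cache <- list(enc = enc, Xt = Xt, l1f = l1f, l1r = l1r, H1 = H1,
                      l2f = l2f, l2r = l2r, Hflat = Hflat, a1 = a1,
                      dp1 = dp1, a2 = a2, dp2 = dp2, probs_flat = probs)
  out
}

# Backward pass given d(loss)/d(prob) as a B x T matrix.
model_bwd <- function(dprobs, fwd, params, cfg) {
  cc <- fwd$cache
  B <- fwd$B; T_len <- fwd$T_len
  p <- cc$probs_flat
  dlogits <- matrix(as.vector(dprobs) * p * (1 - p), ncol = 1L)
  g <- list()
  ob <- dense_bwd(dlogits, cc$dp2$y, params$out_W)
  g$out_W <- ob$dW; g$out_b <- ob$db
  da2 <- ob$dx
  if (!is.null(cc$dp2$mask)) da2 <- da2 * cc$dp2$mask
  dz2 <- da2 * (cc$a2 > 0)
  d2b <- dense_bwd(dz2, cc$dp1$y, params$dense2_W)
  g$dense2_W <- d2b$dW; g$dense2_b <- d2b$db
  da1 <- d2b$dx
  if (!is.null(cc$dp1$mask)) da1 <- da1 * cc$dp1$mask
  dz1 <- da1 * (cc$a1 > 0)
  d1b <- dense_bwd(dz1, cc$Hflat, params$dense1_W)
  g$dense1_W <- d1b$dW; g$dense1_b <- d1b$db
  H <- cfg$lstm_units
  dH2 <- lapply(seq_len(T_len), function(t)
    d1b$dx[(t - 1L) * B + seq_len(B), , drop = FALSE])
  dH2f <- lapply(dH2, function(x) x[, seq_len(H), drop = FALSE])
  dH2r <- lapply(dH2, function(x) x[, H + seq_len(H), drop = FALSE])
  b2f <- lstm_bwd(dH2f, cc$l2f, cc$H1, params$lstm2f_Wx, params$lstm2f_Wh)
  b2r <- lstm_bwd(dH2r, cc$l2r, cc$H1, params$lstm2r_Wx, params$lstm2r_Wh)
  g$lstm2f_Wx <- b2f$dWx; g$lstm2f_Wh <- b2f$dWh; g$lstm2f_b <- b2f$db
  g$lstm2r_Wx <- b2r$dWx; g$lstm2r_Wh <- b2r$dWh; g$lstm2r_b <- b2r$db
  dH1 <- lapply(seq_len(T_len), function(t) b2f$dX[[t]] + b2r$dX[[t]])
  dH1f <- lapply(dH1, function(x) x[, seq_len(H), drop = FALSE])
  dH1r <- lapply(dH1, function(x) x[, H + seq_len(H), drop = FALSE])
  b1f <- lstm_bwd(dH1f, cc$l1f, cc$Xt, params$lstm1f_Wx, params$lstm1f_Wh)
  b1r <- lstm_bwd(dH1r, cc$l1r, cc$Xt, params$lstm1r_Wx, params$lstm1r_Wh)
  g$lstm1f_Wx <- b1f$dWx; g$lstm1f_Wh <- b1f$dWh; g$lstm1f_b <- b1f$db
  g$lstm1r_Wx <- b1r$dWx; g$lstm1r_Wh <- b1r$dWh; g$lstm1r_b <- b1r$db
  dE <- matrix(0, B * T_len, cfg$F)
  for (t in seq_len(T_len))
    dE[(t - 1L) * B + seq_len(B), ] <- b1f$dX[[t]] + b1r$dX[[t]]
  c(g, encoder_bwd(dE, cc$enc, params, cfg))
}

#' Score one batch of consecutive windows
#'
#' Runs the full network in inference mode (dropout off) over one sample of
#' `T` consecutive windows and returns one probability per window, each
#' strictly inside (0, 1).
#'
#' @param model A `del_model`.
#' @param X3 An n x m x T numeric array of feature matrices (e.g. from
#'   [featset_tensor()]).
#' @return Numeric vector of `T` probabilities.
#' @export
classify_batch <- function(model, X3) {
  cfg <- model$cfg
  if (dim(X3)[3L] != cfg$T_steps)
    stop("batch has ", dim(X3)[3L], " windows; model expects ", cfg$T_steps,
         call. = FALSE)
  drop(model_fwd(X3, B = 1L, model$params, cfg)$probs)
}

#' Class-asymmetric logarithmic loss
#'
#' `loss = (ln(prediction - label + 1 + a))^2`. At a perfect prediction the
#' loss is near zero; a missed true deletion (label 1, prediction 0) gives
#' `(ln a)^2`, a large value, while a positive prediction unsupported by the
#' truth set (label 0, prediction 1) gives only `(ln(2 + a))^2`. The
#' asymmetry encodes that curated truth sets are incomplete but rarely
#' wrong: unconfirmed predictions are penalised lightly, missed known
#' deletions heavily.
#'
#' @param prediction Numeric vector in `[0, 1]`.
#' @param label Numeric vector in `{0, 1}`.
#' @param a Positive offset controlling the maximum loss (default 0.001).
#' @return Non-negative numeric vector of losses.
#' @export
custom_loss <- function(prediction, label, a = 0.001) {
  stopifnot(a > 0)
  x <- pmax(prediction - label + 1 + a, 1e-12)
  log(x)^2
}

# d loss / d prediction (same clamp as the forward value)
custom_loss_grad <- function(prediction, label, a = 0.001) {
  x <- pmax(prediction - label + 1 + a, 1e-12)
  2 * log(x) / x
}

#' Score every window of a feature set
#'
#' Streams batches through the network in inference mode, strips mask
#' padding and re-attaches window coordinates.
#'
#' @param model A `del_model`.
#' @param featset A `feature_set`.
#' @param batches Batches from [make_batches()]; regenerated from `featset`
#'   when omitted.
#' @return data.frame `contig`, `start`, `end`, `index`, `prob` with one row
#'   per real (unmasked) window.
#' @export
predict_windows <- function(model, featset, batches = NULL) {
  cfg <- model$cfg
  if (featset$m != cfg$m || featset$n != cfg$n)
    stop("feature set (m=", featset$m, ", n=", featset$n,
         ") is incompatible with the model (m=", cfg$m, ", n=", cfg$n, ")",
         call. = FALSE)
  if (is.null(batches)) batches <- make_batches(featset, cfg$T_steps)
  if (length(batches) == 0L)
    return(cbind(featset$windows[0, ], prob = numeric(0)))
  # several samples per forward pass keeps the GEMMs large
  chunk <- 8L
  res <- vector("list", length(batches))
  for (lo in seq(1L, length(batches), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(batches))
    bs <- batches[lo:hi]
    B <- length(bs)
    idx <- integer(B * cfg$T_steps)
    for (t in seq_len(cfg$T_steps))
      for (b in seq_len(B))
        idx[b + (t - 1L) * B] <- bs[[b]]$idx[t]
    X3 <- featset_tensor(featset, idx)
    probs <- model_fwd(X3, B, model$params, cfg)$probs
    for (b in seq_len(B)) {
      bt <- bs[[b]]
      res[[lo + b - 1L]] <- cbind(
        featset$windows[bt$idx[bt$mask], , drop = FALSE],
        prob = probs[b, bt$mask])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
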