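#' Early-stopping state machine
#'
#' Tracks the best value of a monitored metric (higher is better). Feed one
#' metric value per epoch with `es_update()`; `$stop` turns TRUE once the
#' metric has not improved for `patience` consecutive epochs, and
#' `$best_epoch` always names the epoch whose weights should be kept.
#'
#' @param patience Epochs without improvement tolerated before stopping.
#' @return `es_init()` returns the initial state; `es_update()` the updated
#'   state, with fields `best`, `best_epoch`, `wait`, `epoch`, `stop`.
#' @export
es_init <- function(patience) {
  stopifnot(patience >= 1)
  list(patience = as.integer(patience), best = -Inf, best_epoch = 0L,
       wait = 0L, epoch = 0L, stop = FALSE)
}

#' @rdname es_init
#' @param state State from [es_init()] or a previous update.
#' @param metric Monitored value for the epoch just finished.
#' @export
es_update <- function(state, metric) {
  state$epoch <- state$epoch + 1L
  if (metric > state$best + 1e-12) {
    state$best <- metric
    state$best_epoch <- state$epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gg <- grads[[nm]]
    if (is.null(gg)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gg
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gg^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Assemble the t-major input tensor, labels and mask for a set of samples.
stack_samples <- function(featset, batches, labels) {
  B <- length(batches)
  T_len <- length(batches[[1L]]$idx)
  idx <- integer(B * T_len)
  y <- matrix(0, B, T_len)
  mask <- matrix(FALSE, B, T_len)
  for (b in seq_len(B)) {
    bt <- batches[[b]]
    for (t in seq_len(T_len)) idx[b + (t - 1L) * B] <- bt$idx[t]
    mask[b, ] <- bt$mask
    y[b, bt$mask] <- labels[bt$idx[bt$mask]]
  }
  list(X3 = featset_tensor(featset, idx), y = y, mask = mask, B = B)
}

#' Train the window classifier
#'
#' Minimises the mean class-asymmetric log loss over unmasked windows with
#' Adam, shuffling the training samples every epoch, monitoring window-level
#' AUC on the validation set, checkpointing the best-on-validation weights
#' and stopping once validation AUC has not improved for `cfg$patience`
#' epochs.
#'
#' @param model An initialised `del_model`.
#' @param train_data,val_data Lists with `featset` (a `feature_set`),
#'   `batches` (from [make_batches()]) and `labels` (per-window 0/1 vector,
#'   aligned with `featset$windows`).
#' @param cfg A [training_config()].
#' @param verbose Print one line per epoch.
#' @return The model with trained `params`, plus `history` (per-epoch
#'   data.frame of mean training loss and validation AUC) and `best_epoch`.
#' @export
train <- function(model, train_data, val_data, cfg = training_config(),
                  verbose = FALSE) {
  labs <- train_data$labels
  real <- unlist(lapply(train_data$batches, function(b) b$idx[b$mask]))
  if (sum(labs[real]) == 0)
    stop("training data contains no positive window; ",
         "cannot fit a deletion classifier on all-negative labels",
         call. = FALSE)
  mcfg <- model$cfg
  params <- model$params
  opt <- adam_init(params)
  per_step <- max(1L, as.integer(round(cfg$batch_size / mcfg$T_steps)))
  n_samp <- length(train_data$batches)
  es <- es_init(cfg$patience)
  best_params <- params
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auc = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    set.seed((cfg$shuffle_seed + epoch) %% .Machine$integer.max)
    ord <- sample.int(n_samp)
    ep_loss <- 0; ep_n <- 0
    for (lo in seq(1L, n_samp, by = per_step)) {
      sel <- ord[lo:min(lo + per_step - 1L, n_samp)]
      st <- stack_samples(train_data$featset, train_data$batches[sel], labs)
      fwd <- model_fwd(st$X3, st$B, params, mcfg, train = TRUE)
      n_real <- sum(st$mask)
      lossmat <- custom_loss(fwd$probs, st$y, cfg$loss_a)
      ep_loss <- ep_loss + sum(lossmat[st$mask])
      ep_n <- ep_n + n_real
      dprobs <- custom_loss_grad(fwd$probs, st$y, cfg$loss_a) / n_real
      dprobs[!st$mask] <- 0
      grads <- model_bwd(dprobs, fwd, params, mcfg)
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    cand <- model
    cand$params <- params
    vp <- predict_windows(cand, val_data$featset, val_data$batches)
    # align by window row order of the feature set
    v_auc <- window_auc(vp$prob, val_data$labels[
      match_window_rows(vp, val_data$featset$windows)])
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, val_auc = v_auc))
    if (verbose)
      message(sprintf("epoch %d  loss %.5f  val AUC %.4f", epoch,
                      ep_loss / ep_n, v_auc))
    es <- es_update(es, v_auc)
    if (es$best_epoch == epoch) best_params <- params
    if (es$stop) break
    if (cfg$stop_loss > 0 && ep_loss / ep_n < cfg$stop_loss) break
  }
  model$params <- best_params
  model$history <- history
  model$best_epoch <- es$best_epoch
  model
}

match_window_rows <- function(pred, windows)
  match(paste(pred$contig, pred$index), paste(windows$contig, windows$index))

#' Save / load a model checkpoint
#'
#' Weights go to a flat binary file of doubles; the JSON sidecar records the
#' full architecture configuration and each parameter's name and shape, so
#' extraction/model compatibility (m, n, T) is machine-checkable on load.
#'
#' @param model A `del_model`.
#' @param path Output stem; writes `<path>.bin` and `<path>.json`.
#' @export
save_model <- function(model, path) {
  shapes <- lapply(model$params, function(x)
    if (is.null(dim(x))) length(x) else dim(x))
  cfg <- model$cfg
  cfg$trace <- NULL
  jsonlite::write_json(list(cfg = unclass(cfg), shapes = shapes),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (nm in names(model$params))
    writeBin(as.numeric(model$params[[nm]]), con, size = 8L,
             endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, list(
    m = side$cfg$m, n = side$cfg$n, T_steps = side$cfg$T_steps,
    conv_filters = side$cfg$conv_filters,
    se_reduction = side$cfg$se_reduction, lstm_units = side$cfg$lstm_units,
    dense_sizes = side$cfg$dense_sizes, dropout_rate = side$cfg$dropout_rate))
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  params <- list()
  for (nm in names(side$shapes)) {
    shp <- unlist(side$shapes[[nm]])
    vals <- readBin(con, "numeric", n = prod(shp), size = 8L,
                    endian = "little")
    params[[nm]] <- if (length(shp) > 1L) array(vals, shp) else vals
  }
  structure(list(cfg = cfg, params = params), class = "del_model")
}
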