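# Training loop: AdamW on the high-load weighted MSE with early stopping.

#' Training configuration
#'
#' Defaults follow the reference regimen: AdamW with weight decay 1e-4,
#' initial learning rate 1e-4, batch size 32, up to 100 epochs with early
#' stopping after 5 non-improving validation epochs, and the high-load loss
#' weighting (threshold 70, weight 1.5).
#'
#' @param lr Initial learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param batch Batch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience in epochs (must be `<= epochs`).
#' @param high_threshold High-load loss threshold.
#' @param high_weight High-load loss weight.
#' @param reduction Loss reduction, `"mean"` (default) or `"sum"`.
#' @param seed Seed for batch shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, batch = 32,
                         epochs = 100, patience = 5, high_threshold = 70,
                         high_weight = 1.5, reduction = "mean", seed = 1) {
  stop_if(patience > epochs, "patience must be <= epochs")
  structure(list(lr = lr, weight_decay = weight_decay, batch = as.integer(batch),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 high_threshold = high_threshold, high_weight = high_weight,
                 reduction = reduction, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the full model
#'
#' Minimizes the high-load weighted MSE over the training split with AdamW,
#' evaluating the validation split after every epoch; training stops early
#' once the validation loss has failed to improve for `patience` consecutive
#' epochs, and the best-validation-epoch weights are returned. Fully
#' deterministic for a fixed seed.
#'
#' @param model A [cogload_model()].
#' @param inputs List of [branch_features()] (one per sequence, typically of
#'   normalized, smoothed sequences).
#' @param labels Numeric labels on the `[0, 100]` scale, aligned with
#'   `inputs`.
#' @param train_idx,val_idx Index vectors into `inputs` for the two splits.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list of class `cogload_fit`: `model` (best-epoch weights),
#'   `history` (data.frame epoch / train_loss / val_loss / val_mae),
#'   `best_epoch`, `stopped_early`.
#' @export
train_model <- function(model, inputs, labels, train_idx, val_idx,
                        cfg = train_config(), verbose = FALSE) {
  stop_if(length(train_idx) == 0L || length(val_idx) == 0L,
          "train and validation splits must be non-empty")
  opt <- adamw_state(model)
  best <- list(loss = Inf, model = model, epoch = 0L)
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_mae = numeric(0))
  epoch_seeds <- derive_seeds(cfg$seed, cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ep <- with_seed(epoch_seeds[epoch], {
      ord <- sample(train_idx)
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1L, length(ord))]
        step <- batch_grads(model, inputs[idx], labels[idx], cfg)
        stop_if(!is.finite(step$loss), "training diverged: non-finite loss")
        opt <- adamw_step(opt, step$grads, cfg$lr, cfg$weight_decay)
        model <- opt$params
        ep_loss <- ep_loss + step$loss
        n_batches <- n_batches + 1L
      }
      list(opt = opt, model = model, loss = ep_loss, n = n_batches)
    })
    opt <- ep$opt; model <- ep$model
    ep_loss <- ep$loss; n_batches <- ep$n
    val_pred <- vapply(val_idx, function(i)
      model_fwd(model, inputs[[i]], training = FALSE)$score, numeric(1))
    val_loss <- weighted_mse(val_pred, labels[val_idx], cfg$high_threshold,
                             cfg$high_weight, reduction = "mean")
    val_mae <- mean(abs(val_pred - labels[val_idx]))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = val_loss, val_mae = val_mae))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val MAE %.3f",
                      epoch, ep_loss / n_batches, val_loss, val_mae))
    }
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, model = model, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  structure(list(model = best$model, history = hist, best_epoch = best$epoch,
                 stopped_early = bad >= cfg$patience),
            class = "cogload_fit")
}

# Mean gradient of the weighted loss over one batch.
batch_grads <- function(model, batch_inputs, batch_labels, cfg) {
  n <- length(batch_inputs)
  preds <- numeric(n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    fw <- model_fwd(model, batch_inputs[[i]], training = TRUE)
    preds[i] <- fw$score
    caches[[i]] <- fw
  }
  dpred <- weighted_mse_grad(preds, batch_labels, cfg$high_threshold,
                             cfg$high_weight)
  if (cfg$reduction == "sum") dpred <- dpred * n
  grads <- NULL
  for (i in seq_len(n)) {
    g <- model_bwd(model, caches[[i]], dpred[i])
    grads <- if (is.null(grads)) g else nn_map2(grads, g, `+`)
  }
  loss <- weighted_mse(preds, batch_labels, cfg$high_threshold,
                       cfg$high_weight, reduction = cfg$reduction)
  list(loss = loss, grads = grads)
}

# ---- AdamW ---------------------------------------------------------------

adamw_state <- function(params) {
  list(params = params,
       m = nn_map(params, function(a) a * 0),
       v = nn_map(params, function(a) a * 0),
       t = 0L)
}

adamw_step <- function(state, grads, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- nn_map2(state$m, state$v, function(m, v) (m * c1) / (sqrt(v * c2) + eps))
  state$params <- nn_map2(state$params, upd, function(p, u) p - lr * (u + wd * p))
  state
}

#' Constant mean-label baseline MAE
#'
#' MAE of always predicting the training-split mean label — the floor any
#' learning model must beat.
#'
#' @param train_labels,eval_labels Label vectors for the fitting and
#'   evaluation splits.
#' @return The baseline MAE on the evaluation split.
#' @export
mean_baseline_mae <- function(train_labels, eval_labels) {
  mean(abs(mean(train_labels) - eval_labels))
}
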