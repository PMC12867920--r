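# Brute-force metric oracles, coded independently of the package
# implementations (explicit loops, no shared helpers).

oracle_mae <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(pred[i] - truth[i])
  s / length(pred)
}

oracle_rmse <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - truth[i])^2
  sqrt(s / length(pred))
}

oracle_mpjpe <- function(pred, gt) {
  n <- dim(pred)[1]
  s <- 0
  for (i in seq_len(n)) {
    for (k in 1:25) {
      s <- s + sqrt(sum((pred[i, k, ] - gt[i, k, ])^2))
    }
  }
  s / (n * 25)
}

oracle_pck <- function(pred, gt, L, tau) {
  n <- dim(pred)[1]
  hits <- 0
  for (i in seq_len(n)) {
    for (k in 1:25) {
      d <- sqrt(sum((pred[i, k, ] - gt[i, k, ])^2))
      if (d / L[i] <= tau) hits <- hits + 1
    }
  }
  hits / (n * 25) * 100
}

oracle_auc <- function(pred, truth, high = 70, low = 30) {
  pos <- which(truth >= high)
  neg <- which(truth < low)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (i in pos) {
    for (j in neg) {
      if (pred[i] > pred[j]) wins <- wins + 1
    }
  }
  wins / (length(pos) * length(neg))
}

oracle_frc <- function(features) {
  M <- ncol(features)
  if (M < 2) return(0)
  s <- 0
  for (j in 1:(M - 1)) {
    for (k in (j + 1):M) {
      r <- suppressWarnings(stats::cor(features[, j], features[, k]))
      if (is.finite(r)) s <- s + abs(r)
    }
  }
  s / M^2
}

# Rank-based AUC (Mann-Whitney U), valid on tie-free scores.
rank_auc <- function(pred, truth, high = 70, low = 30) {
  pos <- pred[truth >= high]
  neg <- pred[truth < low]
  r <- rank(c(pos, neg))
  U <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  U / (length(pos) * length(neg))
}
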