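# Evaluation metric suite: MAE, RMSE, MPJPE, PCK, pairwise AUC, plus report
# assembly.

#' Mean absolute error and root mean square error
#'
#' @param pred,truth Equal-length non-empty numeric vectors.
#' @return A named vector `c(mae = , rmse = )`.
#' @export
mae_rmse <- function(pred, truth) {
  stop_if(length(pred) == 0L, "empty input")
  stop_if(length(pred) != length(truth), "length mismatch")
  c(mae = mean(abs(pred - truth)),
    rmse = sqrt(mean((pred - truth)^2)))
}

#' Mean per-joint position error (MPJPE)
#'
#' Mean over samples and joints of the Euclidean distance between predicted
#' and reference 3D joint positions, in metres.
#'
#' @param pred,gt N x 25 x 3 arrays (a single T x 25 x 3 sequence works too,
#'   frames acting as samples).
#' @return MPJPE in metres.
#' @export
mpjpe <- function(pred, gt) {
  stop_if(!identical(dim(pred), dim(gt)), "shape mismatch")
  d <- pred - gt
  mean(sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2))
}

#' Percentage of correct keypoints (PCK)
#'
#' Percentage of joints whose prediction error, normalized by the sample's
#' torso diagonal `L_i`, is within the threshold `tau` (`<=`, boundary
#' correct). `tau = 0.1` is the conventional threshold for dance-movement
#' evaluation.
#'
#' @param pred,gt N x 25 x 3 arrays.
#' @param torso_diag Positive per-sample torso diagonal lengths (length N),
#'   removing body-size differences.
#' @param tau Deviation threshold (default 0.1).
#' @return PCK in percent (0-100).
#' @export
pck <- function(pred, gt, torso_diag, tau = 0.1) {
  stop_if(!identical(dim(pred), dim(gt)), "shape mismatch")
  stop_if(any(torso_diag <= 0), "torso diagonals must be positive")
  d <- pred - gt
  dist <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)  # N x 25
  mean(dist / torso_diag <= tau) * 100
}

#' Torso diagonal length per frame
#'
#' Distance between the left-shoulder and right-hip extremes of the default
#' topology (the torso's diagonal), used as the PCK normalizer.
#'
#' @param seq A [pose_sequence()] or T x 25 x 3 array.
#' @param topo Skeleton topology providing the joint names.
#' @return Numeric vector of per-frame diagonals.
#' @export
torso_diagonal <- function(seq, topo = default_skeleton()) {
  coords <- as_coords(seq)
  i <- match("l_shoulder", topo$joint_names)
  j <- match("r_hip", topo$joint_names)
  stop_if(is.na(i) || is.na(j),
          "topology must name l_shoulder and r_hip for the torso diagonal")
  sqrt(rowSums((coords[, i, , drop = FALSE] - coords[, j, , drop = FALSE])^2))
}

#' Pairwise AUC between high- and low-load movements
#'
#' The fraction of (high, low) pairs ranked correctly:
#' `1/(P*Q) * sum I(yhat+ > yhat-)`, where the high-load class is
#' `y >= 70` (P samples), the low-load class `y < 30` (Q samples), and
#' mid-range samples are excluded from the pair count. Ties contribute 0
#' under the literal strict inequality (default); `ties = "half"` gives the
#' conventional half credit.
#'
#' @param pred Predicted scores.
#' @param truth True labels on the `[0, 100]` scale.
#' @param high,low Class thresholds (defaults 70 and 30).
#' @param ties `"strict"` (default) or `"half"`.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when either class is
#'   empty.
#' @export
pairwise_auc <- function(pred, truth, high = 70, low = 30,
                         ties = c("strict", "half")) {
  ties <- match.arg(ties)
  pos <- pred[truth >= high]
  neg <- pred[truth < low]
  if (length(pos) == 0L || length(neg) == 0L) {
    warning("pairwise AUC undefined: a class is empty")
    return(NA_real_)
  }
  cmp <- outer(pos, neg, `>`)
  score <- sum(cmp)
  if (ties == "half") score <- score + 0.5 * sum(outer(pos, neg, `==`))
  score / (length(pos) * length(neg))
}

#' Assemble an evaluation report
#'
#' Bundles the full metric suite for one model/dataset pairing: score errors
#' (MAE, RMSE, AUC on the predicted vs true load), pose-reconstruction
#' errors (MPJPE, PCK of the processed coordinates against the reference
#' coordinates), and the redundancy (FRC) of the selected feature columns.
#'
#' @param pred_scores,true_scores Predicted and true load labels.
#' @param pred_poses,gt_poses Optional N x 25 x 3 arrays (or lists of
#'   sequences) for the pose-error metrics.
#' @param torso_diag Per-sample torso diagonals for PCK (computed from
#'   `gt_poses` when omitted).
#' @param features Optional matrix of the selected feature columns for FRC.
#' @param tau PCK threshold.
#' @return A list of class `eval_report` with fields `mae`, `rmse`, `mpjpe`,
#'   `pck`, `auc`, `frc`, `n`.
#' @export
evaluate_scores <- function(pred_scores, true_scores, pred_poses = NULL,
                            gt_poses = NULL, torso_diag = NULL,
                            features = NULL, tau = 0.1) {
  mr <- mae_rmse(pred_scores, true_scores)
  rep_mpjpe <- rep_pck <- NA_real_
  if (!is.null(pred_poses) && !is.null(gt_poses)) {
    if (is.list(pred_poses)) pred_poses <- stack_poses(pred_poses)
    if (is.list(gt_poses)) gt_poses <- stack_poses(gt_poses)
    rep_mpjpe <- mpjpe(pred_poses, gt_poses)
    if (is.null(torso_diag)) torso_diag <- torso_diagonal(gt_poses)
    rep_pck <- pck(pred_poses, gt_poses, torso_diag, tau)
  }
  auc <- suppressWarnings(pairwise_auc(pred_scores, true_scores))
  fr <- if (is.null(features)) NA_real_ else frc(features)
  structure(list(mae = unname(mr["mae"]), rmse = unname(mr["rmse"]),
                 mpjpe = rep_mpjpe, pck = rep_pck, auc = auc, frc = fr,
                 n = length(pred_scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  MAE %.3f  RMSE %.3f  MPJPE %s  PCK %s  AUC %s  FRC %s\n",
    x$n, x$mae, x$rmse,
    if (is.na(x$mpjpe)) "-" else sprintf("%.4f m", x$mpjpe),
    if (is.na(x$pck)) "-" else sprintf("%.1f%%", x$pck),
    if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc),
    if (is.na(x$frc)) "-" else sprintf("%.3f", x$frc)))
  invisible(x)
}

# Stack the frames of a list of sequences into one N x 25 x 3 array.
stack_poses <- function(seqs) {
  mats <- lapply(seqs, function(s) flatten_coords(as_coords(s)))
  unflatten_coords(do.call(rbind, mats))
}
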