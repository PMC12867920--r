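test_that("MAE and RMSE match hand arithmetic", {
  expect_equal(mae_rmse(c(1, 2), c(1, 2)), c(mae = 0, rmse = 0))
  mr <- mae_rmse(c(0, 0), c(3, 4))
  expect_equal(unname(mr["mae"]), 3.5)
  expect_equal(unname(mr["rmse"]), sqrt(12.5))
  expect_equal(round(unname(mr["rmse"]), 4), 3.5355)
  expect_error(mae_rmse(numeric(0), numeric(0)), "empty")
  set.seed(4)
  for (r in 1:50) {
    p <- rnorm(20); t <- rnorm(20)
    mr <- mae_rmse(p, t)
    expect_gte(mr["rmse"], mr["mae"] - 1e-12)
  }
})

test_that("MPJPE is the mean per-joint Euclidean distance", {
  gt <- array(rnorm(4 * 75), c(4, 25, 3))
  expect_equal(mpjpe(gt, gt), 0)
  # 3-4-5 translation: every joint off by exactly 0.05 m
  pred <- gt
  pred[, , 1] <- pred[, , 1] + 0.03
  pred[, , 3] <- pred[, , 3] + 0.04
  expect_equal(mpjpe(pred, gt), 0.05)
  # invariant to a joint permutation applied to both arrays
  perm <- sample(25)
  expect_equal(mpjpe(pred[, perm, ], gt[, perm, ]), mpjpe(pred, gt))
  expect_error(mpjpe(gt[1:2, , ], gt), "shape")
})

test_that("PCK counts joints within the torso-normalized threshold", {
  gt <- array(0, c(1, 25, 3))
  expect_equal(pck(gt, gt, torso_diag = 1), 100)
  # deviation exactly at tau counts as correct
  pred <- gt
  pred[1, , 1] <- 0.1
  expect_equal(pck(pred, gt, torso_diag = 1, tau = 0.1), 100)
  # one of two displaced joints within threshold
  pred2 <- gt
  pred2[1, 1, 1] <- 0.05
  pred2[1, 2, 1] <- 0.5
  expect_equal(pck(pred2, gt, torso_diag = 1, tau = 0.1), 24 / 25 * 100)
  # stricter tau never increases PCK
  set.seed(6)
  predr <- gt + array(rnorm(75, sd = 0.05), c(1, 25, 3))
  taus <- c(0.2, 0.1, 0.05, 0.02)
  vals <- vapply(taus, function(tau) pck(predr, gt, 1, tau), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(pck(gt, gt, torso_diag = 0), "positive")
})

test_that("pairwise AUC scores high/low separability with strict ties", {
  truth <- c(90, 85, 75, 10, 20, 50)      # mid-range 50 excluded
  expect_equal(pairwise_auc(c(9, 8, 7, 1, 2, 5), truth), 1)
  expect_equal(pairwise_auc(c(1, 2, 3, 9, 8, 5), truth), 0)
  # ties contribute nothing under the strict rule, half under "half":
  # pos scores (5,5,5) vs neg scores (5,1): 3 wins, 3 ties of 6 pairs
  pred_t <- c(5, 5, 5, 5, 1, 0)
  expect_equal(pairwise_auc(pred_t, truth), 3 / 6)
  expect_equal(pairwise_auc(pred_t, truth, ties = "half"), 3 / 6 + 0.5 * 3 / 6)
  expect_warning(auc_na <- pairwise_auc(c(1, 2), c(40, 50)), "empty")
  expect_true(is.na(auc_na))
})

test_that("pairwise AUC equals the rank formulation on tie-free data", {
  set.seed(9)
  for (r in 1:30) {
    n <- 40
    truth <- c(runif(15, 70, 100), runif(15, 0, 29.9), runif(10, 30, 69))
    pred <- rnorm(n)
    expect_equal(pairwise_auc(pred, truth), rank_auc(pred, truth))
  }
})

test_that("all score metrics are invariant to sample reordering", {
  set.seed(13)
  truth <- c(runif(8, 70, 100), runif(8, 0, 29), runif(4, 30, 69))
  pred <- truth + rnorm(20, sd = 5)
  perm <- sample(20)
  expect_equal(mae_rmse(pred, truth), mae_rmse(pred[perm], truth[perm]))
  expect_equal(pairwise_auc(pred, truth), pairwise_auc(pred[perm], truth[perm]))
})

test_that("a perfect oracle model yields the perfect-score report", {
  set.seed(21)
  truth <- c(runif(10, 70, 100), runif(10, 0, 29))
  poses <- array(rnorm(20 * 75), c(20, 25, 3))
  rep <- evaluate_scores(truth, truth, pred_poses = poses, gt_poses = poses,
                         torso_diag = rep(1, 20))
  expect_equal(rep$mae, 0)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$mpjpe, 0)
  expect_equal(rep$pck, 100)
  expect_equal(rep$auc, 1)
  expect_identical(rep$n, 20L)
})

test_that("implementations agree with brute-force oracles on random instances", {
  set.seed(77)
  for (r in 1:20) {
    n <- sample(6:15, 1)
    truth <- c(runif(ceiling(n / 3), 70, 100), runif(ceiling(n / 3), 0, 29.9),
               runif(n - 2 * ceiling(n / 3) + 2, 30, 69))
    n <- length(truth)
    pred <- truth + rnorm(n, sd = 10)
    gt <- array(rnorm(n * 75), c(n, 25, 3))
    pd <- gt + array(rnorm(n * 75, sd = 0.05), c(n, 25, 3))
    L <- runif(n, 0.5, 1.5)
    feats <- matrix(rnorm(n * 4), n, 4)

    mr <- mae_rmse(pred, truth)
    expect_equal(unname(mr["mae"]), oracle_mae(pred, truth))
    expect_equal(unname(mr["rmse"]), oracle_rmse(pred, truth))
    expect_equal(mpjpe(pd, gt), oracle_mpjpe(pd, gt))
    expect_equal(pck(pd, gt, L, 0.1), oracle_pck(pd, gt, L, 0.1))
    expect_equal(pairwise_auc(pred, truth), oracle_auc(pred, truth))
    expect_equal(frc(feats), oracle_frc(feats))
  }
})

test_that("torso diagonal uses the shoulder-hip extremes", {
  coords <- array(0, c(3, 25, 3))
  topo <- default_skeleton()
  i <- match("l_shoulder", topo$joint_names)
  j <- match("r_hip", topo$joint_names)
  coords[, i, ] <- rep(c(0.3, 0, 0.4), each = 3)
  expect_equal(torso_diagonal(coords), rep(0.5, 3))
})
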