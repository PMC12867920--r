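test_that("coordination entropy matches hand-computed distributions", {
  # all 25 joints move the same distance: uniform maximum log2(25)
  expect_equal(coordination_entropy(path_coords(rep(1, 25))), log2(25))
  # one joint moves: degenerate distribution, 0 bits
  expect_equal(coordination_entropy(path_coords(c(2, rep(0, 24)))), 0)
  # path lengths 3 and 1: -(0.75 log2 0.75 + 0.25 log2 0.25)
  expect_equal(coordination_entropy(path_coords(c(3, 1, rep(0, 23)))),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(round(coordination_entropy(path_coords(c(3, 1, rep(0, 23)))), 4),
               0.8113)
  # zero total motion
  expect_equal(coordination_entropy(array(1, c(5, 25, 3))), 0)
  expect_error(coordination_entropy(array(0, c(1, 25, 3))), "2 frames")
})

test_that("entropy is bounded in [0, log2 25] over random sequences", {
  set.seed(55)
  for (r in 1:200) {
    coords <- array(rnorm(6 * 75), c(6, 25, 3))
    e <- coordination_entropy(coords)
    expect_gte(e, 0)
    expect_lte(e, log2(25) + 1e-12)
  }
  # the maximum is attained only near the uniform path distribution
  expect_lt(coordination_entropy(path_coords(c(10, rep(1, 24)))), log2(25))
})

test_that("composite load applies the fixed weights", {
  expect_equal(composite_load(5, 4, 2, 1), 0.4 * 5 + 0.3 * 4 + 0.2 * 2 + 0.1 * 1)
  expect_equal(composite_load(5, 4, 2, 1), 3.7)
  expect_equal(composite_load(1, 0, 0, 0), 0.4)
  # weights sum to 1: equal inputs pass through
  expect_equal(composite_load(3, 3, 3, 3), 3)
  expect_error(composite_load(0, 1, 1, 1), "\\[1, 5\\]")
  # strict monotonicity in each argument
  base <- composite_load(3, 2, 1.5, 0.4)
  expect_gt(composite_load(4, 2, 1.5, 0.4), base)
  expect_gt(composite_load(3, 2.5, 1.5, 0.4), base)
  expect_gt(composite_load(3, 2, 2.0, 0.4), base)
  expect_gt(composite_load(3, 2, 1.5, 0.9), base)
})

test_that("label scaling maps the corpus onto [0, 100]", {
  expect_equal(scale_labels(c(2, 3, 4)), c(0, 50, 100))
  expect_equal(scale_labels(rep(7, 5)), rep(0, 5))
  set.seed(8)
  y <- rnorm(50)
  s <- scale_labels(y)
  expect_equal(min(s), 0)
  expect_equal(max(s), 100)
  # affine invariance
  expect_equal(scale_labels(3 * y + 11), s)
})

test_that("ICC(2,1) behaves as an absolute-agreement statistic", {
  items <- seq(1, 10, length.out = 20)
  perfect <- cbind(items, items, items)
  expect_equal(icc_reliability(perfect), 1)

  # independent white noise: near zero
  set.seed(42)
  noise <- matrix(rnorm(300), 100, 3)
  expect_lt(abs(icc_reliability(noise)), 0.15)

  # a constant rater bias lowers absolute agreement below 1
  biased <- cbind(items, items + 2, items)
  expect_lt(icc_reliability(biased), 1)
  expect_gt(icc_reliability(biased), 0)

  bad <- perfect; bad[1, 1] <- NA
  expect_error(icc_reliability(bad), "missing")
  expect_error(icc_reliability(matrix(1, 1, 3)), "at least 2")
})

test_that("ICC(2,1) agrees with lme4 variance components on balanced data", {
  library(lme4)
  set.seed(19)
  n <- 60; k <- 4
  item <- rnorm(n, sd = 3)
  rater <- rnorm(k, sd = 1)
  ratings <- outer(item, rep(1, k)) + outer(rep(1, n), rater) +
    matrix(rnorm(n * k), n, k)
  long <- data.frame(value = as.vector(ratings),
                     item = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- suppressMessages(lmer(value ~ 1 + (1 | item) + (1 | rater), data = long))
  vc <- as.data.frame(VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  icc_lmer <- v[["item"]] / (v[["item"]] + v[["rater"]] + v[["Residual"]])
  expect_equal(icc_reliability(ratings), unname(icc_lmer), tolerance = 1e-4)
})

test_that("label table assembly is consistent with its parts", {
  d <- local_dataset()
  lab <- build_labels(d$sequences)
  i <- 7
  expect_equal(lab$E[i], coordination_entropy(d$sequences[[i]]))
  expect_equal(lab$D[i], d$sequences[[i]]$difficulty)
  expect_equal(lab$y, scale_labels(lab$y_raw))
})
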