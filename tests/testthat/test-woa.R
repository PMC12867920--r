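test_that("FRC follows the printed pairwise-correlation formula", {
  set.seed(3)
  # single column: no pairs
  expect_equal(frc(matrix(rnorm(20), 10, 2)[, 1, drop = FALSE]), 0)
  # two identical columns: |corr| = 1, normalized by M^2 = 4
  x <- rnorm(10)
  expect_equal(frc(cbind(x, x)), 0.25)
  # independent white noise, large n: near zero
  big <- matrix(rnorm(2e4), 1e4, 2)
  expect_lt(frc(big), 0.01)
  # constant columns contribute zero
  expect_equal(frc(cbind(x, rep(1, 10))), 0)
  # signed mode lets anticorrelation cancel
  expect_equal(frc(cbind(x, -x), method = "signed"), -0.25)
  expect_equal(frc(cbind(x, -x)), 0.25)
  expect_error(frc(matrix(1, 1, 3)), "2 rows")
})

test_that("fitness is the weighted MAE/FRC sum", {
  expect_equal(woa_fitness(0.1, 0.2), 0.7 * 0.1 + 0.3 * 0.2)
  expect_equal(woa_fitness(0.1, 0.2), 0.13)
  expect_equal(woa_fitness(0.5, 0), 0.35)
  expect_equal(woa_fitness(0, 0), 0)
  expect_error(woa_fitness(1, 1, alpha = 1), "alpha")
})

test_that("the encircling coefficient schedule is exactly linear from 2 to 0", {
  max_iter <- 50
  a <- woa_a_schedule(0:max_iter, max_iter)
  expect_equal(a[1], 2)
  expect_equal(a[max_iter + 1], 0)
  expect_equal(diff(a), rep(-2 / max_iter, max_iter))
})

test_that("position decoding maps blocks to hyperparameters and top-k features", {
  space <- woa_space(lower = c(lr = -4, k = 1.5), upper = c(lr = -2, k = 4.5),
                     integer = c(FALSE, TRUE), log10 = c(TRUE, FALSE),
                     n_mask = 10, n_select = 3)
  dec <- decode_position(c(-3, 3.5, seq(1, 0.1, length.out = 10)), space)
  expect_equal(unname(dec$hyper["lr"]), 1e-3)
  expect_identical(unname(dec$hyper["k"]), 4)  # half-up rounding at .5
  # strictly decreasing logits: first k indices win
  expect_identical(dec$features, 1:3)
  # ties broken toward the lowest index
  dec2 <- decode_position(c(-3, 2, rep(0.7, 10)), space)
  expect_identical(dec2$features, 1:3)
  expect_length(decode_position(c(-3, 2, runif(10)), space)$features, 3L)
  # clipping into bounds
  dec3 <- decode_position(c(-10, 99, runif(10)), space)
  expect_equal(unname(dec3$hyper["lr"]), 1e-4)
  expect_identical(unname(dec3$hyper["k"]), 4)
})

test_that("whale position updates follow the three-branch rule", {
  space <- woa_space(lower = rep(-5, 4), upper = rep(5, 4))
  cfg <- woa_config(max_iter = 50, explore_prob = 0, seed = 1)
  best <- rep(1, 4)
  # population collapsed onto the best: spiral and encircle whales stay put or
  # land exactly on the best (distance terms vanish)
  pop <- matrix(1, 20, 4)
  set.seed(5)
  out <- whale_step(pop, best, t = 25, cfg, space)
  br <- attr(out, "branch")
  for (i in which(br == "spiral")) expect_equal(out[i, ], best)
  # at t = max_iter, a = 0, so |A| = 0 < 1: random search is unreachable
  set.seed(9)
  pop2 <- matrix(runif(80, -5, 5), 20, 4)
  out2 <- whale_step(pop2, best, t = 50, cfg, space)
  expect_false(any(attr(out2, "branch") == "search"))
  # early iterations with a near 2 do exercise the search branch
  set.seed(11)
  branches <- character(0)
  for (r in 1:20) {
    o <- whale_step(pop2, best, t = 1, cfg, space)
    branches <- c(branches, attr(o, "branch"))
  }
  expect_true(all(c("spiral", "encircle", "search") %in% branches))
  # positions always respect the bounds
  expect_true(all(out2 >= -5 & out2 <= 5))
  expect_error(whale_step(pop2[0, , drop = FALSE], best, 1, cfg, space),
               "empty")
})

test_that("the optimizer is elitist, reproducible and runs the full schedule", {
  space <- woa_space(lower = rep(-5, 3), upper = rep(5, 3))
  sphere <- function(dec, pos) list(mae = sum(pos^2), frc = 0)
  cfg <- woa_config(population = 15, max_iter = 30, seed = 2)
  r1 <- woa_optimize(sphere, space, cfg)
  r2 <- woa_optimize(sphere, space, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(nrow(r1$trace), 30L)
  expect_true(all(diff(r1$trace$best_so_far) <= 0))
  expect_lt(r1$best$fitness, 0.7 * 1e-2)
  # failing evaluations are absorbed as +Inf fitness, search continues
  flaky <- function(dec, pos) {
    if (pos[1] > 0) stop("invalid region")
    list(mae = sum(pos^2), frc = 0)
  }
  rf <- woa_optimize(flaky, space, woa_config(population = 10, max_iter = 10,
                                              seed = 3))
  expect_true(is.finite(rf$best$fitness))
  expect_lte(rf$best$position[1], 0)
})

test_that("the dual feature search recovers load-linked slots above chance", {
  d <- generate_dataset(gen_config(n_sequences = 100, frames_per_seq = 20,
                                   seed = 12))
  res <- woa_select_features(d$features[d$splits$train, ],
                             d$labels$y[d$splits$train],
                             woa_config(population = 20, max_iter = 10, seed = 5))
  sel <- res$best$decoded$features
  expect_length(sel, 300L)
  hit_frac <- length(intersect(sel, d$informative_ids)) / length(d$informative_ids)
  chance <- 300 / 512
  expect_gt(hit_frac, chance)
})
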