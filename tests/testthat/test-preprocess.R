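test_that("gray-variance filter drops blurry frames", {
  flat <- matrix(128, 8, 8)                   # variance 0: blurry
  checker <- matrix(c(0, 255), 8, 8)          # variance 127.5^2
  expect_identical(gray_variance_filter(list(flat)), integer(0))
  expect_identical(gray_variance_filter(list(checker)), 1L)
  expect_equal(mean((checker - mean(checker))^2), 16256.25)
  expect_identical(gray_variance_filter(list(flat, checker, flat)), 2L)
  expect_identical(gray_variance_filter(list(flat, checker), threshold = 0), 1:2)
  expect_identical(gray_variance_filter(list()), integer(0))
  expect_error(gray_variance_filter(list(1:5)), "2-D")
})

test_that("min-max normalization follows the affine rule with degenerate axes", {
  stats <- structure(list(x_min = matrix(1, 25, 3), x_max = matrix(3, 25, 3)),
                     class = "normalization_stats")
  coords <- array(2, c(4, 25, 3))
  out <- minmax_normalize(pose_sequence(coords), stats)
  expect_equal(as_array <- out$coords, array(0.5, c(4, 25, 3)))
  # endpoints
  expect_equal(minmax_normalize(pose_sequence(array(1, c(2, 25, 3))), stats)$coords,
               array(0, c(2, 25, 3)))
  expect_equal(minmax_normalize(pose_sequence(array(3, c(2, 25, 3))), stats)$coords,
               array(1, c(2, 25, 3)))
  # degenerate axis maps to 0
  stats$x_max[1, 1] <- stats$x_min[1, 1]
  out <- minmax_normalize(pose_sequence(coords), stats)
  expect_equal(out$coords[, 1, 1], rep(0, 4))
})

test_that("normalization with a sequence's own stats is idempotent", {
  s <- tiny_seq(frames = 20)
  st <- pose_stats(list(s))
  norm1 <- minmax_normalize(s, st)
  st2 <- pose_stats(list(norm1))
  norm2 <- minmax_normalize(norm1, st2)
  expect_equal(norm2$coords, norm1$coords, tolerance = 1e-12)
  expect_true(all(norm1$coords >= 0 & norm1$coords <= 1))
})

test_that("length standardization yields exactly the target frame count", {
  s <- tiny_seq(frames = 100)
  out <- standardize_length(s, 100)
  expect_length(out, 1)
  expect_identical(out[[1]]$coords, s$coords)

  # linear ramp stays linear under interpolation
  ramp <- array(0, c(50, 25, 3))
  for (j in 1:25) ramp[, j, 1] <- seq(0, 1, length.out = 50) * j
  rs <- standardize_length(pose_sequence(ramp), 100)[[1]]
  expect_identical(dim(rs$coords), c(100L, 25L, 3L))
  expect_equal(rs$coords[1, 3, 1], 0)
  expect_equal(rs$coords[100, 3, 1], 3)
  expect_lt(max(abs(diff(diff(rs$coords[, 3, 1])))), 1e-12)

  # beat segmentation: 250 frames with beats at 0/100/200 -> 3 segments
  coords <- array(rnorm(250 * 75), c(250, 25, 3))
  long <- pose_sequence(coords, beat_frames = c(0, 100, 200))
  segs <- standardize_length(long, 100)
  expect_length(segs, 3)
  for (seg in segs) expect_identical(dim(seg$coords)[1], 100L)
  # first two segments are exact cuts at the beats
  expect_equal(segs[[1]]$coords, coords[1:100, , ])
  expect_equal(segs[[2]]$coords, coords[101:200, , ])

  # uniform fallback without beats
  nb <- pose_sequence(coords)
  segs2 <- standardize_length(nb, 100)
  expect_length(segs2, 3)
  expect_error(standardize_length(pose_sequence(array(0, c(1, 25, 3)))), "2 frames")
})

test_that("length law holds for randomized input lengths", {
  set.seed(303)
  for (r in 1:25) {
    n <- sample(2:600, 1)
    coords <- array(rnorm(n * 75, sd = 0.1), c(n, 25, 3))
    beats <- sort(sample(0:(n - 1), min(n, sample(0:8, 1))))
    s <- pose_sequence(coords, beat_frames = beats)
    out <- standardize_length(s, 100)
    expect_true(all(vapply(out, function(x) dim(x$coords)[1], integer(1)) == 100L))
  }
})

test_that("gaussian smoothing preserves constants and matches kernel weights", {
  const <- pose_sequence(array(0.7, c(20, 25, 3)))
  expect_equal(gaussian_smooth(const)$coords, const$coords, tolerance = 1e-12)
  expect_error(gaussian_smooth(const, window = 4), "odd")

  # unit impulse at the centre: response equals the kernel centre weight,
  # computed here from the Gaussian density directly
  sigma <- 0.8
  w <- exp(-(-2:2)^2 / (2 * sigma^2)); w <- w / sum(w)
  coords <- array(0, c(21, 25, 3))
  coords[11, 1, 1] <- 1
  sm <- gaussian_smooth(pose_sequence(coords), window = 5, sigma = sigma)
  expect_equal(sm$coords[11, 1, 1], w[3])
  expect_equal(sm$coords[10, 1, 1], w[2])
  expect_equal(sm$coords[9, 1, 1], w[1])
  expect_equal(gaussian_kernel(5, sigma), w)
})

test_that("smoothing never increases per-channel variance", {
  set.seed(77)
  for (r in 1:10) {
    coords <- array(rnorm(30 * 75), c(30, 25, 3))
    sm <- gaussian_smooth(pose_sequence(coords))$coords
    for (j in sample(1:25, 3)) {
      expect_lte(var(sm[, j, 1]), var(coords[, j, 1]) + 1e-12)
    }
  }
})

test_that("zero-magnitude augmentation is the identity", {
  s <- tiny_seq(frames = 20)
  out <- augment(s, augment_spec(0, 0, 0, seed = 1))
  expect_equal(out$coords, s$coords, tolerance = 1e-12)
  expect_equal(attr(out, "temporal_factor"), 1)
})

test_that("augmentation perturbations respect their declared bounds", {
  s <- tiny_seq(frames = 10, noise_sd = 0)
  st <- pose_stats(list(s))
  norm <- minmax_normalize(s, st)
  # spatial noise on a [0,1]-normalized sequence: bounded by 0.05
  for (seed in 1:300) {
    out <- augment(norm, augment_spec(0, 5, 0, seed = seed))
    expect_lte(max(abs(out$coords - norm$coords)), 0.05 + 1e-12)
  }
  # temporal factor within [0.9, 1.1]
  factors <- vapply(1:300, function(seed)
    attr(augment(norm, augment_spec(10, 0, 0, seed = seed)), "temporal_factor"),
    numeric(1))
  expect_true(all(factors >= 0.9 & factors <= 1.1))
  # angle jitter: every bone rotated by at most 3 degrees, lengths preserved
  topo <- default_skeleton()
  for (seed in 1:20) {
    out <- augment(s, augment_spec(0, 0, 3, seed = seed), topo)
    b0 <- bone_vectors(s, topo)
    b1 <- bone_vectors(out, topo)
    for (bone in seq_len(24)) {
      cols <- (3 * bone - 2):(3 * bone)
      for (t in c(1, 5, 10)) {
        u <- b0[t, cols]; v <- b1[t, cols]
        expect_equal(sqrt(sum(v^2)), sqrt(sum(u^2)), tolerance = 1e-8)
        cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
        expect_gte(cosang, cos(3 * pi / 180) - 1e-9)
      }
    }
  }
})
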