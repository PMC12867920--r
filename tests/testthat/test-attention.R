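test_that("scaled attention reduces to known closed forms", {
  # singleton softmax: weight 1, output = V
  out <- scaled_attention(matrix(1, 1, 4), matrix(2, 1, 4), matrix(3:6, 1, 4))
  expect_equal(out$weights, matrix(1, 1, 1))
  expect_equal(out$output, matrix(3:6, 1, 4))

  # Q orthogonal to every K row: uniform weights, output = column means of V
  Q <- matrix(c(1, 0, 0, 0), 1, 4)
  K <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  V <- matrix(rnorm(12), 3, 4)
  out <- scaled_attention(Q, K, V)
  expect_equal(drop(out$weights), rep(1 / 3, 3))
  expect_equal(drop(out$output), colMeans(V))
  expect_error(scaled_attention(matrix(1, 1, 0), matrix(1, 1, 0), matrix(1, 1, 1)),
               "d_k")
})

test_that("attention rows are a probability distribution on random inputs", {
  set.seed(12)
  for (r in 1:50) {
    n <- sample(2:8, 1); d <- sample(2:6, 1)
    out <- scaled_attention(matrix(rnorm(n * d), n, d),
                            matrix(rnorm(n * d), n, d),
                            matrix(rnorm(n * d), n, d))
    expect_true(all(out$weights >= 0))
    expect_equal(rowSums(out$weights), rep(1, n), tolerance = 1e-6)
  }
})

test_that("gelu is the Gaussian-CDF weighting of its input", {
  expect_equal(gelu(0), 0)
  expect_equal(gelu(10), 10, tolerance = 1e-6)
  expect_equal(gelu(1), pnorm(1), tolerance = 1e-12)
  expect_equal(round(gelu(1), 4), 0.8413)
  expect_equal(gelu(-10), 0, tolerance = 1e-6)
})

test_that("multi-head attention has the declared head geometry", {
  spec <- attention_spec()  # 8 heads, 512 dims
  expect_identical(spec$head_dim, 64L)
  expect_identical(spec$model_dim / spec$heads, 64)
  expect_error(attention_spec(heads = 7, model_dim = 512), "divisible")

  small <- attention_spec(heads = 2, model_dim = 8, seed = 4)
  x <- matrix(rnorm(40), 5, 8)
  y <- multi_head(x, small)
  expect_identical(dim(y), dim(x))
})

test_that("one identity-projected head reduces to scaled attention", {
  d <- 6
  spec <- structure(list(heads = 1L, model_dim = d, head_dim = d, dropout = 0,
                         Wq = list(diag(d)), Wk = list(diag(d)),
                         Wv = list(diag(d)), Wo = diag(d)),
                    class = "attention_spec")
  x <- matrix(rnorm(30), 5, d)
  expect_equal(multi_head(x, spec), scaled_attention(x, x, x)$output,
               tolerance = 1e-12)
})

test_that("encoder maps local features to the global width with a pooled summary", {
  params <- encoder_init(tiny_enc(), seed = 2)
  x <- matrix(rnorm(10 * 6), 10, 6)
  out <- encoder_forward(params, x)
  expect_identical(dim(out$seq), c(10L, 8L))
  expect_length(out$pooled, 8L)
  expect_equal(out$pooled, colMeans(out$seq))
  # eval-mode determinism
  expect_identical(out$seq, encoder_forward(params, x)$seq)
  expect_error(encoder_forward(params, matrix(0, 4, 5)), "input_dim")
})

test_that("full-width encoder emits 512-dimensional global features", {
  params <- encoder_init(encoder_config(), seed = 1)
  x <- matrix(rnorm(8 * 256, sd = 0.5), 8, 256)
  out <- encoder_forward(params, x)
  expect_identical(dim(out$seq), c(8L, 512L))
  expect_length(out$pooled, 512L)
})

test_that("positional encoding controls permutation sensitivity", {
  set.seed(31)
  x <- matrix(rnorm(12 * 6), 12, 6)
  perm <- sample(12)
  with_pe <- encoder_init(tiny_enc(positional = TRUE), seed = 3)
  no_pe <- encoder_init(tiny_enc(positional = FALSE), seed = 3)
  expect_false(isTRUE(all.equal(encoder_forward(with_pe, x)$pooled,
                                encoder_forward(with_pe, x[perm, ])$pooled)))
  expect_equal(encoder_forward(no_pe, x)$pooled,
               encoder_forward(no_pe, x[perm, ])$pooled, tolerance = 1e-10)
})

test_that("zeroed attention and feed-forward blocks make layers LayerNorm-only", {
  params <- encoder_init(tiny_enc(layers = 1, positional = FALSE), seed = 6)
  params$layers[[1]]$attn$Wo[] <- 0
  params$layers[[1]]$ffn$W2[] <- 0
  x <- matrix(rnorm(5 * 6), 5, 6)
  lifted <- t(t(x %*% params$lift$W) + params$lift$b)
  expected <- layer_norm(layer_norm(lifted))
  expect_equal(encoder_forward(params, x)$seq, expected, tolerance = 1e-12)
})

test_that("dropout draws are seeded and only active in training mode", {
  params <- encoder_init(tiny_enc(dropout = 0.5), seed = 8)
  x <- matrix(rnorm(10 * 6), 10, 6)
  eval1 <- encoder_forward(params, x, training = FALSE)$seq
  eval2 <- encoder_forward(params, x, training = FALSE)$seq
  expect_identical(eval1, eval2)
  tr1 <- cogload:::with_seed(5, encoder_forward(params, x, training = TRUE)$seq)
  tr2 <- cogload:::with_seed(5, encoder_forward(params, x, training = TRUE)$seq)
  expect_identical(tr1, tr2)
  expect_false(identical(tr1, eval1))
})
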