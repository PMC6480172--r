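test_that("architecture specs follow the filter-length and pooling rules", {
  s3 <- cnn_spec(3, input_len = 600, fs = 300, n_classes = 3)
  expect_equal(s3$filter_lengths, c(300L, 150L, 75L))
  expect_true(all(s3$pool_after_block))
  expect_equal(s3$stage_lengths, c(300L, 150L, 75L))
  expect_equal(s3$flatten_len, 750L) # 10 filters x 75 samples

  s8 <- cnn_spec(8, input_len = 1200, fs = 300, n_classes = 3)
  expect_equal(s8$pool_after_block, c(rep(TRUE, 6), FALSE, TRUE))
  expect_equal(s8$filter_lengths[8], s8$filter_lengths[7])
  expect_equal(s8$filter_lengths[1:7], c(300L, 150L, 75L, 37L, 18L, 9L, 4L))

  s6 <- cnn_spec(6, input_len = 1200, fs = 300, n_classes = 3)
  expect_equal(s6$stage_lengths[6], 18L)
  expect_equal(s6$flatten_len, 180L)

  expect_error(cnn_spec(2, 600, 300), class = "cecg_invalid_depth")
  expect_error(cnn_spec(9, 600, 300), class = "cecg_invalid_depth")
  expect_error(cnn_spec(8, input_len = 8, fs = 300),
               class = "cecg_degenerate_architecture")
})

test_that("the depth sweep yields 6 distinct variants with closed-form sizes", {
  for (input_len in c(600L, 1200L)) {
    specs <- lapply(3:8, cnn_spec, input_len = input_len, fs = 300,
                    n_classes = 3)
    expect_length(unique(vapply(specs, function(s)
      paste(s$n_blocks, s$flatten_len), character(1))), 6)
    for (s in specs) {
      # brute-force per-stage simulation of the pooling cascade
      len <- input_len
      for (r in seq_len(s$n_blocks)) {
        if (s$pool_after_block[r]) len <- floor(len / 2)
        expect_equal(s$stage_lengths[r], len)
      }
      expect_equal(s$flatten_len, 10L * len)
      # parameter count re-derived independently: conv kernels + biases,
      # two BN parameters per filter, dense weights + biases
      cin <- c(1L, rep(10L, s$n_blocks - 1))
      expect_equal(s$n_params,
                   sum(s$filter_lengths * cin * 10L + 10L + 20L) +
                     s$flatten_len * 3L + 3L)
    }
  }
})

test_that("spec JSON serialization round-trips", {
  s <- cnn_spec(5, input_len = 600, fs = 300, n_classes = 3)
  expect_equal(cnn_spec_from_json(cnn_spec_to_json(s)), s)
})

test_that("relu is the standard rectifier", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(2), 2)
  for (x in c(-3, 0, 5)) expect_equal(relu(relu(x)), relu(x))
  m <- matrix(c(-1, 2, -3, 4), 2)
  expect_equal(relu(m), matrix(c(0, 2, 0, 4), 2))
})

test_that("batch normalization matches its algebraic identities", {
  expect_equal(batch_normalize(c(0, 0, 0, 0), gamma = 1, beta = 5),
               rep(5, 4))
  expect_equal(batch_normalize(c(1, 3), gamma = 1, beta = 0, eps = 0),
               c(-1, 1))
  expect_equal(batch_normalize(rnorm(10), gamma = 0, beta = 2.5),
               rep(2.5, 10))
  # with gamma=1, beta=0: mean 0, variance shrunk by var/(var+eps)
  set.seed(2)
  x <- rnorm(400, 3, 2)
  y <- batch_normalize(x, eps = 0.001)
  v <- mean((x - mean(x))^2)
  expect_equal(mean(y), 0, tolerance = 1e-9)
  expect_equal(mean(y^2), v / (v + 0.001), tolerance = 1e-9)
  expect_error(batch_normalize(1), class = "cecg_invalid_batch")
})

test_that("softmax is stable, shift-invariant and lives on the simplex", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  big <- softmax(c(1000, 0, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  set.seed(3)
  X <- matrix(rnorm(30000, sd = 5), 10000, 3)
  P <- softmax(X)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 10000), tolerance = 1e-12)
  expect_equal(softmax(X + 7), P, tolerance = 1e-12) # shift invariance
})

test_that("FFT convolution agrees with the direct im2col reference", {
  set.seed(4)
  cases <- list(c(64, 4, 1, 3, 7), c(50, 3, 4, 5, 11), c(37, 8, 10, 10, 9),
                c(20, 2, 2, 3, 31)) # includes kernel longer than the input
  for (cs in cases) {
    L <- cs[1]; B <- cs[2]; C <- cs[3]; F <- cs[4]; k <- cs[5]
    A <- array(rnorm(L * B * C), c(L, B, C))
    W <- matrix(rnorm(k * C * F), k * C, F)
    b <- rnorm(F)
    dZ <- array(rnorm(L * B * F), c(L, B, F))
    expect_equal(cecg:::cpp_conv1d_fw(A, W, b, k),
                 cecg:::cpp_conv1d_fw_ref(A, W, b, k), tolerance = 1e-10)
    g1 <- cecg:::cpp_conv1d_bw(A, W, dZ, k)
    g2 <- cecg:::cpp_conv1d_bw_ref(A, W, dZ, k)
    expect_equal(g1$dW, g2$dW, tolerance = 1e-10)
    expect_equal(g1$db, g2$db, tolerance = 1e-10)
    expect_equal(g1$dA, g2$dA, tolerance = 1e-10)
  }
})

test_that("max pooling halves the length and routes gradients to the max", {
  A <- array(c(1, 3, 2, 2, 5, 4, 0, -1), c(4, 2, 1))
  P <- cecg:::cpp_maxpool_fw(A)
  expect_equal(dim(P), c(2, 2, 1))
  expect_equal(as.numeric(P[, 1, 1]), c(3, 2))
  dZ <- array(1, c(2, 2, 1))
  dA <- cecg:::cpp_maxpool_bw(A, dZ)
  expect_equal(as.numeric(dA[, 1, 1]), c(0, 1, 1, 0))
  # odd length drops the trailing sample
  expect_equal(dim(cecg:::cpp_maxpool_fw(array(rnorm(5 * 2), c(5, 2, 1)))),
               c(2, 2, 1))
})

test_that("forward pass yields simplex outputs for every grid cell", {
  set.seed(5)
  X <- matrix(rnorm(3 * 1200), 3, 1200)
  for (input_len in c(600L, 1200L)) {
    for (d in 3:8) {
      spec <- cnn_spec(d, input_len = input_len, fs = 300, n_classes = 3)
      params <- cecg:::init_params(spec)
      out <- cecg:::net_forward(params, spec, X[, 1:input_len],
                                training = FALSE)
      expect_equal(dim(out$probs), c(3L, 3L))
      expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
    }
  }
})

test_that("backpropagated gradients match finite differences", {
  # tiny network: fs = 16 gives kernels 16/8/4 on a 64-sample input
  spec <- cnn_spec(3, input_len = 64, fs = 16, n_classes = 2,
                   dropout_rate = 0)
  set.seed(6)
  params <- cecg:::init_params(spec)
  X <- matrix(rnorm(4 * 64), 4, 64)
  y <- c(1L, 2L, 1L, 2L)
  loss_at <- function(p) {
    fw <- cecg:::net_forward(p, spec, X, training = TRUE)
    cecg:::xent_loss(fw$probs, y)
  }
  fw <- cecg:::net_forward(params, spec, X, training = TRUE)
  gr <- cecg:::net_backward(params, spec, fw, y)
  eps <- 1e-5
  check <- function(get, set, ganal, label) {
    for (i in seq_len(5)) {
      p2 <- params
      idx <- sample(length(get(p2)), 1)
      v <- get(p2)[idx]
      pp <- p2; tmp <- get(pp); tmp[idx] <- v + eps
      pp <- set(pp, tmp); up <- loss_at(pp)
      pm <- p2; tmp <- get(pm); tmp[idx] <- v - eps
      pm <- set(pm, tmp); dn <- loss_at(pm)
      expect_equal(ganal[idx], (up - dn) / (2 * eps), tolerance = 1e-4,
                   label = paste(label, "index", idx))
    }
  }
  for (r in 1:3) {
    check(function(p) p$blocks[[r]]$W,
          function(p, v) { p$blocks[[r]]$W <- v; p }, gr$blocks[[r]]$W,
          paste("conv W block", r))
    check(function(p) p$blocks[[r]]$gamma,
          function(p, v) { p$blocks[[r]]$gamma <- v; p }, gr$blocks[[r]]$gamma,
          paste("bn gamma block", r))
  }
  check(function(p) p$dense$W, function(p, v) { p$dense$W <- v; p },
        gr$dense$W, "dense W")
  check(function(p) p$dense$b, function(p, v) { p$dense$b <- v; p },
        gr$dense$b, "dense b")
})
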