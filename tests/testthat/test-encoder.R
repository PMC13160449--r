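test_that("local propagation is the plain operator product", {
  prev <- matrix(1:6, 3, 2)
  expect_equal(local_propagate(Matrix::Diagonal(3), prev), prev,
               ignore_attr = TRUE)
  # all-0.5 operator on two cells averages the rows
  op <- matrix(0.5, 2, 2)
  pr <- rbind(c(1, 3), c(5, 7))
  expect_equal(local_propagate(op, pr),
               rbind(c(3, 5), c(3, 5)), ignore_attr = TRUE)
  # row-stochastic operator preserves constant inputs
  rs <- withr::with_seed(1, matrix(runif(16), 4, 4))
  rs <- rs / rowSums(rs)
  const <- matrix(rep(c(2, -1), each = 4), 4, 2)
  expect_equal(local_propagate(rs, const), const, tolerance = 1e-12)
  expect_error(local_propagate(diag(3), matrix(0, 2, 2)), "dimensions")
})

test_that("global propagation factors through the K-dimensional bottleneck", {
  base <- withr::with_seed(2, matrix(rnorm(12), 4, 3))
  prev <- withr::with_seed(3, matrix(rnorm(12), 4, 3))
  # W = 0 -> zero output; identity incidence -> identity map
  expect_equal(global_propagate(base, matrix(0, 3, 5), prev),
               matrix(0, 4, 3))
  prev3 <- withr::with_seed(4, matrix(rnorm(9), 3, 3))
  expect_equal(global_propagate(diag(3), diag(3), prev3), prev3)
  # n = 1: output = ||h||^2 * prev
  b1 <- matrix(c(1, 2), 1, 2)
  w1 <- matrix(c(1, 0, 0, 1), 2, 2)
  p1 <- matrix(c(3, 4), 1, 2)
  expect_equal(global_propagate(b1, w1, p1), (1 + 4) * p1)
  # factored evaluation equals the explicit (HH^T) prev product
  for (s in 1:10) {
    W <- withr::with_seed(s, matrix(rnorm(3 * 6), 3, 6))
    h <- base %*% W
    expect_equal(global_propagate(base, W, prev),
                 (h %*% t(h)) %*% prev, tolerance = 1e-10)
  }
})

test_that("contrastive loss matches closed forms and a brute-force oracle", {
  # single cell: partition function is the positive itself -> loss 0
  e1 <- matrix(c(1, 2), 1, 2)
  expect_equal(contrastive_loss(list(e1), list(2 * e1), tau = 0.7), 0)

  # all pairwise similarities equal (identical rows): loss = n * L * ln n
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(contrastive_loss(list(same, same), list(same, same), tau = 0.5),
               8 * log(4), tolerance = 1e-9)

  # n = 2, tau = 1, sim(i,i) = 1, cross-sims 0 -> 2 * ln(1 + exp(-1))
  lo <- rbind(c(1, 0), c(0, 1))
  expect_equal(contrastive_loss(list(lo), list(lo), tau = 1),
               2 * log(1 + exp(-1)), tolerance = 1e-9)

  # loss is non-negative and equals the double-loop oracle on random input
  for (s in 1:10) {
    eb <- withr::with_seed(s, matrix(rnorm(15), 5, 3))
    et <- withr::with_seed(s + 50, matrix(rnorm(15), 5, 3))
    got <- contrastive_loss(list(eb, et), list(et, eb), tau = 0.5)
    want <- brute_force_contrastive(list(eb, et), list(et, eb), 0.5)
    expect_equal(got, want, tolerance = 1e-10)
    expect_gte(got, 0)
  }
  # zero-norm rows use similarity 0 instead of NaN
  z <- rbind(c(0, 0), c(1, 1))
  expect_true(is.finite(contrastive_loss(list(z), list(z), tau = 0.5)))
  expect_error(contrastive_loss(list(z), list(z), tau = 0), "tau")
})

test_that("analytic encoder gradient agrees with numerical differentiation", {
  n <- 6; d <- 3; K <- 4
  init <- withr::with_seed(11, matrix(rnorm(n * d), n, d))
  a <- withr::with_seed(12, matrix(runif(n * n), n, n))
  a <- (a + t(a)) / 2; diag(a) <- 0
  nb <- normalize_adjacency(list(adjacency = Matrix::Matrix(a, sparse = TRUE)))
  W <- withr::with_seed(13, matrix(rnorm(d * K, sd = 0.3), d, K))
  tau <- 0.5; lambda <- 0.01
  obj <- function(wv) {
    Wm <- matrix(wv, d, K)
    fw <- mmihcl:::encoder_forward(init, nb$normalized, Wm, L = 2)
    contrastive_loss(fw$local, fw$global, tau) + lambda * sum(Wm^2)
  }
  fw <- mmihcl:::encoder_forward(init, nb$normalized, W, L = 2)
  got <- mmihcl:::encoder_backward(init, nb$normalized, W, fw, tau, lambda)
  eps <- 1e-6
  num <- matrix(0, d, K)
  for (i in seq_len(d * K)) {
    wp <- as.vector(W); wm <- as.vector(W)
    wp[i] <- wp[i] + eps; wm[i] <- wm[i] - eps
    num[i] <- (obj(wp) - obj(wm)) / (2 * eps)
  }
  expect_equal(got$grad, num, tolerance = 1e-5)
  expect_equal(got$loss, obj(as.vector(W)), tolerance = 1e-10)
})

test_that("encoder training is seeded, regularized and fusion-consistent", {
  sim <- small_sim(seed = 5, nx = 60, ny = 60)
  init <- sim$x$values[, 1:10]
  g <- aknn_graph(init, k = 10)
  cfg <- encoder_config(epochs = 15, K = 8, seed = 42)

  st <- train_encoder(init, g$normalized, cfg)
  # fusion identity: fused = sum over layers of both branches
  expect_equal(st$fused,
               Reduce(`+`, Map(`+`, st$local_layers, st$global_layers)),
               tolerance = 1e-12)
  # determinism
  st2 <- train_encoder(init, g$normalized, cfg)
  expect_identical(st$fused, st2$fused)

  # epochs = 0 leaves W at its seeded init but still defines the output
  st0 <- train_encoder(init, g$normalized,
                       encoder_config(epochs = 0, K = 8, seed = 42))
  expect_length(st0$loss_trace, 0)
  expect_true(all(is.finite(st0$fused)))

  # huge weight decay shrinks W below its initial norm
  stw <- train_encoder(init, g$normalized,
                       encoder_config(epochs = 30, K = 8, lambda = 1e6,
                                      seed = 42))
  expect_lt(sum(stw$W^2), sum(st0$W^2))

  # encode() preserves shape; changing K changes the embedding
  e1 <- encode(init, g$normalized, encoder_config(epochs = 5, K = 8, seed = 1))
  expect_equal(dim(e1), dim(init))
  e2 <- encode(init, g$normalized, encoder_config(epochs = 5, K = 16, seed = 1))
  expect_false(isTRUE(all.equal(e1, e2)))
})

test_that("training lowers the contrastive objective on most seeds", {
  sim <- small_sim(seed = 9, nx = 80, ny = 80)
  init <- sim$x$values[, 1:15]
  g <- aknn_graph(init, k = 15)
  improved <- vapply(1:5, function(s) {
    st <- train_encoder(init, g$normalized,
                        encoder_config(epochs = 25, K = 16, seed = s))
    st$loss_trace[length(st$loss_trace)] <= st$loss_trace[1]
  }, logical(1))
  expect_gte(sum(improved), 4)
})
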