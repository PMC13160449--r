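test_that("PCA scores are deterministic, sign-fixed and variance-ordered", {
  v <- withr::with_seed(3, matrix(rnorm(500), 50, 10))
  s1 <- reduce_dimension(v, 5)
  s2 <- reduce_dimension(v, 5)
  expect_identical(s1, s2)
  vars <- apply(s1, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  # eigen-spectrum oracle: score variances equal covariance eigenvalues
  ev <- eigen(cov(v), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(vars), ev[1:5], tolerance = 1e-8)

  # rank-1 matrix reconstructs exactly from one component
  r1 <- withr::with_seed(4, tcrossprod(rnorm(20), rnorm(6)))
  s <- reduce_dimension(r1, 1)
  recon <- s %*% t(attr(s, "rotation"))
  recon <- sweep(recon, 2, attr(s, "center"), "+")
  expect_equal(recon, r1, tolerance = 1e-8)

  # full-rank retention preserves total variance
  sfull <- reduce_dimension(v, 10)
  expect_equal(sum(apply(sfull, 2, var)), sum(apply(v, 2, var)),
               tolerance = 1e-8)
  expect_error(reduce_dimension(v, 11), "n_components")
})

test_that("kNN candidate weights follow the declared similarity maps", {
  # identical cells -> cosine01 weight 1; orthogonal unit vectors -> 0.5
  sc <- rbind(c(1, 0), c(1, 0), c(0, 1))
  cand <- knn_candidates(sc, k = 2, weight_fn = "cosine01")
  expect_equal(cand$w[1, 1], 1.0)
  expect_equal(cand$idx[1, 1], 2L)
  expect_equal(cand$w[1, 2], 0.5)

  # inv_dist on collinear points: nearest neighbour wins
  sc3 <- cbind(c(0, 1, 3), 0)
  c3 <- knn_candidates(sc3, k = 1, weight_fn = "inv_dist")
  expect_equal(c3$idx[, 1], c(2L, 1L, 2L))
  expect_equal(c3$w[1, 1], 1 / (1 + 1))

  expect_warning(knn_candidates(sc3, k = 5), "clipped")
})

test_that("adaptive pruning reproduces the closed-form hand examples", {
  mk <- function(w) structure(list(idx = matrix(seq_along(w) + 1L, 1),
                                   w = matrix(w, 1), k = length(w),
                                   metric = "cosine01"),
                              class = "neighbor_candidates")
  # mean 0.6, t = 1 - 0.16 = 0.84 -> only 0.9 retained
  p1 <- adaptive_prune(mk(c(0.9, 0.8, 0.1)), delta = 0)
  expect_equal(p1$adaptive_k, 1L)
  expect_equal(p1$threshold, 0.84)
  # t = 1 - 0.49 = 0.51 -> all retained
  p2 <- adaptive_prune(mk(c(0.7, 0.7, 0.7)), delta = -1)
  expect_equal(p2$adaptive_k, 3L)
  # degenerate all-ones: strict inequality fails -> forced top-1
  p3 <- adaptive_prune(mk(c(1, 1, 1)), delta = 0)
  expect_equal(p3$adaptive_k, 1L)
  expect_error(adaptive_prune(mk(c(0.1, 0.9)), 0), "descending")
  expect_error(adaptive_prune(mk(c(0.9, 0.1)), 0.5), "delta")
})

test_that("adaptive pruning agrees with the brute-force threshold test", {
  for (case in 1:200) {
    w <- withr::with_seed(case, sort(runif(5), decreasing = TRUE))
    delta <- withr::with_seed(case + 1000, -runif(1, 0, 2))
    cand <- structure(list(idx = matrix(2:6, 1), w = matrix(w, 1), k = 5,
                           metric = "cosine01"),
                      class = "neighbor_candidates")
    got <- adaptive_prune(cand, delta)
    want <- brute_force_prune(w, delta)
    expect_equal(got$adaptive_k, length(want))
    expect_equal(got$edges[, "w"], w[want], ignore_attr = TRUE)
  }
})

test_that("retained neighbour counts shrink as delta rises through the monotone regime", {
  # the retention threshold 1 - (mean(w) - 1 - delta)^2 grows with delta
  # for delta <= mean(w) - 1, so k_i is non-increasing on delta in [-2, -1]
  for (s in 1:20) {
    w <- withr::with_seed(s, sort(runif(8), decreasing = TRUE))
    cand <- structure(list(idx = matrix(2:9, 1), w = matrix(w, 1), k = 8,
                           metric = "cosine01"),
                      class = "neighbor_candidates")
    ks <- vapply(seq(-2, -1, by = 0.1),
                 function(d) adaptive_prune(cand, d)$adaptive_k, integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("adjacency is max-symmetrized with zero diagonal", {
  pr <- structure(list(edges = cbind(i = 1L, j = 2L, w = 0.8),
                       adaptive_k = c(1L, 0L, 0L), n = 3L),
                  class = "aknn_pruned")
  g <- build_adjacency(pr)
  expect_equal(g$adjacency[1, 2], 0.8)
  expect_equal(g$adjacency[2, 1], 0.8)
  expect_true(all(Matrix::diag(g$adjacency) == 0))

  # conflicting weights on the same unordered pair: max wins
  pr2 <- structure(list(edges = cbind(i = c(1L, 2L), j = c(2L, 1L),
                                      w = c(0.6, 0.9)),
                        adaptive_k = c(1L, 1L), n = 2L),
                   class = "aknn_pruned")
  g2 <- build_adjacency(pr2)
  expect_equal(g2$adjacency[1, 2], 0.9)
  expect_equal(g2$adjacency[2, 1], 0.9)
})

test_that("normalized operator matches hand computations and stays contractive", {
  # no edges -> identity
  g0 <- normalize_adjacency(list(adjacency = Matrix::Matrix(0, 3, 3), n = 3))
  expect_equal(as.matrix(g0$normalized), diag(3), ignore_attr = TRUE)

  # two cells, mutual weight 1: D = diag(2,2), all entries 0.5
  g1 <- build_adjacency(structure(list(
    edges = cbind(i = 1L, j = 2L, w = 1), adaptive_k = c(1L, 1L), n = 2L),
    class = "aknn_pruned"))
  g1 <- normalize_adjacency(g1)
  expect_equal(as.matrix(g1$normalized), matrix(0.5, 2, 2), ignore_attr = TRUE)

  # random symmetric adjacencies: symmetric operator, spectral radius <= 1
  for (s in 1:10) {
    a <- withr::with_seed(s, matrix(runif(36), 6, 6))
    a <- (a + t(a)) / 2; diag(a) <- 0
    gn <- normalize_adjacency(list(adjacency = Matrix::Matrix(a, sparse = TRUE)))
    nm <- as.matrix(gn$normalized)
    expect_equal(nm, t(nm), tolerance = 1e-12)
    expect_lte(max(abs(eigen(nm, only.values = TRUE)$values)), 1 + 1e-10)
    # rows finite; operator applied to all-ones stays in (0, sqrt(n)]
    v <- nm %*% rep(1, 6)
    expect_true(all(is.finite(v)) && all(v > 0) && all(v <= sqrt(6) + 1e-12))
  }

  # the alternative right-scaled variant is asymmetric once degrees differ
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  g2 <- normalize_adjacency(list(adjacency = Matrix::Matrix(chain, sparse = TRUE)),
                            symmetric = FALSE)
  expect_false(isTRUE(all.equal(as.matrix(g2$normalized),
                                t(as.matrix(g2$normalized)))))
})

test_that("aknn_graph produces valid per-cell neighbourhood sizes end to end", {
  sim <- small_sim(seed = 21, nx = 300, ny = 300)
  g <- aknn_graph(sim$x$values, k = 30, delta = -0.5)
  expect_length(g$adaptive_k, 300)
  expect_true(all(g$adaptive_k >= 1 & g$adaptive_k <= 30))
  expect_equal(dim(g$adjacency), c(300L, 300L))
  expect_true(all(g$adjacency@x >= 0 & g$adjacency@x <= 1))
  expect_true(all(is.finite(g$normalized@x)))
  # every cell has at least its forced top neighbour
  expect_true(all(Matrix::rowSums(g$adjacency > 0) >= 1))

  path <- withr::local_tempfile(fileext = ".tsv")
  kpath <- withr::local_tempfile(fileext = ".tsv")
  write_graph_edges(g, path, kpath)
  edges <- read.delim(path)
  expect_true(all(edges$weight > 0 & edges$weight <= 1))
  expect_equal(nrow(read.delim(kpath)), 300L)
})
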