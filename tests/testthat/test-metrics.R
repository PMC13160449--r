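test_that("matching accuracy counts label-consistent triples", {
  m <- matching_pairs(x = 1:4, y = c(1, 2, 3, 4), degree = rep(0.1, 4),
                      nx = 4, ny = 4)
  lab <- c("a", "a", "b", "b")
  expect_equal(matching_accuracy(m, lab, lab), 1.0)
  expect_equal(matching_accuracy(m, lab, c("a", "b", "b", "b")), 0.75)
  expect_equal(matching_accuracy(m, lab, rev(lab)), 0.0)
  expect_error(matching_accuracy(m, lab, c("a", NA, "b", "b")),
               "missing label")
})

test_that("FOSCTTM hits its boundary cases and its permutation expectation", {
  emb <- withr::with_seed(1, matrix(rnorm(20), 10, 2))
  tp <- cbind(1:10, 1:10)
  expect_equal(foscttm(emb, emb, tp), 0)

  # n = 2 with every true match the farthest cell -> exactly 1
  x2 <- rbind(c(0, 0), c(10, 10))
  y2 <- rbind(c(10, 10), c(0, 0))
  expect_equal(foscttm(x2, y2, cbind(1:2, 1:2)), 1)

  # random embeddings average to 1/2 under the (n-1) normalizer
  vals <- vapply(1:20, function(s) {
    xa <- withr::with_seed(s, matrix(rnorm(200 * 3), 200, 3))
    ya <- withr::with_seed(s + 500, matrix(rnorm(200 * 3), 200, 3))
    foscttm(xa, ya, cbind(1:200, 1:200))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.5), 0.05)
  expect_error(foscttm(emb, emb, NULL), "true pairing")
})

test_that("clustering scores recover planted structure and are null-calibrated", {
  # three well-separated blobs: perfect recovery
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  lab <- rep(1:3, each = 40)
  emb <- centers[lab, ] + withr::with_seed(2, matrix(rnorm(240, sd = 0.4),
                                                     120, 2))
  cs <- clustering_scores(emb, lab, seed = 1)
  expect_equal(cs$nmi, 1, tolerance = 1e-9)
  expect_equal(cs$ari, 1, tolerance = 1e-9)
  csk <- clustering_scores(emb, lab, method = "kmeans", seed = 1)
  expect_equal(csk$ari, 1, tolerance = 1e-9)

  # random label shuffles: ARI concentrates near 0
  aris <- vapply(1:20, function(s) {
    shuffled <- withr::with_seed(s, sample(lab))
    clustering_scores(emb, shuffled, resolutions = c(0.5, 1), seed = 1)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)

  expect_warning(out <- clustering_scores(emb, rep(1, 120)), "single label")
  expect_equal(out$nmi, 0)
})

test_that("silhouette scores separate labels and reward batch mixing", {
  centers <- rbind(c(0, 0), c(15, 0))
  lab <- rep(c("t1", "t2"), each = 60)
  base <- centers[rep(1:2, each = 60), ] +
    withr::with_seed(3, matrix(rnorm(240, sd = 0.5), 120, 2))
  batch_mixed <- rep(c("x", "y"), 60)
  s1 <- silhouette_scores(base, lab, batch_mixed)
  expect_gt(s1$asw_label, 0.9)
  expect_gt(s1$asw_batch, 0.9)

  # batches fully separated within each label -> asw_batch near 0
  shift <- ifelse(batch_mixed == "x", 0, 6)
  s2 <- silhouette_scores(base + cbind(shift, 0), lab, batch_mixed)
  expect_lt(s2$asw_batch, 0.2)

  # random labels on one isotropic blob: silhouette ~ 0 -> asw_label ~ 0.5
  blob <- withr::with_seed(4, matrix(rnorm(300), 150, 2))
  s3 <- silhouette_scores(blob, rep(c("a", "b"), 75),
                          rep(c("x", "y"), each = 75))
  expect_lt(abs(s3$asw_label - 0.5), 0.1)
  expect_error(silhouette_scores(base, lab, rep("x", 120)), "one batch")
})

test_that("graph connectivity counts largest components per class", {
  # one compact class -> 1
  emb <- withr::with_seed(5, matrix(rnorm(80), 40, 2))
  expect_equal(graph_connectivity(emb, rep("a", 40), k_gc = 5), 1)

  # a class split into two equal distant islands scores 0.5 at small k
  islands <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
                   matrix(rnorm(40, sd = 0.1) + 100, 20, 2))
  mixed <- rbind(islands, matrix(rnorm(20, sd = 0.1), 10, 2))
  labs <- c(rep("split", 40), rep("tight", 10))
  gcv <- graph_connectivity(mixed, labs, k_gc = 3)
  expect_equal(gcv, mean(c(0.5, 1)))
  expect_lte(gcv, 1)
})

test_that("nested scores implement the weighted scorecard with clipping", {
  # all-perfect paired report
  s <- overall_score(acc = 1, foscttm = 0, nmi = 1, ari = 1, asw_label = 1,
                     gc = 1, asw_batch = 1)
  expect_equal(s$s_bio, 1)
  expect_equal(s$s_batch, 1)
  expect_equal(s$s_overall, 1)

  # hand case with negative ARI clipped to zero, N_bio = 5 when paired
  s2 <- overall_score(acc = 0.5, foscttm = 0.5, nmi = 0.5, ari = -0.2,
                      asw_label = 0.5, gc = 0.8, asw_batch = 0.6)
  expect_equal(s2$s_bio, 0.4)
  expect_equal(s2$s_batch, 0.7)
  expect_equal(s2$s_overall, 0.6 * 0.4 + 0.4 * 0.7)

  # unpaired: FOSCTTM term and its denominator slot drop out (N_bio = 4)
  s3 <- overall_score(acc = 0.8, foscttm = NULL, nmi = 0.6, ari = 0.4,
                      asw_label = 0.6, gc = 1, asw_batch = 1)
  expect_equal(s3$s_bio, (0.8 + 0.6 + 0.4 + 0.6) / 4)
  expect_error(overall_score(acc = 1.2, foscttm = 0, nmi = 1, ari = 1,
                             asw_label = 1, gc = 1, asw_batch = 1), "acc")
})

test_that("scores stay in [0,1] and respond monotonically to base metrics", {
  for (s in 1:1000) {
    v <- withr::with_seed(s, runif(7))
    ari <- withr::with_seed(s + 5000, runif(1, -1, 1))
    paired <- s %% 2 == 0
    sc <- overall_score(acc = v[1], foscttm = if (paired) v[2], nmi = v[3],
                        ari = ari, asw_label = v[4], gc = v[5],
                        asw_batch = v[6], paired = paired)
    expect_true(sc$s_bio >= 0 && sc$s_bio <= 1)
    expect_true(sc$s_batch >= 0 && sc$s_batch <= 1)
    expect_true(sc$s_overall >= 0 && sc$s_overall <= 1)
  }
  # pairwise monotonicity: bumping any base metric never lowers s_overall
  base <- list(acc = 0.5, foscttm = 0.5, nmi = 0.5, ari = 0.1,
               asw_label = 0.5, gc = 0.5, asw_batch = 0.5)
  s0 <- do.call(overall_score, base)$s_overall
  for (nm in names(base)) {
    up <- base
    up[[nm]] <- if (nm == "foscttm") up[[nm]] - 0.2 else up[[nm]] + 0.2
    expect_gte(do.call(overall_score, up)$s_overall, s0)
  }
})

test_that("the integrated scorecard runs end to end and serializes", {
  sim <- small_sim(seed = 30, nx = 60, ny = 60)
  fit <- mmihcl(sim$x, sim$y, config = small_config(seed = 30, epochs = 5))
  rep <- evaluate_integration(fit$x_embedding, fit$y_embedding,
                              sim$x$cell_type_labels, sim$y$cell_type_labels,
                              matching = fit$matching,
                              true_pairs = sim$true_pairs, seed = 1)
  expect_s3_class(rep, "mmihcl_metrics")
  expect_true(rep$paired)
  expect_true(rep$s_overall >= 0 && rep$s_overall <= 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$s_overall, rep$s_overall, tolerance = 1e-12)
})
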