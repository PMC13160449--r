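#' Pipeline configuration
#'
#' All tunable parameters of the integration pipeline, grouped as in the
#' three stages: graph construction (`k`, `delta`, `weight_fn`,
#' `n_components`), encoder (`encoder`, an [encoder_config()]), matching
#' (`p` assignment rounds, matching-degree threshold `alpha`, final
#' partners `N`), and joint embedding (`rx`, `ry`, `r`, `r_star`, outer
#' iterations `T`). One master `seed` is fanned out to every stochastic
#' stage.
#'
#' @param T outer refinement iterations (default 3; 0 = initial matching
#'   and first CCA embeddings only).
#' @param k initial neighbour count for the adaptive kNN graphs.
#' @param delta adaptive pruning sensitivity (`<= 0`).
#' @param weight_fn graph edge weight map (see [knn_candidates()]).
#' @param n_components PCA dimensionality for graph construction.
#' @param encoder an [encoder_config()].
#' @param p assignment rounds of the initial many-to-many matching.
#' @param alpha matching-degree filter threshold in `(0, 1]`.
#' @param N final partners per x-cell (`N * nx <= ny` for `N > 1`).
#' @param rx,ry per-modality principal components for CCA.
#' @param r joint CCA dimension inside the loop.
#' @param r_star final joint embedding dimension.
#' @param distance_method `"clip"` (default; the matching-degree scale on
#'   which `alpha` is calibrated) or `"half"` (see
#'   [correlation_distance()]).
#' @param seed master seed.
#' @return list of class `mmihcl_config`.
#' @export
mmihcl_config <- function(T = 3, k = 30, delta = -0.5,
                          weight_fn = c("cosine01", "inv_dist"),
                          n_components = 100, encoder = encoder_config(),
                          p = 3, alpha = 0.6, N = 1,
                          rx = 40, ry = 40, r = 20, r_star = 20,
                          distance_method = c("clip", "half"), seed = 1L) {
  if (T < 0) stop_mmihcl("T must be >= 0")
  if (N < 1) stop_mmihcl("N must be >= 1")
  if (alpha <= 0 || alpha > 1) stop_mmihcl("alpha must be in (0, 1]")
  if (r > min(rx, ry)) stop_mmihcl("r must be <= min(rx, ry)")
  structure(list(T = as.integer(T), k = as.integer(k), delta = delta,
                 weight_fn = match.arg(weight_fn),
                 n_components = as.integer(n_components), encoder = encoder,
                 p = as.integer(p), alpha = alpha, N = as.integer(N),
                 rx = as.integer(rx), ry = as.integer(ry), r = as.integer(r),
                 r_star = as.integer(r_star),
                 distance_method = match.arg(distance_method),
                 seed = as.integer(seed)),
            class = "mmihcl_config")
}

#' Integrate two unpaired single-cell modalities
#'
#' Fits the full integration model: (1) per-modality adaptive kNN graphs
#' and their normalized operators; (2) hypergraph-contrastive embedding of
#' the linked-feature submatrices, cross-modal correlation distances, and
#' an initial many-to-many matching by p-best linear assignment with a
#' matching-degree filter; (3) `T` refinement iterations alternating CCA
#' joint embedding (conditioned on the current matching) with hypergraph
#' re-embedding and re-matching; finally a 1-to-N assignment and the CCA
#' joint embeddings at dimension `r_star`.
#'
#' @param x,y [modality_matrix()] objects with `nx <= ny` cells.
#' @param linkage a [feature_linkage()]; defaults to [link_by_name()].
#' @param config a [mmihcl_config()].
#' @return An object of class `mmihcl` with elements `matching` (the final
#'   [matching_pairs()]), `assignment` (sparse binary matrix),
#'   `x_embedding`, `y_embedding` (`nx x r_star`, `ny x r_star`, row
#'   names = cell ids), `cca` (the final [fit_cca()] model),
#'   `graphs` (per-modality adaptive k), `diagnostics` (per-iteration
#'   matching size, mean matching degree, encoder losses), `linkage`,
#'   `config`, `labels`.
#' @seealso [predict.mmihcl()], [evaluate_integration()],
#'   [generate_multimodal()]
#' @examples
#' \donttest{
#' sim <- generate_multimodal(synthetic_spec(
#'   n_types = 3, proportions = c(0.5, 0.3, 0.2), nx = 120, ny = 120,
#'   px = 60, py = 60, p_link = 30, linkage_strength = 0.9,
#'   noise_sd = 0.3, seed = 7))
#' fit <- mmihcl(sim$x, sim$y,
#'               config = mmihcl_config(T = 1, seed = 7,
#'                                      encoder = encoder_config(epochs = 10)))
#' fit
#' matching_accuracy(fit$matching, sim$x$cell_type_labels,
#'                   sim$y$cell_type_labels)
#' }
#' @export
mmihcl <- function(x, y, linkage = NULL, config = mmihcl_config()) {
  stopifnot(inherits(x, "modality_matrix"), inherits(y, "modality_matrix"))
  nx <- nrow(x$values); ny <- nrow(y$values)
  if (nx > ny)
    stop_mmihcl("configuration error: x must be the smaller modality (nx <= ny)")
  if (config$N > 1 && config$N * nx > ny)
    stop_mmihcl("configuration error: N * nx > ny")
  linkage <- linkage %||% link_by_name(x, y)
  if (linkage$p_link < 1) stop_mmihcl("configuration error: empty linkage")

  seeds <- derive_seeds(config$seed, 6 + 2 * max(config$T, 1))
  xv <- as_dense_values(x); yv <- as_dense_values(y)

  # clip embedding dimensions for small inputs
  rx <- min(config$rx, min(dim(xv)) - 1L)
  ry <- min(config$ry, min(dim(yv)) - 1L)
  r <- min(config$r, rx, ry)
  r_star <- min(config$r_star, rx, ry)
  ncomp_x <- min(config$n_components, min(dim(xv)) - 1L)
  ncomp_y <- min(config$n_components, min(dim(yv)) - 1L)

  # stage 1: shared PCA scores, adaptive kNN graphs, normalized operators
  x_scores_full <- reduce_dimension(xv, max(ncomp_x, rx))
  y_scores_full <- reduce_dimension(yv, max(ncomp_y, ry))
  gx <- aknn_graph(xv, k = config$k, delta = config$delta,
                   weight_fn = config$weight_fn,
                   scores = x_scores_full[, seq_len(ncomp_x), drop = FALSE])
  gy <- aknn_graph(yv, k = config$k, delta = config$delta,
                   weight_fn = config$weight_fn,
                   scores = y_scores_full[, seq_len(ncomp_y), drop = FALSE])
  x_scores <- x_scores_full[, seq_len(rx), drop = FALSE]  # `[` drops attrs
  y_scores <- y_scores_full[, seq_len(ry), drop = FALSE]

  enc_cfg <- function(seed) {
    cfg <- config$encoder
    cfg$seed <- seed
    cfg
  }

  # stage 2: encode linked features, initial many-to-many matching
  x_link <- xv[, linkage$pairs[, 1], drop = FALSE]
  y_link <- yv[, linkage$pairs[, 2], drop = FALSE]
  enc_x <- train_encoder(x_link, gx$normalized, enc_cfg(seeds[1]))
  enc_y <- train_encoder(y_link, gy$normalized, enc_cfg(seeds[2]))
  d_cur <- correlation_distance(enc_x$fused, enc_y$fused,
                                method = config$distance_method)
  m_cur <- filter_pairs(p_best_matchings(d_cur, config$p), config$alpha)

  diagnostics <- data.frame(iteration = 0L, matches = nrow(m_cur),
                            mean_degree = mean(m_cur$degree),
                            encoder_loss_x = tail_loss(enc_x),
                            encoder_loss_y = tail_loss(enc_y))

  # stage 3: iterative refinement
  if (config$T > 0) {
    for (t in seq_len(config$T)) {
      cca_t <- fit_cca(x, y, m_cur, rx = rx, ry = ry, r = r,
                       x_scores = x_scores, y_scores = y_scores)
      joint <- cca_transform(cca_t)
      enc_x <- train_encoder(joint$x_joint, gx$normalized,
                             enc_cfg(seeds[5 + 2 * t]))
      enc_y <- train_encoder(joint$y_joint, gy$normalized,
                             enc_cfg(seeds[6 + 2 * t]))
      d_cur <- correlation_distance(enc_x$fused, enc_y$fused,
                                    method = config$distance_method)
      if (t == config$T) break
      m_cur <- filter_pairs(p_best_matchings(d_cur, config$p), config$alpha)
      diagnostics <- rbind(diagnostics, data.frame(
        iteration = t, matches = nrow(m_cur),
        mean_degree = mean(m_cur$degree),
        encoder_loss_x = tail_loss(enc_x), encoder_loss_y = tail_loss(enc_y)))
    }
  }

  # final 1-to-N matching and joint embeddings at r_star
  fm <- final_matching(d_cur, config$N)
  cca_star <- fit_cca(x, y, fm$pairs, rx = rx, ry = ry, r = r_star,
                      x_scores = x_scores, y_scores = y_scores)
  emb <- cca_transform(cca_star)
  rownames(emb$x_joint) <- x$cell_ids
  rownames(emb$y_joint) <- y$cell_ids
  diagnostics <- rbind(diagnostics, data.frame(
    iteration = max(config$T, 0L) + 0L, matches = nrow(fm$pairs),
    mean_degree = mean(fm$pairs$degree),
    encoder_loss_x = tail_loss(enc_x), encoder_loss_y = tail_loss(enc_y)))

  structure(list(matching = fm$pairs, assignment = fm$assignment,
                 x_embedding = emb$x_joint, y_embedding = emb$y_joint,
                 cca = cca_star,
                 graphs = list(x_adaptive_k = gx$adaptive_k,
                               y_adaptive_k = gy$adaptive_k),
                 diagnostics = diagnostics, linkage = linkage,
                 config = config,
                 labels = list(x = x$cell_type_labels, y = y$cell_type_labels),
                 cell_ids = list(x = x$cell_ids, y = y$cell_ids),
                 dims = c(nx = nx, ny = ny, r_star = r_star)),
            class = "mmihcl")
}

tail_loss <- function(enc) {
  if (length(enc$loss_trace)) enc$loss_trace[length(enc$loss_trace)] else NA_real_
}

#' @export
print.mmihcl <- function(x, ...) {
  cat(sprintf("<mmihcl> %d x-cells ~ %d y-cells, %d linked features (rho = %.3f, %s)\n",
              x$dims["nx"], x$dims["ny"], x$linkage$p_link, x$linkage$rho,
              x$linkage$category))
  cat(sprintf("  %d refinement iteration(s); final matching: %d pairs (N = %d), mean degree %.3f\n",
              x$config$T, nrow(x$matching), x$config$N, mean(x$matching$degree)))
  cat(sprintf("  joint embeddings: %d x %d and %d x %d\n",
              nrow(x$x_embedding), ncol(x$x_embedding),
              nrow(x$y_embedding), ncol(x$y_embedding)))
  invisible(x)
}

#' @export
summary.mmihcl <- function(object, ...) {
  cat("Integration summary\n")
  print(object)
  cat("\nPer-iteration diagnostics:\n")
  print(object$diagnostics, row.names = FALSE)
  cat("\nMatching degree quantiles:\n")
  print(round(quantile(object$matching$degree), 4))
  if (!is.null(object$labels$x) && !is.null(object$labels$y)) {
    cat(sprintf("\nLabel-transfer accuracy: %.4f\n",
                matching_accuracy(object$matching, object$labels$x,
                                  object$labels$y)))
  }
  invisible(object)
}

#' Cross-modality feature prediction from an explicit matching
#'
#' Regression-free projection: each x-cell's predicted feature profile is
#' the mean of its matched y-cells' full feature rows (optionally
#' weighted by `1 - d_ij`).
#'
#' @param object a fitted `mmihcl` model.
#' @param reference the y [modality_matrix()] whose features are to be
#'   projected onto the x-cells.
#' @param weighted weight partners by `1 - matching degree`.
#' @param ... unused.
#' @return `nx x py` matrix of predicted feature values.
#' @export
predict.mmihcl <- function(object, reference, weighted = FALSE, ...) {
  predict_features(object$matching, reference, weighted = weighted)
}

#' @rdname predict.mmihcl
#' @param m_star a [matching_pairs()] covering all x-cells.
#' @export
predict_features <- function(m_star, reference, weighted = FALSE) {
  yv <- as_dense_values(reference)
  nx <- attr(m_star, "nx") %||% max(m_star$x)
  if (length(setdiff(seq_len(nx), m_star$x)))
    stop_mmihcl("matching must cover every x-cell")
  w <- if (weighted) 1 - m_star$degree else rep(1, nrow(m_star))
  num <- rowsum(yv[m_star$y, , drop = FALSE] * w, group = m_star$x)
  den <- rowsum(w, group = m_star$x)
  out <- num / as.vector(den)
  rownames(out) <- NULL
  colnames(out) <- colnames(yv)
  out
}

#' Smooth expression over joint-embedding neighbourhoods
#'
#' Replaces each cell's expression row by the mean over itself and its
#' `k_smooth` nearest neighbours (Euclidean) in the joint embedding — the
#' aggregation step used to de-noise expression before downstream
#' differential testing.
#'
#' @param embedding `n x r` joint embedding.
#' @param expression `n x g` expression matrix (same cell order).
#' @param k_smooth neighbour count, `< n`.
#' @return smoothed `n x g` matrix.
#' @export
smooth_by_neighbors <- function(embedding, expression, k_smooth) {
  embedding <- as.matrix(embedding); expression <- as.matrix(expression)
  n <- nrow(embedding)
  if (nrow(expression) != n) stop_mmihcl("row counts differ")
  if (k_smooth >= n) stop_mmihcl("k_smooth must be < n")
  d2 <- as.matrix(stats::dist(embedding))
  diag(d2) <- -Inf  # self is always included
  out <- matrix(0, n, ncol(expression), dimnames = dimnames(expression))
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k_smooth + 1)]
    out[i, ] <- colMeans(expression[nb, , drop = FALSE])
  }
  out
}

#' Export joint embeddings as TSV
#'
#' Writes the row-wise concatenation of both modalities' joint embeddings
#' with cell ids and modality tags in the leading columns.
#'
#' @param fit a fitted `mmihcl` model.
#' @param path output TSV path.
#' @export
write_embeddings <- function(fit, path) {
  emb <- rbind(fit$x_embedding, fit$y_embedding)
  df <- data.frame(
    cell_id = c(fit$cell_ids$x, fit$cell_ids$y),
    modality = rep(c("x", "y"),
                   c(nrow(fit$x_embedding), nrow(fit$y_embedding))),
    emb, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("dim_", seq_len(ncol(emb)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot method for mmihcl fits
#'
#' Scatter of the first two joint-embedding dimensions, colored by
#' modality (default) or cell-type label.
#'
#' @param x a fitted `mmihcl` model.
#' @param color_by `"modality"` or `"label"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mmihcl <- function(x, color_by = c("modality", "label"), ...) {
  color_by <- match.arg(color_by)
  emb <- rbind(x$x_embedding[, 1:2, drop = FALSE],
               x$y_embedding[, 1:2, drop = FALSE])
  grp <- if (color_by == "modality") {
    rep(c("x", "y"), c(nrow(x$x_embedding), nrow(x$y_embedding)))
  } else {
    c(x$labels$x %||% rep("x", nrow(x$x_embedding)),
      x$labels$y %||% rep("y", nrow(x$y_embedding)))
  }
  grp <- factor(grp)
  graphics::plot(emb[, 1], emb[, 2], col = as.integer(grp),
                 pch = 16, cex = 0.5, xlab = "dim 1", ylab = "dim 2", ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_len(nlevels(grp)), pch = 16, cex = 0.8)
  invisible(x)
}
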