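#' Principal-component scores of a modality
#'
#' Deterministic PCA (centred, unscaled) with a fixed sign convention: in
#' each component the loading entry of largest absolute value is made
#' positive, so repeated fits give identical scores.
#'
#' @param x a [modality_matrix()] or numeric matrix, cells x features.
#' @param n_components number of components, `1 <= n_components <=
#'   min(n_cells, n_features)`.
#' @return numeric matrix, cells x `n_components`, with a `"rotation"`
#'   attribute (features x components) and a `"center"` attribute.
#' @export
reduce_dimension <- function(x, n_components) {
  v <- as_dense_values(x)
  n <- nrow(v); p <- ncol(v)
  if (n_components < 1 || n_components > min(n, p))
    stop_mmihcl("n_components must lie in [1, min(n_cells, n_features)]")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)),
                 function(j) rot[which.max(abs(rot[, j])), j] < 0, logical(1))
  rot[, flip] <- -rot[, flip]
  scores <- pc$x
  scores[, flip] <- -scores[, flip]
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- pc$center
  scores
}

#' k-nearest-neighbour candidates with bounded similarity weights
#'
#' For each cell, the `k` other cells of highest edge weight, where the
#' weight maps similarity into `[0, 1]`:
#' `cosine01` is `(1 + cosine similarity)/2` (all-zero rows have cosine 0)
#' and `inv_dist` is `1 / (1 + Euclidean distance)`. Candidates are sorted
#' by decreasing weight (ties by increasing index).
#'
#' @param scores numeric matrix of cell embeddings (e.g. from
#'   [reduce_dimension()]).
#' @param k number of candidates per cell; values `>= n` are clipped to
#'   `n - 1` with a warning.
#' @param weight_fn `"cosine01"` or `"inv_dist"`.
#' @return list of class `neighbor_candidates`: `idx` and `w` are `n x k`
#'   matrices of neighbour indices and weights (rows sorted by decreasing
#'   weight), plus `k` and `metric`.
#' @export
knn_candidates <- function(scores, k, weight_fn = c("cosine01", "inv_dist")) {
  weight_fn <- match.arg(weight_fn)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2) stop_mmihcl("need at least 2 cells")
  if (k < 1) stop_mmihcl("k must be >= 1")
  if (k >= n) {
    warning(sprintf("k = %d >= n = %d; clipped to %d", k, n, n - 1L))
    k <- n - 1L
  }
  w <- if (weight_fn == "cosine01") {
    u <- normalize_rows(scores)
    (1 + tcrossprod(u)) / 2
  } else {
    1 / (1 + as.matrix(stats::dist(scores)))
  }
  w <- pmin(pmax(w, 0), 1)
  diag(w) <- -Inf  # no self-neighbours
  idx <- matrix(0L, n, k)
  wk <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(-w[i, ], seq_len(n))[seq_len(k)]
    idx[i, ] <- ord
    wk[i, ] <- w[i, ord]
  }
  structure(list(idx = idx, w = wk, k = k, metric = weight_fn),
            class = "neighbor_candidates")
}

# closed-form per-cell retention threshold: t_i = 1 - (mean_k(w_i) - 1 - delta)^2
aknn_threshold <- function(w, delta) 1 - (rowMeans(w) - 1 - delta)^2

#' Adaptive per-cell neighbour selection
#'
#' Chooses each cell's neighbour count `k_i` from its candidate weight
#' distribution: a candidate `j` of cell `i` is retained iff
#' `w_ij > 1 - (mean_l w_il - 1 - delta)^2`, where the mean runs over the
#' initial `k` candidates and `delta <= 0` tunes the sensitivity to local
#' distance change. A cell whose candidates all fail the strict inequality
#' keeps its single top neighbour, so every cell has degree >= 1.
#'
#' @param candidates a [knn_candidates()] result.
#' @param delta non-positive sensitivity parameter (default -0.5).
#' @return list of class `aknn_pruned`: `edges` (three-column matrix `i`,
#'   `j`, `w`), `adaptive_k` (per-cell retained counts), `threshold`
#'   (per-cell `t_i`), `n`.
#' @export
adaptive_prune <- function(candidates, delta = -0.5) {
  if (delta > 0) stop_mmihcl("delta must be <= 0")
  w <- candidates$w
  if (any(w[, -1, drop = FALSE] > w[, -ncol(w), drop = FALSE] + 1e-12))
    stop_mmihcl("candidate weights must be sorted in descending order")
  n <- nrow(w)
  thr <- aknn_threshold(w, delta)
  keep <- w > thr
  k_i <- rowSums(keep)
  forced <- k_i == 0
  if (any(forced)) {            # degenerate all-equal weights: keep top-1
    keep[forced, 1] <- TRUE
    k_i[forced] <- 1L
  }
  ii <- rep(seq_len(n), times = k_i)
  sel <- which(t(keep))         # row-major so neighbours stay weight-ordered
  jj <- t(candidates$idx)[sel]
  ww <- t(w)[sel]
  structure(list(edges = cbind(i = ii, j = jj, w = ww),
                 adaptive_k = as.integer(k_i), threshold = thr, n = n),
            class = "aknn_pruned")
}

#' Build the symmetric weighted adjacency from pruned edges
#'
#' Directed retained edges are symmetrized by elementwise maximum (the
#' strongest evidence of proximity wins) and the diagonal is zero.
#'
#' @param pruned an [adaptive_prune()] result.
#' @return list of class `cell_graph`: sparse `adjacency` (n x n, entries in
#'   `[0,1]`), `adaptive_k`, `n`.
#' @export
build_adjacency <- function(pruned) {
  n <- pruned$n
  e <- pruned$edges
  a <- Matrix::sparseMatrix(i = e[, "i"], j = e[, "j"], x = e[, "w"],
                            dims = c(n, n), use.last.ij = TRUE)
  at <- Matrix::t(a)
  adj <- (a + at + abs(a - at)) / 2   # elementwise max for sparse matrices
  Matrix::diag(adj) <- 0
  adj <- Matrix::drop0(adj)
  structure(list(adjacency = adj, adaptive_k = pruned$adaptive_k, n = n),
            class = "cell_graph")
}

#' Normalized propagation operator of a cell graph
#'
#' Symmetric GCN normalization `D^{-1/2} (A + I) D^{-1/2}` with
#' `D_ii = sum_j (A + I)_ij` (always >= 1, so no division by zero). Setting
#' `symmetric = FALSE` switches the right factor to `D^{+1/2}`, a
#' non-symmetric variant retained for comparison.
#'
#' @param graph a [build_adjacency()] result (or any list with a square
#'   `adjacency` element).
#' @param symmetric use the symmetric operator (default); `FALSE` gives
#'   `D^{-1/2}(A+I)D^{+1/2}`.
#' @return The input graph with a sparse `normalized` element added.
#' @export
normalize_adjacency <- function(graph, symmetric = TRUE) {
  a <- graph$adjacency
  n <- nrow(a)
  ai <- a + Matrix::Diagonal(n)
  d <- Matrix::rowSums(ai)
  dl <- Matrix::Diagonal(x = 1 / sqrt(d))
  dr <- if (symmetric) dl else Matrix::Diagonal(x = sqrt(d))
  graph$normalized <- methods::as(dl %*% ai %*% dr, "CsparseMatrix")
  graph
}

#' Adaptive kNN cell graph of one modality
#'
#' Convenience wrapper chaining [reduce_dimension()], [knn_candidates()],
#' [adaptive_prune()], [build_adjacency()] and [normalize_adjacency()].
#'
#' @param x a [modality_matrix()] or numeric matrix.
#' @param k initial neighbour count before adaptive pruning (default 30).
#' @param delta adaptive sensitivity, `<= 0` (default -0.5).
#' @param weight_fn edge weight map, see [knn_candidates()].
#' @param n_components PCA dimensionality; the default 100 is clipped to
#'   `min(n_cells, n_features) - 1` on small inputs.
#' @param scores optional precomputed score matrix (skips the PCA).
#' @return A `cell_graph` with `adjacency`, `normalized`, `adaptive_k`.
#' @export
aknn_graph <- function(x, k = 30, delta = -0.5,
                       weight_fn = c("cosine01", "inv_dist"),
                       n_components = 100, scores = NULL) {
  weight_fn <- match.arg(weight_fn)
  if (is.null(scores)) {
    v <- as_dense_values(x)
    n_components <- min(n_components, min(dim(v)) - 1L)
    n_components <- max(n_components, 1L)
    scores <- reduce_dimension(v, n_components)
  }
  cand <- knn_candidates(scores, k, weight_fn)
  pruned <- adaptive_prune(cand, delta)
  normalize_adjacency(build_adjacency(pruned))
}

#' Export a cell graph as edge-list and neighbour-count tables
#'
#' Writes a 3-column TSV (i, j, weight) of the upper-triangle adjacency and,
#' optionally, a per-cell adaptive_k TSV.
#'
#' @param graph a `cell_graph`.
#' @param edges_path output TSV path for edges.
#' @param k_path optional output TSV path for per-cell adaptive k.
#' @export
write_graph_edges <- function(graph, edges_path, k_path = NULL) {
  tm <- methods::as(Matrix::triu(graph$adjacency), "TsparseMatrix")
  df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, weight = tm@x)
  write.table(df, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(k_path))
    write.table(data.frame(cell = seq_len(graph$n),
                           adaptive_k = graph$adaptive_k),
                k_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(edges_path)
}
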