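#' Label-transfer accuracy of a matching
#'
#' Fraction of matching triples whose x-cell and y-cell carry the same
#' cell-type label (each triple counted once; for a 1-to-N matching this
#' averages over all `N * nx` triples).
#'
#' @param m a [matching_pairs()].
#' @param x_labels,y_labels per-cell label vectors.
#' @return value in `[0, 1]`.
#' @export
matching_accuracy <- function(m, x_labels, y_labels) {
  if (anyNA(x_labels[m$x]) || anyNA(y_labels[m$y]))
    stop_mmihcl("missing label for a matched cell")
  mean(x_labels[m$x] == y_labels[m$y])
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' For each truly paired cell, the fraction of other-modality cells
#' strictly closer (Euclidean, in the joint embedding) than its true
#' match, normalized by `n_other - 1` so the worst case is exactly 1;
#' averaged over both directions. 0 means perfect cross-modal alignment.
#'
#' @param x_emb,y_emb joint embeddings.
#' @param true_pairs two-column index matrix of known pairs.
#' @return value in `[0, 1]`.
#' @export
foscttm <- function(x_emb, y_emb, true_pairs) {
  if (is.null(true_pairs) || nrow(true_pairs) == 0)
    stop_mmihcl("FOSCTTM needs a known true pairing (paired evaluation only)")
  x_emb <- as.matrix(x_emb); y_emb <- as.matrix(y_emb)
  nx <- nrow(x_emb); ny <- nrow(y_emb)
  if (nx < 2 || ny < 2) stop_mmihcl("need at least 2 cells per modality")
  d2 <- outer(rowSums(x_emb^2), rowSums(y_emb^2), "+") - 2 * tcrossprod(x_emb, y_emb)
  ix <- true_pairs[, 1]; iy <- true_pairs[, 2]
  dtrue <- d2[cbind(ix, iy)]
  # strict inequality excludes the true match itself automatically
  fx <- rowSums(d2[ix, , drop = FALSE] < dtrue) / (ny - 1)
  fy <- rowSums(t(d2)[iy, , drop = FALSE] < dtrue) / (nx - 1)
  mean(c(fx, fy))
}

# shared-embedding kNN graph used by clustering and connectivity metrics
knn_igraph <- function(embedding, k) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  d2 <- as.matrix(stats::dist(embedding))
  diag(d2) <- Inf
  nb <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Clustering agreement scores (NMI, ARI)
#'
#' Communities are detected on a kNN graph of the joint embedding by
#' modularity clustering over a resolution sweep; the resolution
#' maximizing NMI against the labels is reported (the scIB protocol).
#' A centroid-based fallback (`method = "kmeans"`, k = number of label
#' classes) is provided.
#'
#' @param embedding joint embedding of all cells (both modalities
#'   concatenated row-wise).
#' @param labels cell-type labels, same length as `nrow(embedding)`.
#' @param resolutions resolution sweep (default `seq(0.1, 2, 0.1)`).
#' @param k_graph kNN graph degree (default 15).
#' @param method `"leiden"` (default) or `"kmeans"`.
#' @param seed seed for the community detection.
#' @return list with `nmi`, `ari`, `resolution`, `n_clusters`.
#' @export
clustering_scores <- function(embedding, labels,
                              resolutions = seq(0.1, 2, by = 0.1),
                              k_graph = 15, method = c("leiden", "kmeans"),
                              seed = 1L) {
  method <- match.arg(method)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) {
    warning("single label class: NMI defined as 0")
    return(list(nmi = 0, ari = 0, resolution = NA_real_, n_clusters = 1L))
  }
  if (method == "kmeans") {
    cl <- with_seed(seed, stats::kmeans(embedding, centers = max(labels),
                                        nstart = 10)$cluster)
    return(list(nmi = nmi_score(cl, labels), ari = ari_score(cl, labels),
                resolution = NA_real_, n_clusters = max(cl)))
  }
  g <- knn_igraph(embedding, k_graph)
  best <- list(nmi = -1)
  for (res in resolutions) {
    cl <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 3)))
    nmi <- nmi_score(cl, labels)
    if (nmi > best$nmi)
      best <- list(nmi = nmi, ari = ari_score(cl, labels), resolution = res,
                   n_clusters = length(unique(cl)))
  }
  best
}

nmi_score <- function(a, b) igraph::compare(a, b, method = "nmi")
ari_score <- function(a, b) igraph::compare(a, b, method = "adjusted.rand")

#' Rescaled silhouette widths for labels and batches
#'
#' scIB-style definitions on the joint embedding:
#' `asw_label = (mean silhouette on cell-type labels + 1) / 2`;
#' `asw_batch` = for each label class with at least two batches, the mean
#' of `1 - |silhouette on batch tags|` within the class, averaged over
#' classes. Both lie in `[0, 1]`; higher is better (separated types,
#' mixed modalities).
#'
#' @param embedding joint embedding of all cells.
#' @param labels cell-type labels.
#' @param batch batch/modality tags (two modalities in this package).
#' @return list with `asw_label`, `asw_batch`.
#' @export
silhouette_scores <- function(embedding, labels, batch) {
  labels <- factor(labels); batch <- factor(batch)
  if (nlevels(labels) < 2) stop_mmihcl("need >= 2 label classes")
  if (nlevels(batch) < 2) stop_mmihcl("asw_batch undefined with one batch")
  d <- stats::dist(embedding)
  sil <- cluster::silhouette(as.integer(labels), d)
  asw_label <- (mean(sil[, "sil_width"]) + 1) / 2

  dm <- as.matrix(d)
  per_class <- c()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    b <- droplevels(batch[idx])
    if (nlevels(b) < 2 || length(idx) <= nlevels(b)) next
    s <- cluster::silhouette(as.integer(b), stats::as.dist(dm[idx, idx]))
    per_class <- c(per_class, mean(1 - abs(s[, "sil_width"])))
  }
  if (length(per_class) == 0)
    stop_mmihcl("no label class contains both batches")
  list(asw_label = asw_label, asw_batch = mean(per_class))
}

#' Graph connectivity of label classes
#'
#' For each cell-type class, the fraction of its cells in the largest
#' connected component of the class's own kNN subgraph in the joint
#' embedding, averaged over classes (scIB definition). Singleton classes
#' count as fully connected.
#'
#' @param embedding joint embedding of all cells.
#' @param labels cell-type labels.
#' @param k_gc kNN degree (default 15).
#' @return value in `(0, 1]`.
#' @export
graph_connectivity <- function(embedding, labels, k_gc = 15) {
  labels <- factor(labels)
  fracs <- vapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 1) return(1)
    g <- knn_igraph(embedding[idx, , drop = FALSE], k_gc)
    comp <- igraph::components(g)
    max(comp$csize) / length(idx)
  }, numeric(1))
  mean(fracs)
}

#' Nested bio/batch/overall integration scores
#'
#' Aggregates the base metrics into the weighted scorecard
#' \deqn{S_{bio} = [ACC + (1 - FOSCTTM) I_{paired} + NMI + max(0, ARI) +
#'   ASW_{label}] / N_{bio}, \quad N_{bio} = 4 + I_{paired}}
#' \deqn{S_{batch} = (GC + ASW_{batch}) / 2, \quad
#'   S_{overall} = 0.6 S_{bio} + 0.4 S_{batch}.}
#' The denominator `N_bio` adapts to whether a true pairing is available so
#' every score stays in `[0, 1]`; ARI is clipped at 0 before averaging.
#'
#' @param acc matching accuracy in `[0, 1]`.
#' @param foscttm in `[0, 1]`, or `NULL` for unpaired data.
#' @param nmi,asw_label,gc,asw_batch base metrics in `[0, 1]`.
#' @param ari adjusted Rand index (may be negative).
#' @param paired logical; defaults to `!is.null(foscttm)`.
#' @return list with `s_bio`, `s_batch`, `s_overall`.
#' @export
overall_score <- function(acc, foscttm = NULL, nmi, ari, asw_label, gc,
                          asw_batch, paired = !is.null(foscttm)) {
  in01 <- function(v, nm) {
    if (is.null(v) || v < 0 || v > 1)
      stop_mmihcl(nm, " must lie in [0, 1]")
    v
  }
  for (nm in c("acc", "nmi", "asw_label", "gc", "asw_batch"))
    in01(get(nm), nm)
  if (paired && is.null(foscttm))
    stop_mmihcl("paired scoring requires a FOSCTTM value")
  if (!is.null(foscttm)) in01(foscttm, "foscttm")
  if (ari < -1 || ari > 1) stop_mmihcl("ari must lie in [-1, 1]")
  ind <- as.numeric(paired)
  n_bio <- 4 + ind
  s_bio <- (acc + (1 - (foscttm %||% 0)) * ind + nmi + max(0, ari) +
              asw_label) / n_bio
  s_batch <- (gc + asw_batch) / 2
  list(s_bio = s_bio, s_batch = s_batch,
       s_overall = combine_scores(s_bio, s_batch))
}

#' Weighted combination of the bio and batch scores
#'
#' `s_overall = 0.6 * s_bio + 0.4 * s_batch` — the fixed trade-off between
#' biological fidelity and batch-effect removal used throughout the
#' scorecard.
#'
#' @param s_bio,s_batch component scores in `[0, 1]`.
#' @return the overall score in `[0, 1]`.
#' @export
combine_scores <- function(s_bio, s_batch) {
  if (any(c(s_bio, s_batch) < 0) || any(c(s_bio, s_batch) > 1))
    stop_mmihcl("component scores must lie in [0, 1]")
  0.6 * s_bio + 0.4 * s_batch
}

#' Full integration scorecard for a pair of joint embeddings
#'
#' Computes all base metrics plus the nested scores for an integration
#' result: ACC from the matching, FOSCTTM from a true pairing (when
#' known), clustering/silhouette/connectivity metrics on the row-wise
#' concatenation of the two embeddings with modality as batch.
#'
#' @param x_emb,y_emb joint embeddings, same number of columns.
#' @param x_labels,y_labels cell-type labels.
#' @param matching optional [matching_pairs()] for ACC.
#' @param true_pairs optional two-column index matrix for FOSCTTM; also
#'   sets the paired flag.
#' @param k_graph kNN degree for graph-based metrics.
#' @param seed seed for community detection.
#' @param clustering `"leiden"` or `"kmeans"` (see [clustering_scores()]).
#' @return list of class `mmihcl_metrics` with the base metrics, the
#'   nested scores and the paired flag.
#' @export
evaluate_integration <- function(x_emb, y_emb, x_labels, y_labels,
                                 matching = NULL, true_pairs = NULL,
                                 k_graph = 15, seed = 1L,
                                 clustering = c("leiden", "kmeans")) {
  emb <- rbind(as.matrix(x_emb), as.matrix(y_emb))
  labels <- c(x_labels, y_labels)
  batch <- rep(c("x", "y"), c(nrow(x_emb), nrow(y_emb)))
  acc <- if (!is.null(matching))
    matching_accuracy(matching, x_labels, y_labels) else NA_real_
  fos <- if (!is.null(true_pairs)) foscttm(x_emb, y_emb, true_pairs)
  cs <- clustering_scores(emb, labels, k_graph = k_graph, seed = seed,
                          method = match.arg(clustering))
  ss <- silhouette_scores(emb, labels, batch)
  gc <- graph_connectivity(emb, labels, k_gc = k_graph)
  sc <- overall_score(acc = if (is.na(acc)) 0 else acc, foscttm = fos,
                      nmi = cs$nmi, ari = cs$ari, asw_label = ss$asw_label,
                      gc = gc, asw_batch = ss$asw_batch,
                      paired = !is.null(true_pairs))
  structure(list(acc = acc, foscttm = fos, nmi = cs$nmi, ari = cs$ari,
                 asw_label = ss$asw_label, gc = gc, asw_batch = ss$asw_batch,
                 paired = !is.null(true_pairs),
                 s_bio = sc$s_bio, s_batch = sc$s_batch,
                 s_overall = sc$s_overall,
                 clustering_resolution = cs$resolution),
            class = "mmihcl_metrics")
}

#' @export
print.mmihcl_metrics <- function(x, ...) {
  cat("<mmihcl_metrics>\n")
  fmt <- function(v) if (is.null(v) || is.na(v)) "   -  " else sprintf("%.4f", v)
  cat(sprintf("  ACC      %s   FOSCTTM %s (paired: %s)\n",
              fmt(x$acc), fmt(x$foscttm), x$paired))
  cat(sprintf("  NMI      %s   ARI     %s   ASW_label %s\n",
              fmt(x$nmi), fmt(x$ari), fmt(x$asw_label)))
  cat(sprintf("  GC       %s   ASW_batch %s\n", fmt(x$gc), fmt(x$asw_batch)))
  cat(sprintf("  S_bio    %s   S_batch %s   S_overall %s\n",
              fmt(x$s_bio), fmt(x$s_batch), fmt(x$s_overall)))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report an `mmihcl_metrics` (or any named list of scalars).
#' @param path output JSON path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
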