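#' Correlation distance between cross-modal embeddings
#'
#' Matching degree between every x-cell and y-cell embedding row:
#' `d_ij = (1 - PCC(x_i, y_j)) / 2`, mapping the correlation range
#' `[-1, 1]` onto `[0, 1]` (default), or `clip(1 - PCC, 0, 1)` when
#' `method = "clip"`. Rows with zero variance have PCC defined as 0, hence
#' `d = 0.5` (default mapping).
#'
#' @param x_emb,y_emb numeric matrices `nx x d` and `ny x d`, `d >= 2`.
#' @param method `"half"` (default, `(1-PCC)/2`) or `"clip"`
#'   (`max(0, min(1, 1-PCC))`).
#' @return `nx x ny` matrix with entries in `[0, 1]`; row/col names carry
#'   over from the embeddings.
#' @export
correlation_distance <- function(x_emb, y_emb, method = c("half", "clip")) {
  method <- match.arg(method)
  x_emb <- as.matrix(x_emb); y_emb <- as.matrix(y_emb)
  if (ncol(x_emb) != ncol(y_emb))
    stop_mmihcl("embedding dimensions differ")
  if (ncol(x_emb) < 2)
    stop_mmihcl("row-wise PCC needs embedding dimension >= 2")
  xc <- x_emb - rowMeans(x_emb)
  yc <- y_emb - rowMeans(y_emb)
  r <- tcrossprod(normalize_rows(xc), normalize_rows(yc)) # constant rows -> 0
  r <- pmin(pmax(r, -1), 1)
  d <- if (method == "half") (1 - r) / 2 else pmin(pmax(1 - r, 0), 1)
  dimnames(d) <- list(rownames(x_emb), rownames(y_emb))
  d
}

# large finite penalty used to forbid pairs inside assignment rounds
.lap_big <- 1e6

# Deterministic tie-breaking: a two-scale perturbation that, among optimal
# assignments, prefers lower column indices and then pairs lower rows with
# lower columns. Solutions and objectives are always reported on the
# unperturbed costs.
lap_perturb <- function(d) {
  nx <- nrow(d); ny <- ncol(d)
  eps1 <- 1e-9 / ny
  eps2 <- 1e-12 / (nx * ny)
  d + outer(rep(1, nx), seq_len(ny)) * eps1 +
    outer(seq_len(nx), ny - seq_len(ny)) * eps2
}

#' Solve the rectangular linear assignment problem
#'
#' Finds the binary assignment `Pi` minimizing `<Pi, D>` subject to each row
#' of `Pi` summing to 1 and each column to at most 1 (`nx <= ny`), by a
#' shortest-augmenting-path solver. Among cost ties the solution with the
#' lowest column indices is preferred.
#'
#' @param dist `nx x ny` cost matrix, `nx <= ny`, finite entries.
#' @return list of class `assignment`: `cols` (column index per row),
#'   `pairs` (two-column matrix), `objective` (total cost on the input
#'   matrix), `nx`, `ny`.
#' @export
solve_assignment <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) > ncol(dist))
    stop_mmihcl("infeasible: more x-cells than y-cells (nx > ny)")
  if (any(!is.finite(dist))) stop_mmihcl("cost matrix must be finite")
  cols <- lap_solve_cpp(lap_perturb(dist))
  structure(list(cols = cols,
                 pairs = cbind(x = seq_len(nrow(dist)), y = cols),
                 objective = sum(dist[cbind(seq_len(nrow(dist)), cols)]),
                 nx = nrow(dist), ny = ncol(dist)),
            class = "assignment")
}

#' Binary assignment matrix of an `assignment`
#'
#' @param a an `assignment` from [solve_assignment()] or [final_matching()].
#' @return sparse binary `nrow x ny` matrix with unit row sums and column
#'   sums at most 1.
#' @export
as_assignment_matrix <- function(a) {
  Matrix::sparseMatrix(i = seq_along(a$cols), j = a$cols, x = 1,
                       dims = c(length(a$cols), a$ny))
}

#' Matching pairs container
#'
#' Triples `(i, j, d_ij)` of cross-modal cell correspondences with their
#' matching degrees (correlation distances; smaller is a better match).
#'
#' @param x,y integer cell indices into the two modalities.
#' @param degree matching degrees in `[0, 1]`.
#' @param nx,ny modality cell counts.
#' @return data frame of class `matching_pairs`.
#' @export
matching_pairs <- function(x, y, degree, nx, ny) {
  df <- data.frame(x = as.integer(x), y = as.integer(y),
                   degree = as.numeric(degree))
  if (any(df$x < 1 | df$x > nx) || any(df$y < 1 | df$y > ny))
    stop_mmihcl("matching indices out of range")
  if (length(setdiff(seq_len(nx), df$x)))
    stop_mmihcl("every x-cell must appear in the matching")
  attr(df, "nx") <- as.integer(nx)
  attr(df, "ny") <- as.integer(ny)
  class(df) <- c("matching_pairs", "data.frame")
  df
}

#' p-best many-to-many matching
#'
#' Solves the assignment problem `p` times in sequence; after each round
#' the selected pairs are forbidden (cost set prohibitively high) before
#' re-solving, so the `p` rounds produce `p * nx` triples in which every
#' x-cell has exactly `p` distinct y-partners. Matching degrees are taken
#' from the input distance matrix. Round objectives are non-decreasing.
#'
#' @param dist `nx x ny` distance matrix, `nx <= ny`.
#' @param p number of rounds, `1 <= p <= ny`.
#' @return A [matching_pairs()] with a `"round_objectives"` attribute.
#' @export
p_best_matchings <- function(dist, p = 3) {
  dist <- as.matrix(dist)
  nx <- nrow(dist); ny <- ncol(dist)
  if (p < 1) stop_mmihcl("p must be >= 1")
  if (p > ny) stop_mmihcl("infeasible: p > ny leaves some x-cell short of partners")
  work <- dist
  xs <- ys <- integer(0); ds <- numeric(0)
  objs <- numeric(p)
  for (r in seq_len(p)) {
    a <- solve_assignment(work)
    sel <- cbind(seq_len(nx), a$cols)
    if (any(work[sel] >= .lap_big))
      stop_mmihcl("infeasible p-best matching: no unused partner left for some ",
                  "x-cell at round ", r)
    objs[r] <- sum(dist[sel])
    xs <- c(xs, seq_len(nx)); ys <- c(ys, a$cols); ds <- c(ds, dist[sel])
    work[sel] <- .lap_big
  }
  out <- matching_pairs(xs, ys, ds, nx, ny)
  attr(out, "round_objectives") <- objs
  out
}

#' Filter matching pairs by matching degree
#'
#' Keeps triples with degree `<= alpha`; any x-cell whose triples all
#' exceed the threshold retains its single best (minimum-degree) triple,
#' so full row coverage is preserved: `nx <= |M| <= p * nx`.
#'
#' @param m a [matching_pairs()].
#' @param alpha matching-degree threshold in `(0, 1]` (default 0.6).
#' @return Filtered [matching_pairs()].
#' @export
filter_pairs <- function(m, alpha = 0.6) {
  if (alpha <= 0) stop_mmihcl("alpha must be in (0, 1]")
  if (nrow(m) == 0) stop_mmihcl("empty matching")
  nx <- attr(m, "nx"); ny <- attr(m, "ny")
  keep <- m$degree <= alpha
  lost <- setdiff(seq_len(nx), m$x[keep])
  for (i in lost) {
    rows <- which(m$x == i)
    best <- rows[order(m$degree[rows], m$y[rows])[1]]
    keep[best] <- TRUE
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  matching_pairs(out$x, out$y, out$degree, nx, ny)
}

#' Final 1-to-N matching
#'
#' For `N = 1`, the plain optimal assignment. For `N > 1`, the distance
#' matrix is copied `N` times and stacked vertically; solving the stacked
#' problem (with its column-sum-at-most-1 constraint) hands every x-cell
#' exactly `N` distinct y-partners.
#'
#' @param dist `nx x ny` distance matrix.
#' @param N partners per x-cell, `N * nx <= ny` required for `N > 1`.
#' @return list of class `final_matching`: `pairs` (a [matching_pairs()]
#'   with `N` rows per x-cell), `assignment` (sparse binary
#'   `N*nx x ny` matrix), `objective`.
#' @export
final_matching <- function(dist, N = 1) {
  dist <- as.matrix(dist)
  nx <- nrow(dist); ny <- ncol(dist)
  if (N < 1) stop_mmihcl("N must be >= 1")
  if (N * nx > ny)
    stop_mmihcl("infeasible: N * nx > ny")
  stacked <- dist[rep(seq_len(nx), times = N), , drop = FALSE]
  a <- solve_assignment(stacked)
  x_idx <- rep(seq_len(nx), times = N)
  pairs <- matching_pairs(x_idx, a$cols, dist[cbind(x_idx, a$cols)], nx, ny)
  structure(list(pairs = pairs, assignment = as_assignment_matrix(a),
                 objective = a$objective, N = N),
            class = "final_matching")
}

#' Read/write matching pairs as 3-column TSV
#'
#' @param m a [matching_pairs()]; `x_ids`, `y_ids` optional cell-id vectors
#'   used in place of indices.
#' @param path TSV path.
#' @export
write_matching <- function(m, path, x_ids = NULL, y_ids = NULL) {
  df <- data.frame(
    x_cell = if (is.null(x_ids)) m$x else x_ids[m$x],
    y_cell = if (is.null(y_ids)) m$y else y_ids[m$y],
    matching_degree = m$degree)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matching
#' @param nx,ny modality sizes for validation on read; inferred from the
#'   data when omitted.
#' @export
read_matching <- function(path, nx = NULL, ny = NULL) {
  df <- read.delim(path)
  if (ncol(df) != 3) stop_mmihcl("matching TSV must have 3 columns")
  x <- df[[1]]; y <- df[[2]]
  if (!is.numeric(x)) stop_mmihcl("matching TSV read-back requires index columns")
  matching_pairs(x, y, df[[3]], nx %||% max(x), ny %||% max(y))
}
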