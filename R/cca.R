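#' Canonical correlation joint embedding `C(X, Y, M)`
#'
#' Fits the cross-modality transform used to couple the two datasets:
#' each modality is first reduced to principal-component scores (`rx`, `ry`
#' components over all of its cells), then canonical correlation analysis
#' is run on the paired sample set defined by the matching `m` — each
#' matching triple `(i, j, d)` contributes one sample coupling score row
#' `i` of x with score row `j` of y (an x-cell with several partners
#' contributes several samples). The leading `r` loading vectors per side
#' maximize successive correlations under the usual orthogonality
#' constraints.
#'
#' Well-posedness: by default no ridge is applied, so canonical
#' correlations retain their exact invariance properties; if a within-set
#' covariance is numerically singular (common when `|m|` is close to
#' `r`), a small ridge (`1e-4` times the mean covariance diagonal) is
#' added automatically. Pass `ridge` to override.
#'
#' @param x,y [modality_matrix()] objects (or numeric matrices).
#' @param m a [matching_pairs()] (or two-column index matrix).
#' @param rx,ry retained principal components per modality.
#' @param r joint dimension, at most `min(rx, ry)`.
#' @param ridge ridge coefficient on the within-set covariances, relative
#'   to their mean diagonal; `NULL` (default) = 0 with automatic fallback.
#' @param weight_by_degree weight each paired sample by `1 - d_ij`.
#' @param x_scores,y_scores optional precomputed score matrices (must carry
#'   the `rotation`/`center` attributes of [reduce_dimension()]).
#' @return list of class `cca_model`: loadings `Cx` (`rx x r`), `Cy`
#'   (`ry x r`), `correlations` (length `r`, non-increasing, in `[0,1]`),
#'   score matrices and pair centering used at fit time.
#' @export
fit_cca <- function(x, y, m, rx = 40, ry = 40, r = 20, ridge = NULL,
                    weight_by_degree = FALSE,
                    x_scores = NULL, y_scores = NULL) {
  pairs <- if (is.data.frame(m)) cbind(m$x, m$y) else as.matrix(m)[, 1:2]
  wts <- if (weight_by_degree && is.data.frame(m) && !is.null(m$degree)) {
    1 - m$degree
  } else rep(1, nrow(pairs))
  if (nrow(pairs) < r)
    stop_mmihcl("rank error: need at least r = ", r, " matched pairs, got ",
                nrow(pairs))
  if (is.null(x_scores)) x_scores <- reduce_dimension(x, rx)
  if (is.null(y_scores)) y_scores <- reduce_dimension(y, ry)
  rx <- ncol(x_scores); ry <- ncol(y_scores)
  if (r > min(rx, ry)) stop_mmihcl("r must be <= min(rx, ry)")

  xp <- x_scores[pairs[, 1], , drop = FALSE]
  yp <- y_scores[pairs[, 2], , drop = FALSE]
  wn <- wts / sum(wts)
  cx <- colSums(xp * wn); cy <- colSums(yp * wn)
  xp <- sweep(xp, 2, cx); yp <- sweep(yp, 2, cy)
  sxx <- crossprod(xp * sqrt(wn), xp * sqrt(wn))
  syy <- crossprod(yp * sqrt(wn), yp * sqrt(wn))
  sxy <- crossprod(xp * sqrt(wn), yp * sqrt(wn))

  if (is.null(ridge)) {
    ridge <- if (rcond_sym(sxx) < 1e-10 || rcond_sym(syy) < 1e-10) 1e-4 else 0
  }
  if (ridge > 0) {
    sxx <- sxx + diag(ridge * mean(diag(sxx)), rx)
    syy <- syy + diag(ridge * mean(diag(syy)), ry)
  }
  wx <- inv_sqrt_sym(sxx)
  wy <- inv_sqrt_sym(syy)
  sv <- svd(wx %*% sxy %*% wy, nu = r, nv = r)
  Cx <- wx %*% sv$u
  Cy <- wy %*% sv$v
  # sign convention: the largest-|entry| of each x-side loading is positive
  for (j in seq_len(r)) {
    if (Cx[which.max(abs(Cx[, j])), j] < 0) {
      Cx[, j] <- -Cx[, j]; Cy[, j] <- -Cy[, j]
    }
  }
  structure(list(Cx = Cx, Cy = Cy, r = r,
                 correlations = pmin(pmax(sv$d[seq_len(r)], 0), 1),
                 x_center = cx, y_center = cy,
                 x_scores = x_scores, y_scores = y_scores,
                 ridge = ridge, n_pairs = nrow(pairs)),
            class = "cca_model")
}

rcond_sym <- function(s) {
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# symmetric inverse square root with small-eigenvalue clipping
inv_sqrt_sym <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> r = %d (fit on %d pairs, ridge %.2g)\n",
              x$r, x$n_pairs, x$ridge))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", head(x$correlations, 5)), collapse = ", "),
      if (x$r > 5) "..." else "", "\n")
  invisible(x)
}

#' Joint embeddings from a fitted CCA model
#'
#' Projects every cell of both modalities (not only matched ones) onto the
#' canonical directions: `X_r = (X_rx - center) Cx`, `Y_r = (Y_ry - center)
#' Cy`.
#'
#' @param model a [fit_cca()] result.
#' @param x_scores,y_scores optional new score matrices; default to the
#'   ones stored at fit time.
#' @return list with `x_joint` (`nx x r`) and `y_joint` (`ny x r`).
#' @export
cca_transform <- function(model, x_scores = NULL, y_scores = NULL) {
  xs <- x_scores %||% model$x_scores
  ys <- y_scores %||% model$y_scores
  if (ncol(xs) != nrow(model$Cx) || ncol(ys) != nrow(model$Cy))
    stop_mmihcl("score dimensions do not match the fitted loadings")
  list(x_joint = sweep(xs, 2, model$x_center) %*% model$Cx,
       y_joint = sweep(ys, 2, model$y_center) %*% model$Cy)
}
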