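#' Hypergraph encoder configuration
#'
#' Hyperparameters of the dual-branch encoder `H(.)`: `L` propagation
#' layers, `K` virtual hyperedges, contrastive temperature `tau`, weight
#' decay `lambda` on the learnable incidence projection, and the training
#' schedule. Negatives default to all other cells (the exact contrastive
#' objective); for very large inputs (`n > 20000`) a seeded subsample of
#' `negatives_per_anchor` negatives per anchor is drawn each epoch.
#'
#' @param L layer count (>= 1).
#' @param K hyperedge count (>= 1).
#' @param tau softmax temperature (> 0).
#' @param lambda weight-decay coefficient (>= 0).
#' @param epochs gradient-descent epochs; 0 leaves the seeded
#'   initialization untouched (a single forward pass still defines the
#'   output).
#' @param learning_rate Adam step size.
#' @param negatives_per_anchor `"all"` or a positive count.
#' @param seed integer seed for the weight initialization (and negative
#'   subsampling, when active).
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(L = 2, K = 128, tau = 0.5, lambda = 0.01,
                           epochs = 60, learning_rate = 1e-3,
                           negatives_per_anchor = "all", seed = 1L) {
  if (L < 1) stop_mmihcl("L must be >= 1")
  if (K < 1) stop_mmihcl("K must be >= 1")
  if (tau <= 0) stop_mmihcl("tau must be > 0")
  if (lambda < 0) stop_mmihcl("lambda must be >= 0")
  if (epochs < 0) stop_mmihcl("epochs must be >= 0")
  structure(list(L = as.integer(L), K = as.integer(K), tau = tau,
                 lambda = lambda, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 negatives_per_anchor = negatives_per_anchor,
                 seed = seed),
            class = "encoder_config")
}

#' Local message passing (graph convolution without weights)
#'
#' One application of the normalized graph operator: `A_bar %*% prev`.
#'
#' @param normalized n x n normalized adjacency operator (sparse or dense).
#' @param prev n x d embedding matrix.
#' @return n x d matrix.
#' @export
local_propagate <- function(normalized, prev) {
  if (nrow(normalized) != ncol(normalized) || ncol(normalized) != nrow(prev))
    stop_mmihcl("operator and embedding dimensions disagree")
  as.matrix(normalized %*% prev)
}

#' Global message passing through a learned soft hypergraph incidence
#'
#' With incidence `H = base %*% W` mapping the n cells onto K virtual
#' hyperedges, computes `H (H^T prev)` right-to-left so only n x K and
#' K x d intermediates are materialized (never the n x n product).
#'
#' @param base n x d layer-0 embedding defining the incidence.
#' @param W d x K incidence projection weights.
#' @param prev n x d embedding to propagate.
#' @return n x d matrix.
#' @export
global_propagate <- function(base, W, prev) {
  if (ncol(base) != nrow(W)) stop_mmihcl("base and W dimensions disagree")
  if (nrow(base) != nrow(prev) || ncol(base) != ncol(prev))
    stop_mmihcl("base and prev dimensions disagree")
  h <- base %*% W
  h %*% crossprod(h, prev)
}

#' Cross-branch contrastive loss
#'
#' InfoNCE-style alignment of the two branches: per layer `l` and anchor
#' cell `i`, the positive is the cell's own global-branch embedding and the
#' negatives are all other cells' global-branch embeddings at that layer,
#' \deqn{L_c = -\sum_i \sum_l \log \frac{\exp(sim(\bar e_i^{(l)}, \tilde
#'   e_i^{(l)})/\tau)}{\sum_j \exp(sim(\bar e_i^{(l)}, \tilde
#'   e_j^{(l)})/\tau)}}
#' with cosine similarity (0 for zero-norm rows). Always >= 0; exactly 0
#' for a single cell.
#'
#' @param local_layers,global_layers lists of n x d matrices, one per layer.
#' @param tau temperature (> 0).
#' @return scalar loss.
#' @export
contrastive_loss <- function(local_layers, global_layers, tau) {
  if (tau <= 0) stop_mmihcl("tau must be > 0")
  if (!is.list(local_layers)) local_layers <- list(local_layers)
  if (!is.list(global_layers)) global_layers <- list(global_layers)
  if (length(local_layers) != length(global_layers))
    stop_mmihcl("branch layer counts differ")
  loss <- 0
  for (l in seq_along(local_layers)) {
    s <- layer_similarity(local_layers[[l]], global_layers[[l]], tau)
    loss <- loss + sum(log_row_sumexp(s)) - sum(diag(s))
  }
  loss
}

# cosine-similarity logits between branches, divided by tau
layer_similarity <- function(local, global, tau) {
  if (!all(dim(local) == dim(global)))
    stop_mmihcl("branch embedding shapes differ")
  u <- normalize_rows(local)
  v <- normalize_rows(global)
  tcrossprod(u, v) / tau
}

row_maxs <- function(s) s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]

log_row_sumexp <- function(s) {
  m <- row_maxs(s)
  m + log(rowSums(exp(s - m)))
}

# gradient of sum_i [logsumexp(S_i.) - S_ii] wrt S: softmax(S) - I
softmax_rows <- function(s) {
  e <- exp(s - row_maxs(s))
  e / rowSums(e)
}

# fused per-layer contrastive loss and branch gradients (shares the
# similarity matrix between the two)
layer_contrast <- function(eb, et, tau) {
  u <- normalize_rows(eb)
  v <- normalize_rows(et)
  s <- tcrossprod(u, v) / tau
  loss <- sum(log_row_sumexp(s)) - sum(diag(s))
  p <- softmax_rows(s)
  diag(p) <- diag(p) - 1
  list(loss = loss,
       g_eb = unnormalize_grad((p %*% v) / tau, eb),
       g_et = unnormalize_grad(crossprod(p, u) / tau, et))
}

# backprop through row normalization u = e / ||e||: given dL/du, returns
# dL/de; zero-norm rows get zero gradient.
unnormalize_grad <- function(g_u, e) {
  nrm <- sqrt(rowSums(e^2))
  nz <- nrm > 0
  u <- e
  u[nz, ] <- e[nz, , drop = FALSE] / nrm[nz]
  proj <- rowSums(g_u * u)
  out <- (g_u - proj * u)
  out[nz, ] <- out[nz, , drop = FALSE] / nrm[nz]
  out[!nz, ] <- 0
  out
}

# One forward pass: returns layer lists and fused output.
encoder_forward <- function(initial, normalized, W, L) {
  e_prev <- initial
  local_layers <- vector("list", L)
  global_layers <- vector("list", L)
  h <- initial %*% W
  for (l in seq_len(L)) {
    local_layers[[l]] <- as.matrix(normalized %*% e_prev)
    global_layers[[l]] <- h %*% crossprod(h, e_prev)
    e_prev <- local_layers[[l]] + global_layers[[l]]
  }
  fused <- Reduce(`+`, Map(`+`, local_layers, global_layers))
  list(local = local_layers, global = global_layers, fused = fused, H = h)
}

# Reverse-mode gradient of (contrastive loss + lambda ||W||^2) wrt W,
# fused with the loss evaluation. `pool` restricts anchors and negatives
# to a cell subset (minibatch InfoNCE for very large n); NULL means the
# exact all-cells objective.
encoder_backward <- function(initial, normalized, W, fw, tau, lambda,
                             pool = NULL) {
  L <- length(fw$local)
  n <- nrow(initial); d <- ncol(initial)
  h <- fw$H
  loss <- lambda * sum(W^2)
  # per-layer loss gradients wrt the two branches
  d_bar <- vector("list", L); d_til <- vector("list", L)
  for (l in seq_len(L)) {
    eb <- fw$local[[l]]; et <- fw$global[[l]]
    if (is.null(pool)) {
      lc <- layer_contrast(eb, et, tau)
      d_bar[[l]] <- lc$g_eb; d_til[[l]] <- lc$g_et
    } else {
      lc <- layer_contrast(eb[pool, , drop = FALSE],
                           et[pool, , drop = FALSE], tau)
      d_bar[[l]] <- matrix(0, n, d); d_til[[l]] <- matrix(0, n, d)
      d_bar[[l]][pool, ] <- lc$g_eb; d_til[[l]][pool, ] <- lc$g_et
    }
    loss <- loss + lc$loss
  }
  # walk layers backwards, accumulating the adjoint of E^(l) and of H
  c_adj <- matrix(0, n, d)
  g_h <- matrix(0, n, ncol(W))
  at <- Matrix::t(normalized)
  for (l in rev(seq_len(L))) {
    e_in <- if (l == 1) initial else fw$local[[l - 1]] + fw$global[[l - 1]]
    pb <- d_bar[[l]] + c_adj
    pt <- d_til[[l]] + c_adj
    g_h <- g_h + pt %*% (crossprod(e_in, h)) + e_in %*% (crossprod(pt, h))
    c_adj <- as.matrix(at %*% pb) + h %*% crossprod(h, pt)
  }
  list(grad = crossprod(initial, g_h) + 2 * lambda * W, loss = loss)
}

#' Train the hypergraph encoder
#'
#' Initializes the incidence projection `W` from a seeded scaled-normal
#' draw (scaled so the global branch starts on the same footing as the
#' local one), then minimizes the contrastive loss plus `lambda * ||W||^2`
#' by Adam. Bitwise-reproducible for a fixed seed; aborts with the epoch
#' index if the loss turns non-finite.
#'
#' @param initial n x d embedding matrix `E^(0)`.
#' @param normalized n x n normalized graph operator.
#' @param config an [encoder_config()].
#' @return list of class `hypergraph_encoder`: `W`, `local_layers`,
#'   `global_layers`, `fused` (the summed output), `loss_trace`, `config`.
#' @export
train_encoder <- function(initial, normalized, config = encoder_config()) {
  initial <- as.matrix(initial)
  if (any(!is.finite(initial))) stop_mmihcl("initial embeddings must be finite")
  n <- nrow(initial); d <- ncol(initial)
  K <- config$K; tau <- config$tau; lambda <- config$lambda
  # scale the init so H H^T E has entries comparable to E itself
  sd_e <- sqrt(mean(initial^2))
  if (sd_e == 0) sd_e <- 1
  sd_w <- 1 / (sd_e * sqrt(n * K * d))
  W <- with_seed(config$seed,
                 matrix(rnorm(d * K, sd = sd_w), d, K))
  m <- matrix(0, d, K); v <- matrix(0, d, K)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(config$epochs)
  pool_size <- if (!identical(config$negatives_per_anchor, "all")) {
    min(n, as.integer(config$negatives_per_anchor))
  } else if (n > 20000) 1024L else n
  pool_seeds <- if (pool_size < n)
    derive_seeds(config$seed %||% 0L, config$epochs)
  for (epoch in seq_len(config$epochs)) {
    fw <- encoder_forward(initial, normalized, W, config$L)
    pool <- if (pool_size < n)
      with_seed(pool_seeds[epoch], sort(sample.int(n, pool_size)))
    bw <- encoder_backward(initial, normalized, W, fw, tau, lambda, pool)
    if (!is.finite(bw$loss))
      stop_mmihcl("encoder training diverged (non-finite loss) at epoch ", epoch)
    trace[epoch] <- bw$loss
    g <- bw$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^epoch)
    vh <- v / (1 - b2^epoch)
    W <- W - config$learning_rate * mh / (sqrt(vh) + eps)
  }
  fw <- encoder_forward(initial, normalized, W, config$L)
  structure(list(W = W, local_layers = fw$local, global_layers = fw$global,
                 fused = fw$fused, loss_trace = trace, config = config),
            class = "hypergraph_encoder")
}

#' @export
print.hypergraph_encoder <- function(x, ...) {
  cat(sprintf("<hypergraph_encoder> n = %d, d = %d, K = %d, L = %d\n",
              nrow(x$fused), ncol(x$fused), x$config$K, x$config$L))
  if (length(x$loss_trace))
    cat(sprintf("  loss: %.4f -> %.4f over %d epochs\n",
                x$loss_trace[1], x$loss_trace[length(x$loss_trace)],
                length(x$loss_trace)))
  invisible(x)
}

#' Hypergraph embedding `H(E, A_bar)`
#'
#' Convenience wrapper over [train_encoder()] returning only the fused
#' n x d output embedding (the layer-wise sum of both branches).
#'
#' @inheritParams train_encoder
#' @return n x d matrix.
#' @export
encode <- function(initial, normalized, config = encoder_config()) {
  train_encoder(initial, normalized, config)$fused
}
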