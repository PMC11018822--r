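#' @importFrom Matrix sparseMatrix t crossprod
NULL

# Per-relation normalized adjacency: A_r[i, j] = 1/c_{i,r} for each edge
# (j, r, i), with c_{i,r} = |N_i^r| (the in-neighbor count of i under r).
.rgcn_adj <- function(kg) {
  n <- nrow(kg$entities)
  lapply(seq_along(kg$relations), function(r) {
    sel <- kg$.r_id == r
    i <- kg$.t_id[sel]; j <- kg$.h_id[sel]
    if (!length(i))
      return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(n, n)))
    cir <- tabulate(i, nbins = n)
    Matrix::sparseMatrix(i = i, j = j, x = 1 / cir[i], dims = c(n, n))
  })
}

#' Initialize R-GCN parameters
#'
#' Learnable input node embeddings, per-relation and self-loop weight
#' matrices for each layer, and DistMult decoder relation vectors. The
#' normalization constants \eqn{c_{i,r}} are fixed to the in-neighbor counts
#' \eqn{|N_i^r|}.
#'
#' @param kg a `kgraph`.
#' @param dims integer vector of layer widths, `dims[1]` the input embedding
#'   dimension and subsequent entries the output width of each convolution
#'   layer (length >= 2 means at least one layer).
#' @param dropout dropout rate applied to layer outputs in training mode.
#' @param activation `"relu"` (default) or `"identity"` (used by exactness
#'   tests).
#' @param seed RNG seed for initialization.
#' @return object of class `rgcn_params`.
#' @export
rgcn_params <- function(kg, dims = c(64, 64), dropout = 0.2,
                        activation = c("relu", "identity"), seed = 1) {
  activation <- match.arg(activation)
  set.seed(seed)
  ne <- nrow(kg$entities); nr <- length(kg$relations)
  layers <- vector("list", length(dims) - 1)
  for (l in seq_along(layers)) {
    din <- dims[l]; dout <- dims[l + 1]
    layers[[l]] <- list(Wr = lapply(seq_len(nr), function(r)
      .xavier(dout, din)), W0 = .xavier(dout, din))
  }
  structure(list(X0 = .xavier(ne, dims[1]), layers = layers,
                 decoder = .xavier(nr, dims[length(dims)]),
                 dims = dims, dropout = dropout, activation = activation),
            class = "rgcn_params")
}

.act <- function(Z, kind) if (kind == "relu") pmax(Z, 0) else Z
.act_grad <- function(Z, kind) if (kind == "relu") (Z > 0) * 1 else
  array(1, dim(Z))

#' R-GCN forward pass
#'
#' Per node and layer computes
#' \deqn{x_i^{(l+1)} = \sigma\Big(\sum_{r} \sum_{j \in N_i^r}
#'   \frac{1}{c_{i,r}} W_r^{(l)} x_j^{(l)} + W_0^{(l)} x_i^{(l)}\Big)}
#' where \eqn{N_i^r} are the in-neighbors of node `i` under relation `r` and
#' \eqn{c_{i,r} = |N_i^r|}. Isolated nodes receive only the self-loop term.
#' In training mode, dropout is applied to each layer's output.
#'
#' @param kg a `kgraph`.
#' @param params an `rgcn_params`.
#' @param node_states input states (defaults to `params$X0`).
#' @param training apply dropout (`FALSE` for deterministic evaluation).
#' @return matrix of final node states (one row per entity).
#' @export
rgcn_forward <- function(kg, params, node_states = params$X0,
                         training = FALSE) {
  .rgcn_forward_cache(kg, params, node_states, training)$X
}

.rgcn_forward_cache <- function(kg, params, node_states, training) {
  A <- .rgcn_adj(kg)
  X <- node_states
  cache <- list(inputs = list(), pre = list(), masks = list(), A = A)
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    cache$inputs[[l]] <- X
    Z <- X %*% t(lay$W0)
    for (r in seq_along(A)) {
      M <- as.matrix(A[[r]] %*% X)
      Z <- Z + M %*% t(lay$Wr[[r]])
    }
    cache$pre[[l]] <- Z
    X <- .act(Z, params$activation)
    if (training && params$dropout > 0) {
      keep <- 1 - params$dropout
      mask <- matrix(stats::runif(length(X)) < keep, nrow(X)) / keep
      cache$masks[[l]] <- mask
      X <- X * mask
    } else cache$masks[l] <- list(NULL)
  }
  list(X = X, cache = cache)
}

#' DistMult decoder score on encoded states
#'
#' Identical contract to [score_distmult()] applied to encoder outputs:
#' `s = sum(states[h] * decoder[r] * states[t])`. Vectorized over triples.
#'
#' @param node_states encoder output matrix.
#' @param relation_vectors decoder relation matrix.
#' @param h,r,t integer indices (entity rows / relation rows).
#' @return numeric score vector.
#' @export
rgcn_score <- function(node_states, relation_vectors, h, r, t) {
  if (any(h > nrow(node_states)) || any(t > nrow(node_states)) ||
      any(r > nrow(relation_vectors)))
    stop("unknown entity or relation index")
  rowSums(node_states[h, , drop = FALSE] *
            relation_vectors[r, , drop = FALSE] *
            node_states[t, , drop = FALSE])
}

# Loss and analytic gradients for one full-graph R-GCN training step.
# pos/neg are integer-id triples; returns loss plus gradients shaped like
# params. Used by the SGD loop and by the finite-difference gradient test.
.rgcn_loss_grads <- function(kg, params, pos, neg, l2_decoder = 0.01,
                             training = FALSE) {
  fc <- .rgcn_forward_cache(kg, params, params$X0, training)
  X <- fc$X; cache <- fc$cache
  hidx <- c(pos$h, neg$h); ridx <- c(pos$r, neg$r); tidx <- c(pos$t, neg$t)
  y <- c(rep(1, length(pos$h)), rep(0, length(neg$h)))
  s <- rgcn_score(X, params$decoder, hidx, ridx, tidx)
  omega <- length(neg$h) / max(1, length(pos$h))
  spec <- loss_spec(neg_ratio = omega, edge_count = length(pos$h))
  loss <- bce_link_loss(s, y, spec)
  loss <- loss + l2_decoder * sum(params$decoder^2)
  # dL/ds of the printed normalized cross-entropy
  norm <- (1 + omega) * length(pos$h)
  g <- (stats::plogis(s) - y) / norm
  H <- X[hidx, , drop = FALSE]; T <- X[tidx, , drop = FALSE]
  D <- params$decoder[ridx, , drop = FALSE]
  dDec <- .acc(nrow(params$decoder), ridx, g * (H * T)) +
    2 * l2_decoder * params$decoder
  Gx <- .acc(nrow(X), hidx, g * (D * T)) + .acc(nrow(X), tidx, g * (H * D))
  grads <- list(layers = vector("list", length(params$layers)),
                decoder = dDec)
  for (l in rev(seq_along(params$layers))) {
    lay <- params$layers[[l]]
    if (!is.null(cache$masks[[l]])) Gx <- Gx * cache$masks[[l]]
    Gz <- Gx * .act_grad(cache$pre[[l]], params$activation)
    Xin <- cache$inputs[[l]]
    dW0 <- as.matrix(crossprod(Gz, Xin))  # t(Gz) %*% Xin : dout x din
    dWr <- vector("list", length(cache$A))
    Gin <- Gz %*% lay$W0
    for (r in seq_along(cache$A)) {
      M <- as.matrix(cache$A[[r]] %*% Xin)
      dWr[[r]] <- as.matrix(crossprod(Gz, M))
      Gin <- Gin + as.matrix(Matrix::t(cache$A[[r]]) %*% (Gz %*% lay$Wr[[r]]))
    }
    grads$layers[[l]] <- list(Wr = dWr, W0 = dW0)
    Gx <- Gin
  }
  grads$X0 <- Gx
  list(loss = loss, grads = grads, states = X)
}
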