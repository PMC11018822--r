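#' Circular correlation composition
#'
#' The compositional operator
#' \eqn{\phi(a, b)_i = \sum_j a_j\, b_{(j+i) \bmod d}} (indices 0-based),
#' computed via FFT: \eqn{\phi(a,b) = \mathcal{F}^{-1}(\overline{\mathcal{F}(a)}
#' \odot \mathcal{F}(b))}. Correlating the unit impulse (first argument)
#' against `b` returns `b` unchanged.
#'
#' @param a,b numeric vectors of equal length, or matrices correlated
#'   row-wise.
#' @return vector or matrix of the same shape.
#' @export
circular_correlation <- function(a, b) {
  if (is.matrix(a)) {
    d <- ncol(a)
    FA <- stats::mvfft(t(a)); FB <- stats::mvfft(t(b))
    t(Re(stats::mvfft(Conj(FA) * FB, inverse = TRUE))) / d
  } else {
    d <- length(a)
    Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / d
  }
}

# row-wise circular convolution (used by the ccorr backward pass)
.circ_conv <- function(a, b) {
  d <- ncol(a)
  FA <- stats::mvfft(t(a)); FB <- stats::mvfft(t(b))
  t(Re(stats::mvfft(FA * FB, inverse = TRUE))) / d
}

.compose <- function(x, y, op) {
  switch(op,
         subtraction = x - y,
         multiplication = x * y,
         circular_correlation = circular_correlation(x, y))
}

# backward of z = .compose(x, y, op) given upstream gradient G
.compose_grad <- function(G, x, y, op) {
  switch(op,
    subtraction = list(dx = G, dy = -G),
    multiplication = list(dx = G * y, dy = G * x),
    circular_correlation = list(dx = circular_correlation(G, y),
                                dy = .circ_conv(x, G)))
}

#' Initialize CompGCN parameters
#'
#' Learnable node embeddings, relation embeddings for original, inverse and
#' self-loop edge classes, direction-specific layer weights
#' (`W_O`, `W_I`, `W_S`), a relation projection `W_rel` per layer, and a ConvE
#' decoder. Every triple `(h, r, t)` is materialized as an original edge, an
#' inverse edge `(t, r_inv, h)`, and each node carries a self-loop.
#'
#' @param kg a `kgraph`.
#' @param dims layer widths as in [rgcn_params()].
#' @param composition one of `"circular_correlation"` (default),
#'   `"subtraction"`, `"multiplication"`.
#' @param conve decoder geometry from [conve_config()] (built from the final
#'   width if `NULL`).
#' @param feature_dropout dropout on input features (training mode).
#' @param layer_dropout dropout after each layer (training mode).
#' @param seed RNG seed.
#' @return object of class `compgcn_params`.
#' @export
compgcn_params <- function(kg, dims = c(32, 32),
                           composition = c("circular_correlation",
                                           "subtraction", "multiplication"),
                           conve = NULL, feature_dropout = 0.1,
                           layer_dropout = 0.3, seed = 1) {
  composition <- match.arg(composition)
  set.seed(seed)
  ne <- nrow(kg$entities); nr <- length(kg$relations)
  layers <- lapply(seq_len(length(dims) - 1), function(l) {
    din <- dims[l]; dout <- dims[l + 1]
    list(W_O = .xavier(dout, din), W_I = .xavier(dout, din),
         W_S = .xavier(dout, din), W_rel = .xavier(dout, din))
  })
  dL <- dims[length(dims)]
  if (is.null(conve)) conve <- conve_config(dL, seed = seed + 1)
  structure(list(X0 = .xavier(ne, dims[1]),
                 Y0 = .xavier(2 * nr + 1, dims[1]),
                 layers = layers, dims = dims, composition = composition,
                 conve = conve, feature_dropout = feature_dropout,
                 layer_dropout = layer_dropout, n_relations = nr),
            class = "compgcn_params")
}

#' CompGCN forward pass
#'
#' Updates node states as \eqn{x_i \leftarrow f\big(\sum_{(j,k)}
#' W_{\lambda(k)} \phi(x_j, y_k)\big)}, summing over original, inverse and
#' self-loop edges incident to `i` (with direction-specific weights), and
#' updates relation states as \eqn{y_k \leftarrow W_{rel}\, y_k}. The outer
#' activation `f` is tanh.
#'
#' @param kg a `kgraph`.
#' @param params a `compgcn_params`.
#' @param node_states,rel_states input states (default the learnable
#'   embeddings).
#' @param training apply dropout masks.
#' @return list with updated `node_states` and `rel_states` (relation rows:
#'   original, then inverse, then self-loop).
#' @export
compgcn_forward <- function(kg, params, node_states = params$X0,
                            rel_states = params$Y0, training = FALSE) {
  fc <- .compgcn_forward_cache(kg, params, node_states, rel_states, training)
  list(node_states = fc$X, rel_states = fc$Y)
}

.compgcn_forward_cache <- function(kg, params, X, Y, training) {
  nr <- params$n_relations
  ne <- nrow(X)
  op <- params$composition
  hi <- kg$.h_id; ri <- kg$.r_id; ti <- kg$.t_id
  classes <- list(
    O = list(src = hi, rel = ri, tgt = ti, W = "W_O"),
    I = list(src = ti, rel = ri + nr, tgt = hi, W = "W_I"),
    S = list(src = seq_len(ne), rel = rep(2L * nr + 1L, ne),
             tgt = seq_len(ne), W = "W_S"))
  cache <- list(layers = list(), in_mask = NULL)
  if (training && params$feature_dropout > 0) {
    keep <- 1 - params$feature_dropout
    m <- matrix(stats::runif(length(X)) < keep, nrow(X)) / keep
    cache$in_mask <- m
    X <- X * m
  }
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    lc <- list(Xin = X, Yin = Y, msgs = list())
    Z <- matrix(0, ne, nrow(lay$W_O))
    for (cl in names(classes)) {
      ed <- classes[[cl]]
      M <- .compose(X[ed$src, , drop = FALSE], Y[ed$rel, , drop = FALSE], op)
      lc$msgs[[cl]] <- M
      Z <- Z + .acc(ne, ed$tgt, M %*% t(lay[[ed$W]]))
    }
    lc$Z <- Z
    Xn <- tanh(Z)
    if (training && params$layer_dropout > 0) {
      keep <- 1 - params$layer_dropout
      m <- matrix(stats::runif(length(Xn)) < keep, nrow(Xn)) / keep
      lc$mask <- m
      Xn <- Xn * m
    }
    Y <- Y %*% t(lay$W_rel)
    cache$layers[[l]] <- lc
    X <- Xn
  }
  list(X = X, Y = Y, cache = cache, classes = classes)
}

#' ConvE decoder configuration and weights
#'
#' The decoder reshapes the head and relation vectors into 2-D maps, stacks
#' them, convolves with a bank of filters (stride 1, no padding), applies
#' ReLU, flattens, linearly projects back to the embedding dimension, applies
#' ReLU again, and scores by the inner product with the tail embedding plus a
#' global bias. Dropout rates of 0.3 on the feature maps and 0.3 on the
#' hidden projection apply only in training mode.
#'
#' @param d embedding dimension; must equal `emb_h * emb_w`.
#' @param emb_h,emb_w reshape geometry (chosen near-square when omitted).
#' @param n_filters number of convolution filters.
#' @param kernel square kernel size.
#' @param hidden_dropout,feature_dropout training-mode dropout rates.
#' @param seed RNG seed for weight initialization.
#' @return object of class `conve_config` (geometry plus weights).
#' @export
conve_config <- function(d, emb_h = NULL, emb_w = NULL, n_filters = 8,
                         kernel = 3, hidden_dropout = 0.3,
                         feature_dropout = 0.3, seed = 1) {
  if (is.null(emb_h)) {
    emb_h <- max(Filter(function(f) f <= sqrt(d), seq_len(d)[d %% seq_len(d) == 0]))
    emb_w <- d %/% emb_h
  }
  if (is.null(emb_w)) emb_w <- d %/% emb_h
  if (emb_h * emb_w != d)
    stop("hidden dimension ", d, " cannot be reshaped to ", emb_h, "x", emb_w)
  ih <- 2 * emb_h; iw <- emb_w
  if (ih < kernel || iw < kernel)
    stop("stacked ", ih, "x", iw, " map smaller than the ", kernel,
         " kernel")
  oh <- ih - kernel + 1; ow <- iw - kernel + 1
  np <- oh * ow; ke <- kernel * kernel
  set.seed(seed)
  # perm: stacked-image flat index -> column of cbind(h_map, r_map)
  perm <- integer(ih * iw)
  for (q in seq_len(iw)) for (p in seq_len(ih)) {
    l <- (q - 1) * ih + p
    perm[l] <- if (p <= emb_h) (q - 1) * emb_h + p
    else d + (q - 1) * emb_h + (p - emb_h)
  }
  # patch index matrix: np x ke, flat indices into the stacked image
  Pidx <- matrix(0L, np, ke)
  pos <- 0
  for (qw in seq_len(ow)) for (ph in seq_len(oh)) {
    pos <- pos + 1
    e <- 0
    for (kq in seq_len(kernel)) for (kp in seq_len(kernel)) {
      e <- e + 1
      Pidx[pos, e] <- (qw + kq - 2) * ih + (ph + kp - 1)
    }
  }
  structure(list(d = d, emb_h = emb_h, emb_w = emb_w, n_filters = n_filters,
                 kernel = kernel, oh = oh, ow = ow, np = np, ke = ke,
                 perm = perm, Pidx = Pidx,
                 hidden_dropout = hidden_dropout,
                 feature_dropout = feature_dropout,
                 K = .xavier(n_filters, ke), bf = numeric(n_filters),
                 Wp = .xavier(np * n_filters, d), bp = numeric(d),
                 b0 = 0),
            class = "conve_config")
}

# forward pass of the ConvE decoder over a batch of (h, r, t) index triples;
# returns scores plus the cache needed for backprop
.conve_forward <- function(dec, X, Y, h, r, t, training = FALSE) {
  B <- length(h)
  H <- X[h, , drop = FALSE]; Rm <- Y[r, , drop = FALSE]
  Tm <- X[t, , drop = FALSE]
  Src <- cbind(H, Rm)
  Im <- Src[, dec$perm, drop = FALSE]
  G <- Im[, as.vector(dec$Pidx), drop = FALSE]       # B x (np*ke), e-major
  Gr <- matrix(array(G, c(B, dec$np, dec$ke)), B * dec$np, dec$ke)
  pre <- Gr %*% t(dec$K)
  pre <- sweep(pre, 2, dec$bf, "+")                  # (B*np) x nf
  Fmap <- pmax(pre, 0)
  fmask <- NULL
  if (training && dec$feature_dropout > 0) {
    keep <- 1 - dec$feature_dropout
    fmask <- matrix(stats::runif(length(Fmap)) < keep, nrow(Fmap)) / keep
    Fmap <- Fmap * fmask
  }
  Fm <- matrix(array(Fmap, c(B, dec$np, dec$n_filters)), B,
               dec$np * dec$n_filters)
  Vp <- sweep(Fm %*% dec$Wp, 2, dec$bp, "+")
  V <- pmax(Vp, 0)
  hmask <- NULL
  if (training && dec$hidden_dropout > 0) {
    keep <- 1 - dec$hidden_dropout
    hmask <- matrix(stats::runif(length(V)) < keep, nrow(V)) / keep
    V <- V * hmask
  }
  s <- rowSums(V * Tm) + dec$b0
  list(s = s, cache = list(B = B, H = H, Rm = Rm, Tm = Tm, Im = Im, Gr = Gr,
                           pre = pre, Fmap = Fmap, Fm = Fm, Vp = Vp, V = V,
                           fmask = fmask, hmask = hmask, h = h, r = r, t = t))
}

#' Score a triple with the ConvE decoder
#'
#' Evaluation-mode (deterministic, dropout disabled) decoder score over
#' encoded node and relation states; see [conve_config()] for the
#' architecture.
#'
#' @param node_states encoder node-state matrix.
#' @param rel_states encoder relation-state matrix (original relations in the
#'   leading rows).
#' @param h,r,t integer indices.
#' @param decoder_cfg a [conve_config()] whose `d` matches the state width.
#' @return numeric score vector.
#' @export
conve_score <- function(node_states, rel_states, h, r, t, decoder_cfg) {
  stopifnot(inherits(decoder_cfg, "conve_config"))
  if (ncol(node_states) != decoder_cfg$d)
    stop("state width does not match decoder reshape")
  .conve_forward(decoder_cfg, node_states, rel_states, h, r, t,
                 training = FALSE)$s
}

# backward pass of the ConvE decoder: gs = dL/ds (length B).
# Returns grads for decoder weights and for the h/r/t state rows.
.conve_backward <- function(dec, cc, gs) {
  B <- cc$B
  dV <- gs * cc$Tm
  dT <- gs * cc$V
  if (!is.null(cc$hmask)) dV <- dV * cc$hmask
  dVp <- dV * (cc$Vp > 0)
  dWp <- crossprod(cc$Fm, dVp)
  dbp <- colSums(dVp)
  dFm <- dVp %*% t(dec$Wp)
  dFmap <- matrix(array(dFm, c(B, dec$np, dec$n_filters)), B * dec$np,
                  dec$n_filters)
  if (!is.null(cc$fmask)) dFmap <- dFmap * cc$fmask
  dpre <- dFmap * (cc$pre > 0)
  dK <- crossprod(dpre, cc$Gr)
  dbf <- colSums(dpre)
  dGr <- dpre %*% dec$K
  dG <- matrix(array(dGr, c(B, dec$np, dec$ke)), B, dec$np * dec$ke)
  L <- length(dec$perm)
  dIm <- matrix(0, B, L)
  targets <- as.vector(dec$Pidx)
  for (u in unique(targets)) {
    cols <- which(targets == u)
    dIm[, u] <- dIm[, u] + if (length(cols) == 1) dG[, cols] else
      rowSums(dG[, cols, drop = FALSE])
  }
  dSrc <- dIm[, match(seq_len(L), dec$perm), drop = FALSE]
  d <- dec$d
  list(dH = dSrc[, seq_len(d), drop = FALSE],
       dR = dSrc[, d + seq_len(d), drop = FALSE],
       dT = dT, dK = dK, dbf = dbf, dWp = dWp, dbp = dbp, db0 = sum(gs))
}

# Loss and analytic gradients for one full-graph CompGCN training step.
.compgcn_loss_grads <- function(kg, params, pos, neg, training = FALSE) {
  fc <- .compgcn_forward_cache(kg, params, params$X0, params$Y0, training)
  X <- fc$X; Y <- fc$Y
  hidx <- c(pos$h, neg$h); ridx <- c(pos$r, neg$r); tidx <- c(pos$t, neg$t)
  y <- c(rep(1, length(pos$h)), rep(0, length(neg$h)))
  dec <- params$conve
  fwd <- .conve_forward(dec, X, Y, hidx, ridx, tidx, training)
  omega <- length(neg$h) / max(1, length(pos$h))
  spec <- loss_spec(neg_ratio = omega, edge_count = length(pos$h))
  loss <- bce_link_loss(fwd$s, y, spec)
  norm <- (1 + omega) * length(pos$h)
  gs <- (stats::plogis(fwd$s) - y) / norm
  db <- .conve_backward(dec, fwd$cache, gs)
  ne <- nrow(X)
  Gx <- .acc(ne, hidx, db$dH) + .acc(ne, tidx, db$dT)
  Gy <- .acc(nrow(Y), ridx, db$dR)
  op <- params$composition
  grads <- list(layers = vector("list", length(params$layers)),
                conve = list(dK = db$dK, dbf = db$dbf, dWp = db$dWp,
                             dbp = db$dbp, db0 = db$db0))
  classes <- fc$classes
  for (l in rev(seq_along(params$layers))) {
    lay <- params$layers[[l]]
    lc <- fc$cache$layers[[l]]
    # relation projection backward: Yout = Yin %*% t(W_rel)
    dW_rel <- crossprod(Gy, lc$Yin)
    GyIn <- Gy %*% lay$W_rel
    if (!is.null(lc$mask)) Gx <- Gx * lc$mask
    Gz <- Gx * (1 - tanh(lc$Z)^2)
    GxIn <- matrix(0, nrow(lc$Xin), ncol(lc$Xin))
    gl <- list(W_rel = dW_rel)
    for (cl in names(classes)) {
      ed <- classes[[cl]]
      M <- lc$msgs[[cl]]
      Gt <- Gz[ed$tgt, , drop = FALSE]
      gl[[ed$W]] <- crossprod(Gt, M)
      dM <- Gt %*% lay[[ed$W]]
      cg <- .compose_grad(dM, lc$Xin[ed$src, , drop = FALSE],
                          lc$Yin[ed$rel, , drop = FALSE], op)
      GxIn <- GxIn + .acc(nrow(GxIn), ed$src, cg$dx)
      GyIn <- GyIn + .acc(nrow(GyIn), ed$rel, cg$dy)
    }
    grads$layers[[l]] <- gl
    Gx <- GxIn
    Gy <- GyIn
  }
  if (!is.null(fc$cache$in_mask)) Gx <- Gx * fc$cache$in_mask
  grads$X0 <- Gx
  grads$Y0 <- Gy
  list(loss = loss, grads = grads)
}
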