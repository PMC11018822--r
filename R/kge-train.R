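#' Training configuration for embedding link-prediction models
#'
#' @param model one of `"transe"`, `"rotate"`, `"distmult"`, `"complex"`.
#' @param learning_rate Adagrad step size.
#' @param hidden_dim embedding dimension `d`.
#' @param regularization_coeff L2 coefficient (DistMult/ComplEx logistic
#'   loss).
#' @param batch_size positives per mini-batch.
#' @param neg_ratio negatives sampled per positive (`omega`, default 20,
#'   the 1:20 positive:negative ratio).
#' @param epochs training epochs; 0 returns the initialization.
#' @param norm_order TransE norm, 1 or 2.
#' @param margin ranking margin `gamma` for the translational models.
#' @param seed RNG seed; fixes initialization and negative sampling.
#' @return object of class `kge_config`.
#' @export
kge_config <- function(model = c("transe", "rotate", "distmult", "complex"),
                       learning_rate = 0.25, hidden_dim = 64,
                       regularization_coeff = 1e-6, batch_size = 512,
                       neg_ratio = 20, epochs = 50, norm_order = 2,
                       margin = 2, seed = 1) {
  model <- match.arg(model)
  if (neg_ratio < 1) stop("neg_ratio must be >= 1")
  if (hidden_dim <= 0) stop("hidden_dim must be positive")
  if (!norm_order %in% c(1, 2)) stop("norm_order must be 1 or 2")
  structure(list(model = model, learning_rate = learning_rate,
                 hidden_dim = hidden_dim,
                 regularization_coeff = regularization_coeff,
                 batch_size = batch_size, neg_ratio = neg_ratio,
                 epochs = epochs, norm_order = norm_order, margin = margin,
                 seed = seed),
            class = "kge_config")
}

#' Filtered negative sampling by head/tail corruption
#'
#' Draws `ratio` corrupted triples per positive by replacing the head or the
#' tail (never both) with a uniformly sampled entity, rejecting corruptions
#' that are present in the graph (corruption with filtering). Reproducible
#' under `seed`.
#'
#' @param kg a `kgraph` (supplies the entity vocabulary and the filter).
#' @param positives `data.frame` with columns head, relation, tail.
#' @param ratio negatives per positive.
#' @param seed optional RNG seed.
#' @param max_tries redraw rounds before giving up.
#' @return `data.frame` (head, relation, tail, pos_index, side) with exactly
#'   `ratio * nrow(positives)` rows; errors if valid corruptions cannot be
#'   found (dense toy graphs), advising a smaller ratio.
#' @export
sample_negatives <- function(kg, positives, ratio, seed = NULL,
                             max_tries = 50) {
  if (nrow(kg$entities) < 2) stop("entity vocabulary must exceed 1")
  if (!is.null(seed)) set.seed(seed)
  ents <- kg$entities$concept_id
  n <- nrow(positives) * ratio
  idx <- rep(seq_len(nrow(positives)), each = ratio)
  side <- sample(c("head", "tail"), n, replace = TRUE)
  h <- positives$head[idx]; r <- positives$relation[idx]
  t <- positives$tail[idx]
  h[side == "head"] <- sample(ents, sum(side == "head"), replace = TRUE)
  t[side == "tail"] <- sample(ents, sum(side == "tail"), replace = TRUE)
  bad <- contains_triple(kg, h, r, t)
  tries <- 0
  while (any(bad)) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not draw ", ratio, " valid filtered corruptions per ",
           "positive after ", max_tries, " rounds; the graph may be too ",
           "dense -- consider a smaller neg_ratio")
    k <- which(bad)
    resample <- sample(ents, length(k), replace = TRUE)
    hk <- h[k]; tk <- t[k]
    hk[side[k] == "head"] <- resample[side[k] == "head"]
    tk[side[k] == "tail"] <- resample[side[k] == "tail"]
    h[k] <- hk; t[k] <- tk
    bad[k] <- contains_triple(kg, h[k], r[k], t[k])
  }
  data.frame(head = h, relation = r, tail = t, pos_index = idx, side = side,
             stringsAsFactors = FALSE)
}

# Fast integer-id corruption used inside training loops: redraws a few
# rounds, then drops still-colliding rows (rare on sparse graphs).
.corrupt_ids <- function(kg, hi, ri, ti, ratio) {
  n <- length(hi) * ratio
  idx <- rep(seq_along(hi), each = ratio)
  ch <- hi[idx]; cr <- ri[idx]; ct <- ti[idx]
  ne <- nrow(kg$entities)
  corrupt_head <- sample(c(TRUE, FALSE), n, replace = TRUE)
  draw <- sample.int(ne, n, replace = TRUE)
  ch[corrupt_head] <- draw[corrupt_head]
  ct[!corrupt_head] <- draw[!corrupt_head]
  ids <- kg$entities$concept_id
  key <- kg_key(ids[ch], kg$relations[cr], ids[ct])
  bad <- key %in% kg$.keys
  for (round in 1:5) {
    if (!any(bad)) break
    k <- which(bad)
    draw <- sample.int(ne, length(k), replace = TRUE)
    ch[k][corrupt_head[k]] <- draw[corrupt_head[k]]
    ct[k][!corrupt_head[k]] <- draw[!corrupt_head[k]]
    bad[k] <- kg_key(ids[ch[k]], kg$relations[cr[k]], ids[ct[k]]) %in% kg$.keys
  }
  keep <- !bad
  list(h = ch[keep], r = cr[keep], t = ct[keep], pos = idx[keep])
}

.xavier <- function(nr, nc) {
  b <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Train a knowledge-graph embedding model
#'
#' Fits one of the four embedding models by Adagrad-scaled stochastic
#' gradient descent with filtered negative sampling. The translational models (TransE, RotatE)
#' minimize the margin ranking loss
#' \eqn{\max(0, \gamma + s(pos) - s(neg))} on distances; the semantic
#' matching models (DistMult, ComplEx) minimize a pointwise logistic loss
#' with L2 regularization. Gradients are analytic; training is deterministic
#' given the seed.
#'
#' @param kg a nonempty `kgraph`.
#' @param cfg a [kge_config()].
#' @return object of class `embedding_table`: entity and relation matrices
#'   (complex for RotatE/ComplEx), dimension `d`, vocabulary ids, the model
#'   name and per-epoch mean loss history.
#' @export
train_kge <- function(kg, cfg) {
  stopifnot(inherits(cfg, "kge_config"))
  if (nrow(kg$triples) == 0) stop("cannot train on an empty graph")
  set.seed(cfg$seed)
  d <- cfg$hidden_dim
  ne <- nrow(kg$entities); nr <- length(kg$relations)
  hi <- kg$.h_id; ri <- kg$.r_id; ti <- kg$.t_id
  npos <- length(hi)
  complex_model <- cfg$model %in% c("rotate", "complex")
  E <- .xavier(ne, d); R <- .xavier(nr, d)
  Ei <- Ri <- NULL
  if (complex_model) Ei <- .xavier(ne, d)
  if (cfg$model == "complex") Ri <- .xavier(nr, d)
  if (cfg$model == "rotate") R <- matrix(stats::runif(nr * d, 0, 2 * pi),
                                         nr, d)  # phases
  loss_hist <- numeric(0)
  lr <- cfg$learning_rate
  omega <- cfg$neg_ratio
  # Adagrad accumulators (per-parameter step scaling)
  GE <- 0 * E; GR <- 0 * R
  GEi <- if (!is.null(Ei)) 0 * Ei
  GRi <- if (!is.null(Ri)) 0 * Ri
  ada <- function(P, Gacc, g) {
    Gacc <- Gacc + g^2
    list(P = P - lr * g / sqrt(Gacc + 1e-10), G = Gacc)
  }
  for (epoch in seq_len(cfg$epochs)) {
    if (cfg$model == "transe") {
      nrm <- sqrt(rowSums(E^2)); nrm[nrm < 1e-12] <- 1
      E <- E / nrm
    }
    perm <- sample.int(npos)
    ep_loss <- 0; ep_n <- 0
    for (b in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      neg <- .corrupt_ids(kg, hi[b], ri[b], ti[b], omega)
      upd <- switch(cfg$model,
        transe = .step_transe(E, R, hi[b], ri[b], ti[b], neg, cfg),
        rotate = .step_rotate(E, Ei, R, hi[b], ri[b], ti[b], neg, cfg),
        distmult = .step_distmult(E, R, hi[b], ri[b], ti[b], neg, cfg),
        complex = .step_complex(E, Ei, R, Ri, hi[b], ri[b], ti[b], neg, cfg))
      if (!is.finite(upd$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      a <- ada(E, GE, upd$dE); E <- a$P; GE <- a$G
      a <- ada(R, GR, upd$dR); R <- a$P; GR <- a$G
      if (!is.null(upd$dEi)) { a <- ada(Ei, GEi, upd$dEi); Ei <- a$P; GEi <- a$G }
      if (!is.null(upd$dRi)) { a <- ada(Ri, GRi, upd$dRi); Ri <- a$P; GRi <- a$G }
      ep_loss <- ep_loss + upd$loss * upd$n
      ep_n <- ep_n + upd$n
    }
    loss_hist <- c(loss_hist, ep_loss / max(1, ep_n))
  }
  entity <- if (complex_model) E + 1i * Ei else E
  relation <- switch(cfg$model,
                     rotate = exp(1i * R),
                     complex = R + 1i * Ri,
                     R)
  structure(list(model = cfg$model, d = d, entity = entity,
                 relation = relation, phases = if (cfg$model == "rotate") R,
                 entity_ids = kg$entities$concept_id,
                 relation_ids = kg$relations,
                 loss_history = loss_hist, config = cfg),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("%s embeddings: %d entities, %d relations, d = %d (%s)\n",
              toupper(x$model), nrow(x$entity), nrow(x$relation), x$d,
              if (is.complex(x$entity)) "complex" else "real"))
  if (length(x$loss_history))
    cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  invisible(x)
}

# ---- per-model SGD steps (analytic gradients) -------------------------------

# scatter-add rows of G into an accumulator of nrow n
.acc <- function(n, idx, G) {
  A <- rowsum(G, idx)
  out <- matrix(0, n, ncol(G))
  out[as.integer(rownames(A)), ] <- A
  out
}

.step_transe <- function(E, R, hb, rb, tb, neg, cfg) {
  p <- cfg$norm_order
  Dp <- E[hb, , drop = FALSE] + R[rb, , drop = FALSE] - E[tb, , drop = FALSE]
  dp <- if (p == 1) rowSums(abs(Dp)) else sqrt(rowSums(Dp^2))
  Dn <- E[neg$h, , drop = FALSE] + R[neg$r, , drop = FALSE] -
    E[neg$t, , drop = FALSE]
  dn <- if (p == 1) rowSums(abs(Dn)) else sqrt(rowSums(Dn^2))
  viol <- cfg$margin + dp[neg$pos] - dn
  act <- viol > 0
  loss <- sum(pmax(viol, 0)) / length(viol)
  n <- sum(act)
  dE <- matrix(0, nrow(E), ncol(E)); dR <- matrix(0, nrow(R), ncol(R))
  if (n > 0) {
    scale <- 1 / length(viol)
    if (p == 1) {
      Gp <- sign(Dp); Gn <- sign(Dn)
    } else {
      Gp <- Dp / pmax(dp, 1e-12); Gn <- Dn / pmax(dn, 1e-12)
    }
    # positive side gradient, weighted by number of active pairs it joins
    w <- tabulate(neg$pos[act], nbins = length(hb))
    Gpw <- Gp * (w * scale)
    Gna <- Gn[act, , drop = FALSE] * scale
    dE <- .acc(nrow(E), hb, Gpw) - .acc(nrow(E), tb, Gpw) -
      .acc(nrow(E), neg$h[act], Gna) + .acc(nrow(E), neg$t[act], Gna)
    dR <- .acc(nrow(R), rb, Gpw) - .acc(nrow(R), neg$r[act], Gna)
  }
  list(loss = loss, n = length(viol), dE = dE, dR = dR)
}

.step_rotate <- function(E, Ei, Th, hb, rb, tb, neg, cfg) {
  rot_parts <- function(h, r, t) {
    Cos <- cos(Th[r, , drop = FALSE]); Sin <- sin(Th[r, , drop = FALSE])
    Hre <- E[h, , drop = FALSE]; Him <- Ei[h, , drop = FALSE]
    Wre <- Hre * Cos - Him * Sin; Wim <- Hre * Sin + Him * Cos
    Cre <- Wre - E[t, , drop = FALSE]; Cim <- Wim - Ei[t, , drop = FALSE]
    d <- sqrt(rowSums(Cre^2 + Cim^2))
    list(Cos = Cos, Sin = Sin, Cre = Cre, Cim = Cim, Wre = Wre, Wim = Wim,
         d = d)
  }
  Pp <- rot_parts(hb, rb, tb)
  Pn <- rot_parts(neg$h, neg$r, neg$t)
  viol <- cfg$margin + Pp$d[neg$pos] - Pn$d
  act <- viol > 0
  loss <- sum(pmax(viol, 0)) / length(viol)
  dE <- matrix(0, nrow(E), ncol(E)); dEi <- dE
  dTh <- matrix(0, nrow(Th), ncol(Th))
  if (any(act)) {
    scale <- 1 / length(viol)
    grads <- function(P) {
      dinv <- 1 / pmax(P$d, 1e-12)
      ghre <- (P$Cre * P$Cos + P$Cim * P$Sin) * dinv
      ghim <- (-P$Cre * P$Sin + P$Cim * P$Cos) * dinv
      gtre <- -P$Cre * dinv; gtim <- -P$Cim * dinv
      gth <- (P$Cim * P$Wre - P$Cre * P$Wim) * dinv
      list(ghre = ghre, ghim = ghim, gtre = gtre, gtim = gtim, gth = gth)
    }
    Gp <- grads(Pp); Gn <- grads(Pn)
    w <- tabulate(neg$pos[act], nbins = length(hb)) * scale
    a <- which(act)
    dE <- .acc(nrow(E), hb, Gp$ghre * w) + .acc(nrow(E), tb, Gp$gtre * w) -
      .acc(nrow(E), neg$h[a], Gn$ghre[a, , drop = FALSE] * scale) -
      .acc(nrow(E), neg$t[a], Gn$gtre[a, , drop = FALSE] * scale)
    dEi <- .acc(nrow(E), hb, Gp$ghim * w) + .acc(nrow(E), tb, Gp$gtim * w) -
      .acc(nrow(E), neg$h[a], Gn$ghim[a, , drop = FALSE] * scale) -
      .acc(nrow(E), neg$t[a], Gn$gtim[a, , drop = FALSE] * scale)
    dTh <- .acc(nrow(Th), rb, Gp$gth * w) -
      .acc(nrow(Th), neg$r[a], Gn$gth[a, , drop = FALSE] * scale)
  }
  list(loss = loss, n = length(viol), dE = dE, dEi = dEi, dR = dTh)
}

.step_distmult <- function(E, R, hb, rb, tb, neg, cfg) {
  H <- rbind(E[hb, , drop = FALSE], E[neg$h, , drop = FALSE])
  Rm <- rbind(R[rb, , drop = FALSE], R[neg$r, , drop = FALSE])
  T <- rbind(E[tb, , drop = FALSE], E[neg$t, , drop = FALSE])
  y <- c(rep(1, length(hb)), rep(-1, length(neg$h)))
  s <- rowSums(H * Rm * T)
  loss <- mean(log1p(exp(-y * s)))
  g <- -y * stats::plogis(-y * s) / length(s)
  lam <- cfg$regularization_coeff
  hidx <- c(hb, neg$h); ridx <- c(rb, neg$r); tidx <- c(tb, neg$t)
  dE <- .acc(nrow(E), hidx, g * (Rm * T)) + .acc(nrow(E), tidx, g * (H * Rm)) +
    2 * lam * E
  dR <- .acc(nrow(R), ridx, g * (H * T)) + 2 * lam * R
  list(loss = loss, n = length(s), dE = dE, dR = dR)
}

.step_complex <- function(E, Ei, R, Ri, hb, rb, tb, neg, cfg) {
  hidx <- c(hb, neg$h); ridx <- c(rb, neg$r); tidx <- c(tb, neg$t)
  Hre <- E[hidx, , drop = FALSE]; Him <- Ei[hidx, , drop = FALSE]
  Rre <- R[ridx, , drop = FALSE]; Rim <- Ri[ridx, , drop = FALSE]
  Tre <- E[tidx, , drop = FALSE]; Tim <- Ei[tidx, , drop = FALSE]
  y <- c(rep(1, length(hb)), rep(-1, length(neg$h)))
  s <- .batch_complex(Hre, Him, Rre, Rim, Tre, Tim)
  loss <- mean(log1p(exp(-y * s)))
  g <- -y * stats::plogis(-y * s) / length(s)
  lam <- cfg$regularization_coeff
  # grads (complex calculus written out in real parts):
  # g_h = conj(r) t ; g_r = conj(h) t ; g_t = h r
  ghre <- Rre * Tre + Rim * Tim; ghim <- Rre * Tim - Rim * Tre
  grre <- Hre * Tre + Him * Tim; grim <- Hre * Tim - Him * Tre
  gtre <- Hre * Rre - Him * Rim; gtim <- Hre * Rim + Him * Rre
  dE <- .acc(nrow(E), hidx, g * ghre) + .acc(nrow(E), tidx, g * gtre) +
    2 * lam * E
  dEi <- .acc(nrow(E), hidx, g * ghim) + .acc(nrow(E), tidx, g * gtim) +
    2 * lam * Ei
  dR <- .acc(nrow(R), ridx, g * grre) + 2 * lam * R
  dRi <- .acc(nrow(R), ridx, g * grim) + 2 * lam * Ri
  list(loss = loss, n = length(s), dE = dE, dEi = dEi, dR = dR, dRi = dRi)
}

# Plausibility (higher = more plausible) for a batch of integer-id triples.
kge_plausibility <- function(emb, h_idx, r_idx, t_idx) {
  d <- emb$d
  switch(emb$model,
    transe = {
      H <- emb$entity[h_idx, , drop = FALSE]
      R <- emb$relation[r_idx, , drop = FALSE]
      T <- emb$entity[t_idx, , drop = FALSE]
      -.batch_transe(H, R, T, emb$config$norm_order)
    },
    rotate = {
      Hre <- Re(emb$entity)[h_idx, , drop = FALSE]
      Him <- Im(emb$entity)[h_idx, , drop = FALSE]
      Cos <- Re(emb$relation)[r_idx, , drop = FALSE]
      Sin <- Im(emb$relation)[r_idx, , drop = FALSE]
      Tre <- Re(emb$entity)[t_idx, , drop = FALSE]
      Tim <- Im(emb$entity)[t_idx, , drop = FALSE]
      -.batch_rotate(Hre, Him, Cos, Sin, Tre, Tim)
    },
    distmult = .batch_distmult(emb$entity[h_idx, , drop = FALSE],
                               emb$relation[r_idx, , drop = FALSE],
                               emb$entity[t_idx, , drop = FALSE]),
    complex = .batch_complex(Re(emb$entity)[h_idx, , drop = FALSE],
                             Im(emb$entity)[h_idx, , drop = FALSE],
                             Re(emb$relation)[r_idx, , drop = FALSE],
                             Im(emb$relation)[r_idx, , drop = FALSE],
                             Re(emb$entity)[t_idx, , drop = FALSE],
                             Im(emb$entity)[t_idx, , drop = FALSE]))
}
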