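#' Training configuration for graph-convolution link predictors
#'
#' @param model `"rgcn"` or `"compgcn"`.
#' @param learning_rate Adam step size.
#' @param hidden_dim layer width (input embeddings share it).
#' @param num_layers number of convolution layers (1 or 2).
#' @param dropout R-GCN encoder dropout rate (0.2 by default).
#' @param l2_decoder L2 penalty on the R-GCN DistMult decoder (0.01).
#' @param neg_ratio negatives per positive edge.
#' @param epochs full-graph training epochs; 0 returns the initialization.
#' @param composition CompGCN composition operator.
#' @param feature_dropout,layer_dropout CompGCN encoder dropout rates
#'   (0.1 / 0.3 by default).
#' @param conve optional [conve_config()] override for the CompGCN decoder.
#' @param seed RNG seed.
#' @return object of class `gcn_config`.
#' @export
gcn_config <- function(model = c("rgcn", "compgcn"), learning_rate = 0.01,
                       hidden_dim = 64, num_layers = 1, dropout = 0.2,
                       l2_decoder = 0.01, neg_ratio = 10, epochs = 60,
                       composition = "circular_correlation",
                       feature_dropout = 0.1, layer_dropout = 0.3,
                       conve = NULL, seed = 1) {
  model <- match.arg(model)
  if (!num_layers %in% c(1, 2)) stop("num_layers must be 1 or 2")
  structure(list(model = model, learning_rate = learning_rate,
                 hidden_dim = hidden_dim, num_layers = num_layers,
                 dropout = dropout, l2_decoder = l2_decoder,
                 neg_ratio = neg_ratio, epochs = epochs,
                 composition = composition,
                 feature_dropout = feature_dropout,
                 layer_dropout = layer_dropout, conve = conve, seed = seed),
            class = "gcn_config")
}

#' Train a relational graph-convolution link predictor
#'
#' Full-graph training of the R-GCN encoder with a DistMult decoder, or the
#' CompGCN encoder with a ConvE decoder, both under the normalized binary
#' cross-entropy of [bce_link_loss()] with filtered negative sampling,
#' optimized with Adam.
#' R-GCN applies encoder dropout 0.2 and an L2 penalty of 0.01 on the
#' decoder; CompGCN applies feature dropout 0.1, layer dropout 0.3 and
#' decoder dropouts 0.3/0.3 (training mode only). Deterministic under the
#' seed.
#'
#' @param kg a nonempty `kgraph`.
#' @param model `"rgcn"` or `"compgcn"` (overrides `cfg$model` if given).
#' @param cfg a [gcn_config()].
#' @return object of class `gcn_model` holding the trained parameters, the
#'   evaluation-mode node (and relation) states, vocabulary ids, the loss
#'   history and the config.
#' @export
train_gcn <- function(kg, model = NULL, cfg = gcn_config()) {
  stopifnot(inherits(cfg, "gcn_config"))
  if (!is.null(model)) cfg$model <- match.arg(model, c("rgcn", "compgcn"))
  if (nrow(kg$triples) == 0) stop("cannot train on an empty graph")
  set.seed(cfg$seed)
  dims <- rep(cfg$hidden_dim, cfg$num_layers + 1)
  params <- if (cfg$model == "rgcn") {
    rgcn_params(kg, dims, dropout = cfg$dropout, seed = cfg$seed)
  } else {
    compgcn_params(kg, dims, composition = cfg$composition,
                   conve = cfg$conve, feature_dropout = cfg$feature_dropout,
                   layer_dropout = cfg$layer_dropout, seed = cfg$seed)
  }
  hi <- kg$.h_id; ri <- kg$.r_id; ti <- kg$.t_id
  pos <- list(h = hi, r = ri, t = ti)
  loss_hist <- numeric(0)
  # Adam optimizer state, keyed by parameter path
  adam <- new.env(parent = emptyenv())
  adam$t <- 0
  adam_step <- function(p, g, key, lr) {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    st <- adam[[key]]
    if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    adam[[key]] <- st
    mhat <- st$m / (1 - b1^adam$t)
    vhat <- st$v / (1 - b2^adam$t)
    p - lr * mhat / (sqrt(vhat) + eps)
  }
  for (epoch in seq_len(cfg$epochs)) {
    neg <- .corrupt_ids(kg, hi, ri, ti, cfg$neg_ratio)
    step <- if (cfg$model == "rgcn") {
      .rgcn_loss_grads(kg, params, pos, neg, l2_decoder = cfg$l2_decoder,
                       training = TRUE)
    } else {
      .compgcn_loss_grads(kg, params, pos, neg, training = TRUE)
    }
    if (!is.finite(step$loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    lr <- cfg$learning_rate
    g <- step$grads
    adam$t <- adam$t + 1
    params$X0 <- adam_step(params$X0, g$X0, "X0", lr)
    for (l in seq_along(params$layers)) {
      for (nm in names(g$layers[[l]])) {
        if (is.list(params$layers[[l]][[nm]])) {
          for (r in seq_along(params$layers[[l]][[nm]]))
            params$layers[[l]][[nm]][[r]] <-
              adam_step(params$layers[[l]][[nm]][[r]],
                        g$layers[[l]][[nm]][[r]],
                        paste0("L", l, nm, r), lr)
        } else {
          params$layers[[l]][[nm]] <- adam_step(params$layers[[l]][[nm]],
                                                g$layers[[l]][[nm]],
                                                paste0("L", l, nm), lr)
        }
      }
    }
    if (cfg$model == "rgcn") {
      params$decoder <- adam_step(params$decoder, g$decoder, "decoder", lr)
    } else {
      params$Y0 <- adam_step(params$Y0, g$Y0, "Y0", lr)
      for (nm in c("K", "bf", "Wp", "bp", "b0"))
        params$conve[[nm]] <- adam_step(params$conve[[nm]],
                                        g$conve[[paste0("d", nm)]], nm, lr)
    }
    loss_hist <- c(loss_hist, step$loss)
  }
  # deterministic evaluation-mode encoding
  if (cfg$model == "rgcn") {
    states <- rgcn_forward(kg, params, training = FALSE)
    rel_states <- params$decoder
  } else {
    enc <- compgcn_forward(kg, params, training = FALSE)
    states <- enc$node_states
    rel_states <- enc$rel_states
  }
  structure(list(model = cfg$model, params = params, node_states = states,
                 rel_states = rel_states,
                 entity_ids = kg$entities$concept_id,
                 relation_ids = kg$relations,
                 loss_history = loss_hist, config = cfg),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("%s link predictor: %d entities, %d relations, d = %d, %d layer(s)\n",
              toupper(x$model), length(x$entity_ids), length(x$relation_ids),
              x$config$hidden_dim, x$config$num_layers))
  if (length(x$loss_history))
    cat(sprintf("  trained %d epochs, final loss %.5f\n",
                length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  invisible(x)
}

# plausibility for gcn models over integer-id triples
gcn_plausibility <- function(fit, h_idx, r_idx, t_idx) {
  if (fit$model == "rgcn") {
    rgcn_score(fit$node_states, fit$rel_states, h_idx, r_idx, t_idx)
  } else {
    conve_score(fit$node_states, fit$rel_states, h_idx, r_idx, t_idx,
                fit$params$conve)
  }
}
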