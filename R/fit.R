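#' Fit a link-prediction model on a knowledge graph
#'
#' The single fitting front-end for the six link-prediction models. Embedding
#' methods (`transe`, `rotate`, `distmult`, `complex`) are trained with
#' [train_kge()]; graph-convolution methods (`rgcn`, `compgcn`) with
#' [train_gcn()]. The returned object carries a uniform plausibility
#' interface: for every method, [predict.kglp()] returns scores in which
#' higher means more plausible (distances of the translational models are
#' negated).
#'
#' @param kg a nonempty `kgraph`.
#' @param method one of `"transe"`, `"rotate"`, `"distmult"`, `"complex"`,
#'   `"rgcn"`, `"compgcn"`.
#' @param ... configuration overrides passed to [kge_config()] or
#'   [gcn_config()] (e.g. `epochs`, `hidden_dim`, `neg_ratio`, `seed`).
#' @return an object of class `kglp`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_entities = c(Drug = 30, Disease = 15, Gene = 15,
#'                                    DS = 8, CIH = 6),
#'                     n_triples = 400, n_planted_mechanisms = 4,
#'                     n_heldout_prevents = 2, seed = 7)
#' gen <- generate_kg(cfg)
#' kg <- build_graph(gen$predications, gen$meta)
#' fit <- fit_lp(kg, "transe", epochs = 5, seed = 7)
#' print(fit)
#' }
#' @export
fit_lp <- function(kg, method = c("transe", "rotate", "distmult", "complex",
                                  "rgcn", "compgcn"), ...) {
  method <- match.arg(method)
  fit <- if (method %in% c("rgcn", "compgcn")) {
    train_gcn(kg, model = method, cfg = gcn_config(model = method, ...))
  } else {
    train_kge(kg, kge_config(model = method, ...))
  }
  structure(list(method = method, fit = fit,
                 entity_ids = fit$entity_ids,
                 relation_ids = fit$relation_ids,
                 loss_history = fit$loss_history,
                 n_triples = nrow(kg$triples)),
            class = "kglp")
}

# integer-id plausibility used by ranking/discovery
.plausibility_ids <- function(object, h_idx, r_idx, t_idx) {
  if (inherits(object$fit, "gcn_model"))
    gcn_plausibility(object$fit, h_idx, r_idx, t_idx)
  else
    kge_plausibility(object$fit, h_idx, r_idx, t_idx)
}

#' Predict triple plausibility
#'
#' Scores triples under the fitted model; higher is more plausible for every
#' method (translational distances are negated).
#'
#' @param object a fitted `kglp`.
#' @param newdata `data.frame` with columns head, relation, tail (concept and
#'   relation identifiers), or three character vectors via `h`, `r`, `t`.
#' @param h,r,t alternative vector interface.
#' @param ... unused.
#' @return numeric plausibility vector.
#' @export
predict.kglp <- function(object, newdata = NULL, h = NULL, r = NULL, t = NULL,
                         ...) {
  if (!is.null(newdata)) {
    h <- newdata$head; r <- newdata$relation; t <- newdata$tail
  }
  h_idx <- match(h, object$entity_ids)
  r_idx <- match(r, object$relation_ids)
  t_idx <- match(t, object$entity_ids)
  if (anyNA(h_idx) || anyNA(t_idx)) stop("unknown entity identifier")
  if (anyNA(r_idx)) stop("unknown relation")
  .plausibility_ids(object, h_idx, r_idx, t_idx)
}

#' @export
print.kglp <- function(x, ...) {
  cat(sprintf("link-prediction fit [%s]: %d entities, %d relations, trained on %d triples\n",
              x$method, length(x$entity_ids), length(x$relation_ids),
              x$n_triples))
  if (length(x$loss_history))
    cat(sprintf("  epochs: %d, final loss: %.5f\n", length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.kglp <- function(object, ...) {
  s <- list(method = object$method,
            n_entities = length(object$entity_ids),
            n_relations = length(object$relation_ids),
            n_triples = object$n_triples,
            epochs = length(object$loss_history),
            loss_first = if (length(object$loss_history))
              object$loss_history[1] else NA_real_,
            loss_final = if (length(object$loss_history))
              object$loss_history[length(object$loss_history)] else NA_real_)
  class(s) <- "summary.kglp"
  s
}

#' @export
print.summary.kglp <- function(x, ...) {
  cat("Link-prediction model summary\n")
  cat(sprintf("  method:    %s\n", x$method))
  cat(sprintf("  graph:     %d entities, %d relations, %d training triples\n",
              x$n_entities, x$n_relations, x$n_triples))
  cat(sprintf("  training:  %d epochs, loss %.5f -> %.5f\n", x$epochs,
              x$loss_first, x$loss_final))
  invisible(x)
}

#' @export
coef.kglp <- function(object, ...) {
  if (inherits(object$fit, "gcn_model"))
    list(entity = object$fit$node_states, relation = object$fit$rel_states)
  else
    list(entity = object$fit$entity, relation = object$fit$relation)
}

#' @export
plot.kglp <- function(x, ...) {
  if (!length(x$loss_history)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "training loss",
       main = sprintf("%s training loss", x$method), ...)
  invisible(x)
}
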