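#' Loss specification for link-prediction cross-entropy
#'
#' Carries the normalization constants of the printed loss: the negative
#' ratio `omega` and the positive edge count.
#'
#' @param neg_ratio negatives per positive (`omega >= 0`).
#' @param edge_count number of positive edges.
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(neg_ratio, edge_count) {
  if (edge_count <= 0) stop("edge_count must be positive")
  structure(list(neg_ratio = neg_ratio, edge_count = edge_count),
            class = "loss_spec")
}

#' Normalized binary cross-entropy over scored triples
#'
#' Computes
#' \deqn{\mathcal{L} = -\frac{1}{(1+\omega)\,|\hat\varepsilon|}
#'   \sum_{(h,r,t,y)} y \log l(s) + (1-y) \log(1 - l(s))}
#' where \eqn{l} is the logistic sigmoid, \eqn{\omega} the negative ratio and
#' \eqn{|\hat\varepsilon|} the positive edge count. Probabilities are clamped
#' away from 0 and 1 by 1e-12 for stability. Permutation-invariant over the
#' triple set.
#'
#' @param scores numeric vector of raw (pre-sigmoid) triple scores.
#' @param labels 0/1 labels (`1` = positive).
#' @param spec a [loss_spec()].
#' @return the loss value.
#' @export
bce_link_loss <- function(scores, labels, spec) {
  stopifnot(inherits(spec, "loss_spec"))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  p <- pmin(pmax(stats::plogis(scores), 1e-12), 1 - 1e-12)
  -sum(labels * log(p) + (1 - labels) * log(1 - p)) /
    ((1 + spec$neg_ratio) * spec$edge_count)
}
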