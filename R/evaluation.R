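#' Chronological (time-sliced) train/validation/test split
#'
#' Orders triples by their first-attestation date (stable tie-break by head,
#' relation, tail) and slices contiguously by count into train, validation
#' and test portions. This evaluates whether links first reported after a
#' cutoff can be predicted from links reported before it. The effective cut
#' dates (latest train date, latest validation date) are reported as outputs;
#' alternatively explicit `cut_dates` assign triples by date.
#'
#' @param kg a `kgraph` in which every triple is dated.
#' @param ratios length-3 positive weights, default `c(8, 1, 1)`.
#' @param cut_dates optional two dates; when given, triples with
#'   `first_date <= cut_dates[1]` train, `(cut_dates[1], cut_dates[2]]`
#'   validate, later ones test.
#' @return object of class `time_split`: `kgraph`s `train`, `valid`, `test`
#'   (all retaining the full vocabulary) and `cut_dates`.
#' @export
chronological_split <- function(kg, ratios = c(8, 1, 1), cut_dates = NULL) {
  tr <- kg$triples
  if (anyNA(tr$first_date)) {
    bad <- which(is.na(tr$first_date))[1]
    stop("undated triple: (", tr$head[bad], ", ", tr$relation[bad], ", ",
         tr$tail[bad], ")")
  }
  o <- order(tr$first_date, tr$head, tr$relation, tr$tail, method = "radix")
  n <- nrow(tr)
  if (is.null(cut_dates)) {
    if (length(ratios) != 3 || any(ratios <= 0)) stop("need 3 positive ratios")
    n_train <- floor(n * ratios[1] / sum(ratios))
    n_valid <- floor(n * ratios[2] / sum(ratios))
    idx_train <- o[seq_len(n_train)]
    idx_valid <- o[n_train + seq_len(n_valid)]
    idx_test <- o[-(seq_len(n_train + n_valid))]
    cuts <- c(max(tr$first_date[idx_train]), max(tr$first_date[idx_valid]))
  } else {
    cut_dates <- as.Date(cut_dates)
    idx_train <- which(tr$first_date <= cut_dates[1])
    idx_valid <- which(tr$first_date > cut_dates[1] &
                         tr$first_date <= cut_dates[2])
    idx_test <- which(tr$first_date > cut_dates[2])
    cuts <- cut_dates
  }
  structure(list(train = kg_subset(kg, sort(idx_train), shrink_vocab = FALSE),
                 valid = kg_subset(kg, sort(idx_valid), shrink_vocab = FALSE),
                 test = kg_subset(kg, sort(idx_test), shrink_vocab = FALSE),
                 cut_dates = cuts),
            class = "time_split")
}

#' @export
print.time_split <- function(x, ...) {
  cat(sprintf("chronological split: %d / %d / %d triples (train/valid/test)\n",
              nrow(x$train$triples), nrow(x$valid$triples),
              nrow(x$test$triples)))
  cat("  effective cut dates:", format(x$cut_dates[1]), "and",
      format(x$cut_dates[2]), "\n")
  invisible(x)
}

#' Build a fixed-relation, fixed-tail ground-truth test set
#'
#' One test triple `(head, relation, tail)` per supplied head (deduplicated).
#' Heads absent from the graph vocabulary are dropped and reported through
#' the `"dropped"` attribute.
#'
#' @param kg a `kgraph` (vocabulary reference).
#' @param head_ids candidate head concept ids (e.g. trial interventions).
#' @param relation the fixed predicate (default `PREVENTS`).
#' @param tail_id the fixed tail concept (the target disease).
#' @return `data.frame` (head, relation, tail).
#' @export
build_ground_truth_testset <- function(kg, head_ids, relation = "PREVENTS",
                                       tail_id) {
  if (!length(head_ids)) stop("head list is empty")
  head_ids <- unique(head_ids)
  known <- head_ids %in% kg$entities$concept_id
  out <- data.frame(head = head_ids[known], relation = relation,
                    tail = tail_id, stringsAsFactors = FALSE)
  attr(out, "dropped") <- head_ids[!known]
  out
}

# mean-rank position of value s among candidates (true score s, others cand),
# ties resolved by the mean over tied orderings, rounded half up
.mean_rank <- function(s, cand) {
  n_greater <- sum(cand > s)
  n_tied <- sum(cand == s) + 1  # including the true triple
  floor(n_greater + (n_tied + 1) / 2 + 0.5)
}

#' Rank a true triple against filtered corruptions
#'
#' Draws `n_negatives` filtered corruptions of the chosen side, scores the
#' true triple and the corruptions under the model, and returns the 1-based
#' rank of the true triple (descending plausibility). Tied scores take the
#' mean rank over tied orderings, rounded half up.
#'
#' @param model a fitted `kglp` (or any object `predict` accepts).
#' @param kg the graph supplying the corruption filter and vocabulary.
#' @param triple one-row `data.frame` (head, relation, tail).
#' @param n_negatives corruptions to draw.
#' @param side `"head"` or `"tail"`: which slot to corrupt.
#' @param seed optional RNG seed.
#' @return integer rank in `1..(n_negatives + 1)`.
#' @export
rank_triple <- function(model, kg, triple, n_negatives = 100,
                        side = c("tail", "head"), seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  neg <- .ranking_negatives(kg, triple, n_negatives, side)
  s_true <- predict(model, h = triple$head, r = triple$relation,
                    t = triple$tail)
  s_neg <- predict(model, h = neg$head, r = neg$relation, t = neg$tail)
  .mean_rank(s_true, s_neg)
}

# corruptions of one side only, filtered against the graph and the triple
.ranking_negatives <- function(kg, triple, n_negatives, side) {
  ents <- kg$entities$concept_id
  pool <- setdiff(ents, if (side == "head") triple$head else triple$tail)
  h <- rep(triple$head, length(pool)); t <- rep(triple$tail, length(pool))
  if (side == "head") h <- pool else t <- pool
  valid <- !contains_triple(kg, h, rep(triple$relation, length(pool)), t)
  if (sum(valid) < n_negatives)
    stop("insufficient valid corruptions: ", sum(valid), " < ", n_negatives)
  pick <- sample(which(valid), n_negatives)
  data.frame(head = h[pick], relation = triple$relation, tail = t[pick],
             stringsAsFactors = FALSE)
}

#' Ranking metrics from a rank list
#'
#' Mean rank `MR = mean(rank)`, mean reciprocal rank `MRR = mean(1/rank)`,
#' and `Hits@k` = fraction of ranks `<= k` for each requested `k`.
#'
#' @param ranks positive integer ranks, nonempty.
#' @param ks cutoffs for Hits at k.
#' @return list with `MR`, `MRR` and `hits` (named vector).
#' @export
metrics_from_ranks <- function(ranks, ks = c(1, 3, 10)) {
  if (!length(ranks)) stop("empty rank list")
  if (any(ranks < 1)) stop("ranks must be >= 1")
  hits <- vapply(ks, function(k) mean(ranks <= k), numeric(1))
  names(hits) <- paste0("hits", ks)
  list(MR = mean(ranks), MRR = mean(1 / ranks), hits = hits)
}

#' ROC and precision-recall curves from score sets
#'
#' Sweeps thresholds over the union of scores (descending). AUROC is the
#' trapezoidal area, equal to the normalized Mann-Whitney U statistic (ties
#' count one half); AUPR uses step interpolation.
#'
#' @param pos_scores,neg_scores numeric score vectors (higher = positive).
#' @return list with `roc` (threshold, fpr, tpr), `pr` (threshold, recall,
#'   precision), `auroc`, `aupr`.
#' @export
curves_from_scores <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score sets must be nonempty")
  th <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(th, function(x) mean(pos_scores >= x), numeric(1))
  fpr <- vapply(th, function(x) mean(neg_scores >= x), numeric(1))
  prec <- vapply(th, function(x) {
    tp <- sum(pos_scores >= x); fp <- sum(neg_scores >= x)
    tp / (tp + fp)
  }, numeric(1))
  rec <- tpr
  fpr_c <- c(0, fpr); tpr_c <- c(0, tpr)
  auroc <- sum(diff(fpr_c) * (utils::head(tpr_c, -1) + tpr_c[-1]) / 2)
  rec_c <- c(0, rec); prec_c <- c(if (length(prec)) prec[1] else 1, prec)
  aupr <- sum(diff(rec_c) * prec_c[-1])
  list(roc = data.frame(threshold = th, fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = th, recall = rec, precision = prec),
       auroc = auroc, aupr = aupr)
}

#' Evaluate a fitted model on a test triple set
#'
#' Ranks every test triple against filtered corruptions (both sides by
#' default, averaged into one rank list with one rank per side per triple)
#' and assembles the full metric report, including ROC/PR over true-triple
#' scores versus corruption scores.
#'
#' @param model a fitted `kglp`.
#' @param kg graph supplying the corruption filter (typically the full graph
#'   so that known triples are excluded from negatives).
#' @param test_triples `data.frame` (head, relation, tail).
#' @param n_negatives corruptions per query (default 100).
#' @param sides `"both"` (default), `"tail"` or `"head"`.
#' @param seed RNG seed.
#' @return object of class `lp_eval`: `ranks`, `metrics` (MR, MRR, hits),
#'   `auroc`, `aupr`, `curves`.
#' @export
evaluate_lp <- function(model, kg, test_triples, n_negatives = 100,
                        sides = c("both", "tail", "head"), seed = 1) {
  sides <- match.arg(sides)
  set.seed(seed)
  use <- if (sides == "both") c("tail", "head") else sides
  ranks <- integer(0)
  pos_scores <- numeric(0); neg_scores <- numeric(0)
  for (i in seq_len(nrow(test_triples))) {
    tri <- test_triples[i, , drop = FALSE]
    s_true <- predict(model, h = tri$head, r = tri$relation, t = tri$tail)
    pos_scores <- c(pos_scores, s_true)
    for (sd in use) {
      neg <- .ranking_negatives(kg, tri, n_negatives, sd)
      s_neg <- predict(model, h = neg$head, r = neg$relation, t = neg$tail)
      ranks <- c(ranks, .mean_rank(s_true, s_neg))
      neg_scores <- c(neg_scores, s_neg)
    }
  }
  m <- metrics_from_ranks(ranks)
  cv <- curves_from_scores(pos_scores, neg_scores)
  structure(list(ranks = ranks, metrics = m, auroc = cv$auroc,
                 aupr = cv$aupr, curves = cv[c("roc", "pr")],
                 n_negatives = n_negatives, sides = sides),
            class = "lp_eval")
}

#' @export
print.lp_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("link-prediction evaluation (%d queries, %d negatives each, %s-side)\n",
              length(x$ranks), x$n_negatives, x$sides))
  cat(sprintf("  MR %.4f | MRR %.4f | %s | AUROC %.4f | AUPR %.4f\n",
              m$MR, m$MRR,
              paste(sprintf("Hits@%s %.4f", sub("hits", "", names(m$hits)),
                            m$hits), collapse = " | "),
              x$auroc, x$aupr))
  invisible(x)
}
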