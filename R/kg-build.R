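#' The fifteen-relation predicate vocabulary
#'
#' The predicate whitelist used by default throughout the package, with the
#' relation frequency profile of the integrated literature graph (proportions
#' of triples per relation type). `default_relations()` returns the names;
#' `default_relation_profile()` returns the proportions (summing to 1).
#'
#' @return character vector / named numeric vector.
#' @export
default_relations <- function() names(default_relation_profile())

#' @rdname default_relations
#' @export
default_relation_profile <- function() {
  p <- c(COEXISTS_WITH = 32.68, INTERACTS_WITH = 20.59, AFFECTS = 9.52,
         TREATS = 8.93, CAUSES = 7.49, ASSOCIATED_WITH = 4.53,
         INHIBITS = 3.85, STIMULATES = 2.76, DISRUPTS = 2.28,
         AUGMENTS = 2.15, PRODUCES = 2.15, PREDISPOSES = 1.33,
         PREVENTS = 1.20, COMPLICATES = 0.35, MANIFESTATION_OF = 0.19)
  p / sum(p)
}

#' Filtering configuration
#'
#' Bundles the rule-filter inputs: generic concepts to drop, excluded
#' semantic groups, the predicate whitelist, and the triple budget for
#' specificity pruning. Defaults ship the fifteen-relation whitelist and the
#' two semantic groups commonly excluded as uninformative for intervention
#' prediction; both are user-overridable.
#'
#' @param generic_concepts concept ids to remove (with all incident triples).
#' @param excluded_groups semantic-group labels whose concepts are removed.
#' @param relation_whitelist predicates to keep (nonempty).
#' @param budget target triple count after specificity pruning.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(generic_concepts = character(),
                          excluded_groups = c("Activities & Behaviors",
                                              "Concepts & Ideas"),
                          relation_whitelist = default_relations(),
                          budget = Inf) {
  if (!length(relation_whitelist)) stop("relation_whitelist must be nonempty")
  if (budget <= 0) stop("budget must be positive")
  structure(list(generic_concepts = as.character(generic_concepts),
                 excluded_groups = as.character(excluded_groups),
                 relation_whitelist = toupper(trimws(relation_whitelist)),
                 budget = budget),
            class = "filter_config")
}

#' Rule-based triple filtering
#'
#' Removes triples touching generic concepts, triples whose endpoint belongs
#' to an excluded semantic group, and triples whose predicate is outside the
#' whitelist. Always returns a subgraph of the input; the entity vocabulary
#' shrinks to entities still touched by a triple.
#'
#' @param kg a `kgraph`.
#' @param cfg a [filter_config()].
#' @return filtered `kgraph`.
#' @export
apply_rule_filters <- function(kg, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!any(kg$relations %in% cfg$relation_whitelist))
    stop("relation whitelist shares no predicate with the graph; ",
         "filtering would empty it")
  tr <- kg$triples
  bad_ent <- kg$entities$concept_id[
    kg$entities$concept_id %in% cfg$generic_concepts |
      kg$entities$semantic_group %in% cfg$excluded_groups]
  keep <- !(tr$head %in% bad_ent) & !(tr$tail %in% bad_ent) &
    tr$relation %in% cfg$relation_whitelist
  kg <- kg_subset(kg, keep)
  kg$relations <- intersect(kg$relations, unique(kg$triples$relation))
  .kg_index(kg)
}

#' Node degrees over distinct triples
#'
#' In- and out-degree of every entity counted over distinct triples (instance
#' multiplicity is ignored). High-degree nodes flag overly general concepts.
#'
#' @param kg a `kgraph`.
#' @return `data.frame` (concept_id, k_in, k_out), one row per entity in
#'   vocabulary order.
#' @export
node_degrees <- function(kg) {
  n <- nrow(kg$entities)
  k_out <- tabulate(kg$.h_id, nbins = n)
  k_in <- tabulate(kg$.t_id, nbins = n)
  data.frame(concept_id = kg$entities$concept_id, k_in = k_in, k_out = k_out,
             stringsAsFactors = FALSE)
}

#' Build a 2x2x2 contingency table for a triple over a predication stream
#'
#' Each predication instance is classified along three binary axes: does its
#' subject equal `h`, its predicate equal `r`, its object equal `t`. The
#' observed counts form the observation table whose independence departure
#' the G-squared statistic measures.
#'
#' @param preds predication `data.frame` (the instance stream; nonempty).
#' @param h,r,t the triple whose specificity is being scored.
#' @return a 2x2x2 array of class `contingency3` (axes: subject, predicate,
#'   object; levels `present`, `absent`), with attribute `T` = stream length.
#' @export
contingency_from_stream <- function(preds, h, r, t) {
  if (nrow(preds) == 0) stop("empty predication stream")
  i <- preds$subject_id == h
  j <- toupper(trimws(preds$predicate)) == r
  k <- preds$object_id == t
  lv <- c("present", "absent")
  tab <- table(factor(ifelse(i, "present", "absent"), levels = lv),
               factor(ifelse(j, "present", "absent"), levels = lv),
               factor(ifelse(k, "present", "absent"), levels = lv))
  arr <- array(as.integer(tab), dim = c(2, 2, 2),
               dimnames = list(subject = lv, predicate = lv, object = lv))
  structure(arr, class = "contingency3", T = sum(arr))
}

#' G-squared log-likelihood-ratio statistic
#'
#' For a 2x2x2 observed table `n_ijk`, computes
#' \deqn{G^2 = 2 \sum_{ijk} n_{ijk} \log(n_{ijk} / m_{ijk}),\quad
#'   m_{ijk} = \frac{\sum_i n_{jk} \cdot \sum_j n_{ik} \cdot \sum_k n_{ij}}{T^2}}
#' the likelihood-ratio test of mutual independence of the three axes
#' (asymptotically chi-squared with 4 df). Cells with `n_ijk = 0` contribute
#' zero (the `0 log 0 = 0` convention). Larger values mean the
#' subject/predicate/object co-occur far more than independence predicts.
#'
#' @param tab a `contingency3` array (or any 2x2x2 numeric array of counts).
#' @return the statistic (nonnegative up to ~1e-9 rounding).
#' @export
g2_statistic <- function(tab) {
  n <- array(as.numeric(tab), dim = c(2, 2, 2))
  if (any(n < 0)) stop("negative cell count")
  T <- sum(n)
  if (T <= 0) stop("total count is zero")
  mi <- apply(n, 1, sum)  # subject marginal n_i..
  mj <- apply(n, 2, sum)  # predicate marginal n_.j.
  mk <- apply(n, 3, sum)  # object marginal n_..k
  m <- outer(outer(mi, mj), mk) / T^2
  if (any(m == 0 & n > 0))
    stop("zero expectation with positive observation (inconsistent marginals)")
  pos <- n > 0
  2 * sum(n[pos] * log(n[pos] / m[pos]))
}

#' G-squared scores for every distinct triple of a graph
#'
#' Computes, per distinct triple, the statistic of [g2_statistic()] on the
#' contingency table induced by the full predication stream. All eight cells
#' are derived from subject/predicate/object marginal and pairwise counts by
#' inclusion-exclusion, so the cost is linear in the stream.
#'
#' @param kg a `kgraph` built from `preds`.
#' @param preds the predication instance stream the graph was built from.
#' @return numeric vector of G-squared values aligned with `kg$triples` rows.
#' @export
triple_g2 <- function(kg, preds) {
  preds$predicate <- toupper(trimws(preds$predicate))
  T <- nrow(preds)
  tr <- kg$triples
  ns <- table(preds$subject_id)
  np <- table(preds$predicate)
  no <- table(preds$object_id)
  nsp <- table(paste(preds$subject_id, preds$predicate, sep = "\r"))
  nso <- table(paste(preds$subject_id, preds$object_id, sep = "\r"))
  npo <- table(paste(preds$predicate, preds$object_id, sep = "\r"))
  cnt <- function(tb, k) { v <- tb[k]; v[is.na(v)] <- 0; as.numeric(v) }
  Ns <- cnt(ns, tr$head); Np <- cnt(np, tr$relation); No <- cnt(no, tr$tail)
  Nsp <- cnt(nsp, paste(tr$head, tr$relation, sep = "\r"))
  Nso <- cnt(nso, paste(tr$head, tr$tail, sep = "\r"))
  Npo <- cnt(npo, paste(tr$relation, tr$tail, sep = "\r"))
  N111 <- tr$count
  vapply(seq_len(nrow(tr)), function(idx) {
    n111 <- N111[idx]
    n110 <- Nsp[idx] - n111
    n101 <- Nso[idx] - n111
    n011 <- Npo[idx] - n111
    n100 <- Ns[idx] - Nsp[idx] - Nso[idx] + n111
    n010 <- Np[idx] - Nsp[idx] - Npo[idx] + n111
    n001 <- No[idx] - Nso[idx] - Npo[idx] + n111
    n000 <- T - Ns[idx] - Np[idx] - No[idx] + Nsp[idx] + Nso[idx] +
      Npo[idx] - n111
    arr <- array(c(n111, n011, n101, n001, n110, n010, n100, n000),
                 dim = c(2, 2, 2))
    g2_statistic(arr)
  }, numeric(1))
}

#' Combined triple specificity scores
#'
#' Min--max normalizes three components over the triple population -- the
#' head's out-degree, the tail's in-degree, and the triple's G-squared -- and
#' sums them. A higher combined score marks a less specific, less informative
#' triple (hub endpoints, generic co-occurrence), which pruning removes
#' first. A constant component (max = min) contributes 0 for every triple.
#'
#' @param kg a `kgraph`.
#' @param degrees output of [node_degrees()] (computed if `NULL`).
#' @param g2 numeric vector of per-triple G-squared values aligned with
#'   `kg$triples` (zeros if `NULL`).
#' @param degree_mode `"pair"` (default) uses head out-degree and tail
#'   in-degree as two components; `"max"` collapses them to their maximum,
#'   used once.
#' @return `data.frame` (head, relation, tail, k_out, k_in, g2, combined).
#' @export
combined_scores <- function(kg, degrees = NULL, g2 = NULL,
                            degree_mode = c("pair", "max")) {
  degree_mode <- match.arg(degree_mode)
  if (is.null(degrees)) degrees <- node_degrees(kg)
  tr <- kg$triples
  if (is.null(g2)) g2 <- numeric(nrow(tr))
  if (length(g2) != nrow(tr)) stop("g2 not aligned with triples")
  k_out <- degrees$k_out[match(tr$head, degrees$concept_id)]
  k_in <- degrees$k_in[match(tr$tail, degrees$concept_id)]
  mm <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  combined <- if (degree_mode == "pair") {
    mm(k_out) + mm(k_in) + mm(g2)
  } else {
    mm(pmax(k_out, k_in)) + mm(g2)
  }
  data.frame(head = tr$head, relation = tr$relation, tail = tr$tail,
             k_out = k_out, k_in = k_in, g2 = g2, combined = combined,
             stringsAsFactors = FALSE)
}

#' Prune a graph to a triple budget
#'
#' Retains the `budget` lowest-combined-score (most specific) triples with a
#' deterministic tie-break by (score, head, relation, tail). Retained sets
#' nest across budgets.
#'
#' @param kg a `kgraph`.
#' @param scores output of [combined_scores()] aligned with `kg$triples`.
#' @param budget number of triples to keep.
#' @return pruned `kgraph`.
#' @export
prune_to_budget <- function(kg, scores, budget) {
  if (budget < 0) stop("budget must be >= 0")
  n <- nrow(kg$triples)
  if (budget >= n) return(kg)
  o <- order(scores$combined, scores$head, scores$relation, scores$tail,
             method = "radix")
  keep_rows <- sort(o[seq_len(budget)])
  kg_subset(kg, keep_rows)
}

#' Pluggable triple-verification filter
#'
#' Keeps triples for which an external boolean predicate returns `TRUE`. The
#' hook interface stands where a trained triple-verification classifier
#' (scoring a triple against its source sentence) would plug in; the default
#' hook keeps everything.
#'
#' @param kg a `kgraph`.
#' @param hook `function(head, relation, tail) -> logical(1)`; must be total
#'   over triples. An error raised by the hook aborts with the offending
#'   triple identified.
#' @return filtered `kgraph`.
#' @export
triple_filter_hook <- function(kg, hook = function(h, r, t) TRUE) {
  tr <- kg$triples
  keep <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    v <- tryCatch(isTRUE(hook(tr$head[i], tr$relation[i], tr$tail[i])),
                  error = function(e)
                    stop("filter hook failed on triple (", tr$head[i], ", ",
                         tr$relation[i], ", ", tr$tail[i], "): ",
                         conditionMessage(e), call. = FALSE))
    keep[i] <- v
  }
  kg_subset(kg, keep)
}
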