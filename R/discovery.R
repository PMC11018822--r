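#' Rank candidate interventions against a target disease
#'
#' Scores every intervention node of the requested class as the head of
#' `(npi, relation, disease)` under the fitted model, drops candidates whose
#' triple already exists in the graph (only novel links are of interest), and
#' ranks the rest by descending plausibility. The reported probability column
#' is the min-max normalization of the plausibility over the scored class, so
#' the top candidate maps to 1; it is an order-preserving normalized score,
#' not a calibrated probability.
#'
#' @param model a fitted `kglp`.
#' @param kg the graph (supplies NPI classes and the exclusion filter).
#' @param npi_class `"DS"` or `"CIH"`.
#' @param relation fixed predicate (default `"PREVENTS"`).
#' @param disease_id target disease concept id.
#' @return `data.frame` of class `candidate_table` with columns npi_id,
#'   npi_class, score, probability, rank, sorted by descending score.
#' @export
score_candidates <- function(model, kg, npi_class = c("DS", "CIH"),
                             relation = "PREVENTS", disease_id) {
  npi_class <- match.arg(npi_class)
  if (!disease_id %in% kg$entities$concept_id)
    stop("disease ", disease_id, " not in vocabulary")
  heads <- kg$entities$concept_id[kg$entities$npi_class == npi_class]
  if (!length(heads)) stop("no NPI nodes of class ", npi_class)
  known <- contains_triple(kg, heads, rep(relation, length(heads)),
                           rep(disease_id, length(heads)))
  heads <- heads[!known]
  if (!length(heads)) stop("every ", npi_class, " candidate already linked")
  s <- predict(model, h = heads, r = rep(relation, length(heads)),
               t = rep(disease_id, length(heads)))
  rng <- range(s)
  prob <- if (rng[1] == rng[2]) rep(1, length(s)) else
    (s - rng[1]) / (rng[2] - rng[1])
  o <- order(-s, heads, method = "radix")
  out <- data.frame(npi_id = heads[o], npi_class = npi_class, score = s[o],
                    probability = prob[o], rank = seq_along(o),
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Closed-discovery patterns
#'
#' A discovery pattern is a two-hop relation template
#' `intervention -[hop1]-> intermediate -[hop2]-> disease` with a negation
#' clause: the direct `(intervention, PREVENTS, disease)` link must NOT
#' already be known. The supplement (DS) pattern constrains hop 1 to
#' INHIBITS/INTERACTS_WITH and hop 2 to
#' AFFECTS/CAUSES/PREDISPOSES/ASSOCIATED_WITH; the complementary-health (CIH)
#' pattern leaves both hops unconstrained.
#'
#' @param hop1_relations,hop2_relations predicate sets, or `"ANY"`.
#' @param head_class `"DS"` or `"CIH"`.
#' @param negation_relation predicate of the negation clause.
#' @return object of class `discovery_pattern`.
#' @export
discovery_pattern <- function(hop1_relations = "ANY", hop2_relations = "ANY",
                              head_class = c("DS", "CIH"),
                              negation_relation = "PREVENTS") {
  head_class <- match.arg(head_class)
  structure(list(hop1_relations = hop1_relations,
                 hop2_relations = hop2_relations,
                 head_class = head_class,
                 negation_relation = negation_relation),
            class = "discovery_pattern")
}

#' @rdname discovery_pattern
#' @export
ds_pattern <- function() {
  discovery_pattern(hop1_relations = c("INHIBITS", "INTERACTS_WITH"),
                    hop2_relations = c("AFFECTS", "CAUSES", "PREDISPOSES",
                                       "ASSOCIATED_WITH"),
                    head_class = "DS")
}

#' @rdname discovery_pattern
#' @export
cih_pattern <- function() discovery_pattern(head_class = "CIH")

#' Match a discovery pattern between an intervention and a disease
#'
#' Enumerates all intermediates `B` with a hop-1 triple
#' `(intervention, p1, B)` and a hop-2 triple `(B, p2, disease)` whose
#' predicates satisfy the pattern. Returns the empty set when the negation
#' triple `(intervention, negation_relation, disease)` exists. Paths are
#' deduplicated by (intermediate, hop-1 predicate, hop-2 predicate) and carry
#' the source-document provenance of each hop.
#'
#' @param kg a `kgraph`.
#' @param pattern a [discovery_pattern()].
#' @param intervention_id,disease_id endpoint concept ids (in vocabulary).
#' @return `data.frame` with columns intervention_id, hop1_predicate,
#'   intermediate_id, hop2_predicate, disease_id, hop1_doc, hop2_doc.
#' @export
match_pattern <- function(kg, pattern, intervention_id, disease_id) {
  stopifnot(inherits(pattern, "discovery_pattern"))
  ids <- kg$entities$concept_id
  if (!intervention_id %in% ids) stop("unknown intervention: ", intervention_id)
  if (!disease_id %in% ids) stop("unknown disease: ", disease_id)
  empty <- data.frame(intervention_id = character(),
                      hop1_predicate = character(),
                      intermediate_id = character(),
                      hop2_predicate = character(),
                      disease_id = character(), hop1_doc = character(),
                      hop2_doc = character(), stringsAsFactors = FALSE)
  if (contains_triple(kg, intervention_id, pattern$negation_relation,
                      disease_id))
    return(empty)
  tr <- kg$triples
  hop1 <- tr[tr$head == intervention_id &
               (identical(pattern$hop1_relations, "ANY") |
                  tr$relation %in% pattern$hop1_relations), , drop = FALSE]
  hop2 <- tr[tr$tail == disease_id &
               (identical(pattern$hop2_relations, "ANY") |
                  tr$relation %in% pattern$hop2_relations), , drop = FALSE]
  if (!nrow(hop1) || !nrow(hop2)) return(empty)
  j <- merge(hop1[, c("tail", "relation", "first_doc")],
             hop2[, c("head", "relation", "first_doc")],
             by.x = "tail", by.y = "head", suffixes = c("_1", "_2"))
  if (!nrow(j)) return(empty)
  out <- data.frame(intervention_id = intervention_id,
                    hop1_predicate = j$relation_1,
                    intermediate_id = j$tail,
                    hop2_predicate = j$relation_2,
                    disease_id = disease_id,
                    hop1_doc = j$first_doc_1, hop2_doc = j$first_doc_2,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("intermediate_id", "hop1_predicate",
                                 "hop2_predicate")]), , drop = FALSE]
  out <- out[order(out$intermediate_id, out$hop1_predicate,
                   out$hop2_predicate, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine mechanism paths for top-ranked candidates
#'
#' Applies the class-appropriate discovery pattern ([ds_pattern()] for DS
#' candidates, [cih_pattern()] for CIH) to the `top_n` highest-ranked rows of
#' a candidate table.
#'
#' @param kg a `kgraph`.
#' @param candidates a `candidate_table` from [score_candidates()].
#' @param disease_id target disease id.
#' @param top_n number of leading candidates to mine (clipped to the table).
#' @return named list mapping candidate id to its path `data.frame`.
#' @export
mine_mechanisms <- function(kg, candidates, disease_id, top_n = 10) {
  if (top_n < 1) stop("top_n must be >= 1")
  n <- min(top_n, nrow(candidates))
  out <- vector("list", n)
  names(out) <- candidates$npi_id[seq_len(n)]
  for (i in seq_len(n)) {
    pat <- if (candidates$npi_class[i] == "DS") ds_pattern() else cih_pattern()
    out[[i]] <- match_pattern(kg, pat, candidates$npi_id[i], disease_id)
  }
  out
}
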