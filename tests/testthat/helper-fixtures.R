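# Shared fixture builders. Everything is generated in code; no stored data.

# a small hand-written predication stream with duplicates and provenance
toy_predications <- function() {
  predications(
    subject_id = c("C01", "C01", "C01", "C02", "C03", "C02"),
    predicate = c("TREATS", "TREATS", "TREATS", "CAUSES", "INHIBITS",
                  "treats "),
    object_id = c("C10", "C10", "C10", "C10", "C20", "C11"),
    doc_id = paste0("PMID", 1:6),
    pub_date = c("2019-05-01", "2018-03-02", "2020-07-09", "2015-01-01",
                 "2021-06-30", "2017-11-11"),
    sentence_ref = paste0("s", 1:6))
}

toy_graph <- function() build_graph(toy_predications())

# a deterministic random graph over n entities / m triples
random_graph <- function(n_ent = 30, n_rel = 4, m = 120, seed = 42) {
  set.seed(seed)
  ids <- sprintf("C%03d", seq_len(n_ent))
  rels <- paste0("REL", seq_len(n_rel))
  preds <- predications(
    subject_id = sample(ids, m, replace = TRUE),
    predicate = sample(rels, m, replace = TRUE),
    object_id = sample(ids, m, replace = TRUE),
    doc_id = sprintf("D%04d", seq_len(m)),
    pub_date = as.Date("2015-01-01") + sample.int(2000, m, replace = TRUE),
    sentence_ref = "")
  build_graph(preds)
}

# small synthetic corpus used across model tests (cached per session)
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_entities = c(Drug = 40, Disease = 20, Gene = 20,
                                         DS = 12, CIH = 8),
                          n_triples = 600, n_planted_mechanisms = 8,
                          n_heldout_prevents = 4, seed = 77)
      gen <- generate_kg(cfg)
      cache <<- list(gen = gen, kg = build_graph(gen$predications, gen$meta))
    }
    cache
  }
})

# random 2x2x2 count table with consistent totals
random_contingency <- function(T = 400, seed = 1) {
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, T, prob = runif(8, 0.02, 1)))
  array(counts, dim = c(2, 2, 2),
        dimnames = list(subject = c("present", "absent"),
                        predicate = c("present", "absent"),
                        object = c("present", "absent")))
}

# independent brute-force G2: explicit marginals and cell-by-cell double sum
oracle_g2 <- function(tab) {
  n <- array(as.numeric(tab), dim = c(2, 2, 2))
  T <- sum(n)
  g <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    ni <- sum(n[i, , ]); nj <- sum(n[, j, ]); nk <- sum(n[, , k])
    m <- ni * nj * nk / T^2
    if (n[i, j, k] > 0) g <- g + n[i, j, k] * log(n[i, j, k] / m)
  }
  2 * g
}
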