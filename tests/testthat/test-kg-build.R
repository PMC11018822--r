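test_that("rule filters drop generic concepts, excluded groups, off-whitelist predicates", {
  set.seed(4)
  ids <- sprintf("C%02d", 1:20)
  preds <- predications(sample(ids[1:10], 50, replace = TRUE),
                        sample(c("TREATS", "CAUSES", "IS_A"), 50,
                               replace = TRUE),
                        sample(ids[11:20], 50, replace = TRUE),
                        paste0("d", 1:50), as.Date("2020-01-01") + 1:50)
  meta <- data.frame(concept_id = ids, name = ids, semantic_type = "t",
                     semantic_group = rep(c("Disorders", "Concepts & Ideas"),
                                          10),
                     npi_class = "none", stringsAsFactors = FALSE)
  kg <- build_graph(preds, meta)
  cfg <- filter_config(generic_concepts = "C01",
                       excluded_groups = "Concepts & Ideas",
                       relation_whitelist = c("TREATS", "CAUSES"))
  out <- apply_rule_filters(kg, cfg)
  tr <- out$triples
  # linear-scan oracle of the expected survivors
  bad_ent <- ids[seq(2, 20, 2)]  # even positions carry the excluded group
  bad_ent <- union(bad_ent, "C01")
  want <- kg$triples[!(kg$triples$head %in% bad_ent) &
                       !(kg$triples$tail %in% bad_ent) &
                       kg$triples$relation %in% c("TREATS", "CAUSES"), ]
  expect_equal(nrow(tr), nrow(want))
  expect_true(all(kg_key(tr$head, tr$relation, tr$tail) %in%
                    kg_key(want$head, want$relation, want$tail)))
  # subgraph property and vocabulary shrinkage
  expect_true(all(kg_key(tr$head, tr$relation, tr$tail) %in%
                    kg_key(kg$triples$head, kg$triples$relation,
                           kg$triples$tail)))
  expect_true(all(out$entities$concept_id %in% c(tr$head, tr$tail)))
  # identity config leaves the graph untouched
  full <- apply_rule_filters(kg, filter_config(
    excluded_groups = character(), relation_whitelist = kg$relations))
  expect_equal(nrow(full$triples), nrow(kg$triples))
  # disjoint whitelist errors rather than emptying the graph
  expect_error(apply_rule_filters(kg, filter_config(
    relation_whitelist = "NO_SUCH_RELATION")), "whitelist")
})

test_that("node_degrees counts distinct triples, matching a brute-force tally", {
  # star graph: hub with 5 out-edges
  preds <- predications(rep("HUB", 5), rep("REL", 5), paste0("L", 1:5),
                        paste0("d", 1:5), rep("2020-01-01", 5))
  kg <- build_graph(preds)
  deg <- node_degrees(kg)
  expect_equal(deg$k_out[deg$concept_id == "HUB"], 5)
  expect_equal(deg$k_in[deg$concept_id == "HUB"], 0)
  expect_equal(deg$k_in[deg$concept_id == "L1"], 1)
  expect_equal(deg$k_out[deg$concept_id == "L1"], 0)

  kg <- random_graph(25, 3, 200, seed = 17)
  deg <- node_degrees(kg)
  for (i in sample(nrow(deg), 10)) {
    id <- deg$concept_id[i]
    expect_equal(deg$k_out[i], sum(kg$triples$head == id))
    expect_equal(deg$k_in[i], sum(kg$triples$tail == id))
  }
})

test_that("contingency_from_stream classifies every instance into the right cell", {
  preds <- toy_predications()
  tab <- contingency_from_stream(preds, "C01", "TREATS", "C10")
  expect_equal(tab["present", "present", "present"], 3)
  expect_equal(sum(tab), nrow(preds))
  # absent focal terms put all mass in the all-absent cell
  tab0 <- contingency_from_stream(preds, "ZZZ", "NOPE", "YYY")
  expect_equal(tab0["absent", "absent", "absent"], nrow(preds))
  # brute-force per-instance classification on a random stream
  set.seed(3)
  n <- 300
  st <- predications(sample(c("s", "x", "y"), n, TRUE),
                     sample(c("P", "Q"), n, TRUE),
                     sample(c("o", "u", "v"), n, TRUE),
                     "d", rep("2020-01-01", n))
  tab <- contingency_from_stream(st, "s", "P", "o")
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    want <- sum((st$subject_id == "s") == (i == 1) &
                  (st$predicate == "P") == (j == 1) &
                  (st$object_id == "o") == (k == 1))
    expect_equal(unname(tab[i, j, k]), want)
  }
})

test_that("G-squared matches the likelihood-ratio oracle and the KL form", {
  # perfect independence gives zero
  p <- outer(outer(c(.3, .7), c(.4, .6)), c(.5, .5))
  expect_equal(g2_statistic(p * 1000), 0, tolerance = 1e-12)
  # spec example table
  tab <- array(c(20, 5, 5, 20, 5, 20, 20, 5), dim = c(2, 2, 2))
  expect_equal(g2_statistic(tab), oracle_g2(tab), tolerance = 1e-12)
  # random tables: oracle equality and the scaled-KL identity
  for (s in 1:25) {
    tab <- random_contingency(T = 300 + 40 * s, seed = s)
    g <- g2_statistic(tab)
    expect_gte(g, -1e-9)
    expect_equal(g, oracle_g2(tab), tolerance = 1e-9)
    # G2 = 2*T*KL(observed || product-of-marginals)
    n <- array(as.numeric(tab), dim = c(2, 2, 2)); T <- sum(n)
    pn <- n / T
    q <- outer(outer(apply(pn, 1, sum), apply(pn, 2, sum)),
               apply(pn, 3, sum))
    kl <- sum(ifelse(pn > 0, pn * log(pn / q), 0))
    expect_equal(g, 2 * T * kl, tolerance = 1e-9)
  }
  expect_error(g2_statistic(array(0, c(2, 2, 2))), "zero")
})

test_that("G-squared is invariant under consistent relabeling of the axis levels", {
  tab <- random_contingency(T = 500, seed = 11)
  flipped <- tab[2:1, 2:1, 2:1]
  expect_equal(g2_statistic(tab), g2_statistic(flipped), tolerance = 1e-12)
})

test_that("triple_g2 equals per-triple contingency construction plus g2_statistic", {
  kg <- random_graph(12, 2, 80, seed = 23)
  set.seed(24)
  preds <- predications(sample(kg$entities$concept_id, 400, TRUE),
                        sample(kg$relations, 400, TRUE),
                        sample(kg$entities$concept_id, 400, TRUE),
                        "d", rep("2020-01-01", 400))
  kg2 <- build_graph(preds)
  g2 <- triple_g2(kg2, preds)
  for (i in sample(nrow(kg2$triples), 12)) {
    tab <- contingency_from_stream(preds, kg2$triples$head[i],
                                   kg2$triples$relation[i],
                                   kg2$triples$tail[i])
    expect_equal(g2[i], g2_statistic(tab), tolerance = 1e-9)
  }
})

test_that("combined scores are min-max normalized sums with documented edge cases", {
  kg <- random_graph(15, 2, 60, seed = 41)
  g2 <- seq_len(nrow(kg$triples)) * 1.0
  sc <- combined_scores(kg, g2 = g2)
  expect_true(all(is.finite(sc$combined)))
  # spreadsheet-style recomputation
  deg <- node_degrees(kg)
  ko <- deg$k_out[match(kg$triples$head, deg$concept_id)]
  ki <- deg$k_in[match(kg$triples$tail, deg$concept_id)]
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(sc$combined, mm(ko) + mm(ki) + mm(g2), tolerance = 1e-12)
  # a triple maximal in all three components scores 3, minimal scores 0
  expect_lte(max(sc$combined), 3)
  expect_gte(min(sc$combined), 0)
  # constant component contributes zero for everyone
  sc0 <- combined_scores(kg, g2 = rep(5, nrow(kg$triples)))
  expect_equal(sc0$combined, mm(ko) + mm(ki), tolerance = 1e-12)
})

test_that("prune_to_budget keeps the most specific triples and nests across budgets", {
  kg <- random_graph(20, 3, 100, seed = 55)
  set.seed(56)
  sc <- combined_scores(kg, g2 = runif(nrow(kg$triples)))
  pr60 <- prune_to_budget(kg, sc, 60)
  # sort-and-slice oracle
  o <- order(sc$combined, sc$head, sc$relation, sc$tail, method = "radix")
  want <- kg$triples[sort(o[1:60]), ]
  expect_equal(pr60$triples$head, want$head)
  expect_equal(pr60$triples$tail, want$tail)
  # edge budgets
  expect_equal(nrow(prune_to_budget(kg, sc, nrow(kg$triples))$triples),
               nrow(kg$triples))
  expect_equal(nrow(prune_to_budget(kg, sc, 0)$triples), 0)
  # nesting: retained set at k is inside retained set at k+1
  keys <- function(g) kg_key(g$triples$head, g$triples$relation,
                             g$triples$tail)
  for (k in c(10, 25, 40, 59, 80)) {
    a <- keys(prune_to_budget(kg, sc, k))
    b <- keys(prune_to_budget(kg, sc, k + 1))
    expect_true(all(a %in% b))
  }
})

test_that("triple_filter_hook applies an arbitrary predicate, with identity/empty extremes", {
  kg <- random_graph(15, 2, 50, seed = 61)
  expect_equal(nrow(triple_filter_hook(kg)$triples), nrow(kg$triples))
  expect_equal(nrow(triple_filter_hook(kg, function(h, r, t) FALSE)$triples),
               0)
  hook <- function(h, r, t) (nchar(h) + nchar(t)) %% 2 == 0
  out <- triple_filter_hook(kg, hook)
  want <- mapply(hook, kg$triples$head, kg$triples$relation, kg$triples$tail)
  expect_equal(nrow(out$triples), sum(want))
  expect_error(triple_filter_hook(kg, function(h, r, t) stop("boom")),
               "filter hook failed")
})
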