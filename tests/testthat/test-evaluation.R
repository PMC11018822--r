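test_that("chronological split slices 8:1:1 and is permutation-invariant", {
  set.seed(7)
  n <- 100
  preds <- predications(sprintf("H%03d", 1:n), "TREATS",
                        sprintf("T%03d", 1:n), paste0("d", 1:n),
                        as.Date("2015-01-01") + sample.int(3000, n))
  kg <- build_graph(preds)
  sp <- chronological_split(kg)
  expect_equal(nrow(sp$train$triples), 80)
  expect_equal(nrow(sp$valid$triples), 10)
  expect_equal(nrow(sp$test$triples), 10)
  # disjoint, covering, ordered by date across slices
  keys <- function(g) kg_key(g$triples$head, g$triples$relation,
                             g$triples$tail)
  expect_length(intersect(keys(sp$train), keys(sp$test)), 0)
  expect_length(c(keys(sp$train), keys(sp$valid), keys(sp$test)), n)
  expect_lte(max(sp$train$triples$first_date), min(sp$test$triples$first_date))
  expect_equal(sp$cut_dates[1], max(sp$train$triples$first_date))
  # shuffled input gives the identical split
  kg2 <- build_graph(preds[sample(n), ])
  sp2 <- chronological_split(kg2)
  expect_setequal(keys(sp$train), keys(sp2$train))
  expect_setequal(keys(sp$test), keys(sp2$test))
})

test_that("all-tied dates still split 8:1:1 through the deterministic tie-break", {
  preds <- predications(sprintf("H%02d", 1:50), "TREATS",
                        sprintf("T%02d", 1:50), paste0("d", 1:50),
                        rep("2020-04-01", 50))
  kg <- build_graph(preds)
  sp <- chronological_split(kg)
  expect_equal(nrow(sp$train$triples), 40)
  expect_equal(nrow(sp$valid$triples), 5)
  expect_equal(nrow(sp$test$triples), 5)
})

test_that("explicit cut dates assign triples by attestation date", {
  preds <- predications(sprintf("H%02d", 1:30), "TREATS",
                        sprintf("T%02d", 1:30), paste0("d", 1:30),
                        as.Date("2019-01-01") + 30 * (0:29))
  kg <- build_graph(preds)
  sp <- chronological_split(kg, cut_dates = c("2020-04-01", "2021-04-01"))
  expect_true(all(sp$train$triples$first_date <= as.Date("2020-04-01")))
  expect_true(all(sp$test$triples$first_date > as.Date("2021-04-01")))
})

test_that("ground-truth test set deduplicates heads and drops unknown ones", {
  kg <- toy_graph()
  ts <- build_ground_truth_testset(kg, c("C01", "C02", "C01", "ZZZ"),
                                   relation = "PREVENTS", tail_id = "C10")
  expect_equal(nrow(ts), 2)
  expect_true(all(ts$relation == "PREVENTS" & ts$tail == "C10"))
  expect_equal(attr(ts, "dropped"), "ZZZ")
  # set-intersection oracle on a random head list
  set.seed(8)
  heads <- sprintf("C%02d", sample(30, 20))
  ts2 <- build_ground_truth_testset(kg, heads, tail_id = "C10")
  expect_equal(nrow(ts2),
               length(intersect(unique(heads), kg$entities$concept_id)))
})

test_that("rank_triple extremes and tie handling follow the mean-rank convention", {
  mr <- kglbd:::.mean_rank
  expect_equal(mr(10, 1:9), 1)           # above all corruptions
  expect_equal(mr(0, 1:9), 10)           # below all nine corruptions
  # ties: mean over tied orderings, rounded half up, vs permutation oracle
  perm_oracle <- function(s, cand) {
    # positions of the true item over all orderings of the tied block
    n_gt <- sum(cand > s); n_tie <- sum(cand == s)
    positions <- n_gt + seq_len(n_tie + 1)
    floor(mean(positions) + 0.5)
  }
  cases <- list(list(s = 5, cand = c(7, 5, 5, 3)),
                list(s = 2, cand = c(2, 2, 2, 2, 2)),
                list(s = 1, cand = c(3, 2, 1, 1, 0)))
  for (cs in cases)
    expect_equal(mr(cs$s, cs$cand), perm_oracle(cs$s, cs$cand))
})

test_that("adding a worse-scored corruption never improves the rank", {
  mr <- kglbd:::.mean_rank
  set.seed(9)
  for (i in 1:50) {
    cand <- rnorm(20); s <- rnorm(1)
    r1 <- mr(s, cand)
    r2 <- mr(s, c(cand, s - abs(rnorm(1)) - 1e-9))
    expect_gte(r2, r1)
  }
})

test_that("metrics match closed forms and a loop oracle", {
  m <- metrics_from_ranks(c(1, 2, 4, 10))
  expect_equal(m$MR, 4.25)
  expect_equal(unname(m$hits["hits3"]), 0.5)
  m2 <- metrics_from_ranks(c(1, 2, 4))
  expect_equal(m2$MRR, (1 + 0.5 + 0.25) / 3, tolerance = 1e-12)
  set.seed(10)
  ranks <- sample.int(50, 500, replace = TRUE)
  m3 <- metrics_from_ranks(ranks)
  acc_mr <- 0; acc_mrr <- 0; h <- c(0, 0, 0)
  for (r in ranks) {
    acc_mr <- acc_mr + r; acc_mrr <- acc_mrr + 1 / r
    h <- h + (r <= c(1, 3, 10))
  }
  expect_equal(m3$MR, acc_mr / 500, tolerance = 1e-12)
  expect_equal(m3$MRR, acc_mrr / 500, tolerance = 1e-12)
  expect_equal(unname(m3$hits), h / 500, tolerance = 1e-12)
  # permutation invariance and monotone hits
  expect_equal(metrics_from_ranks(rev(ranks))$MRR, m3$MRR)
  expect_true(m3$hits["hits1"] <= m3$hits["hits3"] &&
                m3$hits["hits3"] <= m3$hits["hits10"])
  expect_error(metrics_from_ranks(integer()), "empty")
})

test_that("AUROC equals the normalized Mann-Whitney U statistic", {
  # perfectly separated
  cv <- curves_from_scores(c(5, 6, 7), c(1, 2, 3))
  expect_equal(cv$auroc, 1)
  expect_equal(cv$aupr, 1)
  # all tied
  cv0 <- curves_from_scores(rep(1, 5), rep(1, 7))
  expect_equal(cv0$auroc, 0.5)
  set.seed(11)
  for (i in 1:20) {
    pos <- round(rnorm(30), 1); neg <- round(rnorm(40, -0.3), 1)
    cv <- curves_from_scores(pos, neg)
    # pairwise-comparison oracle: wins + half ties
    u <- 0
    for (p in pos) for (n in neg) u <- u + (p > n) + 0.5 * (p == n)
    expect_equal(cv$auroc, u / (30 * 40), tolerance = 1e-9)
    # cross-check against the W statistic of the rank-sum test
    w <- unname(stats::wilcox.test(pos, neg, exact = FALSE)$statistic)
    expect_equal(cv$auroc, w / (30 * 40), tolerance = 1e-9)
  }
})

test_that("a random scorer's MRR over m candidates matches the harmonic expectation", {
  # ranking one true item among m-1 sampled corruptions by an uninformative
  # model: rank is uniform on 1..m, so E[MRR] = sum(1/i)/m
  set.seed(12)
  m <- 10; n <- 10000
  ranks <- integer(n)
  for (i in seq_len(n)) {
    s <- runif(1); cand <- runif(m - 1)
    ranks[i] <- kglbd:::.mean_rank(s, cand)
  }
  got <- mean(1 / ranks)
  want <- sum(1 / seq_len(m)) / m
  se <- stats::sd(1 / ranks) / sqrt(n)
  expect_lt(abs(got - want), 3 * se)
})

test_that("head- and tail-side ranking agree for DistMult on a symmetrized graph", {
  sx <- small_synth()
  kg <- sx$kg
  # symmetrize: add the reverse of every triple
  tr <- kg$triples
  preds <- predications(c(tr$head, tr$tail), c(tr$relation, tr$relation),
                        c(tr$tail, tr$head), "d",
                        rep("2020-01-01", 2 * nrow(tr)))
  kgs <- build_graph(preds)
  fit <- fit_lp(kgs, "distmult", epochs = 10, hidden_dim = 16, neg_ratio = 3,
                seed = 17)
  test <- kgs$triples[sample(nrow(kgs$triples), 20), ]
  rh <- rt <- integer(20)
  for (i in 1:20) {
    rh[i] <- rank_triple(fit, kgs, test[i, ], n_negatives = 50,
                         side = "head", seed = 100 + i)
    rt[i] <- rank_triple(fit, kgs, test[i, ], n_negatives = 50,
                         side = "tail", seed = 100 + i)
  }
  # identical rank distributions up to sampling noise of the corruption draw
  expect_lt(abs(mean(rh) - mean(rt)), 6)
})

test_that("evaluate_lp assembles ranks, metrics and curves consistently", {
  sx <- small_synth()
  kg <- sx$kg
  fit <- fit_lp(kg, "distmult", epochs = 15, hidden_dim = 16, neg_ratio = 3,
                seed = 19)
  test <- kg$triples[1:10, c("head", "relation", "tail")]
  ev <- evaluate_lp(fit, kg, test, n_negatives = 30, sides = "both",
                    seed = 23)
  expect_length(ev$ranks, 20)  # both sides
  expect_true(all(ev$ranks >= 1 & ev$ranks <= 31))
  expect_equal(ev$metrics$MR, mean(ev$ranks))
  expect_gte(ev$auroc, 0); expect_lte(ev$auroc, 1)
})
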