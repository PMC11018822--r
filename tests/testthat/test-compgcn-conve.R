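test_that("circular correlation matches the index-arithmetic brute force", {
  # spec'd example: a = (1,2,3), b = (0,1,0)
  a <- c(1, 2, 3); b <- c(0, 1, 0)
  brute <- function(a, b) {
    d <- length(a)
    vapply(0:(d - 1), function(i)
      sum(a * b[((seq_len(d) - 1 + i) %% d) + 1]), numeric(1))
  }
  expect_equal(circular_correlation(a, b), brute(a, b), tolerance = 1e-12)
  set.seed(14)
  for (d in c(2, 3, 5, 8)) {
    x <- rnorm(d); y <- rnorm(d)
    expect_equal(circular_correlation(x, y), brute(x, y), tolerance = 1e-9)
  }
  # matrix rows correlate row-wise
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(12), 3, 4)
  M <- circular_correlation(A, B)
  for (i in 1:3) expect_equal(M[i, ], brute(A[i, ], B[i, ]),
                              tolerance = 1e-9)
})

test_that("correlating the unit impulse against b returns b (identity element)", {
  set.seed(15)
  b <- rnorm(6)
  delta <- c(1, rep(0, 5))
  expect_equal(circular_correlation(delta, b), b, tolerance = 1e-12)
})

test_that("CompGCN composition reductions: zero relation and all-ones relation", {
  kg <- random_graph(8, 2, 30, seed = 19)
  ne <- nrow(kg$entities)
  # subtraction with y = 0 reduces to aggregation of W x_j
  dec3 <- conve_config(3, emb_h = 1, emb_w = 3, n_filters = 2, kernel = 1,
                       seed = 55)
  p <- compgcn_params(kg, dims = c(3, 3), composition = "subtraction",
                      conve = dec3, feature_dropout = 0, layer_dropout = 0,
                      seed = 5)
  p$Y0 <- matrix(0, nrow(p$Y0), 3)
  out_sub <- compgcn_forward(kg, p, training = FALSE)
  # multiplication with y = 1 gives the same reduction
  q <- p
  q$composition <- "multiplication"
  q$Y0 <- matrix(1, nrow(p$Y0), 3)
  out_mul <- compgcn_forward(kg, q, training = FALSE)
  expect_equal(out_sub$node_states, out_mul$node_states, tolerance = 1e-9)
  # oracle for one node: tanh( sum_classes W_class * sum_j x_j )
  X <- p$X0
  ids <- kg$entities$concept_id
  i <- 3
  orig_in <- match(kg$triples$head[kg$triples$tail == ids[i]], ids)
  inv_in <- match(kg$triples$tail[kg$triples$head == ids[i]], ids)
  z <- p$layers[[1]]$W_S %*% X[i, ]
  if (length(orig_in))
    z <- z + p$layers[[1]]$W_O %*% colSums(X[orig_in, , drop = FALSE])
  if (length(inv_in))
    z <- z + p$layers[[1]]$W_I %*% colSums(X[inv_in, , drop = FALSE])
  expect_equal(unname(out_sub$node_states[i, ]), as.vector(tanh(z)),
               tolerance = 1e-9)
})

test_that("CompGCN relation update projects relation states through W_rel", {
  kg <- random_graph(6, 2, 20, seed = 23)
  p <- compgcn_params(kg, dims = c(4, 4), feature_dropout = 0,
                      layer_dropout = 0, seed = 6,
                      conve = conve_config(4, emb_h = 2, emb_w = 2,
                                           n_filters = 2, kernel = 2))
  out <- compgcn_forward(kg, p, training = FALSE)
  expect_equal(out$rel_states, p$Y0 %*% t(p$layers[[1]]$W_rel),
               tolerance = 1e-12)
})

test_that("ConvE scores match a pencil-and-paper 1x1-kernel configuration", {
  # d = 4 reshaped 2x2, one 1x1 filter of weight 1, identity-like projection
  dec <- conve_config(4, emb_h = 2, emb_w = 2, n_filters = 1, kernel = 1,
                      seed = 7)
  dec$K <- matrix(1, 1, 1); dec$bf <- 0
  # projection picks the h-map positions (first half of each column block)
  # stacked image columns: (h1,h2,r1,r2, h3,h4,r3,r4) column-major
  Wp <- matrix(0, 8, 4)
  Wp[1, 1] <- 1; Wp[2, 2] <- 1; Wp[5, 3] <- 1; Wp[6, 4] <- 1
  dec$Wp <- Wp; dec$bp <- rep(0, 4); dec$b0 <- 0
  X <- rbind(c(1, 2, 3, 4), c(0.5, 1, 1.5, 2))
  Y <- rbind(c(0.1, 0.2, 0.3, 0.4))
  # with ReLU-positive inputs the score is <h, t>
  s <- conve_score(X, Y, h = 1, r = 1, t = 2, decoder_cfg = dec)
  expect_equal(s, sum(X[1, ] * X[2, ]), tolerance = 1e-12)
  # all-zero embeddings leave only the bias path
  dec$b0 <- 0.7
  X0 <- matrix(0, 2, 4); Y0 <- matrix(0, 1, 4)
  expect_equal(conve_score(X0, Y0, 1, 1, 2, dec), 0.7, tolerance = 1e-12)
})

test_that("ConvE evaluation scoring is deterministic (dropout disabled)", {
  kg <- random_graph(10, 2, 40, seed = 29)
  p <- compgcn_params(kg, dims = c(16, 16), seed = 8)
  enc <- compgcn_forward(kg, p, training = FALSE)
  s1 <- conve_score(enc$node_states, enc$rel_states, 1:5, c(1, 2, 1, 2, 1),
                    6:10, p$conve)
  s2 <- conve_score(enc$node_states, enc$rel_states, 1:5, c(1, 2, 1, 2, 1),
                    6:10, p$conve)
  expect_identical(s1, s2)
})

test_that("non-factorable reshape is a configuration error", {
  expect_error(conve_config(10, emb_h = 3, emb_w = 3), "reshaped")
})

test_that("analytic CompGCN/ConvE gradients agree with finite differences", {
  kg <- random_graph(6, 2, 18, seed = 37)
  p <- compgcn_params(kg, dims = c(4, 4), feature_dropout = 0,
                      layer_dropout = 0, seed = 9,
                      conve = conve_config(4, emb_h = 2, emb_w = 2,
                                           n_filters = 2, kernel = 2,
                                           hidden_dropout = 0,
                                           feature_dropout = 0, seed = 10))
  pos <- list(h = kg$.h_id, r = kg$.r_id, t = kg$.t_id)
  neg <- list(h = rev(kg$.h_id), r = kg$.r_id, t = kg$.t_id)
  res <- kglbd:::.compgcn_loss_grads(kg, p, pos, neg)
  loss_at <- function(q) kglbd:::.compgcn_loss_grads(kg, q, pos, neg)$loss
  eps <- 1e-6
  probes <- list(
    list(g = res$grads$X0[2, 3],
         s = function(q, v) { q$X0[2, 3] <- v; q },
         v = p$X0[2, 3]),
    list(g = res$grads$Y0[1, 2],
         s = function(q, v) { q$Y0[1, 2] <- v; q },
         v = p$Y0[1, 2]),
    list(g = res$grads$layers[[1]]$W_O[1, 4],
         s = function(q, v) { q$layers[[1]]$W_O[1, 4] <- v; q },
         v = p$layers[[1]]$W_O[1, 4]),
    list(g = res$grads$layers[[1]]$W_rel[2, 2],
         s = function(q, v) { q$layers[[1]]$W_rel[2, 2] <- v; q },
         v = p$layers[[1]]$W_rel[2, 2]),
    list(g = res$grads$conve$dK[1, 2],
         s = function(q, v) { q$conve$K[1, 2] <- v; q },
         v = p$conve$K[1, 2]),
    list(g = res$grads$conve$dWp[3, 2],
         s = function(q, v) { q$conve$Wp[3, 2] <- v; q },
         v = p$conve$Wp[3, 2]))
  for (pr in probes) {
    fd <- (loss_at(pr$s(p, pr$v + eps)) - loss_at(pr$s(p, pr$v - eps))) /
      (2 * eps)
    expect_equal(pr$g, fd, tolerance = 1e-4)
  }
})

test_that("the normalized cross-entropy matches its closed forms and a loop oracle", {
  # perfect separation drives the loss to zero
  sp <- loss_spec(neg_ratio = 1, edge_count = 1)
  expect_lt(bce_link_loss(c(40, -40), c(1, 0), sp), 1e-10)
  # all-zero scores give log(2) x count / ((1+omega)|e|)
  sp2 <- loss_spec(neg_ratio = 1, edge_count = 2)
  expect_equal(bce_link_loss(rep(0, 4), c(1, 1, 0, 0), sp2),
               log(2) * 4 / (2 * 2), tolerance = 1e-12)
  # random scores vs scalar loop
  set.seed(16)
  s <- rnorm(30); y <- rbinom(30, 1, 0.3)
  sp3 <- loss_spec(neg_ratio = 2, edge_count = 10)
  acc <- 0
  for (i in 1:30) {
    p <- 1 / (1 + exp(-s[i]))
    acc <- acc + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  expect_equal(bce_link_loss(s, y, sp3), -acc / (3 * 10), tolerance = 1e-9)
  # permutation invariance
  o <- sample(30)
  expect_equal(bce_link_loss(s, y, sp3), bce_link_loss(s[o], y[o], sp3),
               tolerance = 1e-12)
  expect_error(bce_link_loss(c(1, 2), c(1, 2), sp3), "labels")
})
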