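#' Configuration for the synthetic literature knowledge-graph generator
#'
#' The generator emulates a predication corpus mined from biomedical
#' literature: typed entities (Drugs, Diseases, Genes, dietary supplements,
#' complementary/integrative health practices), the fifteen-relation
#' vocabulary with its skewed frequency profile, per-instance publication
#' dates, latent low-rank structure that a link predictor can recover, and
#' planted two-hop mechanism paths whose direct preventive closure is held
#' out for evaluation.
#'
#' @param n_entities named counts per type (`Drug`, `Disease`, `Gene`, `DS`,
#'   `CIH`).
#' @param relation_profile predicate proportions (must sum to 1).
#' @param latent_model `"TransE"` or `"DistMult"`: the latent scorer that
#'   shapes which typed triples are emitted.
#' @param latent_dim latent dimension.
#' @param n_triples distinct triples to emit.
#' @param noise_fraction fraction of triples replaced by uniform random typed
#'   triples, in `[0, 1)`.
#' @param date_range two dates bounding the uniform publication dates.
#' @param n_planted_mechanisms number of planted `(npi, INHIBITS, gene)` +
#'   `(gene, CAUSES, disease)` paths toward the target disease.
#' @param n_heldout_prevents how many planted interventions have their
#'   `(npi, PREVENTS, disease)` closure withheld from the emitted graph
#'   (must not exceed `n_planted_mechanisms`).
#' @param seed RNG seed; the whole stream is reproducible from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_entities = c(Drug = 200, Disease = 100, Gene = 100,
                                        DS = 60, CIH = 40),
                         relation_profile = default_relation_profile(),
                         latent_model = c("TransE", "DistMult"),
                         latent_dim = 32, n_triples = 5000,
                         noise_fraction = 0.1,
                         date_range = c("2012-01-01", "2022-12-31"),
                         n_planted_mechanisms = 24, n_heldout_prevents = 6,
                         seed = 1) {
  latent_model <- match.arg(latent_model)
  if (abs(sum(relation_profile) - 1) > 1e-9)
    stop("relation_profile proportions must sum to 1")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must lie in [0, 1)")
  if (n_heldout_prevents > n_planted_mechanisms)
    stop("n_heldout_prevents must not exceed n_planted_mechanisms")
  need <- c("Drug", "Disease", "Gene", "DS", "CIH")
  if (!all(need %in% names(n_entities)))
    stop("n_entities must name counts for: ", paste(need, collapse = ", "))
  structure(list(n_entities = n_entities[need],
                 relation_profile = relation_profile,
                 latent_model = latent_model, latent_dim = latent_dim,
                 n_triples = n_triples, noise_fraction = noise_fraction,
                 date_range = as.Date(date_range),
                 n_planted_mechanisms = n_planted_mechanisms,
                 n_heldout_prevents = n_heldout_prevents, seed = seed),
            class = "synth_config")
}

# head/tail type compatibility per relation; our construction, config-visible
# through this function.
synth_type_rules <- function() {
  all5 <- c("Drug", "Disease", "Gene", "DS", "CIH")
  list(
    COEXISTS_WITH = list(h = all5, t = all5),
    INTERACTS_WITH = list(h = c("Drug", "DS", "Gene"),
                          t = c("Drug", "DS", "Gene")),
    AFFECTS = list(h = c("Drug", "DS", "CIH", "Gene"),
                   t = c("Disease", "Gene")),
    TREATS = list(h = c("Drug", "DS", "CIH"), t = "Disease"),
    CAUSES = list(h = c("Gene", "Drug", "Disease"), t = "Disease"),
    ASSOCIATED_WITH = list(h = c("Gene", "Disease"), t = "Disease"),
    INHIBITS = list(h = c("Drug", "DS", "CIH", "Gene"), t = "Gene"),
    STIMULATES = list(h = c("Drug", "DS", "Gene"), t = "Gene"),
    DISRUPTS = list(h = c("Drug", "DS"), t = c("Gene", "Disease")),
    AUGMENTS = list(h = c("Drug", "DS"), t = c("Gene", "Disease")),
    PRODUCES = list(h = c("Gene", "Drug", "DS"), t = c("Drug", "Gene")),
    PREDISPOSES = list(h = c("Gene", "Drug", "Disease"), t = "Disease"),
    PREVENTS = list(h = c("Drug", "DS", "CIH"), t = "Disease"),
    COMPLICATES = list(h = "Disease", t = "Disease"),
    MANIFESTATION_OF = list(h = "Disease", t = "Disease"))
}

.latent_score <- function(model, E, R, h, r, t) {
  # plausibility: higher = better under the latent generator
  if (model == "TransE") {
    -sqrt(rowSums((E[h, , drop = FALSE] + R[r, , drop = FALSE] -
                     E[t, , drop = FALSE])^2))
  } else {
    rowSums(E[h, , drop = FALSE] * R[r, , drop = FALSE] *
              E[t, , drop = FALSE])
  }
}

#' Generate a synthetic predication corpus with planted structure
#'
#' Samples latent entity/relation vectors, emits the best-scoring
#' type-compatible triples per relation (respecting the configured relation
#' frequency profile), replaces `noise_fraction` of them with uniform random
#' typed triples, attaches uniformly distributed publication dates and
#' document ids (a triple may be mentioned by several documents), plants a
#' latent subpopulation of genuinely preventive interventions (clustered
#' around the latent scorer's ideal preventer for the target disease) with
#' two-hop mechanism paths `(npi, INHIBITS, gene)`, `(gene, CAUSES, target
#' disease)`, and withholds the direct `(npi, PREVENTS, disease)` closure
#' for the held-out subset.
#' Fully deterministic given the seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `predications` (the instance stream, shuffled),
#'   `meta` (entity metadata), and `ground_truth`: latent vectors, the planted
#'   mechanism table, the held-out PREVENTS triples, and the target disease.
#' @export
generate_kg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  ne <- cfg$n_entities
  types <- rep(names(ne), ne)
  prefix <- c(Drug = "C1", Disease = "C2", Gene = "C3", DS = "DC4",
              CIH = "C5")
  ids <- unlist(lapply(names(ne), function(ty)
    sprintf("%s%05d", prefix[ty], seq_len(ne[ty]))), use.names = FALSE)
  meta <- data.frame(concept_id = ids,
                     name = paste(tolower(types), ave(seq_along(types),
                                                     types, FUN = seq_along)),
                     semantic_type = c(Drug = "phsu", Disease = "dsyn",
                                       Gene = "gngm", DS = "phsu",
                                       CIH = "topp")[types],
                     semantic_group = c(Drug = "Chemicals & Drugs",
                                        Disease = "Disorders",
                                        Gene = "Genes & Molecular Sequences",
                                        DS = "Chemicals & Drugs",
                                        CIH = "Procedures")[types],
                     npi_class = ifelse(types == "DS", "DS",
                                        ifelse(types == "CIH", "CIH", "none")),
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  d <- cfg$latent_dim
  rels <- names(cfg$relation_profile)
  E <- matrix(stats::runif(length(ids) * d, -1, 1), ncol = d)
  R <- matrix(stats::runif(length(rels) * d, -0.3, 0.3), ncol = d)
  rownames(E) <- ids; rownames(R) <- rels
  rules <- synth_type_rules()
  target <- ids[types == "Disease"][1]
  gt <- list(latent_entities = E, latent_relations = R,
             latent_model = cfg$latent_model, target_disease = target)

  # planted interventions: a latent subpopulation of genuinely preventive
  # NPIs, clustered around the ideal preventer point of the latent scorer
  npi_ids <- ids[types %in% c("DS", "CIH")]
  n_plant <- min(cfg$n_planted_mechanisms, length(npi_ids))
  prev_r <- match("PREVENTS", rels)
  planted_npi <- sample(npi_ids, n_plant)
  if (n_plant > 0) {
    center <- if (cfg$latent_model == "TransE") {
      E[match(target, ids), ] - R[prev_r, ]
    } else {
      # DistMult: align with the sign pattern of r * t for a high product
      E[match(target, ids), ] * sign(R[prev_r, ])
    }
    E[match(planted_npi, ids), ] <-
      matrix(rep(center, each = n_plant), nrow = n_plant) +
      matrix(stats::rnorm(n_plant * d, 0, 0.1), nrow = n_plant)
    gt$latent_entities <- E
  }
  heldout_npi <- planted_npi[seq_len(min(cfg$n_heldout_prevents, n_plant))]
  genes <- ids[types == "Gene"]
  plant_gene <- sample(genes, n_plant, replace = length(genes) < n_plant)
  mech <- data.frame(npi = planted_npi, gene = plant_gene,
                     disease = rep(target, n_plant),
                     stringsAsFactors = FALSE)
  heldout <- data.frame(head = heldout_npi,
                        relation = rep("PREVENTS", length(heldout_npi)),
                        tail = rep(target, length(heldout_npi)),
                        stringsAsFactors = FALSE)

  # signal triples: per-relation top scoring type-compatible pairs
  n_signal <- round(cfg$n_triples * (1 - cfg$noise_fraction))
  counts <- round(cfg$relation_profile * n_signal)
  sample_pairs <- function(rel, m, top = TRUE) {
    if (m <= 0) return(NULL)
    rule <- rules[[rel]]
    hs <- which(types %in% rule$h); ts <- which(types %in% rule$t)
    if (!length(hs) || !length(ts))
      stop("type rules infeasible for ", rel, ": no entities of required type")
    pool <- max(5000, 80 * m)
    hp <- sample(hs, pool, replace = TRUE)
    tp <- sample(ts, pool, replace = TRUE)
    ok <- hp != tp
    hp <- hp[ok]; tp <- tp[ok]
    dup <- duplicated(paste(hp, tp))
    hp <- hp[!dup]; tp <- tp[!dup]
    m <- min(m, length(hp))
    pick <- if (top) {
      s <- .latent_score(cfg$latent_model, E, R, hp,
                         rep(match(rel, rels), length(hp)), tp)
      order(-s)[seq_len(m)]
    } else sample(length(hp), m)
    data.frame(head = ids[hp[pick]], relation = rel, tail = ids[tp[pick]],
               stringsAsFactors = FALSE)
  }
  signal <- do.call(rbind, lapply(rels, function(rl)
    sample_pairs(rl, counts[[rl]], top = TRUE)))
  n_noise <- cfg$n_triples - (if (is.null(signal)) 0 else nrow(signal))
  noise <- NULL
  if (n_noise > 0) {
    nrel <- sample(rels, n_noise, replace = TRUE, prob = cfg$relation_profile)
    noise <- do.call(rbind, lapply(rels, function(rl)
      sample_pairs(rl, sum(nrel == rl), top = FALSE)))
  }
  triples <- rbind(signal, noise)
  # planted mechanism edges and, for non-held-out interventions, the
  # preventive closure (training signal for the PREVENTS relation)
  if (n_plant > 0 && cfg$n_triples > 0) {
    closure_npi <- setdiff(planted_npi, heldout_npi)
    triples <- rbind(triples,
                     data.frame(head = mech$npi, relation = "INHIBITS",
                                tail = mech$gene, stringsAsFactors = FALSE),
                     data.frame(head = mech$gene, relation = "CAUSES",
                                tail = mech$disease, stringsAsFactors = FALSE),
                     if (length(closure_npi))
                       data.frame(head = closure_npi, relation = "PREVENTS",
                                  tail = target, stringsAsFactors = FALSE))
  }
  if (!is.null(triples) && nrow(triples)) {
    # held-out closures must be absent from the emitted graph
    hk <- kg_key(heldout$head, heldout$relation, heldout$tail)
    triples <- triples[!(kg_key(triples$head, triples$relation,
                                triples$tail) %in% hk), , drop = FALSE]
    triples <- triples[!duplicated(kg_key(triples$head, triples$relation,
                                          triples$tail)), , drop = FALSE]
  }
  gt$planted_mechanisms <- mech
  gt$heldout_prevents <- heldout
  if (is.null(triples) || nrow(triples) == 0) {
    preds <- predications(character(), character(), character(),
                          character(), as.Date(character()), character())
    return(list(predications = preds, meta = meta, ground_truth = gt))
  }
  # instance multiplicities and provenance
  mult <- 1L + stats::rpois(nrow(triples), 0.4)
  idx <- rep(seq_len(nrow(triples)), mult)
  n_inst <- length(idx)
  span <- as.integer(cfg$date_range[2] - cfg$date_range[1])
  dates <- cfg$date_range[1] + sample.int(span + 1L, n_inst, replace = TRUE) -
    1L
  preds <- predications(triples$head[idx], triples$relation[idx],
                        triples$tail[idx],
                        doc_id = sprintf("PMID%07d", sample.int(9999999,
                                                                n_inst)),
                        pub_date = dates,
                        sentence_ref = sprintf("s%d", seq_len(n_inst)))
  preds <- preds[sample.int(n_inst), , drop = FALSE]
  rownames(preds) <- NULL
  list(predications = preds, meta = meta, ground_truth = gt)
}

#' Emit a predication stream with a controlled three-way joint
#'
#' Generates `T` predication instances whose subject/predicate/object
#' presence indicators follow a specified 2x2x2 joint distribution, for
#' calibrating the G-squared statistic: under an independent joint its
#' p-values against the chi-squared(4 df) reference are uniform.
#'
#' @param joint 2x2x2 probability array, axes (subject, predicate, object),
#'   level 1 = the focal term present; must sum to 1.
#' @param T number of instances.
#' @param h,r,t focal subject/predicate/object labels.
#' @param seed optional RNG seed.
#' @return predication `data.frame`; the generating joint is attached as the
#'   `"joint"` attribute.
#' @export
emit_contingency_stream <- function(joint, T, h = "CFOCUS", r = "PFOCUS",
                                    t = "OFOCUS", seed = NULL) {
  joint <- array(as.numeric(joint), dim = c(2, 2, 2))
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-9)
    stop("joint must be a nonnegative 2x2x2 array summing to 1")
  if (!is.null(seed)) set.seed(seed)
  cell <- sample.int(8, T, replace = TRUE, prob = as.vector(joint))
  # cell index decomposes as i + 2(j-1) + 4(k-1) with i,j,k in {1,2}
  i <- (cell - 1) %% 2 + 1
  j <- ((cell - 1) %/% 2) %% 2 + 1
  k <- (cell - 1) %/% 4 + 1
  out <- predications(ifelse(i == 1, h, "COTHER"),
                      ifelse(j == 1, r, "POTHER"),
                      ifelse(k == 1, t, "OOTHER"),
                      doc_id = "SYN", pub_date = as.Date("2020-01-01"),
                      sentence_ref = "")
  attr(out, "joint") <- joint
  out
}

#' @rdname emit_contingency_stream
#' @param ps,pp,po marginal presence probabilities for the independent joint.
#' @export
independent_joint <- function(ps, pp, po) {
  outer(outer(c(ps, 1 - ps), c(pp, 1 - pp)), c(po, 1 - po))
}
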