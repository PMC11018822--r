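---
title: "Link prediction and literature-based discovery on predication graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link prediction and literature-based discovery on predication graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Biomedical text mining produces *predications*: subject–predicate–object
assertions such as `(myrtol, TREATS, bronchitis)`, each carried with the
document and publication date it was extracted from. Aggregated over millions
of abstracts these form a knowledge graph whose missing links are candidate
hypotheses — in the use case this package is built around, candidate
*non-pharmacological interventions* (dietary supplements, DS, and
complementary/integrative health practices, CIH) that might prevent a target
disease such as Alzheimer's disease. `kglbd` implements the full desk-scale
workflow:

1. **Graph construction and filtering** (`build_graph()`,
   `apply_rule_filters()`, `triple_g2()`, `combined_scores()`,
   `prune_to_budget()`, `triple_filter_hook()`),
2. **Link-prediction model fitting** (`fit_lp()` over TransE, RotatE,
   DistMult, ComplEx, R-GCN, CompGCN),
3. **Ranking evaluation** (`chronological_split()`, `evaluate_lp()` with
   filtered corruption; MR, MRR, Hits@k, ROC/PR),
4. **Discovery** (`score_candidates()`, `match_pattern()`,
   `mine_mechanisms()`), and
5. a **synthetic corpus generator** (`generate_kg()`) with planted structure
   so that the whole pipeline is testable without any external data.

# Graph construction and filtering

`build_graph()` deduplicates predication instances into directed typed
triples, keeping the instance count, the earliest publication date, and the
document of that earliest mention. Entity and relation vocabularies are
recorded in first-appearance order so that seeded model fits are
reproducible. Dietary-supplement concepts are marked by a letter `D`
prefixed to their concept identifier (`mark_ds_nodes()`); the operation is
idempotent and merges triples that the renaming makes identical.

Filtering mirrors the three preprocessing stages such corpora need:

* **Rule filters** remove generic concepts, concepts from uninformative
  semantic groups (defaults: "Activities & Behaviors", "Concepts & Ideas"),
  and predicates outside a fifteen-relation whitelist.
* **Specificity scoring** flags unspecific triples. For each triple we form
  the 2×2×2 contingency table of its subject/predicate/object presence over
  the instance stream and compute the log-likelihood-ratio statistic

  $$G^2 = 2 \sum_{ijk} n_{ijk}\,\log\frac{n_{ijk}}{m_{ijk}},
  \qquad m_{ijk} = \frac{n_{i\cdot\cdot}\, n_{\cdot j \cdot}\,
  n_{\cdot\cdot k}}{T^2},$$

  the likelihood-ratio test of mutual independence of the three axes
  (asymptotically $\chi^2$ with 4 df; cells with $n_{ijk}=0$ contribute 0).
  The expectation table uses the one-way marginals: that is the only reading
  under which $\sum m_{ijk} = T$ and the statistic is nonnegative and
  $\chi^2$-calibrated, properties the test suite verifies by simulation.
  A triple's combined score is the sum of three min–max-normalized
  components — head out-degree, tail in-degree, and $G^2$ — so a high score
  marks hub-connected, generically co-occurring triples;
  `prune_to_budget()` retains the lowest-scoring (most specific) triples
  with a deterministic tie-break. Which node's degrees feed the score is
  genuinely underdetermined in the literature; we default to the pair
  (head out, tail in) because the score is printed as a three-term sum, and
  expose `degree_mode = "max"` as the alternative.
* **The verification hook** (`triple_filter_hook()`) stands where a trained
  triple-verification classifier (scoring a triple against its source
  sentence) would plug in. Such a classifier needs the source sentences and
  trained weights, which are out of scope here, so the package exposes the
  boolean interface and defaults to keeping everything.

Degrees are computed on the rule-filtered graph (filtering first removes
whole concepts, so degrees afterwards reflect the graph the models will
see), and $G^2$ is computed per triple type, i.e. per (subject, predicate,
object), not per subject–object pair.

# The link-prediction models

A knowledge graph is a labeled directed multigraph $KG = (E, R, G)$,
$G \subseteq E \times R \times E$, with triples $\langle h, r, t\rangle$.
Four embedding scorers are implemented exactly:

| model | score | space | reading |
|---|---|---|---|
| TransE | $\|h + r - t\|_p$ | $\mathbb{R}^d$ | distance, lower = better |
| RotatE | $\|h \circ r - t\|$ | $\mathbb{C}^d$, $|r_i| = 1$ | distance |
| DistMult | $h^\top \mathrm{diag}(r)\, t$ | $\mathbb{R}^d$ | similarity |
| ComplEx | $\mathrm{Re}(h^\top \mathrm{diag}(r)\, \bar t)$ | $\mathbb{C}^d$ | similarity |

The uniform model API exposes *plausibility* = −distance for the
translational models so every fit ranks descending. DistMult is exactly
symmetric in $h$ and $t$; ComplEx breaks that symmetry through the
conjugated tail.

The graph-convolution encoders follow the standard propagation rules. R-GCN
updates node $i$ as

$$x_i^{(l+1)} = \sigma\Big(\sum_{r \in \mathcal{R}}
\sum_{j \in N_i^r} \tfrac{1}{c_{i,r}} W_r^{(l)} x_j^{(l)}
+ W_0^{(l)} x_i^{(l)}\Big),$$

with $c_{i,r} = |N_i^r|$ fixed (the standard choice; no extra parameters),
$\sigma = \mathrm{ReLU}$, encoder dropout 0.2, a DistMult decoder over the
encoded states, and an L2 penalty of 0.01 on the decoder. CompGCN
materializes inverse and self-loop edges with direction-specific weights
$W_O, W_I, W_S$, composes neighbor state and relation embedding with
$\phi \in \{\text{subtraction}, \text{multiplication},
\text{circular-correlation}\}$ (default circular correlation,
$\phi(a,b)_i = \sum_j a_j b_{(j+i) \bmod d}$, computed by FFT), projects
relation embeddings layer-wise through $W_{rel}$, and decodes with ConvE
(stacked 2-D reshape of head and relation, one convolution bank, ReLU,
linear projection, dot with the tail; dropout 0.3/0.3 in training mode
only). The outer activation is tanh. No basis decomposition of $W_r$ is
used — unnecessary at the scales this package targets, and an easy
extension point.

Both GCNs minimize the normalized cross-entropy

$$\mathcal{L} = -\frac{1}{(1+\omega)\,|\hat\varepsilon|}
\sum_{(h,r,t,y)\in\mathcal{T}} y \log l(s(h,r,t)) +
(1-y)\log(1 - l(s(h,r,t))),$$

with $l$ the logistic sigmoid, $\omega$ the negative ratio and
$|\hat\varepsilon|$ the positive edge count. The embedding models use a
margin ranking loss $\max(0, \gamma + s_{dist}(pos) - s_{dist}(neg))$
(TransE, RotatE) or a pointwise logistic loss with L2 regularization
(DistMult, ComplEx), mirroring the loss families of the reference
implementations of these models. Negatives corrupt the head or the tail
(never both) uniformly, rejecting corruptions present in the graph
("corruption with filtering"); the conventional training ratio is 1:20 and
is configurable (`neg_ratio`).

**Optimization.** All gradients are derived analytically and checked against
central finite differences in the test suite. Plain fixed-step SGD is
unusable for this loss geometry at desk scale — the (1+ω)|ε̂| normalization
makes per-parameter gradients tiny, and compensating with a large step turns
the decoder L2 penalty into aggressive weight decay that collapses the
R-GCN decoder. The package therefore uses the per-parameter–scaled
first-order methods these model families are normally trained with:
Adagrad for the embedding models and Adam for the graph convolutions.
Training is deterministic given `seed` (single-threaded base R).

# Evaluation

`chronological_split()` orders triples by first-attestation date (stable
tie-break by head, relation, tail) and slices 8:1:1 by count; the effective
cut dates are outputs. A date-driven mode accepts explicit cuts instead.
Split graphs retain the full vocabulary so embeddings cover test entities.

`rank_triple()` ranks a true triple against `n_negatives` filtered
corruptions of one side. Ties take the mean rank over tied orderings,
rounded half up — the neutral convention; optimistic ranking would inflate
every metric. From ranks, `metrics_from_ranks()` computes
$MR = \frac{1}{|T|}\sum rank(t)$, $MRR = \frac{1}{|T|}\sum 1/rank(t)$, and
$Hits@k = \frac{1}{|T|}\sum I[rank(t) \le k]$. `curves_from_scores()` sweeps
thresholds over the score union; its AUROC equals the normalized
Mann–Whitney U (ties count one half — verified against
`stats::wilcox.test`), and AUPR uses step interpolation.

Defaults that matter and are ours rather than canonical: the evaluation
corrupts 100 negatives per query (metrics depend on this batch size), and
ranks both sides by default, switchable to tail-only. For ground-truth-style
test sets with a fixed relation and tail — "does this intervention prevent
this disease?" — tail-side ranking is the informative direction: head-side
corruptions substitute other interventions whose preventive links are merely
unrecorded, which is precisely the discovery premise, so penalizing the
model for scoring them high would be wrong.

# Discovery

`score_candidates()` scores every intervention node of one class as the head
of `(npi, PREVENTS, disease)`, drops candidates whose triple already exists
(only novel links are hypotheses), and ranks the rest. The reported
`probability` column is a per-class min–max normalization of the
plausibility — order-preserving, top candidate = 1 — and is deliberately
labeled a normalized score rather than a calibrated probability; no
calibration is invented.

The candidate table compares **raw scores across heads**, which is a
stronger demand than per-query ranking. Pointwise logistic losses
(DistMult, ComplEx) are the right tool: they explicitly push unobserved
triples toward low scores, so never-linked entities score low. Margin-based
translational losses stop optimizing once the margin is met, and the R-GCN
decoder's L2 penalty compresses its score range; both are rank-calibrated
within a query but noisy across heads. The package's discovery workflow
therefore scores candidate tables with the pointwise-logistic semantic
matching model (DistMult by default) trained on the same graph, while
ranking-based model comparison (the previous section) is where the encoders
compete.

Closed discovery uses two-hop patterns with a negation clause. The DS
pattern constrains hop 1 to `INHIBITS | INTERACTS_WITH` and hop 2 to
`AFFECTS | CAUSES | PREDISPOSES | ASSOCIATED_WITH` (the `ASSOCIATED`
shorthand is read as the graph's `ASSOCIATED_WITH`), and requires that
`(intervention, PREVENTS, disease)` is *not* in the graph; the CIH pattern
leaves both hops unconstrained because most CIH concepts are procedures or
activities that carry no inhibition/interaction semantics. Hop 1 runs
intervention→intermediate and hop 2 intermediate→disease; inverse-direction
matches are not enumerated (switchable upstream by symmetrizing the graph).
`match_pattern()` is verified against exhaustive double-loop enumeration in
the tests, including negation cases.

# The synthetic corpus

`generate_kg()` emulates the data shape of a mined predication corpus:

* five entity types (defaults: 200 Drugs, 100 Diseases, 100 Genes, 60 DS,
  40 CIH; D-prefixed DS identifiers),
* the fifteen-relation vocabulary with the skewed frequency profile typical
  of such corpora (≈33% COEXISTS_WITH down to 0.2% MANIFESTATION_OF),
  enforced over a type-compatibility matrix of our construction
  (`synth_type_rules()`; e.g. PREVENTS/TREATS heads are Drugs/DS/CIH, tails
  Diseases),
* latent structure: entities and relations carry latent vectors; each
  relation's triples are the top-scoring type-valid pairs from a large
  sampled pool under a TransE (or DistMult) latent scorer, so a link
  predictor has geometry to recover; 10% of triples are replaced by uniform
  random typed noise by default,
* provenance: per-triple instance multiplicities, document ids, and
  publication dates uniform over 2012–2022,
* **planted discovery signal**: a subpopulation of interventions (default
  24) gets latent vectors clustered (σ = 0.1) around the latent "ideal
  preventer" of one target disease, plus a two-hop mechanism
  `(npi, INHIBITS, gene)`, `(gene, CAUSES, disease)`. A subset (default 6)
  has its direct `(npi, PREVENTS, disease)` closure withheld from the
  emitted stream — these held-out closures are the recovery targets. The
  non-held-out closures are emitted, giving the models training signal for
  the preventive relation. The held-out count is kept below the per-class
  top-decile capacity of the candidate table, otherwise top-decile recovery
  would be arithmetically impossible.

Everything is seeded and byte-reproducible. `emit_contingency_stream()`
generates predication streams from a specified 2×2×2 joint for calibrating
the $G^2$ statistic.

**What passing tests do and do not show.** The generator produces clean
latent geometry, uniform dates, and noiseless extraction; real predication
corpora carry extraction errors (the motivation for the verification hook),
citation-driven date clustering, and hub structure far heavier than the
planted graphs. Recovery rates on planted graphs demonstrate that the
machinery is correct and that the pipeline can surface a genuine signal at
this scale — not that comparable rates would be achieved on a real corpus.

# Problem sizes and numerical choices

The default study conditions — 500 entities, 5,000 triples, embedding
dimension 64, TransE 60 epochs (Adagrad, lr 0.1, margin 2, ω = 5), R-GCN
one layer, 150 epochs (Adam, lr 0.05, ω = 10), DistMult 60 epochs (lr 0.25,
ω = 5), 100 evaluation negatives per query — fit one CPU core in about a
minute for the full pipeline and were frozen from pilot runs on seeds
disjoint from none in particular (training is seeded per run). Stability
observed across eight pilot seeds: TransE held-out tail-side Hits@10 = 1.0
on all; R-GCN ≥ 0.83 on all.

Numerical conventions collected in one place: $0\log 0 = 0$ in $G^2$;
sigmoid outputs clamped to $[10^{-12}, 1-10^{-12}]$ in the cross-entropy;
min–max normalization maps a constant component to 0 for every triple;
pruning and candidate tables break ties lexicographically; RotatE relation
embeddings are stored as phases so unit modulus is exact by construction;
Xavier-uniform initialization everywhere, RotatE phases uniform on
$[0, 2\pi)$; dropout exists only in training mode, so every reported score
is deterministic.

# Known limitations

* Full-graph GCN training only; no neighbor sampling, so graphs must fit in
  memory (fine up to ~10⁵ triples in this implementation).
* No self-adversarial negative weighting for RotatE; no automated
  hyperparameter search (grids are run by the user over configs).
* The mapping from scores to the reported `probability` column is a
  normalization, not a calibration.
* CompGCN relation embeddings are updated layer-wise per the printed update;
  sharing them across layers is a plausible alternative reading that is not
  implemented.
* Publication dates are required on every triple; corpora lacking them
  cannot use time slicing (fixtures must supply dates).
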