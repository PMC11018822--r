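Package: kglbd
Title: Literature-Based Discovery on Biomedical Knowledge Graphs via Link Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for literature-based discovery of candidate interventions
    from a knowledge graph of semantic predications mined from biomedical
    text. Builds and filters predication knowledge graphs (rule filters,
    degree statistics, G-squared specificity scoring, budgeted pruning),
    fits six link-prediction models (TransE, RotatE, DistMult, ComplEx
    embeddings; R-GCN and CompGCN relational graph convolutions with
    DistMult and ConvE decoders) through a single fitting front-end,
    evaluates them with time-sliced splits and filtered-corruption ranking
    (MR, MRR, Hits at k, ROC and precision-recall curves), ranks candidate
    non-pharmacological interventions against a target disease, and mines
    two-hop mechanistic path hypotheses with closed-discovery patterns.
    Includes a seeded synthetic knowledge-graph generator with planted
    latent structure and planted mechanism paths for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
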