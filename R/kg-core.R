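#' @importFrom stats runif rnorm rpois pchisq ks.test setNames plogis mvfft fft
#' @importFrom utils read.delim write.table head
NULL

PRED_COLS <- c("subject_id", "predicate", "object_id", "doc_id", "pub_date",
               "sentence_ref")
META_COLS <- c("concept_id", "name", "semantic_type", "semantic_group",
               "npi_class")

kg_key <- function(h, r, t) paste(h, r, t, sep = "\r")

#' Construct a predication table
#'
#' A predication is one subject--predicate--object assertion extracted from a
#' sentence of a publication, carried with its provenance (source document and
#' publication date). Predicates are uppercased and trimmed on construction;
#' concept identifiers are taken verbatim.
#'
#' @param subject_id,predicate,object_id character vectors of equal length.
#' @param doc_id source document identifiers.
#' @param pub_date publication dates (`Date` or ISO-8601 strings).
#' @param sentence_ref optional opaque sentence references.
#' @return a `data.frame` with one row per predication instance.
#' @export
predications <- function(subject_id, predicate, object_id, doc_id,
                         pub_date, sentence_ref = "") {
  if (any(!nzchar(subject_id)) || any(!nzchar(object_id)))
    stop("subject_id and object_id must be non-empty")
  pub_date <- as.Date(pub_date)
  if (anyNA(pub_date)) stop("unparseable pub_date")
  data.frame(subject_id = as.character(subject_id),
             predicate = toupper(trimws(predicate)),
             object_id = as.character(object_id),
             doc_id = as.character(doc_id),
             pub_date = pub_date,
             sentence_ref = as.character(sentence_ref),
             stringsAsFactors = FALSE)
}

#' Read a predication table from a delimited file
#'
#' Expects a header row with columns `subject_id predicate object_id doc_id
#' pub_date sentence_ref`. In strict mode (default) any malformed row (empty
#' subject/object, unparseable date) aborts the read with an error naming the
#' offending line numbers; in lenient mode malformed rows are dropped and
#' their count is reported via a message and the `"n_dropped"` attribute.
#'
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @param date_format date parsing format (default ISO-8601 `%Y-%m-%d`).
#' @param strict abort on malformed rows (default `TRUE`).
#' @return predication `data.frame` in file order.
#' @export
read_predications <- function(path, delim = "\t", date_format = "%Y-%m-%d",
                              strict = TRUE) {
  if (!file.exists(path)) stop("cannot read predication file: ", path)
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(PRED_COLS[1:5], names(raw))
  if (length(missing))
    stop("predication file lacks columns: ", paste(missing, collapse = ", "))
  if (!"sentence_ref" %in% names(raw)) raw$sentence_ref <- ""
  dates <- as.Date(raw$pub_date, format = date_format)
  bad <- which(!nzchar(raw$subject_id) | !nzchar(raw$object_id) | is.na(dates))
  if (length(bad)) {
    # +1 for the header line
    lines <- bad + 1L
    if (strict)
      stop("malformed predication rows at line(s): ",
           paste(utils::head(lines, 20), collapse = ", "))
    message(length(bad), " malformed predication row(s) dropped")
    raw <- raw[-bad, , drop = FALSE]
    dates <- dates[-bad]
  }
  out <- predications(raw$subject_id, raw$predicate, raw$object_id,
                      raw$doc_id, dates, raw$sentence_ref)
  attr(out, "n_dropped") <- if (exists("bad") && !strict) length(bad) else 0L
  rownames(out) <- NULL
  out
}

#' Write a predication table
#' @param preds predication `data.frame`.
#' @param path output path (TSV with header).
#' @export
write_predications <- function(preds, path) {
  out <- preds[, PRED_COLS]
  out$pub_date <- format(as.Date(out$pub_date), "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write entity metadata tables
#'
#' Entity metadata associates a concept identifier with a display name, a
#' semantic type code, a semantic group label, and a non-pharmacological
#' intervention class (`DS`, `CIH`, or `none`).
#'
#' @param path TSV path with header `concept_id name semantic_type
#'   semantic_group npi_class`.
#' @return metadata `data.frame`.
#' @export
read_entity_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing <- setdiff(META_COLS, names(meta))
  if (length(missing))
    stop("metadata file lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$concept_id))
    stop("duplicate concept_id in metadata table")
  meta[, META_COLS]
}

#' @rdname read_entity_meta
#' @param meta metadata `data.frame`.
#' @export
write_entity_meta <- function(meta, path) {
  utils::write.table(meta[, META_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.default_meta <- function(ids) {
  data.frame(concept_id = ids, name = ids, semantic_type = "",
             semantic_group = "",
             npi_class = ifelse(grepl("^DC", ids), "DS", "none"),
             stringsAsFactors = FALSE)
}

# Rebuild the fast-membership hash and integer-id adjacency for a graph.
.kg_index <- function(kg) {
  tr <- kg$triples
  kg$.keys <- kg_key(tr$head, tr$relation, tr$tail)
  kg$index <- new.env(hash = TRUE, parent = emptyenv(),
                      size = max(1L, nrow(tr)))
  for (k in kg$.keys) assign(k, TRUE, envir = kg$index)
  kg$.h_id <- match(tr$head, kg$entities$concept_id)
  kg$.r_id <- match(tr$relation, kg$relations)
  kg$.t_id <- match(tr$tail, kg$entities$concept_id)
  kg
}

#' Build a knowledge graph from predications
#'
#' Deduplicates predication instances into a set of directed, typed triples
#' `(head, relation, tail)`, keeping the instance count, the earliest
#' publication date and the document id of that earliest mention per triple.
#' Entity and relation vocabularies are recorded in first-appearance order
#' (scanning subject then object, row by row) so downstream embeddings are
#' reproducible.
#'
#' @param preds predication `data.frame` (see [predications()]).
#' @param meta optional entity metadata table; entities without metadata get
#'   defaults (name = id, `npi_class` `DS` for D-prefixed ids, else `none`).
#' @return an object of class `kgraph` with fields `entities`, `relations`,
#'   `triples` (head, relation, tail, count, first_date, first_doc) and a
#'   fast membership index.
#' @export
build_graph <- function(preds, meta = NULL) {
  if (nrow(preds) == 0) {
    kg <- structure(list(entities = .default_meta(character()),
                         relations = character(),
                         triples = data.frame(head = character(),
                                              relation = character(),
                                              tail = character(),
                                              count = integer(),
                                              first_date = as.Date(character()),
                                              first_doc = character(),
                                              stringsAsFactors = FALSE)),
                    class = "kgraph")
    return(.kg_index(kg))
  }
  preds$predicate <- toupper(trimws(preds$predicate))
  key <- kg_key(preds$subject_id, preds$predicate, preds$object_id)
  first <- !duplicated(key)
  ord <- preds[first, c("subject_id", "predicate", "object_id")]
  count <- as.integer(table(factor(key, levels = key[first])))
  dates <- as.Date(preds$pub_date)
  grp <- match(key, key[first])
  o <- order(grp, dates, method = "radix")
  earliest_row <- o[!duplicated(grp[o])]
  triples <- data.frame(head = ord$subject_id, relation = ord$predicate,
                        tail = ord$object_id, count = count,
                        first_date = dates[earliest_row],
                        first_doc = preds$doc_id[earliest_row],
                        stringsAsFactors = FALSE)
  ids <- unique(as.vector(t(as.matrix(preds[, c("subject_id", "object_id")]))))
  ents <- .default_meta(ids)
  if (!is.null(meta)) {
    m <- match(ids, meta$concept_id)
    hit <- !is.na(m)
    ents[hit, ] <- meta[m[hit], META_COLS]
  }
  kg <- structure(list(entities = ents,
                       relations = unique(preds$predicate),
                       triples = triples),
                  class = "kgraph")
  .kg_index(kg)
}

#' @export
print.kgraph <- function(x, ...) {
  cat(sprintf("knowledge graph: %d entities, %d relations, %d triples\n",
              nrow(x$entities), length(x$relations), nrow(x$triples)))
  npi <- table(x$entities$npi_class)
  if (any(names(npi) != "none"))
    cat("  NPI nodes:", paste(sprintf("%s=%d", names(npi), npi),
                              collapse = ", "), "\n")
  if (nrow(x$triples)) {
    cat("  dates:", format(min(x$triples$first_date)), "..",
        format(max(x$triples$first_date)), "\n")
  }
  invisible(x)
}

#' Exact triple membership test
#'
#' Vectorized over `h`, `r`, `t`; hash-backed, O(1) expected per query. Used
#' by filtered corruption sampling and by the negation (ANDNOT) clause of
#' discovery patterns.
#'
#' @param kg a `kgraph`.
#' @param h,r,t head ids, relation labels, tail ids.
#' @return logical vector.
#' @export
contains_triple <- function(kg, h, r, t) {
  keys <- kg_key(h, r, t)
  vapply(keys, exists, logical(1), envir = kg$index, inherits = FALSE,
         USE.NAMES = FALSE)
}

# Subset a graph to triple rows `keep` (logical or integer index).
# shrink_vocab drops entities no longer touched (filtering semantics);
# keep_vocab = TRUE retains the full vocabulary (splitting semantics).
kg_subset <- function(kg, keep, shrink_vocab = TRUE) {
  tr <- kg$triples[keep, , drop = FALSE]
  rownames(tr) <- NULL
  kg$triples <- tr
  if (shrink_vocab) {
    touched <- kg$entities$concept_id %in% c(tr$head, tr$tail)
    kg$entities <- kg$entities[touched, , drop = FALSE]
    rownames(kg$entities) <- NULL
  }
  .kg_index(kg)
}

#' Mark dietary-supplement nodes with the D-prefix
#'
#' Renames every occurrence of a supplied concept id `x` to `Dx`, following
#' the convention that supplement concepts carry a letter D before their CUI
#' (for example `C0633482`, myrtol, becomes `DC0633482`). The operation is
#' idempotent; triples touching renamed nodes merge with pre-existing
#' D-prefixed triples (counts summed, earliest date kept). Metadata
#' `npi_class` is set to `DS` for renamed nodes.
#'
#' @param kg a `kgraph`.
#' @param ds_ids concept ids in prefix-free form.
#' @return the renamed `kgraph`.
#' @export
mark_ds_nodes <- function(kg, ds_ids) {
  ds_ids <- setdiff(ds_ids, grep("^D", ds_ids, value = TRUE))
  ids <- kg$entities$concept_id
  hit <- ids %in% ds_ids
  if (!any(hit)) {
    pre <- ids %in% paste0("D", ds_ids)
    kg$entities$npi_class[pre] <- "DS"
    return(kg)
  }
  new_ids <- ifelse(hit, paste0("D", ids), ids)
  # collision check: both C... and DC... present with conflicting metadata
  dup <- new_ids[duplicated(new_ids)]
  for (d in unique(dup)) {
    rows <- kg$entities[new_ids == d, c("name", "semantic_type",
                                        "semantic_group")]
    rows$name[rows$name %in% c(d, substring(d, 2))] <- ""  # default names ok
    rows <- unique(rows[nzchar(rows$name) | nzchar(rows$semantic_type) |
                          nzchar(rows$semantic_group), , drop = FALSE])
    if (nrow(rows) > 1)
      stop("D-prefix collision with conflicting metadata for: ", d)
  }
  map <- stats::setNames(new_ids, ids)
  tr <- kg$triples
  tr$head <- unname(map[tr$head])
  tr$tail <- unname(map[tr$tail])
  # merge duplicates created by renaming
  key <- kg_key(tr$head, tr$relation, tr$tail)
  if (anyDuplicated(key)) {
    grp <- match(key, key[!duplicated(key)])
    keep <- !duplicated(key)
    agg_count <- as.integer(rowsum(tr$count, grp))
    o <- order(grp, tr$first_date, method = "radix")
    first_rows <- o[!duplicated(grp[o])]
    merged <- tr[keep, , drop = FALSE]
    merged$count <- agg_count
    merged$first_date <- tr$first_date[first_rows]
    merged$first_doc <- tr$first_doc[first_rows]
    tr <- merged
    rownames(tr) <- NULL
  }
  ents <- kg$entities
  default_name <- ents$name == ents$concept_id
  ents$concept_id <- new_ids
  ents$npi_class[hit] <- "DS"
  ents$name[default_name] <- new_ids[default_name]
  keep_ent <- !duplicated(ents$concept_id)
  merged_ents <- ents[keep_ent, , drop = FALSE]
  # prefer non-default metadata from either copy
  for (d in unique(ents$concept_id[duplicated(ents$concept_id)])) {
    rows <- ents[ents$concept_id == d, , drop = FALSE]
    pick <- rows[which.max(nzchar(rows$semantic_type) +
                             nzchar(rows$semantic_group)), , drop = FALSE]
    pick$npi_class <- "DS"
    merged_ents[merged_ents$concept_id == d, ] <- pick
  }
  rownames(merged_ents) <- NULL
  kg$entities <- merged_ents
  kg$triples <- tr
  .kg_index(kg)
}

#' Serialize / load a knowledge graph
#'
#' The on-disk form is a directory holding `entities.tsv`, `relations.tsv`
#' and `triples.tsv` (head, relation, tail, count, first_date, first_doc),
#' preserving vocabulary order.
#'
#' @param kg a `kgraph`.
#' @param dir directory path (created if absent).
#' @export
write_graph <- function(kg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_entity_meta(kg$entities, file.path(dir, "entities.tsv"))
  utils::write.table(data.frame(relation = kg$relations),
                     file.path(dir, "relations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- kg$triples
  tr$first_date <- format(tr$first_date, "%Y-%m-%d")
  utils::write.table(tr, file.path(dir, "triples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir) {
  ents <- read_entity_meta(file.path(dir, "entities.tsv"))
  rel <- utils::read.delim(file.path(dir, "relations.tsv"),
                           stringsAsFactors = FALSE)$relation
  tr <- utils::read.delim(file.path(dir, "triples.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(head = "character",
                                         relation = "character",
                                         tail = "character"))
  tr$first_date <- as.Date(tr$first_date)
  if (is.null(tr$first_doc)) tr$first_doc <- ""
  kg <- structure(list(entities = ents, relations = as.character(rel),
                       triples = tr), class = "kgraph")
  .kg_index(kg)
}

#' Per-relation adjacency index
#'
#' Rebuilds out/in neighbor indices from the triple set: for each relation, a
#' list mapping entity index to the integer indices of its neighbors. Used by
#' graph-convolution encoders and pattern matching, and by tests to verify
#' index consistency.
#'
#' @param kg a `kgraph`.
#' @return list with `out[[r]][[i]]` = tail indices of triples `(i, r, .)`
#'   and `in_[[r]][[i]]` = head indices of triples `(., r, i)`.
#' @export
kg_adjacency <- function(kg) {
  n <- nrow(kg$entities)
  out <- in_ <- vector("list", length(kg$relations))
  for (r in seq_along(kg$relations)) {
    sel <- kg$.r_id == r
    out[[r]] <- split(kg$.t_id[sel], factor(kg$.h_id[sel], levels = seq_len(n)))
    in_[[r]] <- split(kg$.h_id[sel], factor(kg$.t_id[sel], levels = seq_len(n)))
  }
  names(out) <- names(in_) <- kg$relations
  list(out = out, in_ = in_)
}
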