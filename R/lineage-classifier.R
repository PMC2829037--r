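# Staged homology classification of a focal proteome:
#   stage 1: any significant hit outside the clade        -> EC
#   stage 2: else any hit in within-clade transcript dbs  -> CLADE_SPECIFIC
#            else                                         -> SPECIES_SPECIFIC
#   stage 3: knowledgebase reassignment with an audit trail of decisions.
# The threshold is strict (E < cutoff) at every stage.

LABELS <- c("EC", "CLADE_SPECIFIC", "SPECIES_SPECIFIC")

query_ids_of <- function(proteome) {
  if (is.character(proteome) && is.null(names(proteome))) proteome
  else names(proteome)
}

collect_hits <- function(proteome, dbs, scheme, e_cutoff) {
  out <- lapply(dbs, function(db) {
    h <- if (db$type == "nt")
      search_protein_vs_nucleotide(proteome, db, scheme, e_cutoff)
    else
      search_protein_vs_protein(proteome, db, scheme, e_cutoff)
    if (nrow(h)) h$db_name <- db$name else h$db_name <- character(0)
    h
  })
  do.call(rbind, out)
}

#' Stage 1: classify against outside-clade databases
#'
#' A gene is Evolutionarily Conserved (EC) iff it has at least one hit with
#' `E < e_cutoff` in ANY outside-clade database (genomic or transcript); the
#' rest form the remainder passed to stage 2. The partition is exhaustive and
#' disjoint.
#'
#' @param proteome [Biostrings::AAStringSet] of representative proteins named
#'   by gene id (or a character vector of gene ids when `hits` is supplied).
#' @param dbs List of [sequence_database()] objects, all tagged
#'   `outside_clade_genomic` or `outside_clade_transcript`.
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff Significance threshold (strict `<`).
#' @param hits Optional precomputed hit data frame (external search output);
#'   when given, `dbs` may be `NULL`.
#' @return List with `ec` and `remainder` gene id vectors and the `hits`
#'   table.
#' @export
classify_outside_clade <- function(proteome, dbs, scheme = scoring_scheme(),
                                   e_cutoff = 1e-5, hits = NULL) {
  if (is.null(hits)) {
    groups <- vapply(dbs, `[[`, "", "taxon_group")
    if (!all(groups %in% c("outside_clade_genomic", "outside_clade_transcript")))
      stopf("configuration error: stage 1 requires outside-clade databases, got: %s",
            paste(unique(groups), collapse = ", "))
    hits <- collect_hits(proteome, dbs, scheme, e_cutoff)
  }
  ids <- query_ids_of(proteome)
  sig <- hits[hits$evalue < e_cutoff, , drop = FALSE]
  ec <- intersect(ids, unique(sig$query_id))
  list(ec = ec, remainder = setdiff(ids, ec), hits = sig)
}

#' Stage 2: classify the remainder against within-clade transcript databases
#'
#' A stage-1 remainder gene with a significant hit in any clade transcript
#' database is CLADE_SPECIFIC; otherwise it is SPECIES_SPECIFIC.
#'
#' @param remainder [Biostrings::AAStringSet] (or id vector with `hits`) of
#'   exactly the stage-1 remainder genes.
#' @param dbs List of [sequence_database()] objects tagged `clade_transcript`.
#' @param stage1_ec Optional stage-1 EC id vector; supplying a gene from it
#'   in `remainder` is a pipeline-order violation and errors.
#' @inheritParams classify_outside_clade
#' @return List with `clade_specific`, `species_specific`, and `hits`.
#' @export
classify_within_clade <- function(remainder, dbs, scheme = scoring_scheme(),
                                  e_cutoff = 1e-5, hits = NULL,
                                  stage1_ec = NULL) {
  ids <- query_ids_of(remainder)
  if (!is.null(stage1_ec) && length(intersect(ids, stage1_ec)))
    stopf("pipeline order violated: gene(s) %s were classified EC at stage 1",
          paste(utils::head(intersect(ids, stage1_ec), 3), collapse = ", "))
  if (is.null(hits)) {
    groups <- vapply(dbs, `[[`, "", "taxon_group")
    if (!all(groups == "clade_transcript"))
      stopf("configuration error: stage 2 requires clade_transcript databases")
    hits <- collect_hits(remainder, dbs, scheme, e_cutoff)
  }
  sig <- hits[hits$evalue < e_cutoff, , drop = FALSE]
  clade <- intersect(ids, unique(sig$query_id))
  list(clade_specific = clade, species_specific = setdiff(ids, clade),
       hits = sig)
}

best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$evalue), , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Stage 3: knowledgebase reassignment
#'
#' Candidate lineage-specific genes are searched against a protein
#' knowledgebase whose records carry taxonomy labels. A hit to a record from
#' outside the clade moves the gene to EC; a species-specific gene whose
#' hits are only to clade records moves to CLADE_SPECIFIC. Accepted moves
#' only broaden conservation. In `auto` mode every candidate move is
#' accepted; in review mode only decisions with `accepted = TRUE` are
#' applied. The full audit trail is returned either way, so the final sets
#' are reproducible from hits + decisions alone.
#'
#' @param clade_ids,species_ids Gene ids of the current clade-specific and
#'   species-specific sets.
#' @param kb A `knowledgebase`-tagged protein [sequence_database()] with a
#'   `taxonomy` mapping (record id -> taxon label); `NULL` when `hits` is
#'   supplied with a `subject_in_clade` column.
#' @param clade_taxa Character vector of taxon labels counted as clade
#'   members.
#' @param proteome [Biostrings::AAStringSet] covering at least the candidate
#'   genes (only needed when hits are computed here).
#' @param review `NULL`/`"auto"` to accept all candidate moves, or a data
#'   frame with columns `gene_id`, `to_label`, `accepted` reviewing them; a
#'   decision naming a gene without a qualifying hit errors.
#' @inheritParams classify_outside_clade
#' @return List with `ec_additions`, `clade_specific`, `species_specific`,
#'   and the `decisions` data frame.
#' @export
knowledgebase_reassign <- function(clade_ids, species_ids, kb = NULL,
                                   clade_taxa = character(0),
                                   proteome = NULL,
                                   scheme = scoring_scheme(),
                                   e_cutoff = 1e-5, review = NULL,
                                   hits = NULL) {
  candidates <- c(clade_ids, species_ids)
  if (is.null(hits)) {
    if (is.null(kb) || kb$taxon_group != "knowledgebase")
      stopf("configuration error: stage 3 requires a knowledgebase database")
    if (is.null(proteome)) stopf("proteome required to search the knowledgebase")
    qset <- proteome[intersect(names(proteome), candidates)]
    hits <- search_protein_vs_protein(qset, kb, scheme, e_cutoff)
  }
  hits <- hits[hits$evalue < e_cutoff & hits$query_id %in% candidates, ,
               drop = FALSE]
  if (nrow(hits) && !"subject_in_clade" %in% names(hits)) {
    if (is.null(kb$taxonomy))
      stopf("knowledgebase has no taxonomy labels")
    hits$subject_in_clade <- unname(kb$taxonomy[hits$subject_id] %in% clade_taxa)
  }

  decisions <- data.frame(gene_id = character(0), from_label = character(0),
                          to_label = character(0), subject_id = character(0),
                          evalue = numeric(0), accepted = logical(0),
                          rationale = character(0), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    nonclade <- best_hit_per_query(hits[!hits$subject_in_clade, , drop = FALSE])
    cladehit <- best_hit_per_query(hits[hits$subject_in_clade, , drop = FALSE])
    add <- function(h, from, to, why) {
      if (!nrow(h)) return()
      decisions <<- rbind(decisions, data.frame(
        gene_id = h$query_id, from_label = from, to_label = to,
        subject_id = h$subject_id, evalue = h$evalue, accepted = TRUE,
        rationale = why, stringsAsFactors = FALSE))
    }
    add(nonclade[nonclade$query_id %in% clade_ids, , drop = FALSE],
        "CLADE_SPECIFIC", "EC", "hit to non-clade knowledgebase entry")
    add(nonclade[nonclade$query_id %in% species_ids, , drop = FALSE],
        "SPECIES_SPECIFIC", "EC", "hit to non-clade knowledgebase entry")
    sp_clade <- cladehit[cladehit$query_id %in% species_ids &
                           !cladehit$query_id %in% nonclade$query_id, ,
                         drop = FALSE]
    add(sp_clade, "SPECIES_SPECIFIC", "CLADE_SPECIFIC",
        "hit to clade knowledgebase entry")
  }

  if (!is.null(review) && !identical(review, "auto")) {
    review <- as.data.frame(review)
    # decisions already applied in a previous run reference genes that have
    # left the input sets or already carry the target label; ignoring them
    # makes re-application a no-op
    review <- review[review$gene_id %in% candidates &
                       !(review$to_label == "CLADE_SPECIFIC" &
                           review$gene_id %in% clade_ids), , drop = FALSE]
    key <- paste(decisions$gene_id, decisions$to_label)
    rkey <- paste(review$gene_id, review$to_label)
    bad <- setdiff(rkey, key)
    if (length(bad))
      stopf("review decision without a qualifying hit: %s",
            paste(utils::head(bad, 3), collapse = "; "))
    decisions$accepted <- key %in% rkey[review$accepted]
  }

  applied <- decisions[decisions$accepted, , drop = FALSE]
  to_ec <- applied$gene_id[applied$to_label == "EC"]
  sp_to_clade <- applied$gene_id[applied$to_label == "CLADE_SPECIFIC"]
  list(ec_additions = to_ec,
       clade_specific = union(setdiff(clade_ids, to_ec), sp_to_clade),
       species_specific = setdiff(species_ids, c(to_ec, sp_to_clade)),
       decisions = decisions)
}

#' Run the full three-stage lineage classification pipeline
#'
#' @param proteome [Biostrings::AAStringSet] of representative proteins named
#'   by gene id.
#' @param outside_dbs,clade_dbs Lists of [sequence_database()] objects for
#'   stages 1 and 2.
#' @param kb Knowledgebase [sequence_database()] for stage 3 (`NULL` skips
#'   stage 3).
#' @inheritParams knowledgebase_reassign
#' @return A `lineage_classification` object: `results` data frame
#'   (gene_id, label, decided_at_stage, best-hit columns), `decisions`,
#'   per-stage hit tables, and `counts`.
#' @export
run_lineage_pipeline <- function(proteome, outside_dbs, clade_dbs, kb = NULL,
                                 clade_taxa = character(0),
                                 scheme = scoring_scheme(), e_cutoff = 1e-5,
                                 review = NULL) {
  s1 <- classify_outside_clade(proteome, outside_dbs, scheme, e_cutoff)
  s2 <- classify_within_clade(proteome[s1$remainder], clade_dbs, scheme,
                              e_cutoff, stage1_ec = s1$ec)
  if (!is.null(kb)) {
    s3 <- knowledgebase_reassign(s2$clade_specific, s2$species_specific, kb,
                                 clade_taxa, proteome, scheme, e_cutoff, review)
  } else {
    s3 <- list(ec_additions = character(0),
               clade_specific = s2$clade_specific,
               species_specific = s2$species_specific,
               decisions = NULL)
  }
  ids <- names(proteome)
  label <- stats::setNames(rep("SPECIES_SPECIFIC", length(ids)), ids)
  label[s3$clade_specific] <- "CLADE_SPECIFIC"
  label[c(s1$ec, s3$ec_additions)] <- "EC"
  stage <- stats::setNames(rep(2L, length(ids)), ids)
  stage[s1$ec] <- 1L
  if (!is.null(s3$decisions) && nrow(s3$decisions)) {
    acc <- s3$decisions[s3$decisions$accepted, , drop = FALSE]
    stage[acc$gene_id] <- 3L
  }
  best <- best_hit_per_query(rbind(s1$hits[, hit_columns], s2$hits[, hit_columns]))
  bix <- match(ids, best$query_id)
  results <- data.frame(
    gene_id = ids, label = unname(label[ids]),
    decided_at_stage = unname(stage[ids]),
    best_hit_subject = best$subject_id[bix],
    best_hit_evalue = best$evalue[bix],
    stringsAsFactors = FALSE)
  counts <- table(factor(results$label, levels = LABELS))
  structure(list(results = results, decisions = s3$decisions,
                 stage1_hits = s1$hits, stage2_hits = s2$hits,
                 counts = counts),
            class = "lineage_classification")
}

#' @export
print.lineage_classification <- function(x, ...) {
  cat("lineage_classification\n")
  print(x$counts)
  invisible(x)
}

#' Summarize a classification with functional annotation cross-tabs
#'
#' Per-label gene counts and percentages of the grand total, plus a
#' cross-tabulation by known-function and transcript-support flags with
#' percentages of each label's total. Percentages are rounded half-up to one
#' decimal.
#'
#' @param results Data frame with `gene_id` and `label` (e.g.
#'   `run_lineage_pipeline(...)$results`), or a `lineage_classification`.
#' @param attributes Data frame with `gene_id`, `known_function`,
#'   `has_transcript_support` covering all genes.
#' @return A `classification_summary`: `totals` (label, n, pct_of_total) and
#'   `crosstab` (label, category, subcategory, n, pct_of_label).
#' @export
summarize_classification <- function(results, attributes) {
  if (inherits(results, "lineage_classification")) results <- results$results
  ix <- match(results$gene_id, attributes$gene_id)
  if (anyNA(ix)) stopf("attributes missing for %d gene(s)", sum(is.na(ix)))
  known <- attributes$known_function[ix]
  sup <- attributes$has_transcript_support[ix]
  grand <- nrow(results)
  totals <- do.call(rbind, lapply(LABELS, function(lb) {
    n <- sum(results$label == lb)
    data.frame(label = lb, n = n, pct_of_total = percent1(n, grand),
               stringsAsFactors = FALSE)
  }))
  cross <- do.call(rbind, lapply(LABELS, function(lb) {
    in_lb <- results$label == lb
    tot <- sum(in_lb)
    cell <- function(category, subcategory, mask) {
      n <- sum(mask & in_lb)
      data.frame(label = lb, category = category, subcategory = subcategory,
                 n = n,
                 pct_of_label = if (tot) percent1(n, tot) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    rbind(cell("no_known_function", "all", !known),
          cell("no_known_function", "transcript_support", !known & sup),
          cell("no_known_function", "no_transcript_support", !known & !sup),
          cell("known_function", "all", known),
          cell("known_function", "transcript_support", known & sup),
          cell("known_function", "no_transcript_support", known & !sup))
  }))
  structure(list(totals = totals, crosstab = cross, n_total = grand),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("classification_summary (%d genes)\n", x$n_total))
  print(x$totals, row.names = FALSE)
  invisible(x)
}
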