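# Stage logic is tested on hit tables (threshold semantics, bookkeeping,
# audit) and end-to-end on the synthetic genomes (plant-and-recover).

mk_hits <- function(query, subject = "S", evalue = 1e-10,
                    in_clade = NULL) {
  if (!length(query)) {
    h <- linspec:::empty_hits()
    if (!is.null(in_clade)) h$subject_in_clade <- logical(0)
    return(h)
  }
  h <- data.frame(query_id = query, subject_id = subject, score = 100,
                  evalue = evalue, identity_fraction = 0.9,
                  aligned_length = 100L, frame = NA_character_,
                  stringsAsFactors = FALSE)
  if (!is.null(in_clade)) h$subject_in_clade <- in_clade
  h
}

test_that("stage-1 threshold is strict and the partition is exhaustive", {
  genes <- paste0("G", 1:4)
  hits <- rbind(mk_hits("G1", evalue = 5e-6),   # below cutoff -> EC
                mk_hits("G2", evalue = 1e-5),   # exactly at cutoff -> not EC
                mk_hits("G3", evalue = 2e-5))   # above -> not EC
  s1 <- classify_outside_clade(genes, dbs = NULL, e_cutoff = 1e-5, hits = hits)
  expect_identical(s1$ec, "G1")
  expect_setequal(s1$remainder, c("G2", "G3", "G4"))
  expect_identical(sort(c(s1$ec, s1$remainder)), sort(genes))
  # empty databases: everything is remainder
  empty_db <- sequence_database(Biostrings::DNAStringSet(),
                                "outside_clade_genomic")
  s1e <- classify_outside_clade(
    Biostrings::AAStringSet(setNames(rep("MKVLLDWFFGG", 4), genes)),
    list(empty_db))
  expect_identical(length(s1e$ec), 0L)
  expect_setequal(s1e$remainder, genes)
  # database with the wrong tag is a configuration error
  expect_error(classify_outside_clade(
    Biostrings::AAStringSet(setNames("MKVLL", "G1")),
    list(sequence_database(Biostrings::DNAStringSet(), "clade_transcript"))),
    "configuration error")
})

test_that("stage 2 splits the remainder and enforces pipeline order", {
  rem <- c("G2", "G3", "G4")
  s2 <- classify_within_clade(rem, dbs = NULL,
                              hits = mk_hits("G3", evalue = 1e-8),
                              stage1_ec = "G1")
  expect_identical(s2$clade_specific, "G3")
  expect_setequal(s2$species_specific, c("G2", "G4"))
  # empty clade databases: all species-specific
  s2e <- classify_within_clade(
    Biostrings::AAStringSet(setNames(rep("MKVLLDWFFGG", 3), rem)),
    list(sequence_database(Biostrings::DNAStringSet(), "clade_transcript")))
  expect_setequal(s2e$species_specific, rem)
  # feeding a stage-1 EC gene back in violates pipeline order
  expect_error(
    classify_within_clade(c("G1", rem), dbs = NULL, hits = mk_hits("G3"),
                          stage1_ec = "G1"),
    "pipeline order")
})

test_that("knowledgebase reassignment reproduces the reference set-transfer arithmetic", {
  # initial sets sized as in the genome-scale Arabidopsis survey, with its
  # numbers of accepted transfers: 33 clade->EC, 20 species->EC,
  # 35 species->clade
  clade <- sprintf("C%04d", 1:912)
  species <- sprintf("S%04d", 1:1379)
  ec <- sprintf("E%05d", 1:24571)
  hits <- rbind(
    mk_hits(clade[1:33], subject = "NC", in_clade = FALSE),
    mk_hits(species[1:20], subject = "NC", in_clade = FALSE),
    mk_hits(species[21:55], subject = "CL", in_clade = TRUE))
  res <- knowledgebase_reassign(clade, species, hits = hits)
  final_ec <- c(ec, res$ec_additions)
  expect_identical(length(res$clade_specific), 914L)
  expect_identical(length(res$species_specific), 1324L)
  expect_identical(length(final_ec), 24624L)
  expect_identical(nrow(res$decisions), 88L)
  # percentages of the grand total, half-up to one decimal
  total <- length(final_ec) + 914L + 1324L
  expect_identical(total, 26862L)
  expect_equal(round_half_up(100 * 914 / total, 1), 3.4)
  expect_equal(round_half_up(100 * 1324 / total, 1), 4.9)
  expect_equal(round_half_up(100 * length(final_ec) / total, 1), 91.7)
})

test_that("reassignment honors review decisions, audit, and idempotence", {
  clade <- c("C1", "C2")
  species <- c("S1", "S2", "S3")
  hits <- rbind(mk_hits("C1", subject = "NC", in_clade = FALSE),
                mk_hits("S1", subject = "NC", in_clade = FALSE),
                mk_hits("S2", subject = "CL", in_clade = TRUE))
  # auto mode applies every candidate move
  auto <- knowledgebase_reassign(clade, species, hits = hits)
  expect_setequal(auto$ec_additions, c("C1", "S1"))
  expect_setequal(auto$clade_specific, c("C2", "S2"))
  expect_identical(auto$species_specific, "S3")
  # accepted decisions only broaden conservation
  expect_true(all(
    (auto$decisions$from_label == "CLADE_SPECIFIC" &
       auto$decisions$to_label == "EC") |
    (auto$decisions$from_label == "SPECIES_SPECIFIC" &
       auto$decisions$to_label %in% c("EC", "CLADE_SPECIFIC"))))
  # review mode: rejecting a move keeps the gene in place
  review <- data.frame(gene_id = c("C1", "S1", "S2"),
                       to_label = c("EC", "EC", "CLADE_SPECIFIC"),
                       accepted = c(TRUE, FALSE, TRUE))
  rev1 <- knowledgebase_reassign(clade, species, hits = hits, review = review)
  expect_identical(rev1$ec_additions, "C1")
  expect_true("S1" %in% rev1$species_specific)
  # a decision naming a gene without a qualifying hit errors
  badrev <- data.frame(gene_id = "S3", to_label = "EC", accepted = TRUE)
  expect_error(
    knowledgebase_reassign(clade, species, hits = hits, review = badrev),
    "without a qualifying hit")
  # re-running with the already-applied decision list is a no-op
  rev2 <- knowledgebase_reassign(rev1$clade_specific, rev1$species_specific,
                                 hits = hits, review = review)
  expect_identical(length(rev2$ec_additions), 0L)
  expect_setequal(rev2$clade_specific, rev1$clade_specific)
  expect_setequal(rev2$species_specific, rev1$species_specific)
  # empty knowledgebase leaves sets unchanged
  none <- knowledgebase_reassign(clade, species, hits = mk_hits(character(0)))
  expect_identical(length(none$ec_additions), 0L)
  expect_setequal(none$clade_specific, clade)
})

test_that("planted three-way labels are recovered on synthetic genomes", {
  sim <- simulate_lineage_genomes(small_sim_spec(seed = 17))
  prot <- get_proteome(sim$annotation)
  cls <- run_lineage_pipeline(prot, sim$outside_dbs, sim$clade_dbs,
                              sim$kb, sim$clade_taxa)
  called <- cls$results$label[match(sim$truth$gene_id, cls$results$gene_id)]
  expect_gte(mean(called == sim$truth$label), 0.9)
  # the partition is exhaustive at the end of the pipeline
  expect_identical(sum(cls$counts), length(prot))
  # planted knowledgebase transfers were discovered at stage 3
  moved <- sim$truth$gene_id[sim$truth$label != sim$truth$planted_label]
  stage3 <- cls$results$gene_id[cls$results$decided_at_stage == 3L]
  expect_true(all(moved %in% stage3))
  # every final label is reproducible from stored hits + decisions alone
  s1_ids <- unique(cls$stage1_hits$query_id)
  replay <- classify_outside_clade(names(prot), dbs = NULL,
                                  hits = cls$stage1_hits)
  expect_setequal(replay$ec,
                  cls$results$gene_id[cls$results$label == "EC" &
                                        cls$results$decided_at_stage == 1L])
})

test_that("adding database sequences never narrows a label (monotonicity)", {
  genes <- paste0("G", 1:3)
  h0 <- mk_hits("G1", evalue = 1e-8)
  h1 <- rbind(h0, mk_hits("G2", evalue = 1e-9))
  rank <- c(EC = 3L, CLADE_SPECIFIC = 2L, SPECIES_SPECIFIC = 1L)
  lab_of <- function(hits) {
    s1 <- classify_outside_clade(genes, dbs = NULL, hits = hits)
    lab <- setNames(rep("SPECIES_SPECIFIC", 3), genes)
    lab[s1$ec] <- "EC"
    lab
  }
  expect_true(all(rank[lab_of(h1)] >= rank[lab_of(h0)]))
})

test_that("classification summaries cross-tabulate and round half-up", {
  results <- data.frame(
    gene_id = sprintf("G%02d", 1:12),
    label = c(rep("EC", 7), rep("CLADE_SPECIFIC", 4), "SPECIES_SPECIFIC"),
    stringsAsFactors = FALSE)
  attributes <- data.frame(
    gene_id = results$gene_id,
    known_function = c(rep(TRUE, 6), rep(FALSE, 6)),
    has_transcript_support = rep(c(TRUE, FALSE), 6))
  s <- summarize_classification(results, attributes)
  expect_equal(sum(s$totals$n), 12)
  # single-gene label is 100.0% of itself in the crosstab sums
  sp <- s$crosstab[s$crosstab$label == "SPECIES_SPECIFIC" &
                     s$crosstab$subcategory == "all", ]
  expect_equal(sum(sp$pct_of_label), 100)
  # crosstab "all" cells sum to the label total
  for (lb in unique(results$label)) {
    cells <- s$crosstab[s$crosstab$label == lb &
                          s$crosstab$subcategory == "all", "n"]
    expect_equal(sum(cells), sum(results$label == lb))
  }
  # half-up rounding convention
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(58.333, 1), 58.3)
})
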