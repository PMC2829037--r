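test_that("six-frame translation matches a codon-walk oracle", {
  expect_identical(
    as.character(translate_six_frames("ATGGCT")[["+1"]]), "MA")
  # frame -1 equals frame +1 of the reverse complement
  expect_identical(
    as.character(translate_six_frames("AGCCAT")[["-1"]]), "MA")
  set.seed(42)
  nt <- paste(sample(c("A", "C", "G", "T", "N"), 300,
                     replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
              collapse = "")
  frames <- translate_six_frames(nt)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  for (off in 0:2) {
    expect_identical(as.character(frames[[sprintf("+%d", off + 1)]]),
                     oracle_translate_frame(nt, off))
    expect_identical(as.character(frames[[sprintf("-%d", off + 1)]]),
                     oracle_translate_frame(rc, off))
  }
  # shorter than a codon: empty translations, no error
  expect_true(all(Biostrings::width(translate_six_frames("AT")) == 0))
})

test_that("local alignment scores match diagonal sums and handle degenerate input", {
  scheme <- scoring_scheme()
  B <- scheme$matrix
  al <- local_align("MKV", "MKV", scheme)
  expect_equal(al$score, B["M", "M"] + B["K", "K"] + B["V", "V"])
  expect_equal(al$identity_fraction, 1)
  expect_identical(al$aligned_length, 3L)
  # all-mismatch pairs have no positive local alignment
  expect_equal(local_align("AAAA", "CCCC", scheme)$score, 0)
  expect_identical(local_align("AAAA", "CCCC", scheme)$aligned_length, 0L)
  # empty input
  expect_equal(local_align("", "MKV", scheme)$score, 0)
})

test_that("Smith-Waterman equals exhaustive local-alignment enumeration", {
  scheme <- scoring_scheme()
  B <- scheme$matrix[SUB_ALPHABET, SUB_ALPHABET]
  strings <- unlist(lapply(1:2, function(L)
    apply(expand.grid(rep(list(SUB_ALPHABET), L)), 1, paste, collapse = "")))
  # all pairs of length <= 2 strings, exhaustively
  for (q in strings) for (s in strings) {
    expect_equal(local_align(q, s, scheme)$score,
                 oracle_local_align(q, s, B, scheme$gap_open,
                                    scheme$gap_extend),
                 info = paste(q, s))
  }
  # seeded longer pairs up to length 5
  set.seed(7)
  for (k in 1:40) {
    q <- paste(sample(SUB_ALPHABET, sample(3:5, 1), TRUE), collapse = "")
    s <- paste(sample(SUB_ALPHABET, sample(3:5, 1), TRUE), collapse = "")
    expect_equal(local_align(q, s, scheme)$score,
                 oracle_local_align(q, s, B, scheme$gap_open,
                                    scheme$gap_extend),
                 info = paste(q, s))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  scheme <- scoring_scheme(K = 0.041, lambda = 0.267)
  expect_equal(evalue_from_score(0, 100, 100, scheme), 0.041 * 100 * 100)
  # doubling n doubles E at fixed S
  expect_equal(evalue_from_score(30, 100, 2000, scheme),
               2 * evalue_from_score(30, 100, 1000, scheme))
  # S solving lambda*S = ln(K*m*n) gives E = 1
  S1 <- log(0.041 * 150 * 1e6) / 0.267
  expect_equal(evalue_from_score(S1, 150, 1e6, scheme), 1)
  # E is strictly decreasing in S
  S <- seq(0, 100, by = 5)
  expect_true(all(diff(evalue_from_score(S, 100, 1e4, scheme)) < 0))
})

test_that("protein-vs-nucleotide search recovers planted homologs", {
  set.seed(5)
  prot <- paste(c("M", sample(linspec:::AA20, 149, TRUE)), collapse = "")
  nt <- with_seed(5, linspec:::back_translate(prot))
  junk <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = ""), "")
  db <- sequence_database(
    Biostrings::DNAStringSet(c(target = nt, setNames(junk, paste0("junk", 1:8)))),
    "outside_clade_genomic")
  hits <- search_protein_vs_nucleotide(
    Biostrings::AAStringSet(c(Q = prot)), db)
  # self-frame hit: perfect identity, tiny E
  expect_identical(hits$subject_id[1], "target")
  expect_equal(hits$identity_fraction[1], 1)
  expect_lt(hits$evalue[1], 1e-20)
  expect_identical(hits$frame[1], "+1")

  # a diverged (80% identity) ortholog is still recovered below the cutoff
  div <- with_seed(6, linspec:::back_translate(
    linspec:::mutate_protein(prot, 0.2)))
  db2 <- sequence_database(
    Biostrings::DNAStringSet(c(ortho = div, setNames(junk, paste0("junk", 1:8)))),
    "outside_clade_genomic")
  hits2 <- search_protein_vs_nucleotide(
    Biostrings::AAStringSet(c(Q = prot)), db2)
  expect_true("ortho" %in% hits2$subject_id)
  expect_lt(hits2$evalue[hits2$subject_id == "ortho"][1], 1e-5)

  # random queries vs unrelated 10 kb database: almost never a hit
  false_pos <- 0L
  for (s in 1:25) {
    set.seed(100 + s)
    rq <- paste(sample(linspec:::AA20, 120, TRUE), collapse = "")
    h <- search_protein_vs_nucleotide(
      Biostrings::AAStringSet(c(R = rq)),
      sequence_database(
        Biostrings::DNAStringSet(setNames(junk, paste0("junk", 1:8))),
        "outside_clade_genomic"))
    false_pos <- false_pos + (nrow(h) > 0L)
  }
  expect_lte(false_pos, 1L)
  # empty database
  expect_identical(nrow(search_protein_vs_nucleotide(
    Biostrings::AAStringSet(c(Q = prot)),
    sequence_database(Biostrings::DNAStringSet(), "outside_clade_genomic"))),
    0L)
})

test_that("protein-vs-protein search agrees with direct pairwise alignment", {
  scheme <- scoring_scheme()
  set.seed(9)
  prots <- vapply(1:6, function(i)
    paste(sample(linspec:::AA20, 80, TRUE), collapse = ""), "")
  names(prots) <- paste0("P", 1:6)
  db <- sequence_database(Biostrings::AAStringSet(prots), "knowledgebase")
  # exact copy in the database: the top hit is itself
  hits <- search_protein_vs_protein(
    Biostrings::AAStringSet(prots["P1"]), db, scheme, e_cutoff = Inf)
  expect_identical(hits$subject_id[1], "P1")
  # every reported score equals local_align on the pair; E respects cutoff
  hits_all <- search_protein_vs_protein(
    Biostrings::AAStringSet(prots), db, scheme, e_cutoff = 1e-3)
  expect_true(all(hits_all$evalue < 1e-3))
  for (k in seq_len(nrow(hits_all))) {
    expect_equal(hits_all$score[k],
                 local_align(prots[hits_all$query_id[k]],
                             prots[hits_all$subject_id[k]], scheme)$score)
  }
  # cutoff 0 admits nothing
  expect_identical(nrow(search_protein_vs_protein(
    Biostrings::AAStringSet(prots), db, scheme, e_cutoff = 0)), 0L)
})

test_that("hits sort consistently in score and E-value and ignore record order", {
  set.seed(21)
  prots <- vapply(1:8, function(i)
    paste(sample(linspec:::AA20, 60, TRUE), collapse = ""), "")
  names(prots) <- paste0("P", 1:8)
  q <- Biostrings::AAStringSet(prots[1])
  db1 <- sequence_database(Biostrings::AAStringSet(prots), "knowledgebase")
  db2 <- sequence_database(Biostrings::AAStringSet(rev(prots)), "knowledgebase")
  h1 <- search_protein_vs_protein(q, db1, e_cutoff = Inf)
  h2 <- search_protein_vs_protein(q, db2, e_cutoff = Inf)
  # E-monotonicity: sorted by E ascending means sorted by score descending
  expect_true(all(diff(h1$evalue) >= 0))
  expect_true(all(diff(h1$score) <= 0))
  # set equality under record order permutation
  expect_setequal(paste(h1$subject_id, h1$score), paste(h2$subject_id, h2$score))
})

test_that("tabular hit ingestion maps outfmt-6 columns", {
  tab <- data.frame(q = "G1", s = "S1", pident = 85.5, len = 120, mm = 17,
                    go = 1, qs = 1, qe = 120, ss = 10, se = 129,
                    evalue = 3e-20, bits = 180.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hits <- read_search_hits(path)
  expect_identical(hits$query_id, "G1")
  expect_equal(hits$identity_fraction, 0.855)
  expect_equal(hits$evalue, 3e-20)
})
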