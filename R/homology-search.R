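# Desk-scale search backend standing in for TBLASTN/BLASTP: six-frame
# translation, Smith-Waterman local alignment (Biostrings), and
# Karlin-Altschul E-values E = K * m * n * exp(-lambda * S).
#
# The backend is pluggable: read_search_hits() ingests tabular (BLAST
# outfmt-6-like) output so an external search can drive the classifier.

#' Alignment scoring scheme
#'
#' Substitution matrix, affine gap penalties, and Karlin-Altschul constants
#' used for local alignment scores and E-values. Defaults are the published
#' gapped BLOSUM62 parameters.
#'
#' @param matrix A square substitution matrix, or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param K,lambda Karlin-Altschul constants (lambda in nats per score unit).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           K = 0.041, lambda = 0.267) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
  }
  stopifnot(gap_open > 0, gap_extend > 0, K > 0, lambda > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' Tag a set of sequences as a search database
#'
#' @param records A [Biostrings::DNAStringSet] (genomic or transcript
#'   databases) or [Biostrings::AAStringSet] (protein knowledgebase), named
#'   by record id.
#' @param taxon_group One of `"outside_clade_genomic"`,
#'   `"outside_clade_transcript"`, `"clade_transcript"`, `"knowledgebase"`.
#' @param name Database name.
#' @param taxonomy Named character vector mapping record id to taxon label
#'   (knowledgebase databases).
#' @return A `sequence_database`.
#' @export
sequence_database <- function(records, taxon_group, name = "db",
                              taxonomy = NULL) {
  taxon_group <- match.arg(taxon_group,
    c("outside_clade_genomic", "outside_clade_transcript",
      "clade_transcript", "knowledgebase"))
  type <- if (methods::is(records, "AAStringSet")) "aa" else "nt"
  if (!is.null(taxonomy) && is.null(names(taxonomy)))
    stopf("taxonomy must be a named vector (record id -> taxon)")
  structure(list(name = name, records = records, taxon_group = taxon_group,
                 taxonomy = taxonomy, type = type,
                 total_length = sum(Biostrings::width(records))),
            class = "sequence_database")
}

#' @export
print.sequence_database <- function(x, ...) {
  cat(sprintf("sequence_database '%s' (%s, %s): %d records, %d residues\n",
              x$name, x$taxon_group, x$type, length(x$records), x$total_length))
  invisible(x)
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1..+3 read the forward strand from offsets 0..2; frames -1..-3
#' read the reverse complement the same way. Codons containing N translate to
#' `X`; stop codons are rendered `*`. Sequences shorter than one codon give
#' empty translations.
#'
#' @param nt A [Biostrings::DNAString] or character string.
#' @return An [Biostrings::AAStringSet] of length 6, named
#'   `"+1"`,`"+2"`,`"+3"`,`"-1"`,`"-2"`,`"-3"`.
#' @export
translate_six_frames <- function(nt) {
  if (is.character(nt)) nt <- Biostrings::DNAString(nt)
  rc <- Biostrings::reverseComplement(nt)
  one <- function(s, off) {
    L <- length(s) - off
    usable <- (L %/% 3L) * 3L
    if (usable < 3L) return(Biostrings::AAString(""))
    Biostrings::translate(Biostrings::subseq(s, off + 1L, off + usable),
                          if.fuzzy.codon = "solve")
  }
  frames <- c(lapply(0:2, function(o) one(nt, o)),
              lapply(0:2, function(o) one(rc, o)))
  out <- Biostrings::AAStringSet(frames)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps under a [scoring_scheme()]. The score is
#' never negative: if no positive-scoring local alignment exists the score is
#' 0 with aligned length 0.
#'
#' @param q,s Protein sequences ([Biostrings::AAString] or character).
#' @param scheme A [scoring_scheme()].
#' @return List with `score`, `identity_fraction` (matches over alignment
#'   columns, gaps included), and `aligned_length`.
#' @export
local_align <- function(q, s, scheme = scoring_scheme()) {
  q <- as.character(q); s <- as.character(s)
  if (!nchar(q) || !nchar(s))
    return(list(score = 0, identity_fraction = 0, aligned_length = 0L))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, identity_fraction = 0, aligned_length = 0L))
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = sc,
       identity_fraction = Biostrings::nmatch(aln) / alen,
       aligned_length = alen)
}

#' Karlin-Altschul E-value from a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least S between a query of length m and a database
#' of total length n.
#'
#' @param S Raw alignment score(s).
#' @param m Query length (residues).
#' @param n Database total length (residues; for translated searches, the
#'   total translated length over all six frames).
#' @param scheme A [scoring_scheme()] supplying K and lambda.
#' @return E-value(s).
#' @export
evalue_from_score <- function(S, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$K * m * n * exp(-scheme$lambda * S)
}

hit_columns <- c("query_id", "subject_id", "score", "evalue",
                 "identity_fraction", "aligned_length", "frame")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             score = numeric(0), evalue = numeric(0),
             identity_fraction = numeric(0), aligned_length = integer(0),
             frame = character(0), stringsAsFactors = FALSE)
}

# Split translated frames at stop codons. Alignments never cross a stop:
# each inter-stop segment is aligned separately. Segments shorter than
# min_width cannot reach a significant E-value and are dropped.
split_at_stops <- function(aa_chr, min_width = 5L) {
  segs <- strsplit(aa_chr, "*", fixed = TRUE)[[1L]]
  keep <- nchar(segs) >= min_width
  segs[keep]
}

# Shared engine: score every query against a set of subject segments grouped
# by (record, frame); keep the best segment score per group; convert to
# E-values; realign kept pairs for identity/aligned length.
search_segments <- function(queries, segments, group_record, group_frame,
                            n_total, scheme, e_cutoff) {
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  if (!length(segments)) return(empty_hits())
  segset <- Biostrings::AAStringSet(segments)
  group <- paste(group_record, group_frame, sep = "\r")
  out <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    m <- length(q)
    if (m == 0L) next
    sc <- Biostrings::pairwiseAlignment(
      segset, q, type = "local", substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE)
    best <- tapply(seq_along(sc), group, function(ix) ix[which.max(sc[ix])])
    best <- unlist(best, use.names = FALSE)
    bsc <- sc[best]
    ev <- evalue_from_score(bsc, m, n_total, scheme)
    keep <- which(ev < e_cutoff & bsc > 0)
    if (!length(keep)) next
    rows <- lapply(keep, function(k) {
      i <- best[k]
      al <- local_align(q, segments[[i]], scheme)
      data.frame(query_id = names(queries)[qi],
                 subject_id = group_record[i],
                 score = bsc[k], evalue = ev[k],
                 identity_fraction = al$identity_fraction,
                 aligned_length = al$aligned_length,
                 frame = group_frame[i], stringsAsFactors = FALSE)
    })
    out[[qi]] <- do.call(rbind, rows)
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(hits)) return(empty_hits())
  hits[order(hits$evalue), ]
}

# Vectorized six-frame segmentation of a whole record set: one translate()
# call per frame. Returns the inter-stop segments (>= min_width), their
# record/frame labels, and the total translated length for the E-value n.
six_frame_segments <- function(records, min_width = 5L) {
  if (is.null(names(records)))
    names(records) <- paste0("record", seq_along(records))
  rc <- Biostrings::reverseComplement(records)
  segments <- character(0); rec <- character(0); frm <- character(0)
  n_total <- 0
  for (f in 1:6) {
    strand_set <- if (f <= 3L) records else rc
    off <- (f - 1L) %% 3L
    w <- Biostrings::width(strand_set)
    usable <- pmax(0L, ((w - off) %/% 3L) * 3L)
    keep <- which(usable >= 3L)
    if (!length(keep)) next
    aa <- Biostrings::translate(
      Biostrings::subseq(strand_set[keep], off + 1L, off + usable[keep]),
      if.fuzzy.codon = "solve")
    n_total <- n_total + sum(Biostrings::width(aa))
    pieces <- strsplit(as.character(aa), "*", fixed = TRUE)
    lens <- lengths(pieces)
    segs <- unlist(pieces, use.names = FALSE)
    ok <- nchar(segs) >= min_width
    segments <- c(segments, segs[ok])
    rec <- c(rec, rep(names(strand_set)[keep], lens)[ok])
    frm <- c(frm, rep(if (f <= 3L) sprintf("+%d", f) else sprintf("-%d", f - 3L),
                      sum(ok)))
  }
  list(segments = segments, record = rec, frame = frm,
       n_total = max(n_total, 1))
}

#' Search protein queries against a nucleotide database
#'
#' TBLASTN-like: every database record is translated in six frames, frames
#' are split at stop codons (alignments never cross a stop), and each query
#' is locally aligned against every segment. Per (query, record, frame) the
#' best-scoring alignment is kept; E-values use the database's total
#' translated length.
#'
#' @param query An [Biostrings::AAStringSet] (or named character vector) of
#'   protein queries.
#' @param db A nucleotide [sequence_database()].
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff Keep hits with `E < e_cutoff` (strict).
#' @return Hit data frame (query_id, subject_id, score, evalue,
#'   identity_fraction, aligned_length, frame), sorted by E-value.
#' @export
search_protein_vs_nucleotide <- function(query, db, scheme = scoring_scheme(),
                                         e_cutoff = 1e-5) {
  if (db$type != "nt") stopf("database '%s' is not nucleotide", db$name)
  if (!length(db$records)) return(empty_hits())
  sf <- six_frame_segments(db$records)
  search_segments(query, sf$segments, sf$record, sf$frame, sf$n_total,
                  scheme, e_cutoff)
}

#' Search protein queries against a protein database
#'
#' BLASTP-like: each query is locally aligned against every record; the
#' E-value uses the database total length; `frame` is `NA`.
#'
#' @inheritParams search_protein_vs_nucleotide
#' @param db A protein [sequence_database()].
#' @return Hit data frame sorted by E-value.
#' @export
search_protein_vs_protein <- function(query, db, scheme = scoring_scheme(),
                                      e_cutoff = 1e-5) {
  if (db$type != "aa") stopf("database '%s' is not protein", db$name)
  if (!length(db$records)) return(empty_hits())
  segments <- as.character(db$records)
  search_segments(query, segments, names(db$records),
                  rep(NA_character_, length(segments)),
                  max(db$total_length, 1), scheme, e_cutoff)
}

#' Read tabular search hits
#'
#' Ingests BLAST outfmt-6-like 12-column TSV output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#' so an external search engine can drive the classifier in place of the
#' built-in backend.
#'
#' @param path Path to the tabular file.
#' @return Hit data frame in the package's hit format.
#' @export
read_search_hits <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stopf("expected >= 12 tab-separated columns in %s", path)
  data.frame(query_id = as.character(tab[[1]]),
             subject_id = as.character(tab[[2]]),
             score = as.numeric(tab[[12]]), evalue = as.numeric(tab[[11]]),
             identity_fraction = as.numeric(tab[[3]]) / 100,
             aligned_length = as.integer(tab[[4]]),
             frame = NA_character_, stringsAsFactors = FALSE)
}
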