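# Paralogous-family construction from curated + novel (alignment-derived)
# protein domains, similar-pair selection, collinear chaining of gene pairs
# into segmentally duplicated blocks, and block-overlap statistics.

#' Protein regions not covered by curated domains
#'
#' Maximal intervals of a protein (1-based, inclusive, amino acids) that do
#' not overlap any curated domain and are at least `min_len` long.
#'
#' @param protein_length Protein length in aa.
#' @param domains Data frame with `start`/`end` columns (may be empty).
#' @param min_len Minimum reported interval length (default 75 aa).
#' @return Data frame with `start`, `end`.
#' @export
uncovered_regions <- function(protein_length, domains = NULL, min_len = 75L) {
  covered <- rep(FALSE, protein_length)
  if (!is.null(domains) && nrow(domains)) {
    if (any(domains$start < 1L) || any(domains$end > protein_length))
      stopf("domain outside protein bounds [1, %d]", protein_length)
    for (k in seq_len(nrow(domains)))
      covered[domains$start[k]:domains$end[k]] <- TRUE
  }
  r <- rle(!covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Cluster uncovered regions into novel domains
#'
#' All-versus-all local alignment of the regions; regions are linked when
#' identity > `min_identity` over an alignment of at least `min_aln_len`
#' columns with `E < e_cutoff`. Novel domains are the single-linkage
#' connected components with at least two members; singletons get no domain.
#'
#' @param regions Named [Biostrings::AAStringSet] (or character vector) of
#'   uncovered region sequences.
#' @param scheme A [scoring_scheme()].
#' @param min_identity Identity threshold (strict `>`, default 0.45).
#' @param min_aln_len Minimum alignment length (default 75).
#' @param e_cutoff E-value threshold (strict `<`, default 1e-3).
#' @return Named character vector mapping region id to novel domain id
#'   (`"ND1"`, `"ND2"`, ...); regions in no cluster are absent.
#' @export
cluster_novel_domains <- function(regions, scheme = scoring_scheme(),
                                  min_identity = 0.45, min_aln_len = 75L,
                                  e_cutoff = 1e-3) {
  if (is.character(regions)) regions <- Biostrings::AAStringSet(regions)
  n <- length(regions)
  if (n < 2L) return(stats::setNames(character(0), character(0)))
  ids <- names(regions)
  total_len <- sum(Biostrings::width(regions))
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- local_align(regions[[i]], regions[[j]], scheme)
      if (al$score <= 0) next
      ev <- evalue_from_score(al$score, Biostrings::width(regions)[i],
                              total_len, scheme)
      if (al$identity_fraction > min_identity &&
          al$aligned_length >= min_aln_len && ev < e_cutoff)
        edges <- rbind(edges, c(i, j))
    }
  }
  if (!nrow(edges)) return(stats::setNames(character(0), character(0)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$csize[comp$membership] >= 2L)
  memb <- comp$membership[keep]
  # renumber clusters in order of first appearance
  newid <- match(memb, unique(memb))
  stats::setNames(paste0("ND", newid), ids[keep])
}

#' Build paralogous families from domain composition
#'
#' Proteins are linked when they share at least one domain id (curated or
#' novel); families are the connected components with at least two members
#' (`mode = "linkage"`, default). `mode = "composition"` instead groups
#' proteins with identical domain-id sets. Proteins with no domain are
#' unclassified either way.
#'
#' @param domains Data frame with `protein_id` and `domain_id` (one row per
#'   domain assignment; `source` column optional).
#' @param all_proteins Character vector of every protein considered, for the
#'   classified-fraction denominator.
#' @param mode `"linkage"` or `"composition"`.
#' @return List: `families` data frame (`family_id`, `protein_id`),
#'   `classified_fraction`, `n_families`.
#' @export
build_families <- function(domains, all_proteins,
                           mode = c("linkage", "composition")) {
  mode <- match.arg(mode)
  domains <- domains[!is.na(domains$domain_id), , drop = FALSE]
  fam <- NULL
  if (nrow(domains)) {
    if (mode == "linkage") {
      # bipartite protein-domain graph: proteins in one component share a
      # domain along some chain
      g <- igraph::graph_from_data_frame(
        data.frame(from = paste0("P\r", domains$protein_id),
                   to = paste0("D\r", domains$domain_id)), directed = FALSE)
      comp <- igraph::components(g)
      vn <- igraph::V(g)$name
      is_p <- startsWith(vn, "P\r")
      memb <- comp$membership[is_p]
      pid <- sub("^P\r", "", vn[is_p])
      sizes <- table(memb)
      keep <- memb %in% as.integer(names(sizes)[sizes >= 2L])
      if (any(keep)) {
        memb <- memb[keep]; pid <- pid[keep]
        fam <- data.frame(family_id = paste0("F", match(memb, unique(memb))),
                          protein_id = pid, stringsAsFactors = FALSE)
      }
    } else {
      comp_of <- tapply(domains$domain_id, domains$protein_id, function(d)
        paste(sort(unique(d)), collapse = ";"))
      grp <- split(names(comp_of), unname(comp_of))
      grp <- grp[lengths(grp) >= 2L]
      if (length(grp))
        fam <- data.frame(
          family_id = rep(paste0("F", seq_along(grp)), lengths(grp)),
          protein_id = unlist(grp, use.names = FALSE),
          stringsAsFactors = FALSE)
    }
  }
  if (is.null(fam))
    fam <- data.frame(family_id = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE)
  fam <- fam[order(fam$family_id, fam$protein_id), , drop = FALSE]
  rownames(fam) <- NULL
  list(families = fam,
       classified_fraction = length(unique(fam$protein_id)) /
         max(1L, length(all_proteins)),
       n_families = length(unique(fam$family_id)))
}

#' Select similar protein pairs by all-versus-all search
#'
#' Per query, the best (by E-value) at most `max_hits_per_query` non-self
#' subjects with `E < e_cutoff` are kept; pairs are deduplicated unordered.
#'
#' @param proteome Named [Biostrings::AAStringSet].
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff E-value threshold (default 1e-10).
#' @param max_hits_per_query Per-query subject cap (default 5).
#' @return Data frame with `gene_a`, `gene_b` (lexicographically ordered
#'   within each row), `evalue` of the pair's best supporting hit.
#' @export
select_similar_pairs <- function(proteome, scheme = scoring_scheme(),
                                 e_cutoff = 1e-10, max_hits_per_query = 5L) {
  db <- sequence_database(proteome, "knowledgebase", name = "self")
  hits <- search_protein_vs_protein(proteome, db, scheme, e_cutoff)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  hits <- hits[order(hits$query_id, hits$evalue), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id),
                        utils::head, max_hits_per_query), use.names = FALSE)
  hits <- hits[keep, , drop = FALSE]
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  pairs <- data.frame(gene_a = a, gene_b = b, evalue = hits$evalue,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b, pairs$evalue), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# maximum-score chain (score +1 per pair) over one dot-plot: pairs strictly
# increasing on both axes, consecutive gaps <= max_gap on both axes.
best_chain_dp <- function(xa, xb, max_gap) {
  n <- length(xa)
  ord <- order(xa, xb)
  xa <- xa[ord]; xb <- xb[ord]
  score <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (xa[j] < xa[i] && xb[j] < xb[i] &&
          xa[i] - xa[j] <= max_gap && xb[i] - xb[j] <= max_gap &&
          score[j] + 1L > score[i]) {
        score[i] <- score[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(score)
  chain <- integer(0)
  while (best != 0L) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  ord[chain]
}

#' Chain collinear gene pairs into segmental-duplication blocks
#'
#' Dynamic programming over the pair dot-plot of every chromosome pair:
#' a chain is a set of pairs with strictly increasing positions on both
#' axes, broken when the gap on either axis exceeds `max_gap`; the score is
#' +1 per pair (unit scoring). Maximum-score chains are extracted
#' iteratively (chains never share a pair); chains with fewer than
#' `min_pairs` pairs are discarded. Self-comparison of a chromosome is
#' allowed but the trivial diagonal (a gene paired with itself) is excluded.
#'
#' @param pairs Data frame with `gene_a`, `gene_b`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b` (positions are gene midpoints in bp).
#' @param max_gap Maximum within-chain gap on either axis (default 100 kb).
#' @param min_pairs Minimum pairs per reported chain (default 4).
#' @return List of chains; each chain is a list with `pairs` (the member
#'   rows) and `blocks` (one row per axis: chrom, start, end).
#' @export
chain_collinear_pairs <- function(pairs, max_gap = 100000, min_pairs = 4L) {
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  chains <- list()
  if (!nrow(pairs)) return(chains)
  key <- paste(pairs$chrom_a, pairs$chrom_b, sep = "\r")
  for (k in unique(key)) {
    sub <- pairs[key == k, , drop = FALSE]
    repeat {
      if (!nrow(sub)) break
      idx <- best_chain_dp(sub$pos_a, sub$pos_b, max_gap)
      if (length(idx) < min_pairs) break
      member <- sub[idx, , drop = FALSE]
      blocks <- data.frame(
        axis = c("a", "b"),
        chrom = c(member$chrom_a[1], member$chrom_b[1]),
        start = c(min(member$pos_a), min(member$pos_b)),
        end = c(max(member$pos_a), max(member$pos_b)),
        stringsAsFactors = FALSE)
      chains[[length(chains) + 1L]] <- list(pairs = member, blocks = blocks,
                                            score = nrow(member))
      sub <- sub[-idx, , drop = FALSE]
    }
  }
  chains
}

#' Fraction of genes inside segmentally duplicated blocks
#'
#' A gene is "in a block" iff its midpoint lies within any chain's block
#' interval (inclusive ends) on either axis of its chromosome. Reports
#' per-label in/out fractions (percent, rounded half-up to 1 decimal) and a
#' 2x2 chi-square comparison of each label against the reference label.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `pos`, `label`.
#' @param chains Output of [chain_collinear_pairs()].
#' @param reference Label compared against (default `"EC"`).
#' @return List: `fractions` data frame (label, n, n_in_block, pct_in_block,
#'   pct_outside), `tests` data frame of chi-square comparisons.
#' @export
fraction_in_blocks <- function(genes, chains, reference = "EC") {
  blocks <- do.call(rbind, lapply(chains, `[[`, "blocks"))
  in_block <- rep(FALSE, nrow(genes))
  if (!is.null(blocks) && nrow(blocks)) {
    for (k in seq_len(nrow(blocks))) {
      in_block <- in_block |
        (genes$chrom == blocks$chrom[k] &
           genes$pos >= blocks$start[k] & genes$pos <= blocks$end[k])
    }
  }
  labs <- unique(genes$label)
  fractions <- do.call(rbind, lapply(labs, function(lb) {
    m <- genes$label == lb
    data.frame(label = lb, n = sum(m), n_in_block = sum(in_block & m),
               pct_in_block = percent1(sum(in_block & m), sum(m)),
               pct_outside = percent1(sum(!in_block & m), sum(m)),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (reference %in% labs) {
    rm_ <- genes$label == reference
    tests <- do.call(rbind, lapply(setdiff(labs, reference), function(lb) {
      m <- genes$label == lb
      res <- tryCatch(compare_sets(
        rbind(c(sum(in_block & m), sum(!in_block & m)),
              c(sum(in_block & rm_), sum(!in_block & rm_))),
        kind = "chi_square_proportion"),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_))
      data.frame(label = lb, reference = reference,
                 statistic = res$statistic, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(fractions = fractions, tests = tests, in_block = in_block)
}
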