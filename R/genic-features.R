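# Per-gene genic feature metrics (exon counts, lengths, GC content including
# the three codon positions) and set-level comparisons (Welch t, chi-square
# on proportions).

# GC fraction of a character sequence; N bases are excluded from both the
# numerator and the denominator. Returns NA for empty/all-N sequences.
gc_fraction <- function(x) {
  if (!nchar(x)) return(NA_real_)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(x), c("G", "C", "N"))
  denom <- nchar(x) - f[["N"]]
  if (denom == 0L) return(NA_real_)
  (f[["G"]] + f[["C"]]) / denom
}

#' Compute the genic feature vector of one gene
#'
#' Metrics are computed on the representative isoform's extracted regions:
#' exon count and lengths, intron lengths, gene/CDS/protein lengths, GC of
#' gene, exons (pooled), introns (pooled), CDS, and the three codon
#' positions of the spliced CDS. For single-exon genes the intron GC is
#' missing (`NA`), not 0.
#'
#' @param regions Output of [extract_gene_regions()].
#' @return One-row data frame; `exon_lengths` and `intron_lengths` are list
#'   columns.
#' @export
compute_feature_vector <- function(regions) {
  exon_lengths <- unname(nchar(regions$exons))
  intron_lengths <- unname(nchar(regions$introns))
  cds <- regions$cds
  usable <- (nchar(cds) %/% 3L) * 3L
  gc_pos <- rep(NA_real_, 3)
  if (usable >= 3L) {
    chars <- strsplit(substr(cds, 1L, usable), "")[[1L]]
    for (p in 1:3) {
      cc <- chars[seq(p, usable, by = 3L)]
      cc <- cc[cc != "N"]
      gc_pos[p] <- if (length(cc)) mean(cc %in% c("G", "C")) else NA_real_
    }
  }
  data.frame(
    gene_id = regions$gene_id,
    exon_count = length(exon_lengths),
    exon_lengths = I(list(exon_lengths)),
    intron_lengths = I(list(intron_lengths)),
    gene_length = nchar(regions$gene),
    cds_length = nchar(cds),
    protein_length = nchar(regions$protein),
    gc_gene = gc_fraction(regions$gene),
    gc_exon = gc_fraction(paste(regions$exons, collapse = "")),
    gc_intron = if (length(intron_lengths))
      gc_fraction(paste(regions$introns, collapse = "")) else NA_real_,
    gc_cds = gc_fraction(cds),
    gc_pos1 = gc_pos[1], gc_pos2 = gc_pos[2], gc_pos3 = gc_pos[3],
    is_single_exon = length(exon_lengths) == 1L,
    stringsAsFactors = FALSE)
}

#' Feature table for every gene in an annotation
#'
#' @param annotation A `genome_annotation`.
#' @param flank Flank length passed to [extract_gene_regions()].
#' @return Data frame with one row per gene.
#' @export
compute_feature_table <- function(annotation, flank = 500L) {
  rows <- lapply(names(annotation$genes), function(id)
    compute_feature_vector(extract_gene_regions(annotation, id, flank)))
  do.call(rbind, rows)
}

summ_cell <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  c(mean = if (n) mean(x) else NA_real_,
    sd = if (n > 1L) stats::sd(x) else NA_real_,
    median = if (n) stats::median(x) else NA_real_,
    n = n)
}

#' Summarize genic features per gene-set label
#'
#' Mean, sample SD (n-1 denominator), and median per label x feature.
#' Exon and intron lengths are pooled over all exons/introns of the set by
#' default; `length_mode = "per_gene"` first averages within each gene.
#' Missing values are excluded per cell; a cell with a single value reports
#' SD as missing.
#'
#' @param features Output of [compute_feature_table()].
#' @param labels Data frame with `gene_id` and `label`.
#' @param length_mode `"pooled"` or `"per_gene"` for exon/intron lengths.
#' @return Long data frame: label, feature, mean, sd, median, n.
#' @export
summarize_features <- function(features, labels,
                               length_mode = c("pooled", "per_gene")) {
  length_mode <- match.arg(length_mode)
  lab <- labels$label[match(features$gene_id, labels$gene_id)]
  scalar_feats <- c("exon_count", "gene_length", "cds_length",
                    "protein_length", "gc_gene", "gc_exon", "gc_intron",
                    "gc_cds", "gc_pos1", "gc_pos2", "gc_pos3")
  rows <- list()
  for (lb in unique(lab[!is.na(lab)])) {
    sub <- features[which(lab == lb), , drop = FALSE]
    for (ft in scalar_feats) {
      s <- summ_cell(sub[[ft]])
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, feature = ft, mean = s[["mean"]], sd = s[["sd"]],
        median = s[["median"]], n = s[["n"]], stringsAsFactors = FALSE)
    }
    for (ft in c("exon_lengths", "intron_lengths")) {
      vals <- if (length_mode == "pooled") unlist(sub[[ft]])
              else vapply(sub[[ft]], function(v)
                if (length(v)) mean(v) else NA_real_, 0)
      s <- summ_cell(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, feature = sub("s$", "", ft), mean = s[["mean"]],
        sd = s[["sd"]], median = s[["median"]], n = s[["n"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare two gene sets on a feature or proportion
#'
#' `welch_t`: two-sided Welch unequal-variance t-test on two numeric
#' vectors (Welch-Satterthwaite degrees of freedom). Two samples with zero
#' variance and equal means give t = 0, p = 1. `chi_square_proportion`:
#' chi-square test without continuity correction on a 2x2 table given either
#' as a matrix in `a`, or as `a = c(count, total)` and `b = c(count, total)`.
#'
#' @param a,b Numeric vectors (welch_t) or counts (chi-square).
#' @param kind `"welch_t"` or `"chi_square_proportion"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_sets <- function(a, b = NULL,
                         kind = c("welch_t", "chi_square_proportion")) {
  kind <- match.arg(kind)
  if (kind == "welch_t") {
    if (length(a) < 2L || length(b) < 2L)
      stopf("welch_t needs >= 2 values per side")
    res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) {
      # zero variance on both sides: equal means -> no evidence (p = 1)
      if (isTRUE(all.equal(mean(a), mean(b))))
        return(list(statistic = 0, p_value = 1))
      return(list(statistic = Inf * sign(mean(a) - mean(b)), p_value = 0))
    }
    return(list(statistic = unname(res$statistic), p_value = res$p.value))
  }
  tab <- if (is.matrix(a)) a
         else rbind(c(a[1], a[2] - a[1]), c(b[1], b[2] - b[1]))
  if (any(tab < 0)) stopf("chi-square counts must be >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("chi-square table has a zero row or column")
  if (all(tab[, 1] == 0) || all(tab[, 2] == 0))
    stopf("chi-square table has a zero column")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
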