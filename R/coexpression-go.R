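# Co-expression neighborhoods from an expression compendium via a resampled
# null Pearson-correlation threshold; per-gene GO enrichment (one-sided
# Fisher exact + Storey q-values); five-group over-representation.

#' Pearson correlation of two expression profiles
#'
#' Pairwise-complete observations. Fewer than 3 complete pairs, or zero
#' variance on either side, give `NA` (undefined), not 0.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_cc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

eligible_rows <- function(mat) {
  n_ok <- rowSums(!is.na(mat))
  v <- apply(mat, 1L, function(r) stats::var(r, na.rm = TRUE))
  which(n_ok >= 3L & !is.na(v) & v > 0)
}

#' Estimate the null co-expression threshold
#'
#' Samples `n_pairs` random gene pairs (seeded), computes their Pearson
#' correlations, and returns the stated percentile of the signed r
#' distribution. With `focal_genes` given, pairs are drawn between a focal
#' gene and any other gene (the alternative reading of "all pairwise
#' correlations obtained during the computation"); otherwise pairs are drawn
#' genome-wide.
#'
#' @param mat Expression matrix, genes x experiments, with rownames.
#' @param n_pairs Number of sampled pairs (default 1e6; at least 1000
#'   recommended for a stable 99th percentile).
#' @param percentile Percentile of the null r distribution (default 99).
#' @param seed Integer seed; the same seed gives the same threshold.
#' @param focal_genes Optional character vector restricting one side of each
#'   pair.
#' @return The threshold `r_star`.
#' @export
estimate_null_threshold <- function(mat, n_pairs = 1e6, percentile = 99,
                                    seed = 1L, focal_genes = NULL) {
  stopifnot(n_pairs >= 1)
  rows <- eligible_rows(mat)
  if (length(rows) < 2L)
    stopf("too few eligible genes (need >= 2 with >= 3 values and variance)")
  if (n_pairs < 1000)
    warnf("n_pairs < 1000 gives an unstable percentile estimate")
  focal_rows <- if (is.null(focal_genes)) rows
                else intersect(rows, which(rownames(mat) %in% focal_genes))
  if (!length(focal_rows)) stopf("no eligible focal genes in the matrix")
  with_seed(seed, {
    i <- sample(focal_rows, n_pairs, replace = TRUE)
    j <- sample(rows, n_pairs, replace = TRUE)
    fix <- which(i == j)
    while (length(fix)) {
      j[fix] <- sample(rows, length(fix), replace = TRUE)
      fix <- fix[i[fix] == j[fix]]
    }
    r <- if (anyNA(mat)) {
      vapply(seq_len(n_pairs), function(k) pearson_cc(mat[i[k], ], mat[j[k], ]),
             0)
    } else {
      z <- t(scale(t(mat)))
      rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]) / (ncol(mat) - 1L)
    }
    unname(stats::quantile(r[!is.na(r)], percentile / 100, type = 7))
  })
}

#' Genes co-expressed with a focal gene
#'
#' All genes `g != focal` with `r(focal, g) > r_star` (strict, signed r).
#'
#' @param focal Focal gene id (must be a row of `mat`).
#' @param mat Expression matrix, genes x experiments.
#' @param r_star Correlation threshold (e.g. from
#'   [estimate_null_threshold()]).
#' @return Character vector of co-expressed gene ids.
#' @export
coexpressed_genes <- function(focal, mat, r_star) {
  if (!focal %in% rownames(mat)) stopf("focal gene '%s' not in matrix", focal)
  f <- mat[focal, ]
  others <- setdiff(rownames(mat), focal)
  r <- vapply(others, function(g) pearson_cc(f, mat[g, ]), 0)
  others[!is.na(r) & r > r_star]
}

#' Filter GO annotations by evidence code
#'
#' Removes annotations whose evidence code is purely expression- or
#' computation-derived (default IEP, IEA, RCA), preventing circularity when
#' enrichment is read off co-expression neighborhoods.
#'
#' @param go Data frame with `gene_id`, `go_id`, `go_term`, `evidence_code`.
#' @param exclude Evidence codes to drop.
#' @return Filtered data frame.
#' @export
filter_go_annotations <- function(go, exclude = c("IEP", "IEA", "RCA")) {
  go[!go$evidence_code %in% exclude, , drop = FALSE]
}

#' GO term enrichment of a gene set (Fisher exact)
#'
#' One-sided (over-representation) Fisher exact test per GO term with at
#' least one annotated gene in the universe, on the 2x2 table (in set x
#' annotated). Evidence filtering is applied first. q-values via
#' [estimate_qvalues()].
#'
#' @param gene_set Character vector, subset of `universe`.
#' @param go GO annotation data frame (`gene_id`, `go_id`, `go_term`,
#'   `evidence_code`).
#' @param universe Character vector of all genes considered.
#' @param exclude_evidence Evidence codes removed before counting.
#' @return Data frame: go_id, go_term, the four 2x2 counts, p_value,
#'   q_value; empty for an empty gene set.
#' @export
fisher_term_enrichment <- function(gene_set, go, universe,
                                   exclude_evidence = c("IEP", "IEA", "RCA")) {
  if (!all(gene_set %in% universe))
    stopf("gene_set must be a subset of the universe")
  empty <- data.frame(go_id = character(0), go_term = character(0),
                      set_annotated = integer(0), set_other = integer(0),
                      out_annotated = integer(0), out_other = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(gene_set)) return(empty)
  go <- filter_go_annotations(go, exclude_evidence)
  go <- go[go$gene_id %in% universe, , drop = FALSE]
  if (!nrow(go)) return(empty)
  terms <- unique(go[, c("go_id", "go_term")])
  N <- length(universe)
  n_set <- length(gene_set)
  rows <- lapply(seq_len(nrow(terms)), function(k) {
    ann <- unique(go$gene_id[go$go_id == terms$go_id[k]])
    a <- length(intersect(gene_set, ann))
    tab <- matrix(c(a, n_set - a,
                    length(ann) - a, N - n_set - (length(ann) - a)),
                  nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(go_id = terms$go_id[k], go_term = terms$go_term[k],
               set_annotated = a, set_other = n_set - a,
               out_annotated = length(ann) - a,
               out_other = N - n_set - (length(ann) - a),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- estimate_qvalues(out$p_value)
  out[order(out$p_value), ]
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 (step
#' 0.05) with a cubic smoothing spline extrapolated at the top of the grid,
#' then converts p-values to q-values (`q = pi0 * p * n / rank`, with the
#' standard step-up monotonicity enforcement). For short p-value lists
#' (fewer than `min_n_storey`) the smoother is unstable and
#' Benjamini-Hochberg (pi0 = 1) is used instead; `method = "bh"` forces it.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` (with BH fallback for short lists) or `"bh"`.
#' @param min_n_storey Minimum list length for the Storey smoother.
#' @return q-values, same length and order as `p`. The pi0 estimate is
#'   attached as attribute `pi0`.
#' @export
estimate_qvalues <- function(p, method = c("storey", "bh"),
                             min_n_storey = 100L) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must be in [0, 1] and non-missing")
  n <- length(p)
  pi0 <- 1
  if (method == "storey" && n >= min_n_storey) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * n / (n:1) * p[o]))[ro]
  attr(q, "pi0") <- pi0
  q
}

#' Over-representation of manually defined gene groups
#'
#' For each group, a 2x2 Fisher exact test (one-sided) of lineage-set versus
#' background membership against in-group versus not, with q-values and
#' significance flags at the stated FDR.
#'
#' @param lineage_set,background_set Disjoint character vectors of gene ids.
#' @param groups Data frame with `gene_id` and `group`.
#' @param fdr Significance level on the q-value (default 0.01).
#' @return Data frame: group, the 2x2 counts, p_value, q_value, significant.
#' @export
group_overrepresentation <- function(lineage_set, background_set, groups,
                                     fdr = 0.01) {
  if (length(intersect(lineage_set, background_set)))
    stopf("lineage and background sets must be disjoint")
  gset <- unique(groups$group)
  if (!length(gset)) stopf("groups table is empty")
  rows <- lapply(gset, function(g) {
    members <- unique(groups$gene_id[groups$group == g])
    a <- length(intersect(lineage_set, members))
    b <- length(lineage_set) - a
    c_ <- length(intersect(background_set, members))
    d <- length(background_set) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(group = g, lineage_in = a, lineage_out = b,
               background_in = c_, background_out = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- estimate_qvalues(out$p_value)
  out$significant <- out$q_value < fdr
  out
}

#' GO enrichment of each focal gene's co-expression neighborhood
#'
#' Convenience wrapper: for every focal gene, the set of genes co-expressed
#' above `r_star` is tested for GO term enrichment.
#'
#' @param focal_genes Character vector of focal gene ids present in `mat`.
#' @param mat Expression matrix.
#' @param r_star Co-expression threshold.
#' @param go GO annotation table.
#' @param universe Gene universe (default: all matrix rows).
#' @return Data frame of enrichment records with a `focal_gene` column; the
#'   number of co-expressed partners per focal gene is attached as attribute
#'   `n_coexpressed`.
#' @export
enrich_coexpressed <- function(focal_genes, mat, r_star, go,
                               universe = rownames(mat)) {
  n_co <- integer(0)
  rows <- lapply(focal_genes, function(f) {
    partners <- coexpressed_genes(f, mat, r_star)
    n_co[[f]] <<- length(partners)
    if (!length(partners)) return(NULL)
    e <- fisher_term_enrichment(partners, go, universe)
    if (!nrow(e)) return(NULL)
    cbind(focal_gene = f, e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "n_coexpressed") <- n_co
  out
}
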