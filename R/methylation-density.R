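# Cytosine methylation density per gene-relative region: number of
# 5-methylcytosine calls per 100 bp, in the 500 bp upstream flank, the
# coding region, and the 500 bp downstream flank.

#' Validate a methylation call set
#'
#' @param calls Data frame with `chrom`, `pos` (1-based), `strand`,
#'   `context` (one of CG, CHG, CHH).
#' @return The validated data frame.
#' @export
methylation_calls <- function(calls) {
  stopifnot(all(c("chrom", "pos", "strand", "context") %in% names(calls)))
  bad <- setdiff(unique(calls$context), c("CG", "CHG", "CHH"))
  if (length(bad)) stopf("unknown methylation context: %s",
                         paste(bad, collapse = ", "))
  calls
}

#' Methylation density of a genomic interval
#'
#' `100 * (number of calls with position in [start, end]) / interval length`.
#' Calls on both strands are counted.
#'
#' @param calls Methylation call data frame.
#' @param interval List or one-row data frame with `chrom`, `start`, `end`.
#' @return Density per 100 bp.
#' @export
region_density <- function(calls, interval) {
  len <- interval$end - interval$start + 1
  stopifnot(len >= 1)
  n <- sum(calls$chrom == interval$chrom &
             calls$pos >= interval$start & calls$pos <= interval$end)
  100 * n / len
}

# gene-relative region intervals for the representative model; flanks are
# strand-aware (upstream = transcriptional) and truncated at chromosome ends
gene_region_intervals <- function(annotation, gene_id, flank = 500L,
                                  coding_mode = c("span", "spliced")) {
  coding_mode <- match.arg(coding_mode)
  gene <- annotation$genes[[gene_id]]
  if (is.null(gene)) stopf("unknown gene id '%s'", gene_id)
  iso <- select_representative_model(gene)
  L <- Biostrings::width(annotation$sequences)[
    match(gene$chrom, names(annotation$sequences))]
  cd <- iso$cds
  span <- c(min(cd$start), max(cd$end))
  minus <- gene$strand == "-"
  mk <- function(s, e) if (s > e) NULL else
    list(chrom = gene$chrom, start = s, end = e)
  up <- if (minus) mk(span[2] + 1L, min(L, span[2] + flank))
        else mk(max(1L, span[1] - flank), span[1] - 1L)
  down <- if (minus) mk(max(1L, span[1] - flank), span[1] - 1L)
          else mk(span[2] + 1L, min(L, span[2] + flank))
  coding <- if (coding_mode == "span") list(mk(span[1], span[2]))
            else lapply(seq_len(nrow(cd)), function(k) mk(cd$start[k], cd$end[k]))
  list(upstream = up, coding = coding, downstream = down)
}

#' Per-gene methylation density profile
#'
#' Densities in the upstream flank, the coding region, and the downstream
#' flank of the representative model. The coding region is the genomic span
#' from the first to the last CDS base (`coding_mode = "span"`, default:
#' introns count in the denominator since the calls are genomic);
#' `"spliced"` instead pools the CDS pieces. Flanks are transcriptional
#' (strand-aware) and truncated at chromosome ends, with the density taken
#' over the truncated length.
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene id.
#' @param calls Methylation call data frame.
#' @param flank Flank length (default 500 bp).
#' @param coding_mode `"span"` or `"spliced"`.
#' @return Named numeric: `upstream`, `coding`, `downstream` (per 100 bp).
#'   A fully truncated flank (gene at a chromosome end) gives `NA`.
#' @export
gene_density_profile <- function(annotation, gene_id, calls, flank = 500L,
                                 coding_mode = c("span", "spliced")) {
  iv <- gene_region_intervals(annotation, gene_id, flank, coding_mode)
  dens1 <- function(x) if (is.null(x)) NA_real_ else region_density(calls, x)
  coding_parts <- iv$coding[!vapply(iv$coding, is.null, TRUE)]
  lens <- vapply(coding_parts, function(x) x$end - x$start + 1, 0)
  counts <- vapply(coding_parts, function(x)
    region_density(calls, x) * (x$end - x$start + 1) / 100, 0)
  c(upstream = dens1(iv$upstream),
    coding = 100 * sum(counts) / sum(lens),
    downstream = dens1(iv$downstream))
}

#' Methylation profiles for every gene
#'
#' @inheritParams gene_density_profile
#' @return Data frame: gene_id, upstream, coding, downstream.
#' @export
methylation_profiles <- function(annotation, calls, flank = 500L,
                                 coding_mode = c("span", "spliced")) {
  ids <- names(annotation$genes)
  prof <- t(vapply(ids, function(id)
    gene_density_profile(annotation, id, calls, flank, coding_mode),
    c(upstream = 0, coding = 0, downstream = 0)))
  data.frame(gene_id = ids, prof, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare methylation density between gene sets
#'
#' Per region, each label's densities are compared to the reference label
#' with a Welch t-test; group means are reported alongside. Any subset of
#' genes (e.g. a secretory-targeted subset) can be compared by subsetting
#' `labels` first.
#'
#' @param profiles Output of [methylation_profiles()].
#' @param labels Data frame with `gene_id`, `label`.
#' @param reference Reference label (default `"EC"`).
#' @return Data frame: region, label, n, mean, mean_reference, statistic,
#'   p_value.
#' @export
compare_methylation <- function(profiles, labels, reference = "EC") {
  lab <- labels$label[match(profiles$gene_id, labels$gene_id)]
  regions <- c("upstream", "coding", "downstream")
  others <- setdiff(unique(lab[!is.na(lab)]), reference)
  rows <- list()
  for (region in regions) {
    ref_vals <- profiles[[region]][which(lab == reference)]
    ref_vals <- ref_vals[!is.na(ref_vals)]
    for (lb in others) {
      v <- profiles[[region]][which(lab == lb)]
      v <- v[!is.na(v)]
      res <- if (length(v) >= 2L && length(ref_vals) >= 2L)
        compare_sets(v, ref_vals, "welch_t")
      else list(statistic = NA_real_, p_value = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, label = lb, n = length(v), mean = mean(v),
        mean_reference = mean(ref_vals), statistic = res$statistic,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
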