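# Thin TSV readers/writers for the pipeline's tabular interchange formats.
# All files are plain tab-separated text with a header row.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read / write an expression matrix
#'
#' Genes x experiments TSV; first column `gene_id`, remaining columns one
#' per experiment. Missing values are empty fields or `NA`.
#'
#' @param path File path.
#' @return A numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_expression_matrix
#' @param mat Matrix with gene rownames.
#' @export
write_expression_matrix <- function(mat, path) {
  write_tsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
            path)
}

#' Read / write GO annotations
#'
#' TSV with columns gene_id, go_id, go_term, evidence_code.
#' @param path File path.
#' @export
read_go_annotations <- function(path) read_tsv(path)

#' @rdname read_go_annotations
#' @param go GO annotation data frame.
#' @export
write_go_annotations <- function(go, path) write_tsv(go, path)

#' Read / write methylation calls
#'
#' BED-like TSV with columns chrom, pos (1-based), strand, context.
#' @param path File path.
#' @export
read_methylation_calls <- function(path) methylation_calls(read_tsv(path))

#' @rdname read_methylation_calls
#' @param calls Methylation call data frame.
#' @export
write_methylation_calls <- function(calls, path) write_tsv(calls, path)

#' Read / write an accession SNP table
#'
#' TSV with columns chrom, pos, ref, then one base-call column per
#' accession (a simplified, documented stand-in for a polymorphism GFF3).
#' @param path File path.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  df$pos <- as.integer(df$pos)
  df
}

#' @rdname read_snp_table
#' @param snps SNP data frame.
#' @export
write_snp_table <- function(snps, path) write_tsv(snps, path)

#' Read / write per-isoform localization predictions
#'
#' TargetP-style TSV with columns isoform_id, gene_id, compartment,
#' reliability_class.
#' @param path File path.
#' @export
read_localization_predictions <- function(path) read_tsv(path)

#' @rdname read_localization_predictions
#' @param predictions Prediction data frame.
#' @export
write_localization_predictions <- function(predictions, path)
  write_tsv(predictions, path)

#' Read / write gene-set labels
#'
#' TSV with columns gene_id, label.
#' @param path File path.
#' @export
read_labels <- function(path) read_tsv(path)

#' @rdname read_labels
#' @param labels Label data frame.
#' @export
write_labels <- function(labels, path) write_tsv(labels, path)
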