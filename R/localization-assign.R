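# Gene-level subcellular localization from per-isoform predictions
# (TargetP-style: compartment + Reliability Class 1..5, 1 = best), plus
# set-level contingency tables and chi-square enrichment tests.

COMPARTMENTS <- c("Chloroplast", "Mitochondrion", "Secretory", "Other")
GENE_LOCALIZATIONS <- c(COMPARTMENTS, "Uncertain")

#' Collapse isoform localization predictions to a gene-level call
#'
#' Among isoforms predicted Chloroplast/Mitochondrion/Secretory, the
#' prediction with the best (lowest) Reliability Class represents the gene.
#' If distinct compartments tie at that best RC the gene is `"Uncertain"`
#' (isoforms agreeing on the same compartment at equal RC are not a tie).
#' If no isoform predicts C/M/S the gene is `"Other"`. Deterministic and
#' invariant to isoform order.
#'
#' @param predictions Data frame of one gene's isoform predictions with
#'   `compartment` (one of Chloroplast, Mitochondrion, Secretory, Other) and
#'   `reliability_class` (integer 1..5).
#' @return One of Chloroplast, Mitochondrion, Secretory, Other, Uncertain.
#' @export
assign_gene_localization <- function(predictions) {
  stopifnot(nrow(predictions) >= 1L)
  bad <- setdiff(unique(predictions$compartment), COMPARTMENTS)
  if (length(bad)) stopf("unknown compartment: %s", paste(bad, collapse = ", "))
  if (any(!predictions$reliability_class %in% 1:5))
    stopf("reliability_class must be in 1..5")
  cms <- predictions[predictions$compartment != "Other", , drop = FALSE]
  if (!nrow(cms)) return("Other")
  best <- min(cms$reliability_class)
  comps <- unique(cms$compartment[cms$reliability_class == best])
  if (length(comps) > 1L) "Uncertain" else comps
}

#' Gene-level localization for all genes
#'
#' @param predictions Data frame with `gene_id`, `isoform_id`,
#'   `compartment`, `reliability_class`.
#' @return Data frame: gene_id, localization.
#' @export
assign_localization <- function(predictions) {
  ids <- unique(predictions$gene_id)
  loc <- vapply(ids, function(g)
    assign_gene_localization(
      predictions[predictions$gene_id == g, , drop = FALSE]), "")
  data.frame(gene_id = ids, localization = unname(loc),
             stringsAsFactors = FALSE)
}

#' Localization contingency table and enrichment tests
#'
#' Counts and percentages (half-up, 1 decimal) of gene-level localizations
#' per label set, plus, for each label and compartment, a 2x2 chi-square
#' test (no continuity correction) of that label against all other genes.
#' Every gene receives exactly one of the five localizations, so counts sum
#' to the label totals.
#'
#' @param assignments Output of [assign_localization()].
#' @param labels Data frame with `gene_id`, `label`.
#' @return List: `counts` (label x localization matrix), `percentages`
#'   (same shape), `tests` data frame (label, localization, statistic,
#'   p_value).
#' @export
localization_contingency <- function(assignments, labels) {
  lab <- labels$label[match(assignments$gene_id, labels$gene_id)]
  if (anyNA(lab)) stopf("labels missing for %d gene(s)", sum(is.na(lab)))
  loc <- factor(assignments$localization, levels = GENE_LOCALIZATIONS)
  counts <- table(label = lab, localization = loc)
  pct <- t(apply(counts, 1L, function(r) percent1(r, sum(r))))
  colnames(pct) <- colnames(counts)
  rows <- list()
  for (lb in rownames(counts)) {
    in_lb <- lab == lb
    for (cp in GENE_LOCALIZATIONS) {
      is_cp <- loc == cp
      tab <- rbind(c(sum(in_lb & is_cp), sum(in_lb & !is_cp)),
                   c(sum(!in_lb & is_cp), sum(!in_lb & !is_cp)))
      res <- tryCatch(compare_sets(tab, kind = "chi_square_proportion"),
                      error = function(e)
                        list(statistic = NA_real_, p_value = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, localization = cp, n = sum(in_lb & is_cp),
        statistic = res$statistic, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = unclass(counts), percentages = pct,
       tests = do.call(rbind, rows))
}
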