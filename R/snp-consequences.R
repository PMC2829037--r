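# Accession SNPs: biallelic filtering, mapping into the spliced CDS of
# representative models, synonymous / non-synonymous classification against
# the reference codon, per-gene densities, and set-level ratios.

accession_columns <- function(snps) {
  setdiff(names(snps), c("chrom", "pos", "ref"))
}

#' Filter SNPs to biallelic sites
#'
#' Per SNP, the distinct non-N bases across the reference and all accession
#' calls are counted; the SNP is kept iff there are exactly two. Sites with
#' more than two variants are excluded (counted as multi-allelic); sites
#' monomorphic after N removal are also dropped and counted separately.
#'
#' @param snps Data frame with `chrom`, `pos`, `ref`, and one column per
#'   accession (base calls in A, C, G, T, N).
#' @return List: `snps` (kept rows), `n_multiallelic`, `n_monomorphic`.
#' @export
filter_biallelic <- function(snps) {
  acc <- accession_columns(snps)
  calls <- as.matrix(snps[, acc, drop = FALSE])
  n_alleles <- vapply(seq_len(nrow(snps)), function(i) {
    b <- c(snps$ref[i], calls[i, ])
    length(unique(b[b != "N" & !is.na(b)]))
  }, 0L)
  list(snps = snps[n_alleles == 2L, , drop = FALSE],
       n_multiallelic = sum(n_alleles > 2L),
       n_monomorphic = sum(n_alleles <= 1L))
}

# spliced CDS coordinate map of a representative model: one row per CDS base
# in transcript (5'->3' coding-strand) order
cds_position_map <- function(gene) {
  iso <- select_representative_model(gene)
  cd <- iso$cds[order(iso$cds$start), , drop = FALSE]
  if (gene$strand == "+") {
    gpos <- unlist(lapply(seq_len(nrow(cd)), function(k) cd$start[k]:cd$end[k]))
  } else {
    gpos <- unlist(lapply(rev(seq_len(nrow(cd))), function(k) cd$end[k]:cd$start[k]))
  }
  data.frame(gene_id = gene$id, chrom = gene$chrom, strand = gene$strand,
             genomic_pos = gpos, cds_pos = seq_along(gpos),
             stringsAsFactors = FALSE)
}

# spliced coding-strand CDS sequence of the representative model
spliced_cds_chr <- function(annotation, gene) {
  extract_gene_regions(annotation, gene$id, flank = 0L)$cds
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Locate a SNP in a gene's spliced CDS
#'
#' Maps a genomic position into the representative model's spliced,
#' strand-corrected CDS. Positions outside the spliced CDS return `NULL`.
#' A trailing partial codon (CDS length not divisible by 3) returns `NULL`
#' with a warning.
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene id.
#' @param pos Genomic position (1-based).
#' @return `NULL`, or a list with `codon_index` (1-based),
#'   `position_in_codon` (1..3), and `reference_codon` (coding strand).
#' @export
locate_in_cds <- function(annotation, gene_id, pos) {
  gene <- annotation$genes[[gene_id]]
  if (is.null(gene)) stopf("unknown gene id '%s'", gene_id)
  map <- cds_position_map(gene)
  cp <- map$cds_pos[match(pos, map$genomic_pos)]
  if (is.na(cp)) return(NULL)
  cds <- spliced_cds_chr(annotation, gene)
  usable <- (nchar(cds) %/% 3L) * 3L
  if (cp > usable) {
    warnf("gene %s: SNP at %d falls in a trailing partial codon", gene_id, pos)
    return(NULL)
  }
  ci <- (cp - 1L) %/% 3L + 1L
  list(codon_index = ci,
       position_in_codon = (cp - 1L) %% 3L + 1L,
       reference_codon = substr(cds, (ci - 1L) * 3L + 1L, ci * 3L))
}

#' Classify a coding SNP as synonymous or non-synonymous
#'
#' Translates the reference codon and the codon with the alternate base
#' substituted at the given position under the standard genetic code. Equal
#' amino acids give `"synonymous"`, different give `"nonsynonymous"`;
#' stop-to-amino-acid changes (either direction) are non-synonymous,
#' stop-to-stop is synonymous. A reference codon containing N is
#' unclassifiable (`NA`).
#'
#' @param reference_codon Three-letter coding-strand codon.
#' @param position_in_codon 1, 2, or 3.
#' @param alternate_base Coding-strand alternate base, different from the
#'   reference base at that position.
#' @return `"synonymous"`, `"nonsynonymous"`, or `NA`.
#' @export
classify_consequence <- function(reference_codon, position_in_codon,
                                 alternate_base) {
  if (grepl("N", reference_codon, fixed = TRUE) || alternate_base == "N")
    return(NA_character_)
  ref_base <- substr(reference_codon, position_in_codon, position_in_codon)
  if (ref_base == alternate_base)
    stopf("alternate base equals the reference base at codon position %d",
          position_in_codon)
  alt_codon <- reference_codon
  substr(alt_codon, position_in_codon, position_in_codon) <- alternate_base
  code <- Biostrings::GENETIC_CODE
  if (code[[reference_codon]] == code[[alt_codon]]) "synonymous"
  else "nonsynonymous"
}

#' Map and classify biallelic SNPs across an annotation
#'
#' Builds the spliced CDS coordinate map of every protein-coding gene's
#' representative model, assigns each SNP falling in a CDS to its codon, and
#' classifies it against the reference codon. On minus-strand genes the
#' alternate base is complemented before classification. The SNP table's
#' reference base is checked against the genome sequence; a conflict is a
#' data-integrity error.
#'
#' @param snps Biallelic SNP data frame (see [filter_biallelic()]).
#' @param annotation A `genome_annotation`.
#' @param check_reference Verify `ref` against the FASTA (default TRUE).
#' @return Data frame of coding SNP calls: chrom, pos, gene_id, codon_index,
#'   position_in_codon, reference_codon, alternate_base (coding strand),
#'   verdict.
#' @export
classify_coding_snps <- function(snps, annotation, check_reference = TRUE) {
  maps <- do.call(rbind, lapply(annotation$genes, function(g)
    if (g$biotype == "protein_coding") cds_position_map(g) else NULL))
  cds_cache <- new.env()
  get_cds <- function(gid) {
    if (is.null(cds_cache[[gid]]))
      cds_cache[[gid]] <- spliced_cds_chr(annotation, annotation$genes[[gid]])
    cds_cache[[gid]]
  }
  acc <- accession_columns(snps)
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    hit <- which(maps$chrom == snps$chrom[i] &
                   maps$genomic_pos == snps$pos[i])
    if (!length(hit)) next
    ref <- snps$ref[i]
    if (check_reference) {
      genome_base <- as.character(Biostrings::subseq(
        annotation$sequences[[snps$chrom[i]]], snps$pos[i], snps$pos[i]))
      if (genome_base != ref)
        stopf("SNP at %s:%d: reference base '%s' conflicts with genome '%s'",
              snps$chrom[i], snps$pos[i], ref, genome_base)
    }
    calls <- as.character(snps[i, acc])
    alts <- setdiff(unique(calls[calls != "N" & !is.na(calls)]), ref)
    if (length(alts) != 1L) next  # not biallelic with a non-reference allele
    for (h in hit) {
      gid <- maps$gene_id[h]
      cds <- get_cds(gid)
      usable <- (nchar(cds) %/% 3L) * 3L
      cp <- maps$cds_pos[h]
      if (cp > usable) next
      ci <- (cp - 1L) %/% 3L + 1L
      pic <- (cp - 1L) %% 3L + 1L
      codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
      alt_cs <- if (maps$strand[h] == "-") COMPLEMENT[[alts]] else alts
      verdict <- classify_consequence(codon, pic, alt_cs)
      out[[length(out) + 1L]] <- data.frame(
        chrom = snps$chrom[i], pos = snps$pos[i], gene_id = gid,
        codon_index = ci, position_in_codon = pic, reference_codon = codon,
        alternate_base = alt_cs, verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(chrom = character(0), pos = integer(0),
                      gene_id = character(0), codon_index = integer(0),
                      position_in_codon = integer(0),
                      reference_codon = character(0),
                      alternate_base = character(0), verdict = character(0),
                      stringsAsFactors = FALSE)
  res
}

#' Per-gene SNP densities
#'
#' Counts and densities (per 100 bp of spliced CDS of the representative
#' model) of all classified SNPs, non-synonymous, and synonymous SNPs for
#' each protein-coding gene. Genes with zero-length CDS are excluded.
#'
#' @param coding_calls Output of [classify_coding_snps()].
#' @param annotation A `genome_annotation`.
#' @return Data frame: gene_id, cds_length, n_snps, n_nonsyn, n_syn,
#'   snp_per_100bp, nonsyn_per_100bp, syn_per_100bp.
#' @export
per_gene_densities <- function(coding_calls, annotation) {
  genes <- Filter(function(g) g$biotype == "protein_coding", annotation$genes)
  rows <- lapply(genes, function(g) {
    len <- cds_length_of(select_representative_model(g))
    if (len == 0L) return(NULL)
    calls <- coding_calls[coding_calls$gene_id == g$id &
                            !is.na(coding_calls$verdict), , drop = FALSE]
    n_non <- sum(calls$verdict == "nonsynonymous")
    n_syn <- sum(calls$verdict == "synonymous")
    data.frame(gene_id = g$id, cds_length = len,
               n_snps = n_non + n_syn, n_nonsyn = n_non, n_syn = n_syn,
               snp_per_100bp = 100 * (n_non + n_syn) / len,
               nonsyn_per_100bp = 100 * n_non / len,
               syn_per_100bp = 100 * n_syn / len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Set-level non-synonymous : synonymous ratio
#'
#' Default ratio is the mean per-gene non-synonymous density over the mean
#' per-gene synonymous density, on unrounded means; the total-counts ratio
#' is reported alongside. Also counts genes with more non-synonymous than
#' synonymous SNPs. A zero synonymous total gives an infinite ratio with a
#' flag.
#'
#' @param densities Per-gene density rows (one gene set) from
#'   [per_gene_densities()].
#' @param mode `"density_mean"` (default) or `"total_counts"` selects which
#'   ratio is reported as `ratio`.
#' @return List: ratio, ratio_density_mean, ratio_total_counts,
#'   mean_densities (snp/nonsyn/syn per 100 bp), n_genes,
#'   n_more_nonsyn, pct_more_nonsyn, infinite_ratio flag.
#' @export
set_level_ratio <- function(densities, mode = c("density_mean", "total_counts")) {
  mode <- match.arg(mode)
  if (!nrow(densities) || sum(densities$n_snps) == 0L)
    stopf("set has no classified SNPs")
  mean_non <- mean(densities$nonsyn_per_100bp)
  mean_syn <- mean(densities$syn_per_100bp)
  r_dens <- if (mean_syn > 0) mean_non / mean_syn else Inf
  tot_syn <- sum(densities$n_syn)
  r_tot <- if (tot_syn > 0) sum(densities$n_nonsyn) / tot_syn else Inf
  more <- sum(densities$n_nonsyn > densities$n_syn)
  list(ratio = if (mode == "density_mean") r_dens else r_tot,
       ratio_density_mean = r_dens, ratio_total_counts = r_tot,
       mean_densities = c(snp = mean(densities$snp_per_100bp),
                          nonsyn = mean_non, syn = mean_syn),
       n_genes = nrow(densities), n_more_nonsyn = more,
       pct_more_nonsyn = percent1(more, nrow(densities)),
       infinite_ratio = !is.finite(r_dens) || !is.finite(r_tot))
}
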