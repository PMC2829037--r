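# Genome annotation model: GFF3 + FASTA in, validated gene/isoform/exon/CDS
# structures out, plus per-gene region sequence extraction.
#
# Coordinates are GFF3 throughout: 1-based, inclusive, on the forward strand
# of the chromosome. Strand awareness (reverse complementing, transcriptional
# "upstream") is applied only when sequences are extracted.

#' Construct a transcript model
#'
#' @param id Isoform identifier.
#' @param exons,cds Data frames with integer `start`/`end` columns (1-based,
#'   inclusive, genomic coordinates), exons sorted by start and
#'   non-overlapping, every CDS interval contained in an exon.
#' @param is_representative Logical flag: this isoform represents the gene.
#' @param has_transcript_support Logical flag: isoform has expression support.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(id, exons, cds = exons, is_representative = FALSE,
                             has_transcript_support = FALSE) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  structure(
    list(id = id, exons = exons, cds = cds,
         is_representative = isTRUE(is_representative),
         has_transcript_support = isTRUE(has_transcript_support)),
    class = "transcript_model"
  )
}

#' Construct a gene model
#'
#' @param id Gene identifier.
#' @param chrom Chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param isoforms List of [transcript_model()] objects (at least one).
#' @param biotype One of `"protein_coding"`, `"transposable_element"`,
#'   `"pseudogene"`.
#' @param known_function Logical: the gene has an annotated function.
#' @return A `gene_model` list.
#' @export
gene_model <- function(id, chrom, strand, isoforms,
                       biotype = "protein_coding", known_function = FALSE) {
  biotype <- match.arg(biotype,
                       c("protein_coding", "transposable_element", "pseudogene"))
  if (!strand %in% c("+", "-")) stopf("gene %s: strand must be '+' or '-'", id)
  if (length(isoforms) < 1L) stopf("gene %s: needs at least one isoform", id)
  names(isoforms) <- vapply(isoforms, `[[`, "", "id")
  structure(
    list(id = id, chrom = chrom, strand = strand, isoforms = isoforms,
         biotype = biotype, known_function = isTRUE(known_function)),
    class = "gene_model"
  )
}

#' Construct a genome annotation
#'
#' @param genes List of [gene_model()] objects.
#' @param sequences A [Biostrings::DNAStringSet] of chromosome sequences,
#'   named by chromosome.
#' @param validate Run [validate_annotation()] on the result.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genes, sequences, validate = TRUE) {
  names(genes) <- vapply(genes, `[[`, "", "id")
  ann <- structure(list(genes = genes, sequences = sequences),
                   class = "genome_annotation")
  if (validate) validate_annotation(ann)
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d sequences\n",
              length(x$genes), length(x$sequences)))
  invisible(x)
}

#' Validate a genome annotation
#'
#' Checks that gene ids are unique, intervals are well formed and lie within
#' their chromosome, exons are sorted and non-overlapping, and every CDS
#' interval is contained in some exon of its isoform.
#'
#' @param annotation A `genome_annotation`.
#' @return Invisibly `TRUE`; stops with a validation error otherwise.
#' @export
validate_annotation <- function(annotation) {
  ids <- names(annotation$genes)
  if (anyDuplicated(ids))
    stopf("duplicate gene ids: %s", paste(ids[duplicated(ids)], collapse = ", "))
  chrlen <- stats::setNames(Biostrings::width(annotation$sequences),
                            names(annotation$sequences))
  for (g in annotation$genes) {
    if (!g$chrom %in% names(chrlen))
      stopf("gene %s: unknown chromosome '%s'", g$id, g$chrom)
    L <- chrlen[[g$chrom]]
    for (iso in g$isoforms) {
      ex <- iso$exons
      cd <- iso$cds
      for (df in list(exons = ex, cds = cd)) {
        if (nrow(df) && any(df$start > df$end))
          stopf("gene %s isoform %s: interval with start > end", g$id, iso$id)
        if (nrow(df) && (any(df$start < 1L) || any(df$end > L)))
          stopf("gene %s isoform %s: interval outside chromosome %s [1, %d]",
                g$id, iso$id, g$chrom, L)
      }
      if (nrow(ex) > 1L) {
        ex <- ex[order(ex$start), ]
        if (any(ex$start[-1L] <= ex$end[-nrow(ex)]))
          stopf("gene %s isoform %s: overlapping exons", g$id, iso$id)
      }
      for (k in seq_len(nrow(cd))) {
        inside <- any(cd$start[k] >= ex$start & cd$end[k] <= ex$end)
        if (!inside)
          stopf("gene %s isoform %s: CDS [%d, %d] not contained in any exon",
                g$id, iso$id, cd$start[k], cd$end[k])
      }
    }
  }
  invisible(TRUE)
}

parse_flag <- function(x) {
  if (is.null(x) || is.na(x)) return(FALSE)
  tolower(as.character(x)) %in% c("1", "true", "yes")
}

first_or_na <- function(x) if (length(x)) x[[1L]] else NA_character_

#' Read a genome annotation from GFF3 + FASTA
#'
#' Parses a gene/mRNA/exon/CDS GFF3 hierarchy (via rtracklayer) together with
#' the genome FASTA and returns a validated [genome_annotation()]. Recognised
#' attributes: `biotype` and `known_function` on gene rows; `representative`
#' and `transcript_support` on mRNA rows.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Path to the genome FASTA.
#' @return A `genome_annotation`.
#' @export
read_genome_annotation <- function(gff3_path, fasta_path) {
  if (!file.exists(gff3_path)) stopf("GFF3 file not found: %s", gff3_path)
  if (!file.exists(fasta_path)) stopf("FASTA file not found: %s", fasta_path)
  gff <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
                  error = function(e)
                    stopf("GFF3 parse error in %s: %s", gff3_path,
                          conditionMessage(e)))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  md <- S4Vectors::mcols(gff)
  type <- as.character(md$type)
  chrom <- as.character(GenomicRanges::seqnames(gff))
  strand <- as.character(BiocGenerics::strand(gff))
  starts <- GenomicRanges::start(gff)
  ends <- GenomicRanges::end(gff)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gff))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, first_or_na, "")
  } else rep(NA_character_, length(gff))

  # structured error for a parent link that names no feature, pointing at the
  # offending line of the source file
  report_bad_parent <- function(parent) {
    raw <- readLines(gff3_path, warn = FALSE)
    ln <- grep(paste0("Parent=", parent, "\\b"), raw)[1L]
    stopf("malformed parent link: Parent=%s names no feature (line %s of %s)",
          parent, ifelse(is.na(ln), "?", ln), gff3_path)
  }

  gene_rows <- which(type %in% c("gene", "transposable_element_gene", "pseudogene"))
  mrna_rows <- which(type %in% c("mRNA", "transcript"))
  exon_rows <- which(type == "exon")
  cds_rows <- which(type == "CDS")

  gene_ids <- ids[gene_rows]
  mrna_ids <- ids[mrna_rows]
  mrna_parent <- parents[mrna_rows]
  bad <- which(!mrna_parent %in% gene_ids)
  if (length(bad)) report_bad_parent(mrna_parent[bad[1L]])
  bad <- which(!parents[exon_rows] %in% mrna_ids)
  if (length(bad)) report_bad_parent(parents[exon_rows][bad[1L]])
  bad <- which(!parents[cds_rows] %in% mrna_ids)
  if (length(bad)) report_bad_parent(parents[cds_rows][bad[1L]])

  biotype_attr <- if ("biotype" %in% names(md)) as.character(md$biotype) else NULL
  known_attr <- if ("known_function" %in% names(md)) as.character(md$known_function) else NULL
  rep_attr <- if ("representative" %in% names(md)) as.character(md$representative) else NULL
  sup_attr <- if ("transcript_support" %in% names(md)) as.character(md$transcript_support) else NULL

  genes <- vector("list", length(gene_rows))
  for (k in seq_along(gene_rows)) {
    i <- gene_rows[k]
    gid <- gene_ids[k]
    bt <- if (type[i] == "transposable_element_gene") "transposable_element"
          else if (type[i] == "pseudogene") "pseudogene"
          else if (!is.null(biotype_attr) && !is.na(biotype_attr[i])) biotype_attr[i]
          else "protein_coding"
    iso_rows <- mrna_rows[mrna_parent == gid]
    isoforms <- lapply(iso_rows, function(j) {
      tid <- ids[j]
      e <- which(parents %in% tid & seq_along(type) %in% exon_rows)
      cc <- which(parents %in% tid & seq_along(type) %in% cds_rows)
      ex <- data.frame(start = starts[e], end = ends[e])
      ex <- ex[order(ex$start), , drop = FALSE]
      cd <- data.frame(start = starts[cc], end = ends[cc])
      cd <- cd[order(cd$start), , drop = FALSE]
      transcript_model(
        tid, exons = ex, cds = cd,
        is_representative = !is.null(rep_attr) && parse_flag(rep_attr[j]),
        has_transcript_support = !is.null(sup_attr) && parse_flag(sup_attr[j])
      )
    })
    genes[[k]] <- gene_model(
      gid, chrom = chrom[i], strand = strand[i], isoforms = isoforms,
      biotype = bt,
      known_function = !is.null(known_attr) && parse_flag(known_attr[i])
    )
  }
  genome_annotation(genes, seqs)
}

#' Write a genome annotation to GFF3 + FASTA
#'
#' Inverse of [read_genome_annotation()]; attributes written are the ones the
#' reader recognises.
#'
#' @param annotation A `genome_annotation`.
#' @param gff3_path,fasta_path Output paths.
#' @return Invisibly, the annotation.
#' @export
write_genome_annotation <- function(annotation, gff3_path, fasta_path) {
  rows <- list()
  add <- function(chrom, start, end, strand, type, id = NA, parent = NA,
                  biotype = NA, known = NA, rep = NA, sup = NA, phase = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand, type = type,
      ID = id, Parent = parent, biotype = biotype, known_function = known,
      representative = rep, transcript_support = sup, phase = phase,
      stringsAsFactors = FALSE)
  }
  type_of <- c(protein_coding = "gene",
               transposable_element = "transposable_element_gene",
               pseudogene = "pseudogene")
  for (g in annotation$genes) {
    span <- range(unlist(lapply(g$isoforms, function(i) c(i$exons$start, i$exons$end))))
    add(g$chrom, span[1L], span[2L], g$strand, type_of[[g$biotype]], id = g$id,
        biotype = g$biotype, known = as.integer(g$known_function))
    for (iso in g$isoforms) {
      ispan <- range(c(iso$exons$start, iso$exons$end))
      add(g$chrom, ispan[1L], ispan[2L], g$strand, "mRNA", id = iso$id,
          parent = g$id, rep = as.integer(iso$is_representative),
          sup = as.integer(iso$has_transcript_support))
      for (k in seq_len(nrow(iso$exons)))
        add(g$chrom, iso$exons$start[k], iso$exons$end[k], g$strand, "exon",
            parent = iso$id)
      if (nrow(iso$cds)) {
        # phase: bases to skip before the first complete codon of each piece
        ord <- if (g$strand == "-") order(-iso$cds$start) else order(iso$cds$start)
        lens <- iso$cds$end[ord] - iso$cds$start[ord] + 1L
        before <- cumsum(c(0L, utils::head(lens, -1L)))
        phase <- (3L - before %% 3L) %% 3L
        for (j in seq_along(ord)) {
          k <- ord[j]
          add(g$chrom, iso$cds$start[k], iso$cds$end[k], g$strand, "CDS",
              parent = iso$id, phase = phase[j])
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    Parent = S4Vectors::unname(IRanges::CharacterList(
      lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))),
    biotype = df$biotype, known_function = df$known_function,
    representative = df$representative,
    transcript_support = df$transcript_support, phase = df$phase)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  Biostrings::writeXStringSet(annotation$sequences, fasta_path)
  invisible(annotation)
}

#' Drop transposable-element and pseudogene models
#'
#' Removes all genes whose biotype is not `protein_coding`, plus any genes
#' named in `extra_te_ids` (e.g. additional screening against transposon
#' databases). The number of removed genes is attached as attribute
#' `n_removed`.
#'
#' @param annotation A `genome_annotation`.
#' @param extra_te_ids Character vector of additional gene ids to drop;
#'   ids absent from the annotation produce a warning, not an error.
#' @return Filtered `genome_annotation` with attribute `n_removed`.
#' @export
filter_te_and_pseudogenes <- function(annotation, extra_te_ids = character(0)) {
  ids <- names(annotation$genes)
  missing <- setdiff(extra_te_ids, ids)
  if (length(missing))
    warnf("%d extra TE id(s) not present in the annotation: %s",
          length(missing), paste(utils::head(missing, 5), collapse = ", "))
  biotypes <- vapply(annotation$genes, `[[`, "", "biotype")
  keep <- biotypes == "protein_coding" & !ids %in% extra_te_ids
  out <- genome_annotation(annotation$genes[keep], annotation$sequences,
                           validate = FALSE)
  attr(out, "n_removed") <- sum(!keep)
  out
}

cds_length_of <- function(iso) {
  if (!nrow(iso$cds)) 0L else sum(iso$cds$end - iso$cds$start + 1L)
}

#' Select the representative isoform of a gene
#'
#' Rule: the isoform flagged representative in the input; if none is flagged,
#' the isoform with the longest total CDS; ties broken by lexicographically
#' smallest isoform id. Deterministic.
#'
#' @param gene A `gene_model`.
#' @return A `transcript_model`.
#' @export
select_representative_model <- function(gene) {
  isoforms <- gene$isoforms
  cdslen <- vapply(isoforms, cds_length_of, 0L)
  if (all(cdslen == 0L))
    stopf("gene %s: no isoform has a CDS (non-coding)", gene$id)
  flagged <- vapply(isoforms, `[[`, TRUE, "is_representative")
  pool <- if (any(flagged)) isoforms[flagged] else isoforms
  plen <- vapply(pool, cds_length_of, 0L)
  best <- which(plen == max(plen))
  if (length(best) > 1L) {
    idx <- order(vapply(pool[best], `[[`, "", "id"))[1L]
    best <- best[idx]
  }
  pool[[best]]
}

#' Ensure exactly one representative isoform per gene
#'
#' Applies [select_representative_model()] to every gene and rewrites the
#' `is_representative` flags so exactly one isoform per gene carries it.
#'
#' @param annotation A `genome_annotation`.
#' @return The annotation with flags normalised.
#' @export
set_representative_models <- function(annotation) {
  annotation$genes <- lapply(annotation$genes, function(g) {
    rep_id <- select_representative_model(g)$id
    g$isoforms <- lapply(g$isoforms, function(iso) {
      iso$is_representative <- iso$id == rep_id
      iso
    })
    names(g$isoforms) <- vapply(g$isoforms, `[[`, "", "id")
    g
  })
  annotation
}

extract_interval <- function(chromseq, start, end, strand) {
  s <- as.character(Biostrings::subseq(chromseq, start, end))
  if (strand == "-") revcomp_chr(s) else s
}

#' Extract per-gene region sequences
#'
#' Returns, for the representative isoform, the gene span, each exon and
#' intron, the spliced CDS, the translated protein, and the upstream and
#' downstream flanks. All sequences are reported 5'->3' on the coding strand:
#' minus-strand genes are reverse complemented and "upstream" means
#' transcriptionally upstream (genomically downstream of the gene end).
#' Flanks are truncated at chromosome ends.
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @param flank Flank length in bp (default 500).
#' @return List with character sequences `gene`, `exons`, `introns`, `cds`,
#'   `protein`, `upstream`, `downstream`, plus `flags` (e.g. CDS length not a
#'   multiple of 3, internal stop) and the representative isoform id.
#' @export
extract_gene_regions <- function(annotation, gene_id, flank = 500L) {
  gene <- annotation$genes[[gene_id]]
  if (is.null(gene)) stopf("unknown gene id '%s'", gene_id)
  iso <- select_representative_model(gene)
  chromseq <- annotation$sequences[[gene$chrom]]
  L <- length(chromseq)
  minus <- gene$strand == "-"

  ex <- iso$exons[order(iso$exons$start), , drop = FALSE]
  span <- c(min(ex$start), max(ex$end))
  gene_seq <- extract_interval(chromseq, span[1L], span[2L], gene$strand)

  # transcript order: ascending for +, descending for -
  ord <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  exon_seqs <- vapply(ord, function(k)
    extract_interval(chromseq, ex$start[k], ex$end[k], gene$strand), "")
  names(exon_seqs) <- paste0(gene_id, ".exon", seq_along(ord))

  intron_seqs <- character(0)
  if (nrow(ex) > 1L) {
    gaps <- data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
    gaps <- gaps[gaps$start <= gaps$end, , drop = FALSE]
    gord <- if (minus) rev(seq_len(nrow(gaps))) else seq_len(nrow(gaps))
    intron_seqs <- vapply(gord, function(k)
      extract_interval(chromseq, gaps$start[k], gaps$end[k], gene$strand), "")
    if (length(intron_seqs))
      names(intron_seqs) <- paste0(gene_id, ".intron", seq_along(intron_seqs))
  }

  cd <- iso$cds[order(iso$cds$start), , drop = FALSE]
  cord <- if (minus) rev(seq_len(nrow(cd))) else seq_len(nrow(cd))
  cds_seq <- paste(vapply(cord, function(k)
    extract_interval(chromseq, cd$start[k], cd$end[k], gene$strand), ""),
    collapse = "")
  tr <- translate_cds_chr(cds_seq)

  flank <- as.integer(flank)
  if (flank <= 0L) {
    up <- down <- ""
  } else if (minus) {
    up <- if (span[2L] < L)
      extract_interval(chromseq, span[2L] + 1L, min(L, span[2L] + flank), "-") else ""
    down <- if (span[1L] > 1L)
      extract_interval(chromseq, max(1L, span[1L] - flank), span[1L] - 1L, "-") else ""
  } else {
    up <- if (span[1L] > 1L)
      extract_interval(chromseq, max(1L, span[1L] - flank), span[1L] - 1L, "+") else ""
    down <- if (span[2L] < L)
      extract_interval(chromseq, span[2L] + 1L, min(L, span[2L] + flank), "+") else ""
  }

  list(gene_id = gene_id, isoform_id = iso$id, strand = gene$strand,
       gene = gene_seq, exons = exon_seqs, introns = intron_seqs,
       cds = cds_seq, protein = tr$protein, upstream = up, downstream = down,
       flags = tr$flags)
}

#' Representative proteome of an annotation
#'
#' Translates the representative isoform of every protein-coding gene.
#'
#' @param annotation A `genome_annotation`.
#' @return An [Biostrings::AAStringSet] named by gene id.
#' @export
get_proteome <- function(annotation) {
  genes <- Filter(function(g) g$biotype == "protein_coding", annotation$genes)
  aa <- vapply(genes, function(g)
    extract_gene_regions(annotation, g$id, flank = 0L)$protein, "")
  Biostrings::AAStringSet(aa)
}
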