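# Synthetic study-condition generator: a focal genome inside a clade inside
# a kingdom with planted conserved / clade-specific / species-specific
# genes, an expression compendium with latent co-expression modules and GO
# structure, a methylome with set-dependent rates, accession SNPs with a
# tunable non-synonymous bias, and localization predictions with
# set-dependent compartment probabilities. Every generator is deterministic
# per seed (distinct fixed offsets keep the streams independent).
#
# Sequence evolution is i.i.d. per-residue substitution at the amino-acid
# level, with fresh synonymous codon choice at back-translation (which adds
# nucleotide-level divergence without touching the protein); this creates
# the detectability tiers the classifier needs without a full evolutionary
# simulator.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# codons per amino acid, stop codons excluded from back-translation
codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

random_dna <- function(len, gc = 0.36) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

back_translate <- function(protein, codons = codon_table()) {
  aa <- strsplit(protein, "")[[1L]]
  paste(vapply(aa, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# substitute each residue with probability `rate` by a random different
# amino acid; the initiator M is kept
mutate_protein <- function(protein, rate) {
  aa <- strsplit(protein, "")[[1L]]
  hit <- which(stats::runif(length(aa)) < rate)
  hit <- hit[hit > 1L]
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

#' Simulation specification
#'
#' Bundles every tunable of the synthetic-data generators with the default
#' study conditions: 70/20/10 planted conserved / clade-specific /
#' species-specific genes, 20% amino-acid divergence to clade relatives and
#' 45% to outgroups, 20 resequenced accessions with a 1:1 target
#' non-synonymous:synonymous ratio, and compartment probabilities that mimic
#' a secretory-enriched clade-specific set.
#'
#' @param seed Integer master seed.
#' @param n_ec,n_clade,n_species Planted set sizes.
#' @param n_clade_relatives,n_outgroups Numbers of clade transcript
#'   databases and outgroup genomic databases.
#' @param divergence_clade,divergence_outgroup Per-residue amino-acid
#'   substitution probabilities for clade-level and outgroup-level homologs
#'   (the outgroup tier must be the more diverged one).
#' @param protein_length_range Focal protein lengths (aa), sampled uniformly.
#' @param exon_count_lambda Exon count is 1 + Poisson(lambda).
#' @param intron_length_range,intergenic_length_range bp ranges.
#' @param gc Base composition of intergenic/intron/flank sequence.
#' @param alt_isoform_prob Probability a multi-exon gene gets a second,
#'   shorter isoform.
#' @param n_te,n_pseudo Planted transposable-element genes and pseudogenes
#'   (exercise the biotype filter; excluded from the labeled sets).
#' @param kb_background Number of unrelated knowledgebase records.
#' @param kb_transfers Named integer vector
#'   `c(clade_to_ec, species_to_ec, species_to_clade)`: how many planted
#'   genes get a knowledgebase homolog that the stage-3 reassignment should
#'   discover.
#' @param transcript_support_prob,known_function_prob Named per-label
#'   probabilities of the two annotation flags.
#' @param expression List: n_experiments, n_modules, module_size, loading,
#'   noise_sd (`NULL` = sqrt(1 - loading^2), unit variance), n_background,
#'   go_noise.
#' @param methylation List with `rates`: label x region (upstream, coding,
#'   downstream) per-cytosine call probabilities.
#' @param snp List: n_snps, target_ratio (non-synonymous : synonymous),
#'   n_accessions, multiallelic_frac, n_call_frac.
#' @param localization List: `probs` (label x compartment matrix over
#'   Chloroplast, Mitochondrion, Secretory, Other), `rc_probs` (Reliability
#'   Class 1..5 weights), `n_tie_genes` (planted equal-RC ties exercising
#'   the Uncertain rule).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(
    seed = 1L,
    n_ec = 70L, n_clade = 20L, n_species = 10L,
    n_clade_relatives = 2L, n_outgroups = 2L,
    divergence_clade = 0.20, divergence_outgroup = 0.45,
    protein_length_range = c(60L, 150L),
    exon_count_lambda = 1.5,
    intron_length_range = c(70L, 200L),
    intergenic_length_range = c(200L, 500L),
    gc = 0.36,
    alt_isoform_prob = 0.2,
    n_te = 4L, n_pseudo = 2L,
    kb_background = 20L,
    kb_transfers = c(clade_to_ec = 3L, species_to_ec = 2L,
                     species_to_clade = 3L),
    transcript_support_prob = c(EC = 0.96, CLADE_SPECIFIC = 0.77,
                                SPECIES_SPECIFIC = 0.53),
    known_function_prob = c(EC = 0.79, CLADE_SPECIFIC = 0.24,
                            SPECIES_SPECIFIC = 0.06),
    expression = list(n_experiments = 60L, n_modules = 5L, module_size = 10L,
                      loading = 0.9, noise_sd = NULL, n_background = 200L,
                      go_noise = 0.1),
    methylation = list(rates = rbind(
      EC = c(upstream = 0.004, coding = 0.008, downstream = 0.004),
      CLADE_SPECIFIC = c(upstream = 0.008, coding = 0.016, downstream = 0.008),
      SPECIES_SPECIFIC = c(upstream = 0.008, coding = 0.016, downstream = 0.008))),
    snp = list(n_snps = 2000L, target_ratio = 1.0, n_accessions = 20L,
               multiallelic_frac = 0.02, n_call_frac = 0.05),
    localization = list(
      probs = rbind(
        EC = c(Chloroplast = 0.16, Mitochondrion = 0.11, Secretory = 0.19,
               Other = 0.54),
        CLADE_SPECIFIC = c(Chloroplast = 0.04, Mitochondrion = 0.08,
                           Secretory = 0.45, Other = 0.43),
        SPECIES_SPECIFIC = c(Chloroplast = 0.05, Mitochondrion = 0.17,
                             Secretory = 0.20, Other = 0.58)),
      rc_probs = c(0.3, 0.3, 0.2, 0.1, 0.1),
      n_tie_genes = 2L)) {
  if (divergence_outgroup <= divergence_clade)
    stopf("divergence_outgroup must exceed divergence_clade to plant detectability tiers")
  stopifnot(all(c(divergence_clade, divergence_outgroup) >= 0),
            all(c(divergence_clade, divergence_outgroup) <= 1))
  if (is.null(expression$noise_sd))
    expression$noise_sd <- sqrt(max(0, 1 - expression$loading^2))
  structure(as.list(environment()), class = "simulation_spec")
}

split_lengths <- function(total, n_parts, min_part) {
  if (n_parts == 1L) return(total)
  cuts <- sort(sample(seq(min_part, total - min_part, by = 1L),
                      n_parts - 1L))
  diff(c(0L, cuts, total))
}

#' Simulate a focal genome with planted lineage labels and search databases
#'
#' Generates the focal annotation + genome, clade-relative transcript
#' databases, outgroup genomic and transcript databases, and a taxonomy-
#' labeled protein knowledgebase. Conserved genes get homologs in both
#' tiers, clade-specific genes only in clade databases, species-specific
#' genes nowhere else; `kb_transfers` plants knowledgebase homologs whose
#' discovery moves genes at stage 3, and the truth table records the
#' expected final label. Deterministic per seed.
#'
#' @param spec A [simulation_spec()].
#' @return List: `annotation`, `outside_dbs`, `clade_dbs`, `kb`,
#'   `clade_taxa`, `truth` (gene_id, label, planted_label, known_function,
#'   has_transcript_support), `proteins` (named character).
#' @export
simulate_lineage_genomes <- function(spec) {
  with_seed(spec$seed, {
    codons <- codon_table()
    n <- spec$n_ec + spec$n_clade + spec$n_species
    labels <- sample(rep(c("EC", "CLADE_SPECIFIC", "SPECIES_SPECIFIC"),
                         times = c(spec$n_ec, spec$n_clade, spec$n_species)))
    ids <- sprintf("FG%03d", seq_len(n))

    proteins <- stats::setNames(vapply(seq_len(n), function(i)
      random_protein(sample(spec$protein_length_range[1]:
                              spec$protein_length_range[2], 1L)), ""), ids)

    # extra unlabeled genes exercising the biotype filter
    extra_bt <- c(rep("transposable_element", spec$n_te),
                  rep("pseudogene", spec$n_pseudo))
    extra_ids <- sprintf("FX%03d", seq_along(extra_bt))

    chrom_of <- stats::setNames(
      sample(rep(c("chr1", "chr2"), length.out = n + length(extra_bt))),
      c(ids, extra_ids))
    genes <- list()
    chromseq <- list(chr1 = character(0), chr2 = character(0))
    cursor <- c(chr1 = 0L, chr2 = 0L)
    push <- function(chrom, s) {
      chromseq[[chrom]] <<- c(chromseq[[chrom]], s)
      cursor[[chrom]] <<- cursor[[chrom]] + nchar(s)
    }

    for (gid in c(ids, extra_ids)) {
      chrom <- chrom_of[[gid]]
      push(chrom, random_dna(sample(spec$intergenic_length_range[1]:
                                      spec$intergenic_length_range[2], 1L),
                             spec$gc))
      is_extra <- startsWith(gid, "FX")
      prot <- if (is_extra) random_protein(40L) else proteins[[gid]]
      cds <- paste0(back_translate(prot, codons),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      n_ex <- 1L + stats::rpois(1L, spec$exon_count_lambda)
      n_ex <- max(1L, min(n_ex, nchar(cds) %/% 30L))
      pieces <- split_lengths(nchar(cds), n_ex, 10L)
      introns <- if (n_ex > 1L)
        vapply(seq_len(n_ex - 1L), function(k)
          random_dna(sample(spec$intron_length_range[1]:
                              spec$intron_length_range[2], 1L), spec$gc), "")
      else character(0)
      # local (coding-strand) coordinates of the exon pieces
      local <- list(); off <- 0L
      body <- character(0)
      pstart <- cumsum(c(1L, utils::head(pieces, -1L)))
      for (k in seq_len(n_ex)) {
        body <- c(body, substr(cds, pstart[k], pstart[k] + pieces[k] - 1L))
        local[[k]] <- c(off + 1L, off + pieces[k])
        off <- off + pieces[k]
        if (k < n_ex) {
          body <- c(body, introns[k])
          off <- off + nchar(introns[k])
        }
      }
      body <- paste(body, collapse = "")
      L <- nchar(body)
      strand <- sample(c("+", "-"), 1L)
      gene_start <- cursor[[chrom]] + 1L
      push(chrom, if (strand == "-") revcomp_chr(body) else body)
      to_genomic <- function(lc) {
        if (strand == "+") c(gene_start + lc[1L] - 1L, gene_start + lc[2L] - 1L)
        else c(gene_start + L - lc[2L], gene_start + L - lc[1L])
      }
      iv <- t(vapply(local, to_genomic, c(0L, 0L)))
      exons <- data.frame(start = iv[, 1L], end = iv[, 2L])
      exons <- exons[order(exons$start), , drop = FALSE]
      lb <- if (is_extra) NA_character_ else labels[[match(gid, ids)]]
      sup <- !is_extra && stats::runif(1) < spec$transcript_support_prob[[lb]]
      isoforms <- list(transcript_model(paste0(gid, ".1"), exons, exons,
                                        is_representative = TRUE,
                                        has_transcript_support = sup))
      if (!is_extra && n_ex >= 2L && stats::runif(1) < spec$alt_isoform_prob) {
        iv2 <- t(vapply(local[-n_ex], to_genomic, c(0L, 0L)))
        ex2 <- data.frame(start = iv2[, 1L], end = iv2[, 2L])
        ex2 <- ex2[order(ex2$start), , drop = FALSE]
        isoforms <- c(isoforms, list(
          transcript_model(paste0(gid, ".2"), ex2, ex2,
                           has_transcript_support = sup)))
      }
      genes[[gid]] <- gene_model(
        gid, chrom, strand, isoforms,
        biotype = if (is_extra) extra_bt[[match(gid, extra_ids)]]
                  else "protein_coding",
        known_function = !is_extra &&
          stats::runif(1) < spec$known_function_prob[[lb]])
    }
    # trailing spacer so every gene has room for a downstream flank
    push("chr1", random_dna(600L, spec$gc))
    push("chr2", random_dna(600L, spec$gc))
    sequences <- Biostrings::DNAStringSet(
      vapply(chromseq, paste, "", collapse = ""))
    annotation <- genome_annotation(genes, sequences)

    homolog_cds <- function(gid, rate)
      paste0(back_translate(mutate_protein(proteins[[gid]], rate), codons),
             sample(c("TAA", "TAG", "TGA"), 1L))

    conserved <- ids[labels %in% c("EC", "CLADE_SPECIFIC")]
    ec_ids <- ids[labels == "EC"]
    clade_dbs <- lapply(seq_len(spec$n_clade_relatives), function(k) {
      recs <- Biostrings::DNAStringSet(vapply(conserved, function(g)
        homolog_cds(g, spec$divergence_clade), ""))
      names(recs) <- sprintf("cl%d_PUT%04d", k, seq_along(recs))
      sequence_database(recs, "clade_transcript",
                        name = paste0("clade_relative_", k))
    })
    outside_dbs <- lapply(seq_len(spec$n_outgroups), function(k) {
      recs <- Biostrings::DNAStringSet(vapply(ec_ids, function(g)
        paste0(random_dna(80L, spec$gc),
               homolog_cds(g, spec$divergence_outgroup),
               random_dna(80L, spec$gc)), ""))
      names(recs) <- sprintf("og%d_ctg%04d", k, seq_along(recs))
      sequence_database(recs, "outside_clade_genomic",
                        name = paste0("outgroup_", k))
    })
    puts <- Biostrings::DNAStringSet(vapply(ec_ids, function(g)
      homolog_cds(g, spec$divergence_outgroup), ""))
    names(puts) <- sprintf("ogT_PUT%04d", seq_along(puts))
    outside_dbs <- c(outside_dbs,
                     list(sequence_database(puts, "outside_clade_transcript",
                                            name = "outgroup_transcripts")))

    clade_taxa <- c("Brassica_rapa", "Raphanus_sativus")
    nonclade_taxa <- c("Oryza_sativa", "Populus_trichocarpa", "Vitis_vinifera")
    kt <- spec$kb_transfers
    clade_pool <- ids[labels == "CLADE_SPECIFIC"]
    species_pool <- ids[labels == "SPECIES_SPECIFIC"]
    if (kt[["clade_to_ec"]] > length(clade_pool) ||
        kt[["species_to_ec"]] + kt[["species_to_clade"]] > length(species_pool))
      stopf("kb_transfers exceed the planted set sizes")
    mv_clade_ec <- sample(clade_pool, kt[["clade_to_ec"]])
    mv_species <- sample(species_pool,
                         kt[["species_to_ec"]] + kt[["species_to_clade"]])
    mv_species_ec <- utils::head(mv_species, kt[["species_to_ec"]])
    mv_species_clade <- utils::tail(mv_species, kt[["species_to_clade"]])

    kb_seq <- character(0); kb_tax <- character(0)
    addkb <- function(prefix, gids, taxa) {
      if (!length(gids)) return()
      s <- vapply(gids, function(g)
        mutate_protein(proteins[[g]], spec$divergence_clade), "")
      names(s) <- sprintf("%s%03d", prefix, length(kb_seq) + seq_along(s))
      kb_seq <<- c(kb_seq, s)
      kb_tax <<- c(kb_tax, stats::setNames(
        sample(taxa, length(s), replace = TRUE), names(s)))
    }
    addkb("KBN", mv_clade_ec, nonclade_taxa)
    addkb("KBN", mv_species_ec, nonclade_taxa)
    addkb("KBC", mv_species_clade, clade_taxa)
    bg <- vapply(seq_len(spec$kb_background), function(i)
      random_protein(60L), "")
    names(bg) <- sprintf("KBB%03d", seq_along(bg))
    kb_seq <- c(kb_seq, bg)
    kb_tax <- c(kb_tax, stats::setNames(
      sample(nonclade_taxa, length(bg), replace = TRUE), names(bg)))
    kb <- sequence_database(Biostrings::AAStringSet(kb_seq), "knowledgebase",
                            name = "knowledgebase", taxonomy = kb_tax)

    final <- labels
    final[ids %in% c(mv_clade_ec, mv_species_ec)] <- "EC"
    final[ids %in% mv_species_clade] <- "CLADE_SPECIFIC"
    truth <- data.frame(
      gene_id = ids, label = final, planted_label = labels,
      known_function = vapply(genes[ids], `[[`, TRUE, "known_function"),
      has_transcript_support = vapply(genes[ids], function(g)
        g$isoforms[[1L]]$has_transcript_support, TRUE),
      stringsAsFactors = FALSE)

    list(annotation = annotation, outside_dbs = outside_dbs,
         clade_dbs = clade_dbs, kb = kb, clade_taxa = clade_taxa,
         truth = truth, proteins = proteins)
  })
}

#' Simulate an expression compendium with planted modules and GO structure
#'
#' Module members load on a shared latent factor
#' (`x = loading * f + noise_sd * e`); all other genes are independent
#' noise. Each module gets a coherent GO term annotated to its members;
#' noise annotations (including IEP/IEA/RCA evidence, so the evidence filter
#' is exercised) are sprinkled across random genes.
#'
#' @param spec A [simulation_spec()].
#' @param truth Truth table from [simulate_lineage_genomes()] (its gene ids
#'   seed the matrix rows; background genes are added).
#' @return List: `matrix` (genes x experiments), `go` annotation data frame,
#'   `modules` (gene_id, module).
#' @export
simulate_expression_compendium <- function(spec, truth) {
  ex <- spec$expression
  with_seed(spec$seed + 1001L, {
    genes <- c(truth$gene_id, sprintf("BG%04d", seq_len(ex$n_background)))
    m <- ex$n_experiments
    X <- matrix(stats::rnorm(length(genes) * m, sd = max(ex$noise_sd, 1e-8)),
                nrow = length(genes),
                dimnames = list(genes, sprintf("E%03d", seq_len(m))))
    members <- sample(genes, ex$n_modules * ex$module_size)
    modules <- data.frame(
      gene_id = members,
      module = rep(seq_len(ex$n_modules), each = ex$module_size),
      stringsAsFactors = FALSE)
    for (k in seq_len(ex$n_modules)) {
      f <- stats::rnorm(m)
      for (g in modules$gene_id[modules$module == k])
        X[g, ] <- ex$loading * f + ex$noise_sd * stats::rnorm(m)
    }
    good_ev <- c("IDA", "IMP", "IGI", "TAS")
    bad_ev <- c("IEP", "IEA", "RCA")
    go <- data.frame(
      gene_id = modules$gene_id,
      go_id = sprintf("GO:%07d", modules$module),
      go_term = sprintf("module %d process", modules$module),
      evidence_code = sample(good_ev, nrow(modules), replace = TRUE),
      stringsAsFactors = FALSE)
    n_noise <- round(ex$go_noise * length(genes))
    if (n_noise) {
      noise <- data.frame(
        gene_id = sample(genes, n_noise, replace = TRUE),
        go_id = sprintf("GO:%07d", 9000000 + sample.int(5L, n_noise, TRUE)),
        go_term = "background process",
        evidence_code = sample(c(good_ev, bad_ev), n_noise, replace = TRUE),
        stringsAsFactors = FALSE)
      # expression-derived decoy annotations on module genes: the evidence
      # filter must drop these
      decoy <- data.frame(
        gene_id = modules$gene_id,
        go_id = "GO:9999999", go_term = "expression-inferred decoy",
        evidence_code = sample(bad_ev, nrow(modules), replace = TRUE),
        stringsAsFactors = FALSE)
      go <- rbind(go, noise, decoy)
    }
    list(matrix = X, go = go, modules = modules)
  })
}

methyl_context <- function(chromchars, pos, strand) {
  L <- length(chromchars)
  if (strand == "+") {
    b1 <- if (pos + 1L <= L) chromchars[pos + 1L] else ""
    b2 <- if (pos + 2L <= L) chromchars[pos + 2L] else ""
    if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
  } else {
    b1 <- if (pos - 1L >= 1L) chromchars[pos - 1L] else ""
    b2 <- if (pos - 2L >= 1L) chromchars[pos - 2L] else ""
    if (b1 == "C") "CG" else if (b2 == "C") "CHG" else "CHH"
  }
}

#' Simulate a methylome with set-dependent rates
#'
#' Each genomic position is assigned the methylation rate of the region it
#' falls in (label x region rates from the spec): coding regions of labeled
#' genes claim their positions first, then the upstream/downstream flanks
#' (first gene wins where flanks of neighboring genes overlap). Every
#' cytosine (both strands) at a positive-rate position then receives one
#' independent Bernoulli methylation call; the context (CG/CHG/CHH) is read
#' off the local sequence.
#'
#' @param spec A [simulation_spec()].
#' @param annotation The simulated `genome_annotation`.
#' @param labels Data frame with `gene_id`, `label` (e.g. the truth table).
#' @param flank Flank length (default 500).
#' @return Methylation call data frame (chrom, pos, strand, context).
#' @export
simulate_methylome <- function(spec, annotation, labels, flank = 500L) {
  rates <- spec$methylation$rates
  with_seed(spec$seed + 2002L, {
    chars <- lapply(as.list(as.character(annotation$sequences)), function(s)
      strsplit(s, "")[[1L]])
    rate_of <- lapply(chars, function(cc) rep(NA_real_, length(cc)))
    ivs <- lapply(seq_len(nrow(labels)), function(i) {
      if (!labels$label[i] %in% rownames(rates)) return(NULL)
      gene_region_intervals(annotation, labels$gene_id[i], flank, "span")
    })
    assign_rate <- function(part, rate) {
      if (is.null(part)) return()
      idx <- part$start:part$end
      take <- idx[is.na(rate_of[[part$chrom]][idx])]
      rate_of[[part$chrom]][take] <<- rate
    }
    # coding regions claim positions first, then flanks
    for (i in seq_len(nrow(labels))) {
      if (is.null(ivs[[i]])) next
      for (part in ivs[[i]]$coding)
        assign_rate(part, rates[labels$label[i], "coding"])
    }
    for (i in seq_len(nrow(labels))) {
      if (is.null(ivs[[i]])) next
      assign_rate(ivs[[i]]$upstream, rates[labels$label[i], "upstream"])
      assign_rate(ivs[[i]]$downstream, rates[labels$label[i], "downstream"])
    }
    rows <- list()
    for (chrom in names(chars)) {
      cc <- chars[[chrom]]
      rr <- rate_of[[chrom]]
      eligible <- which(!is.na(rr) & rr > 0 & cc %in% c("C", "G"))
      if (!length(eligible)) next
      hit <- eligible[stats::runif(length(eligible)) < rr[eligible]]
      for (p in hit) {
        strand <- if (cc[p] == "C") "+" else "-"
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = p, strand = strand,
          context = methyl_context(cc, p, strand), stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, rows)
    if (is.null(calls))
      calls <- data.frame(chrom = character(0), pos = integer(0),
                          strand = character(0), context = character(0),
                          stringsAsFactors = FALSE)
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    calls
  })
}

#' Simulate accession SNPs with a tunable non-synonymous bias
#'
#' Places biallelic SNPs at distinct spliced-CDS sites of representative
#' models. The synonymous/non-synonymous mix targets `target_ratio`:
#' sites are drawn, each site's three alternate bases are classified against
#' the reference codon, and consequence classes are assigned to fill the
#' target quotas (sites that can only yield one class keep it). Accession
#' calls carry the alternate in 1..n-1 accessions, N calls at
#' `n_call_frac`, and a third allele is injected at `multiallelic_frac` of
#' sites (which [filter_biallelic()] must then exclude).
#'
#' @param spec A [simulation_spec()].
#' @param annotation The simulated `genome_annotation`.
#' @return SNP data frame (chrom, pos, ref, acc01..accNN) with the per-site
#'   planted verdicts attached as attribute `truth`.
#' @export
simulate_accession_snps <- function(spec, annotation) {
  sp <- spec$snp
  with_seed(spec$seed + 3003L, {
    genes <- Filter(function(g) g$biotype == "protein_coding",
                    annotation$genes)
    maps <- do.call(rbind, lapply(genes, cds_position_map))
    cds_of <- vapply(genes, function(g) spliced_cds_chr(annotation, g), "")
    usable <- (nchar(cds_of) %/% 3L) * 3L
    maps <- maps[maps$cds_pos <= usable[maps$gene_id], , drop = FALSE]
    # vectorized consequence classes of every site's three alternates
    ci <- (maps$cds_pos - 1L) %/% 3L + 1L
    pic_all <- (maps$cds_pos - 1L) %% 3L + 1L
    codon_all <- substr(cds_of[maps$gene_id], (ci - 1L) * 3L + 1L, ci * 3L)
    ref_cs_all <- substr(codon_all, pic_all, pic_all)
    code <- Biostrings::GENETIC_CODE
    ref_aa <- unname(code[codon_all])
    syn_alts <- vector("list", nrow(maps))
    non_alts <- vector("list", nrow(maps))
    for (b in c("A", "C", "G", "T")) {
      mut <- codon_all
      substr(mut, pic_all, pic_all) <- b
      is_syn <- unname(code[mut]) == ref_aa
      usable_b <- b != ref_cs_all
      for (i in which(usable_b & is_syn)) syn_alts[[i]] <- c(syn_alts[[i]], b)
      for (i in which(usable_b & !is_syn)) non_alts[[i]] <- c(non_alts[[i]], b)
    }
    # per-class site quotas meet the target ratio exactly (up to rounding):
    # synonymous SNPs are drawn from synonymous-capable sites only
    n <- min(sp$n_snps, nrow(maps))
    if (n < sp$n_snps)
      warnf("only %d CDS sites available for %d requested SNPs", n, sp$n_snps)
    want_syn <- round(n / (1 + sp$target_ratio))
    syn_pool <- which(lengths(syn_alts) > 0L)
    non_pool <- which(lengths(non_alts) > 0L)
    n_syn <- min(want_syn, length(syn_pool))
    if (n_syn < want_syn)
      warnf("only %d synonymous-capable sites for a quota of %d",
            n_syn, want_syn)
    syn_sites <- if (n_syn) sample(syn_pool, n_syn) else integer(0)
    non_pool <- setdiff(non_pool, syn_sites)
    n_non <- min(n - n_syn, length(non_pool))
    non_sites <- if (n_non) sample(non_pool, n_non) else integer(0)
    take <- c(syn_sites, non_sites)
    verdict <- rep(c("synonymous", "nonsynonymous"), c(n_syn, n_non))
    sites <- maps[take, , drop = FALSE]
    info <- lapply(seq_along(take), function(k)
      list(syn = syn_alts[[take[k]]], non = non_alts[[take[k]]]))
    n <- length(take)

    nacc <- sp$n_accessions
    acc_names <- sprintf("acc%02d", seq_len(nacc))
    chromchars <- lapply(as.list(as.character(annotation$sequences)),
                         function(s) strsplit(s, "")[[1L]])
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      pick <- info[[i]][[if (verdict[i] == "synonymous") "syn" else "non"]]
      alt_cs <- pick[sample.int(length(pick), 1L)]
      minus <- sites$strand[i] == "-"
      ref_g <- chromchars[[sites$chrom[i]]][sites$genomic_pos[i]]
      alt_g <- if (minus) COMPLEMENT[[alt_cs]] else alt_cs
      calls <- rep(ref_g, nacc)
      carriers <- sample.int(nacc, sample.int(nacc - 1L, 1L))
      calls[carriers] <- alt_g
      calls[stats::runif(nacc) < sp$n_call_frac] <- "N"
      rows[[i]] <- c(list(chrom = sites$chrom[i], pos = sites$genomic_pos[i],
                          ref = ref_g), stats::setNames(as.list(calls),
                                                        acc_names))
    }
    snps <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    n_multi <- round(sp$multiallelic_frac * n)
    multi_ix <- if (n_multi) sample.int(n, n_multi) else integer(0)
    for (i in multi_ix) {
      present <- unique(unlist(snps[i, acc_names]))
      third <- setdiff(c("A", "C", "G", "T"), c(present, snps$ref[i]))
      if (!length(third)) next
      victim <- acc_names[sample.int(nacc, 1L)]
      snps[i, victim] <- third[1L]
    }
    o <- order(snps$chrom, snps$pos)
    truth <- data.frame(gene_id = sites$gene_id, verdict = verdict,
                        multiallelic = seq_len(n) %in% multi_ix,
                        stringsAsFactors = FALSE)[o, , drop = FALSE]
    snps <- snps[o, , drop = FALSE]
    rownames(snps) <- rownames(truth) <- NULL
    attr(snps, "truth") <- truth
    snps
  })
}

#' Simulate per-isoform localization predictions
#'
#' Draws each gene's compartment from its label's probability vector and a
#' Reliability Class from the spec's weights. `n_tie_genes` genes get a
#' second isoform predicting a different organellar/secretory compartment
#' at the same RC, exercising the Uncertain rule.
#'
#' @param spec A [simulation_spec()].
#' @param truth Data frame with `gene_id`, `label`.
#' @return Prediction data frame (isoform_id, gene_id, compartment,
#'   reliability_class).
#' @export
simulate_localization_predictions <- function(spec, truth) {
  lc <- spec$localization
  with_seed(spec$seed + 4004L, {
    comp <- vapply(truth$label, function(lb)
      sample(colnames(lc$probs), 1L, prob = lc$probs[lb, ]), "")
    rc <- sample.int(5L, nrow(truth), replace = TRUE, prob = lc$rc_probs)
    preds <- data.frame(isoform_id = paste0(truth$gene_id, ".1"),
                        gene_id = truth$gene_id, compartment = unname(comp),
                        reliability_class = rc, stringsAsFactors = FALSE)
    n_tie <- min(lc$n_tie_genes, nrow(truth))
    if (n_tie) {
      tie_ix <- sample.int(nrow(truth), n_tie)
      cms <- setdiff(COMPARTMENTS, "Other")
      extra <- lapply(tie_ix, function(i) {
        first <- if (preds$compartment[i] %in% cms) preds$compartment[i]
                 else sample(cms, 1L)
        preds$compartment[i] <<- first
        data.frame(isoform_id = paste0(preds$gene_id[i], ".2"),
                   gene_id = preds$gene_id[i],
                   compartment = sample(setdiff(cms, first), 1L),
                   reliability_class = preds$reliability_class[i],
                   stringsAsFactors = FALSE)
      })
      preds <- rbind(preds, do.call(rbind, extra))
    }
    preds
  })
}
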