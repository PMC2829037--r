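mk_snp <- function(chrom, pos, ref, calls) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   stringsAsFactors = FALSE)
  for (i in seq_along(calls)) df[[sprintf("acc%02d", i)]] <- calls[i]
  df
}

test_that("biallelic filtering counts alleles across reference and calls", {
  snps <- rbind(
    mk_snp("c", 1, "A", c("A", "A", "N", "G")),   # {A,G} -> kept
    mk_snp("c", 2, "A", c("A", "G", "T", "A")),   # {A,G,T} -> multi-allelic
    mk_snp("c", 3, "A", c("A", "N", "A", "A")),   # monomorphic
    mk_snp("c", 4, "C", c("T", "T", "T", "T")))   # ref + T -> kept
  fb <- filter_biallelic(snps)
  expect_identical(fb$snps$pos, c(1L, 4L))
  expect_identical(fb$n_multiallelic, 1L)
  expect_identical(fb$n_monomorphic, 1L)
  # planted multi-allelic fraction comes back out
  spec <- small_sim_spec(seed = 91)
  sim <- simulate_lineage_genomes(spec)
  snps2 <- simulate_accession_snps(spec, sim$annotation)
  truth <- attr(snps2, "truth")
  fb2 <- filter_biallelic(snps2)
  expect_identical(fb2$n_multiallelic, sum(truth$multiallelic))
})

test_that("CDS location arithmetic is exact on plus, minus, and spliced genes", {
  ann <- tiny_annotation()
  # plus-strand two-exon gene: CDS starts at 11; position 17 is codon 3,
  # position 1 of the codon
  loc <- locate_in_cds(ann, "TG1", 17)
  expect_identical(loc$codon_index, 3L)
  expect_identical(loc$position_in_codon, 1L)
  expect_identical(loc$reference_codon, "GAA")
  # a position in the second exon maps through the hand-spliced coordinates:
  # genomic 31 is spliced position 10 -> codon 4, position 1 ("TGG")
  loc2 <- locate_in_cds(ann, "TG1", 31)
  expect_identical(loc2$codon_index, 4L)
  expect_identical(loc2$position_in_codon, 1L)
  expect_identical(loc2$reference_codon, "TGG")
  # intronic and intergenic positions are outside the CDS
  expect_null(locate_in_cds(ann, "TG1", 25))
  expect_null(locate_in_cds(ann, "TG1", 5))
  # minus-strand gene: genomic end is spliced position 1
  loc3 <- locate_in_cds(ann, "TG2", 87)
  expect_identical(loc3$codon_index, 1L)
  expect_identical(loc3$position_in_codon, 1L)
  expect_identical(loc3$reference_codon, "ATG")
})

test_that("consequence classification matches the exhaustive codon oracle", {
  # a fourfold site
  expect_identical(classify_consequence("GCT", 3, "C"), "synonymous")
  # tryptophan has a single codon: every change is non-synonymous
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                   substr("TGG", p, p)))
    expect_identical(classify_consequence("TGG", p, b), "nonsynonymous")
  # CGA -> AGA keeps arginine
  expect_identical(classify_consequence("CGA", 1, "A"), "synonymous")
  # stop <-> amino acid is non-synonymous, stop -> stop synonymous
  expect_identical(classify_consequence("TAA", 1, "C"), "nonsynonymous")
  expect_identical(classify_consequence("TAA", 3, "G"), "synonymous")
  # N codons are unclassifiable
  expect_true(is.na(classify_consequence("ANA", 1, "C")))
  expect_error(classify_consequence("GCT", 1, "G"), "equals the reference")
  # full enumeration: 64 codons x 3 positions x 3 alternates against a
  # direct translate-and-compare oracle
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (codon in names(code)) {
    for (p in 1:3) {
      for (alt in setdiff(bases, substr(codon, p, p))) {
        mutated <- codon
        substr(mutated, p, p) <- alt
        want <- if (code[[codon]] == code[[mutated]]) "synonymous"
                else "nonsynonymous"
        expect_identical(classify_consequence(codon, p, alt), want)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_identical(n_checked, 576L)
})

test_that("minus-strand SNPs are complemented before classification", {
  ann <- tiny_annotation()
  # TG2 codon 1 is ATG (coding strand); genomic position 85 carries the
  # complement of its third base, so the genome shows C and a genomic C>T
  # call classifies as coding-strand G>A
  chrom <- as.character(ann$sequences$chrT)
  ref_g <- substr(chrom, 85, 85)  # third base of codon 1 on the genome
  expect_identical(ref_g, "C")    # codon pos 3 'G' complemented
  snp <- mk_snp("chrT", 85, ref_g, c("C", "T", "C", "C"))
  calls <- classify_coding_snps(snp, ann)
  expect_identical(calls$gene_id, "TG2")
  expect_identical(calls$position_in_codon, 3L)
  expect_identical(calls$alternate_base, "A")  # genomic T -> coding A
  # ATG -> ATA changes Met to Ile
  expect_identical(calls$verdict, "nonsynonymous")
  # a reference base conflicting with the genome is a data-integrity error
  bad <- mk_snp("chrT", 85, "A", c("C", "T", "C", "C"))
  expect_error(classify_coding_snps(bad, ann), "conflicts with genome")
})

test_that("strand mirror images classify identically", {
  cds <- "ATGGCTGAATGGTTCTAA"
  chrp <- paste0(strrep("A", 10), cds, strrep("A", 10))
  chrm <- paste0(strrep("T", 10),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(cds))), strrep("T", 10))
  plus <- genome_annotation(list(gene_model("G", "c", "+", list(
    transcript_model("G.1", data.frame(start = 11, end = 28))))),
    Biostrings::DNAStringSet(c(c = chrp)))
  minus <- genome_annotation(list(gene_model("G", "c", "-", list(
    transcript_model("G.1", data.frame(start = 11, end = 28))))),
    Biostrings::DNAStringSet(c(c = chrm)))
  # the same coding-strand change at spliced position 6 (codon 2, pos 3)
  snp_p <- mk_snp("c", 16, "T", c("G", "T", "T", "T"))
  pos_m <- 11 + (28 - 11) - (16 - 11)     # mirrored genomic position
  snp_m <- mk_snp("c", pos_m, "A", c("C", "A", "A", "A"))
  vp <- classify_coding_snps(snp_p, plus)
  vm <- classify_coding_snps(snp_m, minus)
  expect_identical(vp$verdict, vm$verdict)
  expect_identical(vp$codon_index, vm$codon_index)
  expect_identical(vp$position_in_codon, vm$position_in_codon)
  expect_identical(vp$reference_codon, vm$reference_codon)
  expect_identical(vp$alternate_base, vm$alternate_base)
})

test_that("per-gene densities and set ratios follow the definitions", {
  dens <- data.frame(gene_id = "G", cds_length = 300L, n_snps = 3L,
                     n_nonsyn = 2L, n_syn = 1L,
                     snp_per_100bp = 1, nonsyn_per_100bp = 2 / 3,
                     syn_per_100bp = 1 / 3)
  r <- set_level_ratio(dens)
  expect_equal(r$ratio_density_mean, 2)
  expect_equal(r$ratio_total_counts, 2)
  expect_identical(r$n_more_nonsyn, 1L)
  # symmetric set gives ratio 1 in both modes
  sym <- data.frame(gene_id = c("A", "B"), cds_length = 300L, n_snps = 4L,
                    n_nonsyn = 2L, n_syn = 2L, snp_per_100bp = 4 / 3,
                    nonsyn_per_100bp = 2 / 3, syn_per_100bp = 2 / 3)
  expect_equal(set_level_ratio(sym)$ratio, 1)
  expect_equal(set_level_ratio(sym, "total_counts")$ratio, 1)
  # zero synonymous total is flagged infinite
  zs <- transform(dens, n_syn = 0L, syn_per_100bp = 0)
  rz <- set_level_ratio(zs)
  expect_true(rz$infinite_ratio)
  expect_identical(rz$ratio, Inf)
})

test_that("simulated SNPs recover the target ratio and conserve counts", {
  spec <- small_sim_spec(seed = 97)
  sim <- simulate_lineage_genomes(spec)
  ann <- filter_te_and_pseudogenes(sim$annotation)
  snps <- simulate_accession_snps(spec, ann)
  truth <- attr(snps, "truth")
  fb <- filter_biallelic(snps)
  calls <- classify_coding_snps(fb$snps, ann)
  # verdicts match the generator's planted verdicts site by site
  key <- paste(fb$snps$chrom, fb$snps$pos)
  tkey <- paste(snps$chrom, snps$pos)
  planted <- truth$verdict[match(key, tkey)]
  got <- calls$verdict[match(key, paste(calls$chrom, calls$pos))]
  ok <- !is.na(got)
  expect_gt(mean(got[ok] == planted[ok]), 0.999)
  # density conservation: per-gene counts sum to the classified total
  dens <- per_gene_densities(calls, ann)
  expect_identical(sum(dens$n_snps), sum(!is.na(calls$verdict)))
  expect_identical(sum(dens$n_nonsyn) + sum(dens$n_syn), sum(dens$n_snps))
  # per-gene density arithmetic
  g <- dens[which(dens$n_snps > 0)[1], ]
  expect_equal(g$snp_per_100bp, 100 * g$n_snps / g$cds_length)
  # the 1:1 target ratio is recovered within Monte-Carlo error
  r <- set_level_ratio(dens, "total_counts")
  expect_gt(r$ratio, 0.8)
  expect_lt(r$ratio, 1.25)
})
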