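# Fixtures built in code at test time.

# A three-gene annotation with known sequences:
#   TG1: + strand, two exons with an intron, CDS ATGGCTGAA|TGGTTCTAA
#   TG2: - strand, single exon, CDS ATGGGATCCGAATTCAAGCTTGCATAA (coding strand)
#   TG3: + strand, single exon, CDS ATGGCCTAA, plus a shorter second isoform
tiny_annotation <- function() {
  base <- strsplit(paste(rep("ACGT", 60), collapse = ""), "")[[1L]]  # 240 bp
  put <- function(chars, start, s) {
    chars[start:(start + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]
    chars
  }
  cds1a <- "ATGGCTGAA"; cds1b <- "TGGTTCTAA"
  cds2 <- "ATGGGATCCGAATTCAAGCTTGCATAA"   # 27 nt, coding strand
  cds3 <- "ATGGCCTAA"
  base <- put(base, 11, cds1a)
  base <- put(base, 31, cds1b)
  base <- put(base, 61, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cds2))))
  base <- put(base, 121, cds3)
  chrom <- paste(base, collapse = "")
  g1 <- gene_model("TG1", "chrT", "+", list(
    transcript_model("TG1.1",
                     exons = data.frame(start = c(11, 31), end = c(19, 39)),
                     is_representative = TRUE,
                     has_transcript_support = TRUE)),
    known_function = TRUE)
  g2 <- gene_model("TG2", "chrT", "-", list(
    transcript_model("TG2.1",
                     exons = data.frame(start = 61, end = 87),
                     is_representative = TRUE)))
  g3 <- gene_model("TG3", "chrT", "+", list(
    transcript_model("TG3.1",
                     exons = data.frame(start = 121, end = 129)),
    transcript_model("TG3.2",
                     exons = data.frame(start = 121, end = 126))),
    known_function = FALSE)
  genome_annotation(
    list(g1, g2, g3),
    Biostrings::DNAStringSet(c(chrT = chrom)))
}

tiny_cds <- function() {
  list(cds1 = "ATGGCTGAATGGTTCTAA",
       cds2 = "ATGGGATCCGAATTCAAGCTTGCATAA",
       cds3 = "ATGGCCTAA")
}

# reduced simulation spec for unit tests (the full default spec is exercised
# by the acceptance suite)
small_sim_spec <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    n_ec = 12L, n_clade = 5L, n_species = 3L,
    n_clade_relatives = 1L, n_outgroups = 1L,
    protein_length_range = c(50L, 90L),
    n_te = 2L, n_pseudo = 1L,
    kb_background = 5L,
    kb_transfers = c(clade_to_ec = 1L, species_to_ec = 1L,
                     species_to_clade = 1L),
    expression = list(n_experiments = 40L, n_modules = 2L, module_size = 8L,
                      loading = 0.9, noise_sd = NULL, n_background = 60L,
                      go_noise = 0.1),
    snp = list(n_snps = 300L, target_ratio = 1.0, n_accessions = 20L,
               multiallelic_frac = 0.05, n_call_frac = 0.05))
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  do.call(simulation_spec, defaults)
}

# small all-protein scoring scheme alphabet for enumeration tests
SUB_ALPHABET <- c("A", "R", "N", "D")
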