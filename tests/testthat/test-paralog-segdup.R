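test_that("uncovered regions complement curated domains", {
  # [1,49] is dropped (< 75 aa), [101,200] kept
  r <- uncovered_regions(200, data.frame(start = 50, end = 100))
  expect_identical(r, data.frame(start = 101L, end = 200L))
  # no domains: the whole protein
  expect_identical(uncovered_regions(120), data.frame(start = 1L, end = 120L))
  # random layouts match a per-position coverage mask
  set.seed(41)
  for (k in 1:20) {
    L <- sample(100:400, 1)
    nd <- sample(0:4, 1)
    dom <- if (nd) {
      s <- sample(L, nd, replace = TRUE)
      data.frame(start = s, end = pmin(L, s + sample(10:80, nd, TRUE)))
    } else NULL
    got <- uncovered_regions(L, dom, min_len = 20)
    mask <- rep(TRUE, L)
    if (!is.null(dom))
      for (i in seq_len(nrow(dom))) mask[dom$start[i]:dom$end[i]] <- FALSE
    r <- rle(mask); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= 20
    expect_equal(got, data.frame(start = as.integer(starts[keep]),
                                 end = as.integer(ends[keep])),
                 ignore_attr = TRUE)
  }
})

test_that("novel-domain clustering is single linkage on identity edges", {
  set.seed(43)
  seg <- paste(sample(linspec:::AA20, 80, TRUE), collapse = "")
  # two identical regions form one cluster
  two <- cluster_novel_domains(c(r1 = seg, r2 = seg))
  expect_identical(unname(two["r1"]), unname(two["r2"]))
  expect_identical(length(unique(two)), 1L)
  # unrelated random regions never link
  zero_edges <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    a <- paste(sample(linspec:::AA20, 80, TRUE), collapse = "")
    b <- paste(sample(linspec:::AA20, 80, TRUE), collapse = "")
    cl <- cluster_novel_domains(c(a = a, b = b))
    zero_edges <- zero_edges + length(cl)
  }
  expect_identical(zero_edges, 0L)
  # A~B, B~C but A and C unrelated: single linkage joins all three
  half1 <- paste(sample(linspec:::AA20, 80, TRUE), collapse = "")
  half2 <- paste(sample(linspec:::AA20, 80, TRUE), collapse = "")
  bridge <- paste0(substr(half1, 1, 80), substr(half2, 1, 80))
  cl3 <- cluster_novel_domains(c(A = half1, B = bridge, C = half2),
                               min_aln_len = 60)
  expect_identical(length(unique(cl3)), 1L)
  expect_setequal(names(cl3), c("A", "B", "C"))
})

test_that("families form shared-domain connected components", {
  doms <- data.frame(protein_id = c("P1", "P2", "P2", "P3"),
                     domain_id = c("D1", "D1", "D2", "D2"))
  fam <- build_families(doms, paste0("P", 1:3))
  expect_identical(fam$n_families, 1L)
  expect_setequal(fam$families$protein_id, c("P1", "P2", "P3"))
  expect_equal(fam$classified_fraction, 1)
  # identical-composition mode separates P1/P3 from P2
  famc <- build_families(doms, paste0("P", 1:3), mode = "composition")
  expect_identical(famc$n_families, 0L)  # all compositions unique
  # domain-less proteins are unclassified
  none <- build_families(doms[0, ], paste0("P", 1:4))
  expect_identical(none$n_families, 0L)
  expect_equal(none$classified_fraction, 0)
  # planted two-member families are recovered exactly, order-invariant
  doms10 <- data.frame(
    protein_id = paste0("Q", rep(1:20)),
    domain_id = paste0("D", rep(1:10, each = 2)))
  f10 <- build_families(doms10, paste0("Q", 1:20))
  expect_identical(f10$n_families, 10L)
  shuf <- doms10[sample(nrow(doms10)), ]
  f10b <- build_families(shuf, paste0("Q", 1:20))
  members <- function(f) sort(vapply(split(f$families$protein_id,
                                           f$families$family_id),
                                     paste, "", collapse = "+"))
  expect_identical(unname(members(f10)), unname(members(f10b)))
})

test_that("similar-pair selection truncates, deduplicates, and respects cutoff", {
  set.seed(47)
  base <- paste(sample(linspec:::AA20, 100, TRUE), collapse = "")
  fam <- vapply(1:8, function(i)
    with_seed(600 + i, linspec:::mutate_protein(base, 0.1)), "")
  names(fam) <- paste0("F", 1:8)
  lone <- paste(sample(linspec:::AA20, 100, TRUE), collapse = "")
  prots <- Biostrings::AAStringSet(c(fam, L1 = lone))
  pairs <- select_similar_pairs(prots, max_hits_per_query = 5L)
  # per query at most 5 subjects -> F genes each contribute <= 5 pairs
  expect_lte(max(table(c(pairs$gene_a, pairs$gene_b))), 8L)
  counts <- table(factor(c(pairs$gene_a, pairs$gene_b),
                         levels = names(prots)))
  # unordered dedup: no pair appears twice
  expect_false(any(duplicated(pairs[, c("gene_a", "gene_b")])))
  expect_true(all(pairs$gene_a < pairs$gene_b))
  # the unrelated protein pairs with nothing
  expect_false("L1" %in% c(pairs$gene_a, pairs$gene_b))
  # nothing below cutoff -> empty
  none <- select_similar_pairs(
    Biostrings::AAStringSet(c(A = lone, B = base)), e_cutoff = 1e-30)
  expect_identical(nrow(none), 0L)
})

test_that("collinear chaining follows the gap rule and matches enumeration", {
  mkpairs <- function(pa, pb, ca = "c1", cb = "c2")
    data.frame(gene_a = paste0("a", seq_along(pa)),
               gene_b = paste0("b", seq_along(pb)),
               chrom_a = ca, pos_a = pa, chrom_b = cb, pos_b = pb,
               stringsAsFactors = FALSE)
  # five pairs on a clean diagonal with 10 kb gaps: one chain of 5
  d5 <- mkpairs(seq(1e5, 5e5, 1e5), seq(2e5, 6e5, 1e5))
  ch <- chain_collinear_pairs(d5)
  expect_identical(length(ch), 1L)
  expect_identical(nrow(ch[[1]]$pairs), 5L)
  expect_lte(max(diff(sort(ch[[1]]$pairs$pos_a))), 1e5)
  # one 150 kb gap splits the diagonal; the short fragment (< min_pairs)
  # is dropped
  d5b <- mkpairs(c(1e5, 1.1e5, 1.2e5, 2.7e5, 2.8e5),
                 c(1e5, 1.1e5, 1.2e5, 2.7e5, 2.8e5))
  ch2 <- chain_collinear_pairs(d5b, min_pairs = 3L)
  expect_identical(length(ch2), 1L)
  expect_identical(nrow(ch2[[1]]$pairs), 3L)
  # the trivial self-diagonal is excluded
  selfp <- data.frame(gene_a = "g1", gene_b = "g1", chrom_a = "c1",
                      pos_a = 100, chrom_b = "c1", pos_b = 100)
  expect_identical(length(chain_collinear_pairs(selfp, min_pairs = 1L)), 0L)
  # chain score never decreases when max_gap increases
  set.seed(53)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    pp <- mkpairs(sample.int(4e5, n), sample.int(4e5, n))
    s1 <- chain_collinear_pairs(pp, max_gap = 5e4, min_pairs = 1L)
    s2 <- chain_collinear_pairs(pp, max_gap = 2e5, min_pairs = 1L)
    top <- function(ch) if (length(ch)) max(vapply(ch, `[[`, 0, "score")) else 0
    expect_gte(top(s2), top(s1))
    # DP top chain equals exhaustive subset enumeration
    expect_identical(as.integer(top(s1)),
                     oracle_best_chain(pp$pos_a, pp$pos_b, 5e4))
    expect_identical(as.integer(top(s2)),
                     oracle_best_chain(pp$pos_a, pp$pos_b, 2e5))
  }
})

test_that("block membership fractions count planted duplications", {
  # a planted 5-gene duplicated block between two chromosome segments
  pos_a <- seq(1e5, 5e5, 1e5)
  pos_b <- seq(1.2e6, 1.6e6, 1e5)
  pairs <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                      chrom_a = "c1", pos_a = pos_a,
                      chrom_b = "c1", pos_b = pos_b)
  chains <- chain_collinear_pairs(pairs)
  genes <- data.frame(
    gene_id = c(paste0("a", 1:5), paste0("b", 1:5), paste0("x", 1:6)),
    chrom = "c1",
    pos = c(pos_a, pos_b, c(6e5, 7e5, 8e5, 9e5, 1e6, 1.1e6)),
    label = c(rep("CLADE_SPECIFIC", 10), rep("EC", 6)))
  fb <- fraction_in_blocks(genes, chains)
  cl <- fb$fractions[fb$fractions$label == "CLADE_SPECIFIC", ]
  ec <- fb$fractions[fb$fractions$label == "EC", ]
  expect_identical(cl$n_in_block, 10L)
  expect_equal(cl$pct_in_block, 100)
  expect_identical(ec$n_in_block, 0L)
  expect_equal(ec$pct_outside, 100)
  # boundary genes are inside (inclusive ends)
  edge <- data.frame(gene_id = "e", chrom = "c1", pos = 1e5, label = "EC")
  expect_true(fraction_in_blocks(edge, chains)$in_block)
  # no chains: everything outside
  none <- fraction_in_blocks(genes, list())
  expect_true(all(none$fractions$pct_outside == 100))
})
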