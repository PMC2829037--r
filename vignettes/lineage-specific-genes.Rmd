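---
title: "Identifying and characterizing lineage-specific genes with linspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing lineage-specific genes with linspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linspec)
```

## The problem

Lineage-specific ("orphan") genes are genes of one taxonomic group with no
detectable sequence similarity to genes of any other lineage. Given a focal
species inside a clade inside a kingdom, linspec partitions the focal
proteome into three sets by staged homology filtering:

1. **Stage 1 — outside the clade.** Every representative protein is searched
   against nucleotide databases from species outside the clade (genomic
   assemblies and EST-assembly transcripts). Any hit with E-value strictly
   below the cutoff (default `1e-5`) marks the gene *evolutionarily
   conserved* (EC).
2. **Stage 2 — inside the clade.** The remainder is searched against
   transcript databases from clade relatives. A hit marks the gene
   *clade-specific*; no hit anywhere marks it *species-specific*.
3. **Stage 3 — knowledgebase review.** Both lineage-specific sets are
   searched against a taxonomy-labeled protein knowledgebase. A hit to a
   non-clade entry promotes the gene to EC; a species-specific gene hitting
   a clade entry moves to the clade-specific set. Each candidate move is an
   explicit `ReassignmentDecision`-style record with an accepted flag, so a
   human review (or the default auto-accept) leaves a complete audit trail
   and the final sets are reproducible from stored hits and decisions alone.

The three labels partition the proteome at every stage, moves at stage 3
only ever broaden conservation, and the threshold comparison is strict
(`E < cutoff`) everywhere.

## The search backend

Genome-scale surveys of this kind run BLAST. linspec ships a desk-scale
backend with the same semantics so the whole pipeline is executable and
testable in memory: six-frame translation for protein-vs-nucleotide
searches, optimal Smith–Waterman local alignment with affine gaps
(delegated to `Biostrings::pairwiseAlignment`), and Karlin–Altschul
statistics

$$E = K \, m \, n \, e^{-\lambda S},$$

with the published gapped BLOSUM62 constants as defaults
(gap open 11, extend 1, $K = 0.041$, $\lambda = 0.267$), all configurable
via `scoring_scheme()`. Translated frames are split at stop codons and each
inter-stop segment is aligned separately, so alignments never cross a stop
— mirroring how translated-search HSPs behave. Per (query, subject, frame)
only the best alignment is kept: the classifier needs the existence of one
significant hit, not HSP sets. For real data at scale, `read_search_hits()`
ingests 12-column tabular (outfmt-6-like) output from an external search
engine; every classifier entry point accepts such a hit table in place of
the built-in search.

Two numerical details worth stating: the E-value length `n` for translated
searches is the total translated length over all six frames, and segments
shorter than 5 residues are dropped during segmentation — at the default
constants even a perfect 4-residue alignment cannot reach `E < 1e-5`
against any database large enough to be interesting, so the floor only
removes provably irrelevant work.

## Gene models and coordinates

All coordinates are GFF3 convention — 1-based, inclusive, forward strand —
from file to internal structures; strand is applied only when sequences are
extracted. Each gene's statistics use one *representative* isoform: the
annotation's flag if present, otherwise the longest-CDS isoform, with ties
broken by the lexicographically smallest isoform id. The fallback is a
design choice (annotation releases rarely document their rule); it is
deterministic, which is what the downstream statistics need. A CDS whose
length is not a multiple of 3 is kept but flagged, and the longest in-frame
prefix is translated — real annotations contain such models and silently
dropping them would skew set-level counts.

"Upstream" and "downstream" are transcriptional everywhere: for a
minus-strand gene the 500 bp upstream flank is the genomic interval
`[gene_end + 1, gene_end + 500]`, reverse complemented. Flanks truncate at
chromosome ends and densities are taken over the truncated length.

## Characterization modules

**Genic features.** Exon counts, exon/intron/gene/CDS/protein lengths, GC
content of gene, exons, introns, CDS, and the three codon positions. N
bases are excluded from both numerator and denominator of GC (avoiding
masking-dependent bias). Set summaries report mean, sample SD (n−1), and
median; exon and intron lengths are pooled over all features of a set by
default, with a per-gene-mean mode available since summary tables of this
kind do not always state which convention they use. Set comparisons are
Welch's unequal-variance t-test and the 2×2 chi-square without continuity
correction (`compare_sets()`).

**Paralogous families.** Protein regions not covered by curated domains
(≥ 75 aa) are clustered by all-versus-all local alignment — an edge
requires > 45% identity over ≥ 75 aligned columns at `E < 1e-3` — into
"novel domains" by single linkage. Families are the connected components of
the protein graph linked by any shared domain id. Shared-domain linkage
(rather than identical-composition grouping) is the default because
identical-composition grouping would split multi-domain relatives into
separate families; both modes are exposed in `build_families()`.

**Segmental duplication.** Similar protein pairs (all-versus-all,
`E < 1e-10`, at most 5 subjects per query) are chained over the dot-plot of
each chromosome pair by dynamic programming: pairs strictly increasing on
both axes, chains broken when either axis gap exceeds 100 kb, unit score
(+1 per pair), chains below 4 pairs discarded, and the trivial
self-diagonal excluded. Unit scoring keeps the exhaustive-enumeration
oracle in the test suite exact; blocks are bounded by their first and last
member genes. `fraction_in_blocks()` reports per-set in/out-of-block
fractions with chi-square comparisons.

**Co-expression and GO.** Pearson correlations use pairwise-complete
observations; a profile with fewer than 3 complete pairs or zero variance
is undefined (`NA`), never 0. The co-expression cutoff is the 99th
percentile of the correlation of randomly sampled gene pairs
(`estimate_null_threshold()`, seeded and deterministic) — signed r, not
absolute, matching positive co-expression semantics, and the membership
rule is strict (`r > r*`). Pairs are sampled (default 10^6) rather than
enumerated, since all-pairs computation is quadratic in the gene count; the
sampling error of the percentile is checked against the closed-form null
(the t-transform $r = t/\sqrt{m-2+t^2}$) in the test suite. GO annotations
with evidence codes IEP, IEA, and RCA are removed before enrichment to
avoid circularity with expression-derived annotation. Enrichment is the
one-sided Fisher exact test with Storey q-values: $\pi_0$ estimated on the
λ grid 0.05–0.95 with a df = 3 smoothing spline evaluated at the top of the
grid, `q = π₀·p·n/rank` with step-up monotonicity. For lists shorter than
100 p-values the smoother is unstable and the package falls back to
Benjamini–Hochberg (π₀ = 1). Five-group over-representation
(`group_overrepresentation()`) runs the same Fisher machinery at FDR 1%.

**Methylation density.** Density is methylcytosine calls per 100 bp per
region, both strands pooled, in the upstream-500, coding, and
downstream-500 regions of the representative model. "Coding region"
defaults to the genomic span from first to last CDS base — the calls are
genomic positions, so introns belong in the denominator — with a spliced
mode available; output is flagged with the mode used. CG/CHG/CHH contexts
are carried through and can be reported per class, pooled by default.

**SNP consequences.** Sites are filtered to biallelic: the distinct non-N
bases across the reference and all accession calls must number exactly two
(monomorphic-after-N-removal sites are dropped and counted separately).
SNPs map through the spliced, strand-corrected CDS — splice first, then
index codons — and each is classified independently against the reference
codon under the standard genetic code (multiple SNPs in one codon are not
haplotype-combined). On minus-strand genes the alternate base is
complemented first; a reference base conflicting with the genome FASTA is a
data-integrity error, not a silent skip. The set-level
non-synonymous:synonymous ratio is reported both as the ratio of mean
per-gene densities (default) and as the total-count ratio, since published
ratios rarely state which aggregation they use; both are computed on
unrounded values.

**Localization.** Per-isoform predictions (compartment + Reliability Class
1–5, 1 best) collapse to gene level: among
chloroplast/mitochondrion/secretory predictions the best RC wins; distinct
compartments tied at that best RC give *Uncertain*; no organellar or
secretory prediction at all gives *Other*. Two isoforms agreeing on the
same compartment at equal RC are **not** a tie — the stricter reading keeps
the Uncertain class as small as real data shows it to be. The predictor
itself is an input adapter; linspec never re-implements it.

## The synthetic study conditions

`simulation_spec()` fixes the conditions every test and the acceptance
script run under; its defaults *are* the study conditions and are not
tuned per test:

* 70 conserved, 20 clade-specific, 10 species-specific genes on two
  chromosomes, proteins 60–150 aa, exon count 1 + Poisson(1.5), introns
  70–200 bp, base composition GC 0.36, plus a handful of
  transposable-element genes and pseudogenes exercising the biotype filter.
* Divergence tiers of 20% (clade) and 45% (outgroup) are per-residue
  amino-acid substitution probabilities, with fresh synonymous codon choice
  at back-translation adding nucleotide-level noise that leaves the protein
  untouched. Substitution at the amino-acid level is what creates
  detectability tiers for a protein-space search: 55% residue identity over
  60+ aa is solidly detectable at `E < 1e-5`, while the same figure imposed
  on nucleotides would destroy most codons and push conserved homologs
  below any alignment-statistics floor, contradicting the recoverability
  the tiers are designed to plant.
* Knowledgebase transfers (3 clade→EC, 2 species→EC, 3 species→clade by
  default) plant the stage-3 moves; the truth table records the expected
  final label.
* Expression: 60 experiments, 5 latent modules of 10 genes with loading
  0.9 (noise SD defaults to $\sqrt{1-\ell^2}$, unit variance), 200
  background genes, coherent per-module GO terms plus noise annotations
  including IEP/IEA/RCA decoys that the evidence filter must remove.
* Methylation: per-cytosine Bernoulli rates of 0.004/0.008/0.004
  (upstream/coding/downstream) for conserved genes and twice that for both
  lineage-specific sets — the doubled-coding-methylation contrast the
  comparison module must detect. Coding regions claim their positions
  before flanks where neighboring genes' regions overlap, and each cytosine
  is drawn exactly once.
* SNPs: 20 accessions, target non-synonymous:synonymous ratio 1.0 achieved
  by per-class site quotas (synonymous SNPs are drawn from
  synonymous-capable sites — about a third of CDS positions — so the
  realized ratio hits the target instead of drifting toward the raw
  mutational expectation), 2% multi-allelic sites and 5% N calls injected
  to exercise the filters.
* Localization: compartment probabilities per label mimic a
  secretory-enriched clade-specific set (45% vs 19% background), plus two
  planted equal-RC ties exercising the Uncertain rule.

Everything is deterministic per seed; the generators derive fixed offsets
from the master seed so the streams stay independent.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: phylogenetic branch-length structure and
rate heterogeneity (substitutions are i.i.d. per site), indels (off by
default), linkage disequilibrium among SNPs, UTRs and trans-splicing,
array-normalization artifacts in expression, and any biology in the GO
graph beyond flat term membership.

## Problem sizes

The test suite runs most modules on a reduced fixture (12/5/3 genes, one
clade relative, one outgroup) and reserves the full default conditions for
the acceptance checks: label recovery over 5 seeds, the SNP ratio at
10,000 SNPs (on 150–300 aa proteins so enough synonymous-capable sites
exist), the null-correlation calibration at 200,000 sampled pairs over
2,000 genes × 20 experiments, Welch type-I error over 10,000 null
simulations, and Storey π₀ on 10,000 uniform p-values. These sizes are the
package's chosen study scale: large enough for the Monte-Carlo tolerances
asserted, small enough to run on a laptop core in minutes.

## Known limitations

* The built-in search is exhaustive Smith–Waterman per segment — correct,
  but not intended for genome-scale inputs; use external search output via
  `read_search_hits()` there.
* Chains only model parallel (same-orientation) collinearity; inverted
  blocks are not chained.
* The Storey smoother needs well-populated p-value lists; the BH fallback
  below 100 entries is deliberately conservative.
* Representative-model fallback may disagree with an annotation project's
  undocumented choice on real data; supply explicit flags to control it.
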