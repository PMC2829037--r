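# Independent oracles used across the suite. Each one recomputes a quantity
# by a route disjoint from the package implementation (enumeration, closed
# form, direct counting), so agreement is evidence, not tautology.

# --- exhaustive local alignment -------------------------------------------
# Enumerates every local alignment (alignments start and end with an aligned
# residue pair; affine gaps opened/extended inside) and returns the maximum
# score, floored at 0. Branch-and-bound pruning keeps it exact but feasible.
oracle_local_align <- function(q, s, mat, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  nq <- length(qc); ns <- length(sc)
  if (!nq || !ns) return(0)
  maxv <- max(mat)
  best <- 0
  rec <- function(i, j, score, last) {
    if (score > best) best <<- score
    bound <- score + maxv * min(nq - i + 1L, ns - j + 1L)
    if (bound <= best) return()
    if (i <= nq && j <= ns)
      rec(i + 1L, j + 1L, score + mat[qc[i], sc[j]], "M")
    if (i <= nq)
      rec(i + 1L, j, score - (if (last == "I") gap_extend
                              else gap_open + gap_extend), "I")
    if (j <= ns)
      rec(i, j + 1L, score - (if (last == "D") gap_extend
                              else gap_open + gap_extend), "D")
  }
  for (i0 in seq_len(nq))
    for (j0 in seq_len(ns))
      rec(i0 + 1L, j0 + 1L, mat[qc[i0], sc[j0]], "M")
  max(best, 0)
}

# --- codon-walk translation -----------------------------------------------
# Walks codons of one frame by hand; N codons are expanded over A/C/G/T and
# translate to the consensus amino acid if unique, else X. Stops are "*".
oracle_translate_frame <- function(nt, offset) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(nt, "")[[1L]]
  out <- character(0)
  i <- offset + 1L
  while (i + 2L <= length(chars)) {
    codon <- chars[i:(i + 2L)]
    if (any(codon == "N")) {
      expand <- expand.grid(lapply(codon, function(b)
        if (b == "N") c("A", "C", "G", "T") else b),
        stringsAsFactors = FALSE)
      aas <- unique(code[apply(expand, 1L, paste, collapse = "")])
      out <- c(out, if (length(aas) == 1L) aas else "X")
    } else {
      out <- c(out, code[[paste(codon, collapse = "")]])
    }
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# --- exhaustive collinear chain search ------------------------------------
# A subset of pairs is a valid chain iff, sorted by the first axis, both
# axes are strictly increasing and no consecutive gap exceeds max_gap.
# Returns the maximum subset size over all 2^n subsets.
oracle_best_chain <- function(pos_a, pos_b, max_gap) {
  n <- length(pos_a)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    ix <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(ix) <= best) next
    o <- order(pos_a[ix])
    a <- pos_a[ix][o]; b <- pos_b[ix][o]
    if (length(ix) > 1L) {
      da <- diff(a); db <- diff(b)
      if (any(da <= 0) || any(db <= 0) ||
          any(da > max_gap) || any(db > max_gap)) next
    }
    best <- length(ix)
  }
  best
}

# --- hypergeometric tail sum ----------------------------------------------
# One-sided (over-representation) Fisher p for the 2x2 table
# rbind(c(a, b), c(c, d)) via direct choose() arithmetic.
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + c_          # annotated
  n <- b + d           # not annotated
  k <- a + b           # set size
  kk <- max(0L, k - n):min(k, m)
  probs <- choose(m, kk) * choose(n, k - kk) / choose(m + n, k)
  sum(probs[kk >= a])
}

# --- Welch t-test from the textbook formulas ------------------------------
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1L) + vy^2 / (length(y) - 1L))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

# --- closed-form null PCC percentile --------------------------------------
# For i.i.d. normal profiles of length m, r = t / sqrt(m - 2 + t^2) with
# t ~ t(m - 2); the 99th percentile follows by transforming the t quantile.
oracle_null_pcc_quantile <- function(m, p = 0.99) {
  t <- stats::qt(p, df = m - 2)
  t / sqrt(m - 2 + t^2)
}

# --- direct Pearson formula -----------------------------------------------
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
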