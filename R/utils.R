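# Shared helpers: rounding, seeded evaluation, small sequence utilities.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero),
#' the convention used for every reported percentage in the package's summary
#' tables, rather than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)  # 0.3 0.4
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators do not perturb the session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# percentage of a count over a total, rounded half-up to 1 decimal
percent1 <- function(n, total) round_half_up(100 * n / total, 1)

# reverse complement of a character DNA string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# translate a coding-strand nucleotide string; returns list(protein, flags).
# Length not divisible by 3: longest in-frame prefix is translated and the
# sequence is flagged; an internal stop is flagged; a trailing stop is dropped.
translate_cds_chr <- function(nt) {
  flags <- character(0)
  len <- nchar(nt)
  usable <- (len %/% 3L) * 3L
  if (usable < len) flags <- c(flags, "cds_not_multiple_of_3")
  if (usable == 0L) {
    return(list(protein = "", flags = c(flags, "cds_too_short")))
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, usable)),
    if.fuzzy.codon = "solve"
  ))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE)) flags <- c(flags, "internal_stop")
  list(protein = aa, flags = flags)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
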