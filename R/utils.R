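#' @keywords internal
"_PACKAGE"

## Coordinates throughout the package are 0-based, half-open [start, end),
## matching BED-style conventions: a fragment [10, 32) has length 22 and its
## sequence is substr(ref, 11, 32) in R's 1-based indexing.

BASES <- c("A", "C", "G", "T")

## Illumina TruSeq small-RNA 3' adapter (RA3); configurable everywhere.
TRUSEQ_SMALLRNA_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's \code{.Random.seed} so that simulators are
#' deterministic for a given seed without disturbing the global RNG stream.
#'
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Random nucleotide sequences
#'
#' @param n number of sequences.
#' @param len integer vector of lengths (recycled).
#' @param gc target GC content in [0, 1].
#' @return character vector of sequences over A/C/G/T.
#' @keywords internal
random_seq <- function(n, len, gc = 0.5) {
  len <- rep_len(as.integer(len), n)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  total <- sum(len)
  bases <- sample(BASES, total, replace = TRUE, prob = p)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  vapply(seq_len(n), function(i) {
    paste(bases[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' GC fraction of sequences
#'
#' @param seqs character vector of nucleotide sequences.
#' @return numeric vector: (G+C) / length per sequence.
#' @export
gc_fraction <- function(seqs) {
  if (length(seqs) == 0L) return(numeric(0))
  n_gc <- nchar(gsub("[^GCgc]", "", seqs))
  n_gc / nchar(seqs)
}

## Pooled GC over a set of sequences: total G+C bases / total bases.
pooled_gc <- function(seqs) {
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L) return(NA_real_)
  sum(nchar(gsub("[^GCgc]", "", seqs))) / sum(nchar(seqs))
}

## Check a sequence vector is over the given alphabet.
assert_alphabet <- function(seqs, extra = "N", what = "read") {
  pat <- sprintf("^[ACGT%s]*$", extra)
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop(sprintf("invalid characters in %s sequence(s), e.g. '%s'",
                 what, seqs[which(bad)[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}
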