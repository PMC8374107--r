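## 3'-adapter trimming with cutadapt-style parameters: maximum error rate
## 0.1, minimum overlap 3, minimum retained length 15, untrimmed reads
## discarded.  Error counting is Hamming (substitutions only, no indels):
## short near-exact adapter matches dominate small-RNA data, and the
## substitution-only model admits an exact exhaustive-search oracle.  An
## occurrence is either the full adapter starting anywhere in the read, or
## a 3'-terminal adapter prefix of length >= min_overlap; 'N' in the read
## never matches.  Among qualifying occurrences the one with the fewest
## errors wins, ties broken by the leftmost adapter start.

#' Trimming configuration
#'
#' @param adapter 3' adapter sequence (A/C/G/T).
#' @param max_error_rate maximum fraction of mismatches per matched adapter
#'   length; the allowed error count is \code{floor(max_error_rate * k)}
#'   for a k-nt match.
#' @param min_overlap minimum 3'-terminal match length, nt.
#' @param min_length minimum retained insert length after trimming, nt.
#' @param discard_untrimmed drop reads in which no qualifying adapter
#'   occurrence is found (the default, as in the targeted protocol).
#' @return a \code{trim_config} list.
#' @export
trim_config <- function(adapter = TRUSEQ_SMALLRNA_ADAPTER,
                        max_error_rate = 0.1, min_overlap = 3L,
                        min_length = 15L, discard_untrimmed = TRUE) {
  stopifnot(max_error_rate >= 0, max_error_rate < 1,
            min_overlap >= 1L, min_length >= 1L, nchar(adapter) >= 1L)
  assert_alphabet(adapter, extra = "", what = "adapter")
  structure(list(adapter = adapter, max_error_rate = max_error_rate,
                 min_overlap = as.integer(min_overlap),
                 min_length = as.integer(min_length),
                 discard_untrimmed = isTRUE(discard_untrimmed)),
            class = "trim_config")
}

#' Locate the best qualifying adapter occurrence in each read
#'
#' Vectorised over reads: for every candidate adapter start, the matched
#' region is compared base by base against the adapter prefix of the same
#' length; occurrences qualify when full or 3'-terminal with length >=
#' min_overlap and error count <= floor(max_error_rate x length).
#'
#' @param seqs character vector of read sequences (A/C/G/T/N).
#' @param cfg a \code{\link{trim_config}}.
#' @return integer vector: 0-based position of the chosen adapter start
#'   (equals the retained insert length), or NA where no occurrence
#'   qualifies.
#' @export
trim_positions <- function(seqs, cfg) {
  stopifnot(inherits(cfg, "trim_config"))
  if (length(seqs) == 0L) return(integer(0))
  assert_alphabet(seqs, extra = "N", what = "read")
  m <- nchar(cfg$adapter)
  achars <- strsplit(cfg$adapter, "")[[1L]]
  out <- rep(NA_integer_, length(seqs))
  for (L in unique(nchar(seqs))) {
    ii <- which(nchar(seqs) == L)
    if (L == 0L) next
    mat <- matrix(unlist(strsplit(seqs[ii], ""), use.names = FALSE),
                  ncol = L, byrow = TRUE)
    best_err <- rep(Inf, length(ii))
    best_pos <- rep(NA_integer_, length(ii))
    for (p in seq_len(L)) {           # 1-based adapter start in the read
      k <- min(m, L - p + 1L)
      terminal <- (p + k - 1L) == L
      if (k < m && (!terminal || k < cfg$min_overlap)) next
      block <- mat[, p:(p + k - 1L), drop = FALSE]
      err <- rowSums(block != matrix(achars[seq_len(k)],
                                     nrow = length(ii), ncol = k,
                                     byrow = TRUE))
      ok <- err <= floor(cfg$max_error_rate * k) & err < best_err
      best_err[ok] <- err[ok]
      best_pos[ok] <- p - 1L          # leftmost wins ties (strict <)
    }
    out[ii] <- best_pos
  }
  out
}

#' Trim one read
#'
#' @param read a read sequence, or a list/data.frame row with
#'   \code{read_id} and \code{sequence}.
#' @param cfg a \code{\link{trim_config}}.
#' @return a list with \code{status} ("retained", "untrimmed",
#'   "too_short"), \code{sequence} (the trimmed insert, or NA when
#'   discarded) and \code{reason} (NA when retained).
#' @export
trim_read <- function(read, cfg = trim_config()) {
  seqs <- if (is.character(read)) read else read$sequence
  stopifnot(length(seqs) == 1L)
  res <- trim_set(data.frame(read_id = "r", sequence = seqs,
                             stringsAsFactors = FALSE), cfg)
  status <- res$status
  list(status = status,
       sequence = if (status == "retained") res$reads$sequence else
         NA_character_,
       reason = if (status == "retained") NA_character_ else status)
}

#' Trim a read set
#'
#' @param reads data.frame with \code{read_id} and \code{sequence} (an
#'   optional \code{library} column is carried through).
#' @param cfg a \code{\link{trim_config}}.
#' @return a list with \code{reads} (retained reads, sequences trimmed),
#'   \code{status} (per input read: retained / untrimmed / too_short) and
#'   \code{report} (counts: input, retained, untrimmed, too_short; the
#'   three outcomes partition the input exactly).
#' @export
trim_set <- function(reads, cfg = trim_config()) {
  stopifnot(is.data.frame(reads), inherits(cfg, "trim_config"))
  n <- nrow(reads)
  pos <- trim_positions(reads$sequence, cfg)
  status <- rep("retained", n)
  trimmed <- substr(reads$sequence, 1L, ifelse(is.na(pos),
                                               nchar(reads$sequence), pos))
  if (cfg$discard_untrimmed) status[is.na(pos)] <- "untrimmed"
  status[status == "retained" & nchar(trimmed) < cfg$min_length] <-
    "too_short"
  status[nchar(reads$sequence) == 0L] <- "too_short"  # empty reads
  keep <- status == "retained"
  out <- reads[keep, , drop = FALSE]
  out$sequence <- trimmed[keep]
  rownames(out) <- NULL
  report <- c(input = n, retained = sum(keep),
              untrimmed = sum(status == "untrimmed"),
              too_short = sum(status == "too_short"))
  list(reads = out, status = status, report = report)
}
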