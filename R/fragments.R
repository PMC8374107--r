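## Predominant-fragment calling from read-termini consensus, in the style
## of FlaiMapper: 5' peaks are strict local maxima of the read-start
## profile, each peak's 3' end is the modal end among reads starting near
## the peak, and near-duplicate fragments are merged into the better
## supported call.  Calling is per reference; fragments never span
## references.

#' Fragment-caller configuration
#'
#' @param peak_window w, nt: 5' peaks must exceed all start counts within
#'   +-w; reads starting within +-w of a peak vote for its 3' end; merge
#'   radius for near-duplicate fragments.
#' @param min_support minimum reads required at a 5' peak.
#' @param assignment_tolerance nt: a read supports a fragment when both its
#'   termini are within this distance of the fragment's termini.
#' @return a \code{caller_config} list.
#' @export
caller_config <- function(peak_window = 2L, min_support = 2L,
                          assignment_tolerance = 2L) {
  stopifnot(peak_window >= 0L, min_support >= 0L, assignment_tolerance >= 0L)
  structure(list(peak_window = as.integer(peak_window),
                 min_support = as.integer(min_support),
                 assignment_tolerance = as.integer(assignment_tolerance)),
            class = "caller_config")
}

#' Read-termini profiles for one reference
#'
#' @param starts,ends integer vectors (0-based start, exclusive end) of the
#'   reads assigned to one reference.
#' @param ref_length reference length, nt.
#' @return list of two integer vectors of length \code{ref_length + 1}
#'   (positions 0..ref_length): counts of read starts and read ends; each
#'   sums to the number of reads.
#' @export
termini_profiles <- function(starts, ends, ref_length) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) &&
      (any(starts < 0L) || any(ends > ref_length) || any(ends <= starts)))
    stop("read termini outside reference bounds")
  list(start = tabulate(starts + 1L, nbins = ref_length + 1L),
       end = tabulate(ends + 1L, nbins = ref_length + 1L))
}

## Fragment calling for one reference from paired read termini.
call_fragments_one <- function(starts, ends, ref_id, cfg) {
  if (!length(starts)) return(NULL)
  w <- cfg$peak_window
  scount <- table(starts)
  spos <- as.integer(names(scount))
  sval <- as.integer(scount)
  ## strict local maxima of the start profile with enough support
  is_peak <- vapply(seq_along(spos), function(i) {
    near <- which(abs(spos - spos[i]) <= w)
    near <- setdiff(near, i)
    sval[i] >= cfg$min_support && all(sval[near] < sval[i])
  }, logical(1))
  peaks <- spos[is_peak]
  if (!length(peaks)) return(NULL)
  frags <- lapply(peaks, function(p) {
    sel <- abs(starts - p) <= w
    etab <- table(ends[sel])
    emax <- as.integer(etab) == max(etab)
    e <- min(as.integer(names(etab))[emax])  # ties: smallest end
    support <- sum(sel & abs(ends - e) <= w)
    data.frame(ref_id = ref_id, start = p, end = e, support = support,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frags)
  ## merge fragments whose both termini lie within +-w of a stronger one
  out <- out[order(-out$support, out$start, out$end), , drop = FALSE]
  keep <- logical(nrow(out))
  merged_into <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    ki <- which(keep)
    near <- ki[abs(out$start[ki] - out$start[i]) <= w &
                 abs(out$end[ki] - out$end[i]) <= w]
    if (length(near)) {
      j <- near[1L]
      out$support[j] <- out$support[j] + out$support[i]
      merged_into[j] <- TRUE
    } else keep[i] <- TRUE
  }
  out$curation_flag <- merged_into
  out <- out[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

#' Call predominant fragments from assigned reads
#'
#' @param assignments assignment table from \code{\link{run_cascade}}
#'   (rows with status "assigned" are used; pooled over libraries).
#' @param refs named character vector of reference sequences (for the
#'   consensus sequence of each fragment).
#' @param cfg a \code{\link{caller_config}}.
#' @return data.frame of fragments: fragment_id, ref_id, start, end,
#'   sequence, support, curation_flag (TRUE when near-duplicate calls were
#'   merged in), ordered by reference and position.
#' @export
call_fragments <- function(assignments, refs, cfg = caller_config()) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(fragment_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      sequence = character(), support = integer(),
                      curation_flag = logical(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(a, a$ref_id), function(ar) {
    call_fragments_one(ar$start, ar$end, ar$ref_id[1L], cfg)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  out <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE))) else NULL
  if (is.null(out) || !nrow(out)) {
    return(data.frame(fragment_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      sequence = character(), support = integer(),
                      curation_flag = logical(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$ref_id, out$start, out$end), , drop = FALSE]
  out$sequence <- substr(refs[out$ref_id], out$start + 1L, out$end)
  out$fragment_id <- sprintf("%s:%d-%d", out$ref_id, out$start, out$end)
  rownames(out) <- NULL
  out[c("fragment_id", "ref_id", "start", "end", "sequence", "support",
        "curation_flag")]
}

#' Count supporting reads per fragment and library
#'
#' A read supports the fragment whose termini are both within
#' \code{assignment_tolerance}; with several candidates the nearest
#' (smallest total termini distance) wins, ties going to the
#' better-supported fragment.  Reads matching no fragment are counted as
#' unassigned residual.
#'
#' @param assignments assignment table (status "assigned" rows are used);
#'   must carry a \code{library} column.
#' @param fragments fragment table from \code{\link{call_fragments}}.
#' @param cfg a \code{\link{caller_config}}.
#' @return list with \code{counts} (fragment x library matrix) and
#'   \code{residual} (named per-library counts of unassigned reads).
#' @export
assign_reads_to_fragments <- function(assignments, fragments,
                                      cfg = caller_config()) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (!("library" %in% names(a))) a$library <- "all"
  libs <- sort(unique(a$library))
  counts <- matrix(0L, nrow = nrow(fragments), ncol = length(libs),
                   dimnames = list(fragments$fragment_id, libs))
  residual <- stats::setNames(integer(length(libs)), libs)
  tol <- cfg$assignment_tolerance
  for (rid in unique(a$ref_id)) {
    ar <- a[a$ref_id == rid, , drop = FALSE]
    fr <- fragments[fragments$ref_id == rid, , drop = FALSE]
    if (!nrow(fr)) {
      tb <- table(ar$library)
      residual[names(tb)] <- residual[names(tb)] + as.integer(tb)
      next
    }
    ## distance of every read to every fragment (fragments per ref are few)
    d5 <- abs(outer(ar$start, fr$start, "-"))
    d3 <- abs(outer(ar$end, fr$end, "-"))
    okmat <- d5 <= tol & d3 <= tol
    dist <- d5 + d3
    dist[!okmat] <- NA_integer_
    n_ok <- rowSums(okmat)
    pick <- rep(NA_integer_, nrow(ar))
    one <- n_ok == 1L
    pick[one] <- max.col(okmat[one, , drop = FALSE], ties.method = "first")
    for (r in which(n_ok > 1L)) {  # ambiguous reads: nearest-termini rule
      dr <- dist[r, ]
      cand <- which(dr == min(dr, na.rm = TRUE))
      if (length(cand) > 1L) cand <- cand[which.max(fr$support[cand])]
      pick[r] <- cand[1L]
    }
    matched <- !is.na(pick)
    if (any(matched)) {
      tb <- table(fragment = fr$fragment_id[pick[matched]],
                  library = ar$library[matched])
      counts[rownames(tb), colnames(tb)] <-
        counts[rownames(tb), colnames(tb), drop = FALSE] + as.integer(tb)
    }
    if (any(!matched)) {
      tb <- table(ar$library[!matched])
      residual[names(tb)] <- residual[names(tb)] + as.integer(tb)
    }
  }
  list(counts = counts, residual = residual)
}
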