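## Tiered exact-match annotation of trimmed reads: rRNA exclusion first,
## then the curated ncRNA database, then piRNA.  The original protocol ran
## a short-read aligner end-to-end with a zero score floor, which admits no
## mismatch or gap penalty, so an alignment is reported exactly when the
## read is a verbatim substring of a reference; this module implements that
## contract directly with a substring index.  Matching is sense-strand only
## by default (small-RNA libraries are stranded).

#' Tier configuration for the annotation cascade
#'
#' @param rrna,ncrnadb,pirna named character vectors (ref_id -> sequence)
#'   for the three tiers, in cascade order.  Empty tiers are allowed.
#' @param sense_only logical; reverse-complement matching is not attempted
#'   when TRUE (default).
#' @return a \code{tier_config}: ordered list of (tier name, substring
#'   index).
#' @export
tier_config <- function(rrna = character(), ncrnadb = character(),
                        pirna = character(), sense_only = TRUE) {
  tiers <- list(rRNA = rrna, ncRNAdb = ncrnadb, piRNA = pirna)
  all_ids <- unlist(lapply(tiers, names))
  if (anyDuplicated(all_ids))
    stop("duplicate ref_id across tiers: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(
    tiers = lapply(tiers, function(x) if (length(x)) build_index(x) else NULL),
    sense_only = isTRUE(sense_only)), class = "tier_config")
}

#' Build an exact-substring index over a reference set
#'
#' The index answers "all (ref_id, offset) pairs where the query occurs as
#' an exact substring".  Substring tables are materialised lazily per query
#' length and cached, which is fast for the short fixed-length queries of
#' small-RNA data.
#'
#' @param refs named character vector, ref_id -> sequence.
#' @return an \code{ev_substring_index}.
#' @export
build_index <- function(refs) {
  if (length(refs) == 0L) stop("non-empty reference set required")
  if (is.null(names(refs)) || any(names(refs) == ""))
    stop("references must be named by ref_id")
  if (anyDuplicated(names(refs)))
    stop("duplicate ref_id: ",
         paste(unique(names(refs)[duplicated(names(refs))]), collapse = ", "))
  assert_alphabet(refs, extra = "", what = "reference")
  structure(list(refs = refs, cache = new.env(parent = emptyenv())),
            class = "ev_substring_index")
}

## Substring table for one query length: parallel vectors of (substring,
## ref index, 0-based offset), plus a name-hashed list of row groups.
index_table <- function(index, L) {
  key <- as.character(L)
  cached <- index$cache[[key]]
  if (!is.null(cached)) return(cached)
  refs <- index$refs
  lens <- nchar(refs)
  use <- which(lens >= L)
  subs <- character(0); ref_i <- integer(0); off <- integer(0)
  for (i in use) {
    n_pos <- lens[i] - L + 1L
    starts <- seq_len(n_pos)
    subs <- c(subs, substring(refs[i], starts, starts + L - 1L))
    ref_i <- c(ref_i, rep.int(i, n_pos))
    off <- c(off, starts - 1L)
  }
  tab <- list(groups = split(seq_along(subs), subs), ref_i = ref_i,
              off = off)
  index$cache[[key]] <- tab
  tab
}

#' Query the substring index
#'
#' @param index an \code{ev_substring_index}.
#' @param query a single query sequence.
#' @return data.frame of hits (ref_id, offset), 0-based offsets, ordered by
#'   ref_id then offset; zero rows when the query is absent.
#' @export
index_lookup <- function(index, query) {
  stopifnot(inherits(index, "ev_substring_index"), length(query) == 1L)
  hits <- index_hits(index, query)[[1L]]
  df <- data.frame(ref_id = names(index$refs)[hits$ref_i],
                   offset = hits$off, stringsAsFactors = FALSE)
  df <- df[order(df$ref_id, df$offset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Vectorised lookup: list (one element per query) of lists with ref_i
## (integer index into refs) and off.
index_hits <- function(index, queries) {
  out <- vector("list", length(queries))
  for (L in unique(nchar(queries))) {
    qi <- which(nchar(queries) == L)
    if (L == 0L) {
      out[qi] <- list(list(ref_i = integer(0), off = integer(0)))
      next
    }
    tab <- index_table(index, L)
    rows <- tab$groups[queries[qi]]
    for (j in seq_along(qi)) {
      r <- rows[[j]]
      if (is.null(r)) r <- integer(0)
      ord <- order(names(index$refs)[tab$ref_i[r]], tab$off[r])
      out[[qi[j]]] <- list(ref_i = tab$ref_i[r][ord], off = tab$off[r][ord])
    }
  }
  out
}

#' Assign one read through the cascade
#'
#' Tiers are tried in order (rRNA, ncRNAdb, piRNA); the first tier with at
#' least one exact hit claims the read.  rRNA hits give status
#' \code{rRNA_excluded}; no hit anywhere gives \code{unmapped}.  Within
#' the claiming tier the reported hit is the lexicographically smallest
#' ref_id, then the smallest offset, and \code{multimap_count} records the
#' total number of (ref_id, offset) hits in that tier.
#'
#' @param read a read sequence (or list with \code{sequence}).
#' @param tiers a \code{\link{tier_config}}.
#' @return one-row data.frame: status, tier, ref_id, start, end,
#'   multimap_count.
#' @export
assign_read <- function(read, tiers) {
  seqs <- if (is.character(read)) read else read$sequence
  df <- run_cascade(data.frame(read_id = "r", sequence = seqs,
                               stringsAsFactors = FALSE), tiers)$assignments
  df[, c("status", "tier", "ref_id", "start", "end", "multimap_count")]
}

#' Run the annotation cascade over a read set
#'
#' @param reads data.frame with \code{read_id} and \code{sequence}
#'   (optional \code{library} carried through).
#' @param tiers a \code{\link{tier_config}}.
#' @return list with \code{assignments} (read_id, status, tier, ref_id,
#'   start, end, multimap_count; one row per read) and \code{report}
#'   (counts per status: rRNA_excluded, assigned_ncRNAdb, assigned_piRNA,
#'   unmapped; they partition the input).
#' @export
run_cascade <- function(reads, tiers) {
  stopifnot(is.data.frame(reads), inherits(tiers, "tier_config"))
  n <- nrow(reads)
  uq <- unique(reads$sequence)
  u_status <- rep("unmapped", length(uq))
  u_tier <- rep(NA_character_, length(uq))
  u_ref <- rep(NA_character_, length(uq))
  u_off <- rep(NA_integer_, length(uq))
  u_mm <- rep(0L, length(uq))
  pending <- seq_along(uq)
  for (tier_name in names(tiers$tiers)) {
    if (!length(pending)) break
    idx <- tiers$tiers[[tier_name]]
    if (is.null(idx)) next
    hits <- index_hits(idx, uq[pending])
    got <- which(vapply(hits, function(h) length(h$ref_i) > 0L, logical(1)))
    if (length(got)) {
      gi <- pending[got]
      u_status[gi] <- if (tier_name == "rRNA") "rRNA_excluded" else "assigned"
      u_tier[gi] <- tier_name
      u_ref[gi] <- vapply(hits[got],
                          function(h) names(idx$refs)[h$ref_i[1L]],
                          character(1))
      u_off[gi] <- vapply(hits[got], function(h) h$off[1L], integer(1))
      u_mm[gi] <- vapply(hits[got], function(h) length(h$ref_i), integer(1))
      pending <- pending[-got]
    }
  }
  mi <- match(reads$sequence, uq)
  assignments <- data.frame(
    read_id = reads$read_id, status = u_status[mi], tier = u_tier[mi],
    ref_id = u_ref[mi], start = u_off[mi],
    end = u_off[mi] + nchar(reads$sequence), multimap_count = u_mm[mi],
    stringsAsFactors = FALSE)
  assignments$end[is.na(assignments$ref_id)] <- NA_integer_
  if ("library" %in% names(reads)) assignments$library <- reads$library
  report <- c(
    input = n,
    rRNA_excluded = sum(assignments$status == "rRNA_excluded"),
    assigned_ncRNAdb = sum(assignments$status == "assigned" &
                             assignments$tier == "ncRNAdb", na.rm = TRUE),
    assigned_piRNA = sum(assignments$status == "assigned" &
                           assignments$tier == "piRNA", na.rm = TRUE),
    unmapped = sum(assignments$status == "unmapped"))
  list(assignments = assignments, report = report)
}
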