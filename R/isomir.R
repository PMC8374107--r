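## IsomiR taxonomy: each miRNA-precursor fragment is compared against the
## canonical mature annotation of its hairpin and classified by its
## signed termini offsets (d5 = fragment start - canonical start, d3 =
## fragment end - canonical end), or as an opposite-arm, stem-loop or
## trailer product when its maximal overlap is with the unannotated arm,
## the loop, or the flanks.  For single-arm hairpins the opposite-arm
## region is the annotated arm mirrored across the loop midpoint.

ISOMIR_END_CATEGORIES <- c("shorter_3p", "shorter_5p", "longer_3p",
                           "longer_5p", "shifted_toward_3p",
                           "shifted_toward_5p", "shorter_both",
                           "longer_both")
ISOMIR_CATEGORIES <- c("canonical", ISOMIR_END_CATEGORIES,
                       "opposite_arm", "trailer", "stem_loop")

#' Locate a fragment on its precursor by exact match
#'
#' @param fragment fragment sequence.
#' @param precursor precursor sequence.
#' @return list with \code{start}, \code{end} (0-based half-open; leftmost
#'   occurrence), \code{n_occurrences}, and \code{found}; \code{found =
#'   FALSE} when the fragment is not a substring.
#' @export
locate_on_precursor <- function(fragment, precursor) {
  hits <- gregexpr(fragment, precursor, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L)
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                n_occurrences = 0L))
  list(found = TRUE, start = hits[1L] - 1L,
       end = hits[1L] - 1L + nchar(fragment),
       n_occurrences = length(hits))
}

#' Precursor region map
#'
#' @param mature data.frame of annotated arms for one precursor
#'   (arm, start, end, name).
#' @param loop c(start, end) of the loop interval.
#' @param ref_length precursor length.
#' @return data.frame of regions (region, start, end, name): annotated
#'   arms, the opposite-arm region when only one arm is annotated
#'   (mirrored across the loop midpoint), loop, and 5'/3' flanks.
#' @export
precursor_regions <- function(mature, loop, ref_length) {
  regions <- data.frame(region = paste0("arm_", mature$arm),
                        start = mature$start, end = mature$end,
                        name = mature$name, stringsAsFactors = FALSE)
  if (nrow(mature) == 1L) {
    mi <- mirror_interval(mature$start[1L], mature$end[1L],
                          loop[1L], loop[2L], ref_length)
    opp_arm <- setdiff(c("5p", "3p"), mature$arm[1L])
    regions <- rbind(regions, data.frame(
      region = "opposite_arm", start = mi[1L], end = mi[2L],
      name = sub("(5p|3p)$", opp_arm, mature$name[1L]),
      stringsAsFactors = FALSE))
  }
  stem_flanks <- data.frame(
    region = c("loop", "flank_5p", "flank_3p"),
    start = c(loop[1L], 0L, max(c(mature$end, loop[2L]))),
    end = c(loop[2L], min(c(mature$start, loop[1L])), ref_length),
    name = NA_character_, stringsAsFactors = FALSE)
  ## flanks outside the outermost annotated/mirrored regions
  stem_flanks$end[2L] <- min(regions$start, stem_flanks$end[2L])
  stem_flanks$start[3L] <- max(regions$end, stem_flanks$start[3L])
  rbind(regions, stem_flanks[stem_flanks$end > stem_flanks$start, ])
}

#' Classify one fragment against its precursor annotation
#'
#' The fragment is attributed to the region of maximal overlap (ties:
#' arms, then loop, then flanks).  On an annotated arm the signed offsets
#' (d5, d3) against the canonical coordinates give the category via the
#' decision table: (0,0) canonical; one-sided offsets shorter/longer 5'
#' or 3'; same-sign offsets a shift toward the 3' or 5' end; opposite
#' signs shorter/longer at both ends.
#'
#' @param frag_start,frag_end fragment coordinates on the precursor
#'   (0-based half-open).
#' @param mature annotated arms for the precursor (data.frame with arm,
#'   start, end, name).
#' @param loop loop interval c(start, end).
#' @param ref_length precursor length.
#' @return one-row data.frame: category, matched_canonical, d5, d3,
#'   region.
#' @export
classify_isomir <- function(frag_start, frag_end, mature, loop,
                            ref_length) {
  if (frag_end <= frag_start || frag_end <= 0L || frag_start >= ref_length)
    stop("fragment has no overlap with the precursor")
  regions <- precursor_regions(mature, loop, ref_length)
  ov <- pmax(0L, pmin(frag_end, regions$end) -
                   pmax(frag_start, regions$start))
  prec <- ifelse(grepl("^arm_|^opposite_arm$", regions$region), 3L,
          ifelse(regions$region == "loop", 2L, 1L))
  best <- order(-ov, -prec)[1L]
  if (ov[best] == 0L) stop("fragment has no overlap with annotated regions")
  reg <- regions$region[best]
  if (reg %in% c("arm_5p", "arm_3p")) {
    d5 <- frag_start - regions$start[best]
    d3 <- frag_end - regions$end[best]
    category <-
      if (d5 == 0L && d3 == 0L) "canonical"
      else if (d5 == 0L) if (d3 < 0L) "shorter_3p" else "longer_3p"
      else if (d3 == 0L) if (d5 > 0L) "shorter_5p" else "longer_5p"
      else if (d5 > 0L && d3 > 0L) "shifted_toward_3p"
      else if (d5 < 0L && d3 < 0L) "shifted_toward_5p"
      else if (d5 > 0L && d3 < 0L) "shorter_both"
      else "longer_both"
    return(data.frame(category = category,
                      matched_canonical = regions$name[best],
                      d5 = d5, d3 = d3, region = reg,
                      stringsAsFactors = FALSE))
  }
  category <- switch(reg, opposite_arm = "opposite_arm",
                     loop = "stem_loop", "trailer")
  data.frame(category = category,
             matched_canonical = if (reg == "opposite_arm")
               regions$name[best] else NA_character_,
             d5 = NA_integer_, d3 = NA_integer_, region = reg,
             stringsAsFactors = FALSE)
}

#' Classify miRNA-precursor fragments of an experiment
#'
#' @param fragments fragment table (\code{\link{call_fragments}}).
#' @param bundle the reference bundle.
#' @param expr optional \code{ev_expression_table}; when given and
#'   \code{only_de = TRUE} (the default, as in the targeted protocol) only
#'   fragments called differentially expressed in \code{contrast} are
#'   classified.
#' @param contrast which differential contrast selects fragments.
#' @param only_de classify only differentially expressed fragments.
#' @return data.frame of isomiR calls: fragment_id, precursor_id,
#'   category, matched_canonical, d5, d3, region, sequence, length.
#' @export
classify_isomirs <- function(fragments, bundle, expr = NULL,
                             contrast = "ev", only_de = TRUE) {
  pre <- bundle$entries[bundle$entries$class == "miRNA_precursor", ]
  frags <- fragments[fragments$ref_id %in% pre$ref_id, , drop = FALSE]
  if (!is.null(expr) && only_de) {
    st <- stats::setNames(expr[[paste0("de_", contrast)]],
                          expr$fragment_id)
    frags <- frags[st[frags$fragment_id] %in% c("up", "down"), ,
                   drop = FALSE]
  }
  if (!nrow(frags)) {
    return(data.frame(fragment_id = character(), precursor_id = character(),
                      category = character(), matched_canonical = character(),
                      d5 = integer(), d3 = integer(), region = character(),
                      sequence = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  reflen <- stats::setNames(nchar(pre$sequence), pre$ref_id)
  calls <- lapply(seq_len(nrow(frags)), function(i) {
    pid <- frags$ref_id[i]
    m <- bundle$mature[bundle$mature$precursor_id == pid, , drop = FALSE]
    lp <- bundle$loops[bundle$loops$precursor_id == pid, , drop = FALSE]
    cl <- classify_isomir(frags$start[i], frags$end[i], m,
                          c(lp$start[1L], lp$end[1L]), reflen[[pid]])
    cbind(data.frame(fragment_id = frags$fragment_id[i],
                     precursor_id = pid, stringsAsFactors = FALSE),
          cl,
          data.frame(sequence = frags$sequence[i],
                     length = frags$end[i] - frags$start[i],
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Taxonomy summary of isomiR calls
#'
#' @param calls data.frame from \code{\link{classify_isomirs}}.
#' @return data.frame (category, n, pct): one row per taxonomy category
#'   plus an \code{isomiRs} subtotal over the end-variant categories and a
#'   grand total; percentages of the grand total, rounded to integers.
#' @export
summarize_isomirs <- function(calls) {
  n_of <- function(cats) sum(calls$category %in% cats)
  total <- nrow(calls)
  rows <- rbind(
    data.frame(category = "canonical", n = n_of("canonical")),
    data.frame(category = "isomiRs", n = n_of(ISOMIR_END_CATEGORIES)),
    do.call(rbind, lapply(ISOMIR_END_CATEGORIES, function(cc)
      data.frame(category = cc, n = n_of(cc)))),
    data.frame(category = "opposite_arm", n = n_of("opposite_arm")),
    data.frame(category = "trailer", n = n_of("trailer")),
    data.frame(category = "stem_loop", n = n_of("stem_loop")),
    data.frame(category = "Total", n = total))
  rows$pct <- if (total > 0) round(100 * rows$n / total) else 0
  rows$is_subtotal <- rows$category %in% c("isomiRs", "Total")
  rownames(rows) <- NULL
  rows
}

#' Opposite-arm discovery report
#'
#' Lists fragments classified as opposite-arm products with a proposed
#' name: the canonical mature name with its arm suffix swapped (a 5p
#' product from a precursor whose canonical is 3p, or vice versa).
#'
#' @param calls data.frame from \code{\link{classify_isomirs}}.
#' @param detected_in label for the compartment the calls come from.
#' @return data.frame: fragment_id, sequence, length, detected_in,
#'   proposed_name.
#' @export
opposite_arm_report <- function(calls, detected_in = "S-EVs") {
  opp <- calls[calls$category == "opposite_arm", , drop = FALSE]
  data.frame(fragment_id = opp$fragment_id, sequence = opp$sequence,
             length = opp$length, detected_in = detected_in,
             proposed_name = opp$matched_canonical,
             stringsAsFactors = FALSE)
}
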