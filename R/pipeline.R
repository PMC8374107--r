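## End-to-end orchestration of the small RNA-seq stages, plus evaluators
## that compare pipeline output against the planted truth of a synthetic
## experiment (parameter-recovery benchmarking).

#' Run the small RNA cargo pipeline on a 4-library read set
#'
#' Stages: 3'-adapter trimming, tiered exact-match annotation (rRNA
#' exclusion, curated ncRNA, piRNA), predominant-fragment calling on the
#' pooled assigned reads, per-library fragment counting, RPM scaling and
#' fold-change differential calls, and isomiR classification of the
#' differentially expressed miRNA-precursor fragments.
#'
#' @param reads named list of read tables (read_id, sequence), one per
#'   library; names must include cell_ctrl, cell_dht, ev_ctrl, ev_dht for
#'   the differential contrasts.
#' @param bundle the \code{ev_reference_bundle} the tiers come from.
#' @param trim_cfg,caller_cfg stage configurations.
#' @param min_reads,strict,fc_threshold,pseudocount quantification rules
#'   (see \code{\link{build_expression_table}}).
#' @return list: trim_reports, cascade (assignments pooled over libraries,
#'   report per library), fragments, counts, residual, expression,
#'   library_summaries, isomir_calls (per contrast), isomir_summary.
#' @export
run_smallrna_pipeline <- function(reads, bundle,
                                  trim_cfg = trim_config(),
                                  caller_cfg = caller_config(),
                                  min_reads = 10L, strict = FALSE,
                                  fc_threshold = 4, pseudocount = 1) {
  tiers <- bundle_tiers(bundle)
  trim_reports <- list(); cascades <- list(); summaries <- list()
  assigned <- list()
  for (lib in names(reads)) {
    tr <- trim_set(reads[[lib]], trim_cfg)
    tr$reads$library <- lib
    casc <- run_cascade(tr$reads, tiers)
    trim_reports[[lib]] <- tr$report
    cascades[[lib]] <- casc$report
    summaries[[lib]] <- summarize_library(tr$report, casc, tr$reads)
    assigned[[lib]] <- casc$assignments
  }
  all_assign <- do.call(rbind, c(assigned, list(make.row.names = FALSE)))
  refs <- bundle_sequences(bundle)
  fragments <- call_fragments(all_assign, refs, caller_cfg)
  fc <- assign_reads_to_fragments(all_assign, fragments, caller_cfg)
  ## fragment class from its reference's class (miRNA-precursor products
  ## count as miRNA, tRNA products as tRFs)
  ref_class <- stats::setNames(bundle$entries$class, bundle$entries$ref_id)
  frag_class <- ref_class[fragments$ref_id]
  frag_class <- ifelse(frag_class == "miRNA_precursor", "miRNA",
                ifelse(frag_class == "tRNA", "tRF", frag_class))
  names(frag_class) <- fragments$fragment_id
  counts <- fc$counts
  miss <- setdiff(LIBRARY_IDS, colnames(counts))
  if (length(miss)) {
    counts <- cbind(counts,
                    matrix(0L, nrow(counts), length(miss),
                           dimnames = list(rownames(counts), miss)))
  }
  counts <- counts[, intersect(c(LIBRARY_IDS, colnames(counts)),
                               colnames(counts)), drop = FALSE]
  expression <- build_expression_table(
    counts, frag_class, min_reads = min_reads, strict = strict,
    fc_threshold = fc_threshold, pseudocount = pseudocount)
  isomir_calls <- list(
    ev = classify_isomirs(fragments, bundle, expression, contrast = "ev"),
    cell = classify_isomirs(fragments, bundle, expression,
                            contrast = "cell"))
  list(trim_reports = trim_reports, cascade_reports = cascades,
       assignments = all_assign, fragments = fragments, counts = counts,
       residual = fc$residual, expression = expression,
       library_summaries = summaries, isomir_calls = isomir_calls,
       isomir_summary = lapply(isomir_calls, summarize_isomirs))
}

#' Fragment-recovery evaluation against planted truth
#'
#' @param fragments called fragment table.
#' @param truth the truth table of \code{\link{simulate_libraries}}.
#' @param min_expected only features whose total expected read count
#'   reaches this value are evaluated (weak features are not recoverable
#'   by construction).
#' @return list: n_evaluated, n_recovered (exact planted coordinates),
#'   recovery_pct.
#' @export
evaluate_fragment_recovery <- function(fragments, truth,
                                       min_expected = 50) {
  exp_cols <- grep("^expected_", names(truth), value = TRUE)
  tot <- rowSums(truth[exp_cols])
  ev <- truth[tot >= min_expected, , drop = FALSE]
  key <- paste(ev$ref_id, ev$start, ev$end)
  called <- paste(fragments$ref_id, fragments$start, fragments$end)
  hit <- key %in% called
  list(n_evaluated = nrow(ev), n_recovered = sum(hit),
       recovery_pct = 100 * mean(hit))
}

#' Differential-call recovery against planted truth
#'
#' A planted responsive feature counts as recovered when the fragment at
#' its exact coordinates is called differentially expressed in at least
#' one compartment contrast (cells or S-EVs) - responsiveness in either
#' compartment is what the study design defines.  A null feature counts
#' as a false call when either contrast flags it.
#'
#' @param result pipeline result list.
#' @param truth the truth table of \code{\link{simulate_libraries}}.
#' @return list: n_de_planted, n_de_recovered, recall_pct, n_null,
#'   n_false, false_call_pct.
#' @export
evaluate_de_recovery <- function(result, truth) {
  frags <- result$fragments
  expr <- result$expression
  key <- paste(frags$ref_id, frags$start, frags$end)
  fid <- stats::setNames(frags$fragment_id, key)
  tkey <- paste(truth$ref_id, truth$start, truth$end)
  tfrag <- fid[tkey]
  st <- expr[match(tfrag, expr$fragment_id), c("de_ev", "de_cell")]
  called <- !is.na(tfrag) &
    (st$de_ev %in% c("up", "down") | st$de_cell %in% c("up", "down"))
  de <- truth$planted_de
  list(n_de_planted = sum(de), n_de_recovered = sum(called[de]),
       recall_pct = 100 * mean(called[de]),
       n_null = sum(!de), n_false = sum(called[!de]),
       false_call_pct = 100 * mean(called[!de]))
}
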