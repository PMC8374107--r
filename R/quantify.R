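## Count-matrix construction, reads-per-million scaling, inclusion
## filtering, fold-change differential calls and per-class summary tables.
## The differential rule is the pure fold-change criterion of the targeted
## protocol: features seen at >= 10 reads in at least one library are
## included, and a linear fold change >= 4 in either direction calls a
## feature androgen-responsive.  No replicate-aware statistical model is
## fitted (the libraries are pooled biological repeats).

TOP_CLASSES <- c("miRNA", "piRNA", "tRF", "sdRNA", "other")
SDRNA_CLASSES <- c("SNORD", "SNORA", "scaRNA")
OTHER_CLASSES <- c("snRNA", "scRNA")
LEAF_CLASSES <- c("miRNA", "piRNA", "tRF", SDRNA_CLASSES, OTHER_CLASSES)

#' Reads-per-million scaling
#'
#' @param counts numeric matrix (features x libraries).
#' @param library_totals per-library totals used as the denominator; the
#'   convention here is reads assigned to any small-RNA tier after rRNA
#'   exclusion, so that RPM columns sum to 1e6 over all small-RNA features.
#'   Defaults to the column sums of \code{counts}.
#' @return matrix of RPM values: count / total x 1e6.
#' @export
rpm_scale <- function(counts, library_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(library_totals <= 0)) stop("library totals must be > 0")
  sweep(counts, 2L, library_totals, "/") * 1e6
}

#' Inclusion filter on raw counts
#'
#' @param counts numeric matrix (features x libraries).
#' @param min_reads minimum raw read count.
#' @param strict when FALSE (default), a feature is included if it reaches
#'   \code{min_reads} in at least one library; when TRUE it must reach it
#'   in every library.
#' @return logical vector of inclusion flags.
#' @export
filter_included <- function(counts, min_reads = 10L, strict = FALSE) {
  counts <- as.matrix(counts)
  if (strict) apply(counts >= min_reads, 1L, all)
  else apply(counts >= min_reads, 1L, any)
}

#' Fold-change differential call between two conditions
#'
#' The linear fold change is \code{(rpm_b + c) / (rpm_a + c)} with a
#' constant pseudocount c added to both sides (continuity at zero and
#' exact antisymmetry under swapping the conditions).
#'
#' @param rpm_a,rpm_b RPM vectors for the reference and treated condition.
#' @param fc_threshold linear fold-change threshold for a call.
#' @param pseudocount c, in RPM units.
#' @return data.frame with \code{linear_fc} and \code{de_status}
#'   (up / down / unchanged).
#' @export
call_de <- function(rpm_a, rpm_b, fc_threshold = 4, pseudocount = 1) {
  fc <- (rpm_b + pseudocount) / (rpm_a + pseudocount)
  status <- ifelse(fc >= fc_threshold, "up",
            ifelse(fc <= 1 / fc_threshold, "down", "unchanged"))
  data.frame(linear_fc = fc, de_status = status, stringsAsFactors = FALSE)
}

#' Expression table for called fragments
#'
#' Combines per-fragment per-library counts with RPM scaling, the
#' inclusion filter and fold-change differential calls for the two
#' within-compartment contrasts (+DHT vs -DHT in cells and in S-EVs).
#'
#' @param counts fragment x library count matrix with columns cell_ctrl,
#'   cell_dht, ev_ctrl, ev_dht (as from
#'   \code{\link{assign_reads_to_fragments}}).
#' @param fragment_class named character vector fragment_id -> leaf class
#'   (miRNA, piRNA, tRF, SNORD, SNORA, scaRNA, snRNA, scRNA, ...).
#' @param library_totals denominators for RPM scaling (default: column
#'   sums, i.e. all small-RNA-assigned fragment reads).
#' @param min_reads,strict inclusion rule (see
#'   \code{\link{filter_included}}).
#' @param fc_threshold,pseudocount differential rule (see
#'   \code{\link{call_de}}).
#' @return an \code{ev_expression_table} data.frame: fragment_id, class,
#'   raw counts, rpm columns, included flag, and per-contrast linear_fc /
#'   de_status (status "excluded" for non-included features).
#' @export
build_expression_table <- function(counts, fragment_class,
                                   library_totals = colSums(counts),
                                   min_reads = 10L, strict = FALSE,
                                   fc_threshold = 4, pseudocount = 1) {
  counts <- as.matrix(counts)
  rpm <- rpm_scale(counts, library_totals)
  included <- filter_included(counts, min_reads, strict)
  tab <- data.frame(fragment_id = rownames(counts),
                    class = unname(fragment_class[rownames(counts)]),
                    stringsAsFactors = FALSE)
  for (lib in colnames(counts)) {
    tab[[paste0("count_", lib)]] <- counts[, lib]
    tab[[paste0("rpm_", lib)]] <- rpm[, lib]
  }
  tab$included <- included
  contrasts <- list(cell = c("cell_ctrl", "cell_dht"),
                    ev = c("ev_ctrl", "ev_dht"))
  for (cn in names(contrasts)) {
    pair <- contrasts[[cn]]
    if (!all(pair %in% colnames(counts))) next
    de <- call_de(rpm[, pair[1L]], rpm[, pair[2L]], fc_threshold,
                  pseudocount)
    de$de_status[!included] <- "excluded"
    tab[[paste0("fc_", cn)]] <- de$linear_fc
    tab[[paste0("de_", cn)]] <- de$de_status
  }
  rownames(tab) <- NULL
  class(tab) <- c("ev_expression_table", "data.frame")
  tab
}

#' Per-class summary from leaf-class differential counts
#'
#' Builds the per-type summary table (detected / differentially expressed
#' / up / down) from counts per leaf class, adding the snoRNA-derived
#' (sdRNA = SNORD + SNORA + scaRNA) and "Other" (snRNA + scRNA) subtotals
#' and a grand total over the mutually exclusive top-level classes
#' (miRNA, piRNA, tRF, sdRNA, other).
#'
#' @param leaf data.frame with columns class, detected, de, up, down; one
#'   row per leaf class (missing leaf classes count as zero).
#' @return data.frame summary with subtotal and Total rows; rows whose
#'   class is a subtotal carry \code{is_subtotal = TRUE}.
#' @export
class_summary <- function(leaf) {
  bad <- setdiff(leaf$class, LEAF_CLASSES)
  if (length(bad))
    stop("unknown class label: ", paste(bad, collapse = ", "))
  cols <- c("detected", "de", "up", "down")
  for (cc in cols) if (is.null(leaf[[cc]])) leaf[[cc]] <- rep(0L, nrow(leaf))
  get <- function(cls) {
    out <- vapply(cols, function(cc)
      sum(leaf[[cc]][leaf$class %in% cls]), numeric(1))
    as.list(out)
  }
  row <- function(name, cls, sub = FALSE)
    data.frame(class = name, get(cls), is_subtotal = sub,
               stringsAsFactors = FALSE)
  out <- rbind(
    row("miRNA", "miRNA"), row("piRNA", "piRNA"), row("tRF", "tRF"),
    row("sdRNA", SDRNA_CLASSES, sub = TRUE),
    row("SNORD", "SNORD"), row("SNORA", "SNORA"), row("scaRNA", "scaRNA"),
    row("other", OTHER_CLASSES, sub = TRUE),
    row("snRNA", "snRNA"), row("scRNA", "scRNA"),
    row("Total", LEAF_CLASSES, sub = TRUE))
  rownames(out) <- NULL
  out
}

#' Per-class differential summary of an expression table
#'
#' @param expr an \code{ev_expression_table}.
#' @param contrast "ev" or "cell": which within-compartment comparison to
#'   summarise.
#' @return the \code{\link{class_summary}} table for that contrast, where
#'   \code{detected} counts included fragments and \code{de} those called
#'   up or down.
#' @export
summarize_classes <- function(expr, contrast = c("ev", "cell")) {
  contrast <- match.arg(contrast)
  st <- expr[[paste0("de_", contrast)]]
  leaf <- do.call(rbind, lapply(unique(expr$class), function(cls) {
    sel <- expr$class == cls
    data.frame(class = cls,
               detected = sum(sel & expr$included),
               de = sum(sel & st %in% c("up", "down")),
               up = sum(sel & st == "up"),
               down = sum(sel & st == "down"),
               stringsAsFactors = FALSE)
  }))
  class_summary(leaf)
}

#' Library-level summary
#'
#' Percentages follow the reporting convention of the targeted study:
#' rRNA and small-RNA fractions are computed against filtered (post-trim,
#' retained) reads; GC is total G+C bases over total bases.
#'
#' @param trim_report report from \code{\link{trim_set}}.
#' @param cascade result list from \code{\link{run_cascade}} on the
#'   retained reads.
#' @param reads the retained (trimmed) read table.
#' @return list: total_reads (input), filtered_reads (retained),
#'   rrna_reads / rrna_pct, smallrna_reads / smallrna_pct, unmapped_reads,
#'   length_histogram (table over retained read lengths), gc_pct (all
#'   retained reads), gc_pct_assigned (small-RNA-assigned reads only).
#' @export
summarize_library <- function(trim_report, cascade, reads) {
  filtered <- unname(trim_report[["retained"]])
  rep <- cascade$report
  small <- unname(rep[["assigned_ncRNAdb"]] + rep[["assigned_piRNA"]])
  assigned <- cascade$assignments$status == "assigned"
  list(total_reads = unname(trim_report[["input"]]),
       filtered_reads = filtered,
       rrna_reads = unname(rep[["rRNA_excluded"]]),
       rrna_pct = 100 * unname(rep[["rRNA_excluded"]]) / filtered,
       smallrna_reads = small,
       smallrna_pct = 100 * small / filtered,
       unmapped_reads = unname(rep[["unmapped"]]),
       length_histogram = table(nchar(reads$sequence)),
       gc_pct = 100 * pooled_gc(reads$sequence),
       gc_pct_assigned = 100 * pooled_gc(reads$sequence[assigned]))
}
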