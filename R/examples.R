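## Bundled example data: published-style summary tables for an LNCaP
## +/- DHT small-RNA profiling experiment (per-class differential counts
## and the isomiR taxonomy breakdown), and the eight mature sequences
## reported as opposite-arm products of known hairpins.  The precursors
## backing the opposite-arm worked example are synthetic (real hairpin
## sequences are not shipped); only the detected mature sequences are
## real, so the example exercises the classifier geometry, not miRBase
## coordinates.

evcargo_extdata <- function(file) {
  system.file("extdata", file, package = "evcargo", mustWork = TRUE)
}

#' Bundled per-class differential-expression counts
#'
#' Leaf-class counts of androgen-responsive small RNAs (with up/down
#' split) for LNCaP cells and their S-EVs, suitable as input to
#' \code{\link{class_summary}}.
#'
#' @return data.frame: class, cell_de, cell_up, cell_down, ev_de, ev_up,
#'   ev_down.
#' @export
example_de_class_counts <- function() {
  utils::read.delim(evcargo_extdata("lncap_de_class_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bundled isomiR taxonomy counts
#'
#' Category counts of differentially expressed canonical miRNAs and
#' isomiR forms detected in S-EVs and in cells.
#'
#' @return data.frame: category, ev_n, cell_n.
#' @export
example_isomir_taxonomy <- function() {
  utils::read.delim(evcargo_extdata("lncap_isomir_taxonomy.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bundled opposite-arm miRNA sequences
#'
#' The mature sequences reported as products of the arm opposite the
#' annotated canonical miRNA, with the proposed swapped-arm names.
#'
#' @return data.frame: id, sequence, length, detected_in, proposed_name.
#' @export
example_opposite_arm_table <- function() {
  utils::read.delim(evcargo_extdata("opposite_arm_mirnas.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference bundle sized for the study presets
#'
#' A convenience bundle large enough to host the default feature plans of
#' \code{\link{design_androgen_experiment}} and
#' \code{\link{design_recovery_benchmark}}.
#'
#' @param seed integer seed.
#' @return an \code{ev_reference_bundle}.
#' @export
make_study_bundle <- function(seed = 1L) {
  make_reference_bundle(
    seed = seed,
    n_per_class = c(miRNA_precursor = 90L, rRNA = 2L, tRNA = 24L,
                    SNORD = 24L, SNORA = 14L, scaRNA = 8L, snRNA = 12L,
                    scRNA = 10L, piRNA = 48L, misc = 2L))
}

#' Worked opposite-arm example on synthetic precursors
#'
#' Embeds each bundled opposite-arm mature sequence on one arm of a
#' synthetic hairpin whose canonical annotation sits on the other arm,
#' then classifies the fragments.  All eight should come back as
#' opposite-arm products whose proposed names match the bundled table.
#'
#' @param seed seed for the synthetic canonical-arm and flank sequences.
#' @return list: bundle, fragments, calls
#'   (\code{\link{classify_isomirs}} output) and the input \code{table}.
#' @export
opposite_arm_example <- function(seed = 1L) {
  tab <- example_opposite_arm_table()
  with_seed(seed, {
    flank <- 8L; loop_len <- 15L; canon_len <- 22L
    entries <- list(); mature <- list(); loops <- list(); frags <- list()
    for (i in seq_len(nrow(tab))) {
      det <- tab$sequence[i]
      det_arm <- sub("^.*-(5p|3p)$", "\\1", tab$proposed_name[i])
      canon_arm <- setdiff(c("5p", "3p"), det_arm)
      canon_name <- sub("(5p|3p)$", canon_arm, tab$proposed_name[i])
      pid <- tolower(sub("-(5p|3p)$", "", sub("miR", "mir",
                                              tab$proposed_name[i])))
      canon <- random_seq(1L, canon_len)
      arm5 <- if (det_arm == "5p") det else canon
      arm3 <- if (det_arm == "3p") det else canon
      seqs <- paste0(random_seq(1L, flank), arm5,
                     random_seq(1L, loop_len), arm3,
                     random_seq(1L, flank))
      s5 <- flank
      loop_start <- s5 + nchar(arm5)
      s3 <- loop_start + loop_len
      entries[[i]] <- data.frame(ref_id = pid, class = "miRNA_precursor",
                                 sequence = seqs, stringsAsFactors = FALSE)
      mature[[i]] <- data.frame(
        precursor_id = pid, arm = canon_arm,
        start = if (canon_arm == "5p") s5 else s3,
        end = if (canon_arm == "5p") s5 + canon_len else s3 + canon_len,
        name = canon_name, stringsAsFactors = FALSE)
      loops[[i]] <- data.frame(precursor_id = pid, start = loop_start,
                               end = s3, stringsAsFactors = FALSE)
      fs <- if (det_arm == "5p") s5 else s3
      frags[[i]] <- data.frame(
        fragment_id = tab$id[i], ref_id = pid, start = fs,
        end = fs + nchar(det), sequence = det, support = 10L,
        curation_flag = FALSE, stringsAsFactors = FALSE)
    }
    bundle <- structure(list(entries = do.call(rbind, entries),
                             mature = do.call(rbind, mature),
                             loops = do.call(rbind, loops)),
                        class = "ev_reference_bundle")
    validate_reference_bundle(bundle)
    fragments <- do.call(rbind, frags)
    calls <- classify_isomirs(fragments, bundle, expr = NULL,
                              only_de = FALSE)
    list(bundle = bundle, fragments = fragments, calls = calls,
         table = tab)
  })
}
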