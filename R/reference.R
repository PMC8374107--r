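## Reference bundles: tiered sequence databases (rRNA / curated ncRNA classes
## / piRNA) plus miRBase-style hairpin annotations (mature arms and loop
## intervals) used by the annotation cascade and the isomiR classifier.

REF_CLASSES <- c("rRNA", "miRNA_precursor", "tRNA", "SNORD", "SNORA",
                 "scaRNA", "snRNA", "scRNA", "piRNA", "misc")

## Typical lengths (nt) for synthetic members of each class.  rRNA entries are
## kept shorter than real 18S/28S so that fixtures stay small; contamination
## reads are windows on them, which does not depend on full-length rRNA.
REF_CLASS_LEN <- list(
  rRNA = c(600L, 900L), miRNA_precursor = NULL, tRNA = c(70L, 74L),
  SNORD = c(70L, 90L), SNORA = c(120L, 140L), scaRNA = c(100L, 130L),
  snRNA = c(100L, 160L), scRNA = c(80L, 120L), piRNA = c(26L, 31L),
  misc = c(60L, 120L)
)

#' Generate a synthetic reference bundle
#'
#' Builds a miRBase-like reference set: hairpin precursors with annotated
#' mature arms and loop intervals, plus members of the other small ncRNA
#' classes used by the tiered annotation cascade (rRNA, tRNA, SNORD, SNORA,
#' scaRNA, snRNA, scRNA, piRNA, misc).  All coordinates are 0-based,
#' half-open.  A fixed fraction of precursors (about one in five, and always
#' at least one when any precursor is requested) carries a single annotated
#' arm, so that opposite-arm products can be exercised downstream.
#'
#' @param seed integer seed; the same seed and arguments give a byte-identical
#'   bundle.
#' @param n_per_class named integer vector or list, class -> number of
#'   entries; classes not mentioned get zero entries.
#' @param hairpin_length length-2 integer range for total precursor length.
#' @param arm_length length-2 integer range for mature arm length.
#' @param flank_length flank (trailer region) length on each side of the
#'   hairpin stem, nt; deposited precursor entries include this much
#'   flanking sequence, the substrate of trailer products.
#' @param gc target GC content for generated sequences.
#' @return an object of class \code{ev_reference_bundle}: a list with
#'   \code{entries} (ref_id, class, sequence), \code{mature} (precursor_id,
#'   arm, start, end, name) and \code{loops} (precursor_id, start, end).
#' @export
make_reference_bundle <- function(seed = 1L,
                                  n_per_class = c(miRNA_precursor = 20L,
                                                  rRNA = 2L, tRNA = 8L,
                                                  SNORD = 8L, SNORA = 4L,
                                                  scaRNA = 2L, snRNA = 3L,
                                                  scRNA = 3L, piRNA = 30L,
                                                  misc = 2L),
                                  hairpin_length = c(120L, 140L),
                                  arm_length = c(20L, 23L),
                                  flank_length = 18L,
                                  gc = 0.5) {
  n_per_class <- unlist(n_per_class)
  if (any(n_per_class < 0)) stop("n_per_class counts must be >= 0")
  bad <- setdiff(names(n_per_class), REF_CLASSES)
  if (length(bad)) stop("unknown reference class: ", paste(bad, collapse = ", "))
  hairpin_length <- as.integer(range(hairpin_length))
  arm_length <- as.integer(range(arm_length))
  min_loop <- 8L
  if (hairpin_length[1L] < 2L * arm_length[2L] + 2L * flank_length + min_loop) {
    stop("infeasible hairpin geometry: arms, flanks and a loop of >= ",
         min_loop, " nt cannot fit in ", hairpin_length[1L], " nt")
  }

  with_seed(seed, {
    entries <- list(); mature <- list(); loops <- list()
    for (cls in REF_CLASSES) {
      n <- if (cls %in% names(n_per_class)) n_per_class[[cls]] else 0L
      if (n == 0L) next
      if (cls == "miRNA_precursor") {
        for (i in seq_len(n)) {
          id <- sprintf("syn-mir-%d", i)
          total <- sample(hairpin_length[1L]:hairpin_length[2L], 1L)
          a5 <- sample(arm_length[1L]:arm_length[2L], 1L)
          a3 <- sample(arm_length[1L]:arm_length[2L], 1L)
          loop_len <- total - a5 - a3 - 2L * flank_length
          seqs <- random_seq(1L, total, gc)
          s5 <- flank_length
          loop_start <- s5 + a5
          s3 <- loop_start + loop_len
          ## every fifth precursor is single-arm (canonical on one arm only);
          ## the first precursor is always single-arm so small bundles still
          ## exercise opposite-arm logic.
          single <- (i %% 5L == 1L)
          keep_arm <- if (single) sample(c("5p", "3p"), 1L) else c("5p", "3p")
          arm_df <- data.frame(
            precursor_id = id,
            arm = c("5p", "3p"),
            start = c(s5, s3),
            end = c(s5 + a5, s3 + a3),
            name = sprintf("syn-miR-%d-%s", i, c("5p", "3p")),
            stringsAsFactors = FALSE)
          mature[[length(mature) + 1L]] <- arm_df[arm_df$arm %in% keep_arm, ]
          loops[[length(loops) + 1L]] <- data.frame(
            precursor_id = id, start = loop_start, end = s3,
            stringsAsFactors = FALSE)
          entries[[length(entries) + 1L]] <- data.frame(
            ref_id = id, class = cls, sequence = seqs,
            stringsAsFactors = FALSE)
        }
      } else {
        rng <- REF_CLASS_LEN[[cls]]
        lens <- sample(rng[1L]:rng[2L], n, replace = TRUE)
        entries[[length(entries) + 1L]] <- data.frame(
          ref_id = sprintf("syn-%s-%d", cls, seq_len(n)),
          class = cls, sequence = random_seq(n, lens, gc),
          stringsAsFactors = FALSE)
      }
    }
    bundle <- structure(list(
      entries = do.call(rbind, entries),
      mature = if (length(mature)) do.call(rbind, mature) else
        data.frame(precursor_id = character(), arm = character(),
                   start = integer(), end = integer(), name = character(),
                   stringsAsFactors = FALSE),
      loops = if (length(loops)) do.call(rbind, loops) else
        data.frame(precursor_id = character(), start = integer(),
                   end = integer(), stringsAsFactors = FALSE)),
      class = "ev_reference_bundle")
    rownames(bundle$entries) <- NULL
    rownames(bundle$mature) <- NULL
    rownames(bundle$loops) <- NULL
    validate_reference_bundle(bundle)
    bundle
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate reference-bundle invariants
#'
#' Checks that ref_ids are unique, mature intervals lie within their
#' precursors, 5p arms end at or before the loop start and 3p arms start at
#' or after the loop end.
#'
#' @param bundle an \code{ev_reference_bundle}.
#' @return the bundle, invisibly; errors on violation.
#' @export
validate_reference_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "ev_reference_bundle"))
  e <- bundle$entries
  if (anyDuplicated(e$ref_id)) stop("duplicate ref_id in bundle")
  assert_alphabet(e$sequence, extra = "", what = "reference")
  len <- stats::setNames(nchar(e$sequence), e$ref_id)
  m <- bundle$mature
  if (nrow(m)) {
    if (any(!m$precursor_id %in% e$ref_id)) stop("mature arm on unknown precursor")
    if (any(m$start < 0L | m$end > len[m$precursor_id] | m$start >= m$end))
      stop("mature interval outside its precursor")
    lp <- bundle$loops
    li <- match(m$precursor_id, lp$precursor_id)
    ok5 <- m$arm != "5p" | m$end <= lp$start[li]
    ok3 <- m$arm != "3p" | m$start >= lp$end[li]
    if (any(!ok5, na.rm = TRUE)) stop("5p arm extends past loop start")
    if (any(!ok3, na.rm = TRUE)) stop("3p arm starts before loop end")
  }
  invisible(bundle)
}

#' @export
print.ev_reference_bundle <- function(x, ...) {
  cat("Synthetic reference bundle:", nrow(x$entries), "entries\n")
  print(table(x$entries$class))
  cat(nrow(x$mature), "annotated mature arms on",
      length(unique(x$mature$precursor_id)), "precursors;",
      nrow(x$loops), "loop intervals\n")
  invisible(x)
}

## Sequence lookup: named character vector ref_id -> sequence.
bundle_sequences <- function(bundle, classes = NULL) {
  e <- bundle$entries
  if (!is.null(classes)) e <- e[e$class %in% classes, ]
  stats::setNames(e$sequence, e$ref_id)
}

#' Split a reference bundle into annotation-cascade tiers
#'
#' rRNA entries form the first (exclusion) tier, piRNA entries the last
#' tier, and everything else the curated ncRNA middle tier.
#'
#' @param bundle an \code{ev_reference_bundle}.
#' @param sense_only logical; small-RNA libraries are stranded, so matching
#'   is sense-strand only by default.
#' @return a \code{tier_config} (see \code{\link{tier_config}}).
#' @export
bundle_tiers <- function(bundle, sense_only = TRUE) {
  tier_config(
    rrna = bundle_sequences(bundle, "rRNA"),
    ncrnadb = bundle_sequences(
      bundle, setdiff(REF_CLASSES, c("rRNA", "piRNA"))),
    pirna = bundle_sequences(bundle, "piRNA"),
    sense_only = sense_only)
}

#' Write a reference bundle to FASTA + annotation TSV
#'
#' @param bundle an \code{ev_reference_bundle}.
#' @param fasta,anno output paths.  The annotation TSV has columns ref_id,
#'   class, feature (entry/mature/loop), arm, start, end, name with 0-based
#'   half-open coordinates.
#' @return invisibly, the two paths.
#' @export
write_reference_bundle <- function(bundle, fasta, anno) {
  seqs <- Biostrings::DNAStringSet(bundle_sequences(bundle))
  Biostrings::writeXStringSet(seqs, fasta)
  e <- bundle$entries
  rows <- data.frame(ref_id = e$ref_id, class = e$class, feature = "entry",
                     arm = NA_character_, start = 0L,
                     end = nchar(e$sequence), name = NA_character_,
                     stringsAsFactors = FALSE)
  m <- bundle$mature
  if (nrow(m)) {
    cls <- e$class[match(m$precursor_id, e$ref_id)]
    rows <- rbind(rows, data.frame(ref_id = m$precursor_id, class = cls,
                                   feature = "mature", arm = m$arm,
                                   start = m$start, end = m$end,
                                   name = m$name, stringsAsFactors = FALSE))
  }
  lp <- bundle$loops
  if (nrow(lp)) {
    cls <- e$class[match(lp$precursor_id, e$ref_id)]
    rows <- rbind(rows, data.frame(ref_id = lp$precursor_id, class = cls,
                                   feature = "loop", arm = NA_character_,
                                   start = lp$start, end = lp$end,
                                   name = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  utils::write.table(rows, anno, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, anno = anno))
}

#' Read a reference bundle from FASTA + annotation TSV
#'
#' @param fasta,anno paths written by \code{\link{write_reference_bundle}}.
#' @return an \code{ev_reference_bundle}.
#' @export
read_reference_bundle <- function(fasta, anno) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- utils::read.delim(anno, stringsAsFactors = FALSE)
  ent <- tab[tab$feature == "entry", ]
  entries <- data.frame(ref_id = ent$ref_id, class = ent$class,
                        sequence = unname(as.character(seqs[ent$ref_id])),
                        stringsAsFactors = FALSE, row.names = NULL)
  m <- tab[tab$feature == "mature", ]
  lp <- tab[tab$feature == "loop", ]
  bundle <- structure(list(
    entries = entries,
    mature = data.frame(precursor_id = m$ref_id, arm = m$arm,
                        start = m$start, end = m$end, name = m$name,
                        stringsAsFactors = FALSE, row.names = NULL),
    loops = data.frame(precursor_id = lp$ref_id, start = lp$start,
                       end = lp$end, stringsAsFactors = FALSE,
                       row.names = NULL)),
    class = "ev_reference_bundle")
  validate_reference_bundle(bundle)
  bundle
}
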