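## Synthetic 4-library small RNA-seq experiments with planted ground truth.
##
## The generator emulates the study design the package targets: LNCaP cells
## grown with or without DHT and the S-EVs they secrete, i.e. four pooled
## libraries (cell_ctrl, cell_dht, ev_ctrl, ev_dht).  Planted features are
## exact windows on a synthetic reference bundle; reads are feature windows
## with small termini jitter, a 3' sequencing adapter and random filler up
## to the 50-nt read length.  Every read id records the library and the
## truth feature (or noise class) it came from.

LIBRARY_IDS <- c("cell_ctrl", "cell_dht", "ev_ctrl", "ev_dht")

## Planted isomiR taxonomy mixture for arm-derived miRNA features, roughly
## following the category proportions reported for androgen-responsive EV
## miRNAs (canonical forms about a third, 3'-end variants dominating).
ARM_CATEGORY_MIX <- c(canonical = 0.40, shorter_3p = 0.25, longer_3p = 0.17,
                      longer_5p = 0.06, shifted_toward_3p = 0.05,
                      shorter_5p = 0.03, shifted_toward_5p = 0.03,
                      shorter_both = 0.01)

## (d5, d3) offset choices per planted category (sampled uniformly).
CATEGORY_OFFSETS <- list(
  canonical = list(c(0L, 0L)),
  shorter_3p = list(c(0L, -1L), c(0L, -1L), c(0L, -2L)),
  longer_3p = list(c(0L, 1L), c(0L, 1L), c(0L, 2L)),
  shorter_5p = list(c(1L, 0L), c(2L, 0L)),
  longer_5p = list(c(-1L, 0L), c(-2L, 0L)),
  shifted_toward_3p = list(c(1L, 1L), c(2L, 2L), c(1L, 2L)),
  shifted_toward_5p = list(c(-1L, -1L), c(-2L, -2L)),
  shorter_both = list(c(1L, -1L)))

DEFAULT_CLASS_MIX <- c(miRNA = 0.48, SNORD = 0.17, piRNA = 0.12, tRF = 0.09,
                       SNORA = 0.05, scaRNA = 0.02, snRNA = 0.04,
                       scRNA = 0.03)

## Length regimes per compartment: planted feature lengths are kept one
## jitter step inside the target read-length support, so that +-1 nt termini
## jitter can never leave it (a length can change by up to 2 nt when both
## termini move).
CELL_FEATURE_LEN <- c(22L, 23L)   # reads stay within 20-25 nt
EV_FEATURE_LEN <- c(18L, 28L)     # reads stay within 16-30 nt

## GC targets for biased feature selection (EV cargo runs GC-richer than
## cellular small RNA); selection weights are Gaussian around the target.
GC_TARGET_CELL <- 0.455
GC_TARGET_EV <- 0.545
GC_SELECT_SD <- 0.035

## Candidate windows are over-generated by this factor before GC-biased
## selection fills the compartment pools.
CANDIDATE_OVERGEN <- 3L

## Minimum 5'-start separation (nt) between planted features sharing a
## reference, so that read-termini peaks never shadow one another under
## +-1 nt jitter and a +-2 nt peak window.
MIN_START_SEP <- 4L


## sample() treats a length-1 positive-integer x as 1:x; this indexed
## variant never does.
sample_of <- function(x, size, prob = NULL) {
  if (size <= 0L || !length(x)) return(x[0])
  x[sample.int(length(x), size, prob = prob)]
}

round_quota <- function(n, mix) {
  q <- floor(n * mix / sum(mix))
  rem <- n - sum(q)
  if (rem > 0) {
    extra <- order(n * mix / sum(mix) - q, decreasing = TRUE)[seq_len(rem)]
    q[extra] <- q[extra] + 1L
  }
  q
}

feature_sequence <- function(bundle, ref_id, start, end) {
  seqs <- bundle_sequences(bundle)
  substr(seqs[ref_id], start + 1L, end)
}

## Random window candidates on a set of entries, margin 1 nt from both
## entry ends (so termini jitter stays in bounds) and pairwise start
## separation >= MIN_START_SEP within an entry.  Window lengths are drawn
## from len_range with extra weight on the cell-regime lengths so both
## compartment pools can be filled.
window_candidates <- function(entries, n, len_range = c(17L, 28L),
                              category = NA_character_) {
  if (n <= 0L || nrow(entries) == 0L) return(NULL)
  idx <- sample(rep(sample.int(nrow(entries)), length.out = n))
  lens <- len_range[1L]:len_range[2L]
  len_w <- ifelse(lens %in% CELL_FEATURE_LEN[1L]:CELL_FEATURE_LEN[2L], 3, 1)
  out <- vector("list", n)
  taken <- split(integer(0), character(0))
  for (i in seq_len(n)) {
    e <- idx[i]
    len_ref <- nchar(entries$sequence[e])
    L <- min(sample(lens, 1L, prob = len_w), len_ref - 2L)
    lo <- 1L; hi <- len_ref - L - 1L
    prev <- taken[[as.character(e)]]
    start <- NA_integer_
    for (try in 1:60) {
      s <- lo + floor(stats::runif(1L) * (hi - lo + 1L))
      if (!length(prev) || all(abs(prev - s) >= MIN_START_SEP)) {
        start <- s; break
      }
    }
    if (is.na(start)) next  # entry too crowded; drop this candidate
    taken[[as.character(e)]] <- c(prev, start)
    out[[i]] <- data.frame(ref_id = entries$ref_id[e],
                           start = as.integer(start),
                           end = as.integer(start + L),
                           category = category, d5 = NA_integer_,
                           d3 = NA_integer_, arm_name = NA_character_,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## Mirror an interval [a, b) across the loop midpoint of its precursor:
## the opposite-arm region used for single-arm hairpins.
mirror_interval <- function(a, b, loop_start, loop_end, ref_len) {
  s <- loop_start + loop_end - b
  e <- loop_start + loop_end - a
  c(max(0L, s), min(ref_len, e))
}

## Build the planted feature table for a 4-library design.  Candidates are
## over-generated, then GC-biased selection fills a cell pool (feature
## lengths 22-23 nt, GC near 45.5%) and an EV pool (lengths 18-28 nt, GC
## near 54.5%) while preserving the class mixture.
plant_features <- function(bundle, n_features, n_de, fc_range,
                           cell_fraction = 0.45,
                           class_mix = DEFAULT_CLASS_MIX) {
  quota <- round_quota(n_features, class_mix)
  names(quota) <- names(class_mix)
  ent <- bundle$entries
  seqs <- bundle_sequences(bundle)
  reflen <- stats::setNames(nchar(ent$sequence), ent$ref_id)
  cand <- list()
  fixed <- list()

  ## --- miRNA-precursor features -------------------------------------
  n_mir <- quota[["miRNA"]]
  if (n_mir > 0L) {
    n_opp <- max(1L, round(0.04 * n_mir))
    n_tra <- max(1L, round(0.04 * n_mir))
    n_stm <- max(1L, round(0.02 * n_mir))
    n_arm <- n_mir - n_opp - n_tra - n_stm
    m <- bundle$mature
    lp <- bundle$loops
    ## arm-derived candidates: one per annotated arm, category from the
    ## planted taxonomy mix; selection below keeps n_arm of them
    cats <- sample(names(ARM_CATEGORY_MIX), nrow(m), replace = TRUE,
                   prob = ARM_CATEGORY_MIX)
    offs <- t(vapply(cats, function(cc) {
      ch <- CATEGORY_OFFSETS[[cc]]
      ch[[sample.int(length(ch), 1L)]]
    }, integer(2)))
    cand$miRNA <- data.frame(
      ref_id = m$precursor_id,
      start = m$start + offs[, 1L],
      end = m$end + offs[, 2L],
      category = cats, d5 = offs[, 1L], d3 = offs[, 2L],
      arm_name = m$name, quota_class = "miRNA", n_keep = n_arm,
      stringsAsFactors = FALSE)
    ## opposite-arm products on single-arm precursors (always planted)
    arms_per <- table(m$precursor_id)
    single <- names(arms_per)[arms_per == 1L]
    if (length(single) && n_opp > 0L) {
      pick <- sample_of(single, min(n_opp, length(single)))
      rows <- lapply(pick, function(pid) {
        a <- m[m$precursor_id == pid, ]
        l <- lp[lp$precursor_id == pid, ]
        mi <- mirror_interval(a$start, a$end, l$start, l$end, reflen[[pid]])
        data.frame(ref_id = pid, start = mi[1L], end = mi[2L],
                   category = "opposite_arm", d5 = NA_integer_,
                   d3 = NA_integer_, arm_name = a$name,
                   stringsAsFactors = FALSE)
      })
      fixed$opp <- do.call(rbind, rows)
    }
    ## trailer (flank) and stem-loop features (always planted, EV pool)
    pre_ids <- ent$ref_id[ent$class == "miRNA_precursor"]
    if (n_tra > 0L) {
      pick <- sample_of(pre_ids, min(n_tra, length(pre_ids)))
      side <- sample(c("5", "3"), length(pick), replace = TRUE)
      L <- sample(18:20, length(pick), replace = TRUE)
      start <- ifelse(side == "5", 1L, reflen[pick] - L - 1L)
      fixed$trailer <- data.frame(ref_id = pick, start = as.integer(start),
                                  end = as.integer(start + L),
                                  category = "trailer", d5 = NA_integer_,
                                  d3 = NA_integer_, arm_name = NA_character_,
                                  stringsAsFactors = FALSE)
    }
    if (n_stm > 0L) {
      pick <- sample_of(lp$precursor_id, min(n_stm, nrow(lp)))
      li <- match(pick, lp$precursor_id)
      avail <- lp$end[li] - lp$start[li]
      L <- pmin(sample(18:23, length(pick), replace = TRUE), avail - 2L)
      start <- lp$start[li] + 1L +
        floor(stats::runif(length(pick)) * (avail - L - 1L))
      fixed$stem <- data.frame(ref_id = pick, start = as.integer(start),
                               end = as.integer(start + L),
                               category = "stem_loop", d5 = NA_integer_,
                               d3 = NA_integer_, arm_name = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }

  ## --- other classes: over-generated window candidates ---------------
  win_class <- c(SNORD = "SNORD", SNORA = "SNORA", scaRNA = "scaRNA",
                 snRNA = "snRNA", scRNA = "scRNA", piRNA = "piRNA",
                 tRF = "tRNA")
  for (cls in names(win_class)) {
    n_cls <- quota[[cls]]
    if (is.na(n_cls) || n_cls == 0L) next
    pool_entries <- ent[ent$class == win_class[[cls]], ]
    w <- window_candidates(pool_entries, n_cls * CANDIDATE_OVERGEN)
    if (is.null(w)) next
    w$quota_class <- cls
    w$n_keep <- n_cls
    cand[[cls]] <- w
  }

  finalize <- function(df) {
    df$ref_class <- stats::setNames(ent$class, ent$ref_id)[df$ref_id]
    df$class <- ifelse(df$ref_class == "miRNA_precursor", "miRNA",
                ifelse(df$ref_class == "tRNA", "tRF", df$ref_class))
    df$length <- df$end - df$start
    df$sequence <- substr(seqs[df$ref_id], df$start + 1L, df$end)
    df$gc <- gc_fraction(df$sequence)
    df[!duplicated(df[c("ref_id", "start", "end")]), ]
  }

  ## --- GC-biased pool selection, class by class ----------------------
  picked <- lapply(cand, function(cc) {
    cc <- finalize(cc)
    n_keep <- min(cc$n_keep[1L], nrow(cc))
    n_cell <- round(cell_fraction * n_keep)
    elig <- cc$length >= CELL_FEATURE_LEN[1L] &
      cc$length <= CELL_FEATURE_LEN[2L]
    w_cell <- stats::dnorm(cc$gc, GC_TARGET_CELL, GC_SELECT_SD) + 1e-9
    i_cell <- sample_of(which(elig), min(n_cell, sum(elig)),
                        prob = w_cell[elig])
    rest <- setdiff(seq_len(nrow(cc)), i_cell)
    ev_ok <- rest[cc$length[rest] >= EV_FEATURE_LEN[1L] &
                    cc$length[rest] <= EV_FEATURE_LEN[2L]]
    w_ev <- stats::dnorm(cc$gc[ev_ok], GC_TARGET_EV, GC_SELECT_SD) + 1e-9
    n_ev <- min(n_keep - length(i_cell), length(ev_ok))
    i_ev <- sample_of(ev_ok, n_ev, prob = w_ev)
    cc$pool <- NA_character_
    cc$pool[i_cell] <- "cell"
    cc$pool[i_ev] <- "ev"
    cc[!is.na(cc$pool), ]
  })
  fixed_df <- if (length(fixed)) {
    fd <- finalize(do.call(rbind, c(fixed, list(make.row.names = FALSE))))
    fd$pool <- "ev"  # special precursor products are EV cargo here
    fd
  } else NULL
  keep <- c("ref_id", "start", "end", "category", "d5", "d3", "arm_name",
            "ref_class", "class", "length", "sequence", "gc", "pool")
  feats <- do.call(rbind, c(lapply(picked, function(x) x[keep]),
                            if (!is.null(fixed_df)) list(fixed_df[keep]),
                            list(make.row.names = FALSE)))
  feats <- feats[!duplicated(feats[c("ref_id", "start", "end")]), ]

  ## --- expression weights and planted fold changes -------------------
  ## Responsive features are planted as mass-balanced up/down pairs within
  ## one compartment pool: the down partner carries weight w x fc, so each
  ## pair holds the same read mass in both conditions and the realized
  ## within-library proportions reproduce the planted fold changes exactly
  ## in expectation (no compositional shrinkage of the contrast).
  n <- nrow(feats)
  feats$weight <- exp(stats::rnorm(n, 0, 0.6))
  feats$fc <- 1
  feats$planted_de <- FALSE
  n_pairs <- floor(min(n_de, n) / 2)
  for (pool in c("cell", "ev")) {
    avail <- which(feats$pool == pool & !feats$planted_de)
    k <- min(round(n_pairs * mean(feats$pool == pool)),
             floor(length(avail) / 2))
    if (pool == "ev") k <- min(n_pairs - sum(feats$planted_de) / 2,
                               floor(length(avail) / 2))
    if (k <= 0) next
    pick <- sample_of(avail, 2L * k)
    up_i <- pick[seq_len(k)]
    dn_i <- pick[k + seq_len(k)]
    w <- stats::runif(k, 2, 5)    # responsive cargo is well expressed
    f <- stats::runif(k, fc_range[1L], fc_range[2L])
    feats$weight[up_i] <- w
    feats$fc[up_i] <- f
    feats$weight[dn_i] <- w * f
    feats$fc[dn_i] <- 1 / f
    feats$planted_de[c(up_i, dn_i)] <- TRUE
  }

  feats$feature_id <- sprintf("feat%03d_%s", seq_len(n), feats$class)
  rownames(feats) <- NULL
  feats[c("feature_id", "ref_id", "class", "start", "end", "length",
          "sequence", "gc", "pool", "category", "d5", "d3", "arm_name",
          "weight", "fc", "planted_de")]
}

library_table <- function(frac_smallrna, frac_rrna, frac_noise,
                          frac_untrimmed = c(0.02, 0.02, 0.02, 0.02),
                          frac_tooshort = c(0.02, 0.02, 0.02, 0.02)) {
  data.frame(
    library = LIBRARY_IDS,
    compartment = c("cell", "cell", "ev", "ev"),
    condition = c("ctrl", "dht", "ctrl", "dht"),
    frac_smallrna = frac_smallrna, frac_rrna = frac_rrna,
    frac_noise = frac_noise, frac_untrimmed = frac_untrimmed,
    frac_tooshort = frac_tooshort,
    len_lo = c(20L, 20L, 16L, 16L), len_hi = c(25L, 25L, 30L, 30L),
    stringsAsFactors = FALSE)
}

new_design <- function(features, libraries, bundle) {
  stopifnot(all(features$fc > 0))
  len <- stats::setNames(nchar(bundle$entries$sequence),
                         bundle$entries$ref_id)
  if (any(is.na(len[features$ref_id])) ||
      any(features$start < 0L | features$end > len[features$ref_id]))
    stop("planted feature outside its reference")
  structure(list(features = features, libraries = libraries),
            class = "ev_design")
}

#' Study-condition 4-library design
#'
#' Emulates the sequencing arm of the androgen-stimulation experiment: cell
#' libraries carry about 80\% small-RNA-mapping reads with a narrow 20-25 nt
#' length regime and GC near 45-46\%, while EV libraries carry about 10\%
#' small-RNA reads with a broad 16-30 nt regime and GC-richer cargo.
#' Features androgen-responsive at >= 4-fold are planted together with an
#' isomiR category mixture.
#'
#' @param bundle an \code{ev_reference_bundle}.
#' @param n_features,n_de planted feature count and how many of them are
#'   androgen-responsive.
#' @param fc_range linear fold-change range for responsive features
#'   (direction is randomised; down-regulated features get 1/fc).
#' @param seed integer seed.
#' @return an \code{ev_design}.
#' @export
design_androgen_experiment <- function(bundle, n_features = 150L,
                                       n_de = 30L, fc_range = c(4, 8),
                                       seed = 1L) {
  with_seed(seed, {
    feats <- plant_features(bundle, n_features, n_de, fc_range)
    libs <- library_table(frac_smallrna = c(0.80, 0.80, 0.10, 0.10),
                          frac_rrna = c(0.05, 0.05, 0.10, 0.10),
                          frac_noise = c(0.11, 0.11, 0.76, 0.76))
    new_design(feats, libs, bundle)
  })
}

#' Parameter-recovery benchmark design
#'
#' A power-adequate recovery design: 200 planted features of which 40 are
#' androgen-responsive at linear fold change 4-8, with a uniform 85\%
#' small-RNA fraction in all four libraries so that planted contrasts are
#' identifiable at moderate depth.
#'
#' @inheritParams design_androgen_experiment
#' @return an \code{ev_design}.
#' @export
design_recovery_benchmark <- function(bundle, n_features = 200L,
                                      n_de = 40L, fc_range = c(4, 8),
                                      seed = 1L) {
  with_seed(seed, {
    feats <- plant_features(bundle, n_features, n_de, fc_range)
    libs <- library_table(frac_smallrna = rep(0.85, 4),
                          frac_rrna = rep(0.05, 4),
                          frac_noise = rep(0.06, 4))
    new_design(feats, libs, bundle)
  })
}

#' @export
print.ev_design <- function(x, ...) {
  cat("4-library synthetic design:", nrow(x$features), "planted features (",
      sum(x$features$planted_de), "responsive )\n")
  print(table(class = x$features$class, pool = x$features$pool))
  invisible(x)
}

## Per-library feature sampling weights: cell libraries draw only from the
## cell pool; EV libraries draw ~85% of small-RNA mass from the EV pool.
feature_weights <- function(features, compartment, condition) {
  w <- features$weight
  if (compartment == "cell") {
    w <- w * (features$pool == "cell")
  } else {
    w <- w * ifelse(features$pool == "ev", 0.85, 0.15)
  }
  if (condition == "dht") w <- w * features$fc
  w
}

#' Simulate the 4 small RNA-seq libraries of a design
#'
#' Each read is a planted-feature window (with termini jitter), an rRNA
#' window, or a noise read, followed by the 3' adapter and random filler up
#' to 50 nt; additional reads without any adapter occurrence and reads with
#' short (< 15 nt) inserts exercise the trimming filters.  Quality is a
#' constant Q30.  Deterministic per seed.
#'
#' @param bundle an \code{ev_reference_bundle}.
#' @param design an \code{ev_design}.
#' @param depth reads per library.
#' @param adapter 3' adapter sequence.
#' @param termini_jitter named probability vector over integer termini
#'   offsets (applied independently to both termini of each feature read);
#'   must sum to 1.
#' @param seed integer seed.
#' @param outdir if non-NULL, write one FASTQ per library plus a truth TSV.
#' @param read_length total read length before trimming.
#' @return a list with \code{reads} (per-library data.frames of read_id,
#'   sequence), \code{truth} (the feature table with expected and realized
#'   per-library counts), \code{libraries}, and \code{files} when
#'   \code{outdir} is given.
#' @export
simulate_libraries <- function(bundle, design, depth = 1e5,
                               adapter = TRUSEQ_SMALLRNA_ADAPTER,
                               termini_jitter = c("-1" = 0.15, "0" = 0.7,
                                                  "1" = 0.15),
                               seed = 1L, outdir = NULL, read_length = 50L) {
  stopifnot(inherits(design, "ev_design"), depth > 0, nchar(adapter) > 0)
  assert_alphabet(adapter, extra = "", what = "adapter")
  if (abs(sum(termini_jitter) - 1) > 1e-9)
    stop("termini_jitter probabilities must sum to 1")
  offsets <- as.integer(names(termini_jitter))
  if (any(is.na(offsets))) stop("termini_jitter must be named by offsets")
  feats <- design$features
  seqs <- bundle_sequences(bundle)
  len <- stats::setNames(nchar(bundle$entries$sequence),
                         bundle$entries$ref_id)
  if (any(feats$start + min(offsets) < 0L |
            feats$end + max(offsets) > len[feats$ref_id]))
    stop("planted feature too close to its reference end for this jitter")
  rrna <- bundle$entries[bundle$entries$class == "rRNA", ]

  with_seed(seed, {
    libs <- design$libraries
    reads <- list()
    truth <- feats
    for (k in seq_len(nrow(libs))) {
      lib <- libs$library[k]
      w <- feature_weights(feats, libs$compartment[k], libs$condition[k])
      p <- w / sum(w)
      n_cat <- stats::rmultinom(1L, depth, c(
        smallrna = libs$frac_smallrna[k], rrna = libs$frac_rrna[k],
        noise = libs$frac_noise[k], untrimmed = libs$frac_untrimmed[k],
        tooshort = libs$frac_tooshort[k]))[, 1L]
      n_feat <- stats::rmultinom(1L, n_cat[["smallrna"]], p)[, 1L]
      truth[[paste0("expected_", lib)]] <-
        depth * libs$frac_smallrna[k] * p
      truth[[paste0("realized_", lib)]] <- n_feat

      ## feature reads with termini jitter
      fi <- rep.int(seq_len(nrow(feats)), n_feat)
      j5 <- offsets[sample.int(length(offsets), length(fi), replace = TRUE,
                               prob = termini_jitter)]
      j3 <- offsets[sample.int(length(offsets), length(fi), replace = TRUE,
                               prob = termini_jitter)]
      ins_feat <- substr(seqs[feats$ref_id[fi]],
                         feats$start[fi] + j5 + 1L, feats$end[fi] + j3)
      origin_feat <- feats$feature_id[fi]

      ## rRNA contamination: windows in the library's length regime
      n_r <- n_cat[["rrna"]]
      ri <- sample.int(nrow(rrna), n_r, replace = TRUE)
      rl <- sample(libs$len_lo[k]:libs$len_hi[k], n_r, replace = TRUE)
      rs <- 1L + floor(stats::runif(n_r) * (nchar(rrna$sequence[ri]) - rl))
      ins_rrna <- substr(rrna$sequence[ri], rs, rs + rl - 1L)

      ## unmappable noise in the library's length regime
      n_n <- n_cat[["noise"]]
      ins_noise <- random_seq(n_n,
                              sample(libs$len_lo[k]:libs$len_hi[k], n_n,
                                     replace = TRUE))

      ## assemble adapter-bearing reads
      ins <- c(ins_feat, ins_rrna, ins_noise)
      origin <- c(origin_feat, rep("rrna", n_r), rep("noise", n_n))
      full <- paste0(ins, adapter)
      pad <- pmax(0L, read_length - nchar(full))
      full <- substr(paste0(full, random_seq(length(full), pmax(pad, 1L))),
                     1L, read_length)

      ## reads that never saw the adapter (rejection-sampled so no
      ## spurious 3'-terminal occurrence qualifies under default trimming)
      n_u <- n_cat[["untrimmed"]]
      un <- random_seq(n_u, read_length)
      cfg0 <- trim_config(adapter = adapter)
      for (it in 1:50) {
        hit <- !is.na(trim_positions(un, cfg0))
        if (!any(hit)) break
        un[hit] <- random_seq(sum(hit), read_length)
      }
      ## short inserts that trim below the length filter
      n_s <- n_cat[["tooshort"]]
      sh <- random_seq(n_s, sample(5:13, n_s, replace = TRUE))
      sh <- substr(paste0(sh, adapter, random_seq(n_s, read_length)),
                   1L, read_length)

      all_seq <- c(full, un, sh)
      all_origin <- c(origin, rep("untrimmed", n_u), rep("tooshort", n_s))
      ord <- sample.int(length(all_seq))
      reads[[lib]] <- data.frame(
        read_id = sprintf("%s|%s|%06d", lib, all_origin[ord],
                          seq_along(ord)),
        sequence = all_seq[ord], stringsAsFactors = FALSE)
    }
    out <- list(reads = reads, truth = truth, libraries = libs)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      files <- vapply(names(reads), function(lib) {
        f <- file.path(outdir, paste0(lib, ".fastq"))
        write_fastq(reads[[lib]], f)
        f
      }, character(1))
      tf <- file.path(outdir, "truth.tsv")
      utils::write.table(truth, tf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$files <- c(files, truth = tf)
    }
    out
  })
}

#' Write reads to FASTQ (constant Q30 qualities)
#'
#' @param reads data.frame with read_id and sequence columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("?", nchar(reads$sequence))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path.
#' @return data.frame with read_id and sequence.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(x))
  data.frame(read_id = ids, sequence = as.character(x),
             stringsAsFactors = FALSE)
}
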