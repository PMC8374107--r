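## Single-vesicle heterogeneity analysis: capture x detection subpopulation
## counting with IgG isotype-control background subtraction, 5-nm
## size-frequency distributions within the 50-200 nm sizing window, and
## group comparisons (Kruskal-Wallis with Dunn-style follow-ups for
## independent patient groups; one-way ANOVA with Tukey comparisons for
## treatment arms).

#' Apply the sizing window
#'
#' @param particles an \code{ev_particle_table}.
#' @param lo,hi window bounds in nm, both inclusive.
#' @return the filtered table.
#' @export
filter_size_window <- function(particles, lo = 50, hi = 200) {
  out <- particles[particles$size_nm >= lo & particles$size_nm <= hi, ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

## All 8 sign combinations over the detection channels, e.g.
## "CD9+CD63-PSMA-".
detection_combinations <- function() {
  g <- expand.grid(CD9 = c("+", "-"), CD63 = c("+", "-"),
                   PSMA = c("+", "-"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  apply(g, 1L, function(r) paste0(DETECTION_CHANNELS, r, collapse = ""))
}

particle_combo <- function(particles) {
  paste0("CD9", ifelse(particles$ch_CD9 == 1L, "+", "-"),
         "CD63", ifelse(particles$ch_CD63 == 1L, "+", "-"),
         "PSMA", ifelse(particles$ch_PSMA == 1L, "+", "-"))
}

#' Subpopulation counts with IgG background subtraction
#'
#' For every non-IgG capture spot of a subject and every sign combination
#' of the detection channels, the corrected count is
#' \code{max(raw - background, 0) x dilution}, where the background is the
#' count of the same combination on that subject's IgG spot.  Subtraction
#' per combination (rather than on spot totals) is a declared refinement
#' of the isotype-control normalisation.
#'
#' @param particles an \code{ev_particle_table} (one or more subjects),
#'   already size-filtered as desired.
#' @return data.frame: subject_id, group, capture, combination, raw,
#'   background, corrected.
#' @export
count_subpopulations <- function(particles) {
  combos <- detection_combinations()
  out <- lapply(split(particles, particles$subject_id), function(ps) {
    if (!any(ps$capture == "IgG"))
      stop("subject ", ps$subject_id[1L], " has no IgG control spot")
    cc <- particle_combo(ps)
    bg <- table(factor(cc[ps$capture == "IgG"], levels = combos))
    dil <- ps$dilution_factor[1L]
    caps <- setdiff(unique(ps$capture), "IgG")
    rows <- lapply(caps, function(cap) {
      raw <- table(factor(cc[ps$capture == cap], levels = combos))
      data.frame(subject_id = ps$subject_id[1L], group = ps$group[1L],
                 capture = cap, combination = combos,
                 raw = as.integer(raw), background = as.integer(bg),
                 corrected = pmax(as.integer(raw) - as.integer(bg), 0) * dil,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Aggregate subpopulation counts over a channel condition
#'
#' Convenience marginal: sums corrected counts over all combinations
#' matching a pattern such as "CD9+" or "CD9+CD63+" (channels not named
#' are summed over).
#'
#' @param subpops output of \code{\link{count_subpopulations}}.
#' @param pattern channel condition, e.g. "PSMA+CD9+".
#' @return data.frame subject_id, group, capture, corrected (summed).
#' @export
subpop_marginal <- function(subpops, pattern) {
  req <- regmatches(pattern,
                    gregexpr("(CD9|CD63|PSMA)[+-]", pattern))[[1L]]
  if (!length(req)) stop("no channel condition in pattern")
  sel <- rep(TRUE, nrow(subpops))
  for (r in req) sel <- sel & grepl(r, subpops$combination, fixed = TRUE)
  agg <- stats::aggregate(corrected ~ subject_id + group + capture,
                          data = subpops[sel, , drop = FALSE], FUN = sum)
  agg[order(agg$group, agg$subject_id, agg$capture), ]
}

#' Size-frequency distribution
#'
#' @param particles a size-filtered \code{ev_particle_table} (or any
#'   data.frame with size_nm).
#' @param bin_width bin width in nm; bins are left-closed and labelled by
#'   their lower edge (50, 55, 60, ... for the default 5 nm).
#' @return data.frame: bin (lower edge), count, pct; percentages sum to
#'   100.
#' @export
size_frequency <- function(particles, bin_width = 5) {
  sz <- particles$size_nm
  if (!length(sz)) {
    return(data.frame(bin = numeric(0), count = integer(0),
                      pct = numeric(0)))
  }
  bin <- floor(sz / bin_width) * bin_width
  lev <- seq(min(bin), max(bin), by = bin_width)
  tab <- table(factor(bin, levels = lev))
  data.frame(bin = lev, count = as.integer(tab),
             pct = 100 * as.integer(tab) / sum(tab))
}

## Dunn-style rank post-hoc after Kruskal-Wallis: pairwise z statistics on
## mean ranks with the tie-corrected variance, Holm-adjusted by default.
dunn_test <- function(value, group, p_adjust = "holm") {
  g <- factor(group)
  N <- length(value)
  r <- rank(value)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(levels(g), 2L)
  z <- apply(pairs, 2L, function(pr) {
    (rbar[pr[1L]] - rbar[pr[2L]]) /
      sqrt(v * (1 / n[pr[1L]] + 1 / n[pr[2L]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = as.numeric(z),
             p_value = as.numeric(p),
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Compare corrected subpopulation counts between groups
#'
#' Independent patient groups are compared with the Kruskal-Wallis rank
#' test followed by Dunn-style pairwise rank comparisons (Holm-adjusted);
#' treatment arms with ordinary one-way ANOVA followed by Tukey honest
#' significant differences.
#'
#' @param counts data.frame with \code{subject_id}, \code{group} and
#'   \code{value} (one corrected count per subject).
#' @param design "independent_groups" (Kruskal-Wallis / Dunn) or
#'   "treatment_arms" (ANOVA / Tukey).
#' @param p_adjust adjustment for the rank-based pairwise follow-ups.
#' @return list: method, statistic, p_value, pairwise (data.frame),
#'   group_summary (n, median, q1, q3 per group for box-plot style
#'   output), degenerate (TRUE when all values are identical).
#' @export
compare_groups <- function(counts,
                           design = c("independent_groups",
                                      "treatment_arms"),
                           p_adjust = "holm") {
  design <- match.arg(design)
  stopifnot(all(c("group", "value") %in% names(counts)))
  g <- factor(counts$group)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("need >= 2 subjects per group")
  qs <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- counts$value[g == lv]
    data.frame(group = lv, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  if (stats::var(counts$value) == 0) {
    return(list(method = design, statistic = 0, p_value = 1,
                pairwise = NULL, group_summary = qs, degenerate = TRUE))
  }
  if (design == "independent_groups") {
    kw <- stats::kruskal.test(counts$value, g)
    pw <- dunn_test(counts$value, counts$group, p_adjust)
    list(method = "kruskal_wallis", statistic = unname(kw$statistic),
         p_value = kw$p.value, pairwise = pw, group_summary = qs,
         degenerate = FALSE)
  } else {
    fit <- stats::aov(value ~ group, data = transform(counts, group = g))
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$group
    pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adjusted = tk[, "p adj"], stringsAsFactors = FALSE,
                     row.names = NULL)
    list(method = "anova", statistic = an[["F value"]][1L],
         p_value = an[["Pr(>F)"]][1L], pairwise = pw, group_summary = qs,
         degenerate = FALSE)
  }
}
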