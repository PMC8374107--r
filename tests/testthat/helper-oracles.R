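# Independent brute-force oracles used by the property tests.  These are
# deliberately naive re-statements of the contracts (exhaustive enumeration
# over placements/offsets) and share no code with the package internals.

# Exhaustive-search 3'-adapter oracle: try every adapter start, count
# Hamming mismatches ('N' never matches), qualify full occurrences or
# 3'-terminal partials >= min_overlap, keep the minimum-error occurrence
# (leftmost on ties).  Returns the 0-based insert length or NA.
oracle_trim_position <- function(seq, adapter, max_error_rate = 0.1,
                                 min_overlap = 3L) {
  L <- nchar(seq)
  m <- nchar(adapter)
  s_chars <- strsplit(seq, "")[[1L]]
  a_chars <- strsplit(adapter, "")[[1L]]
  best_err <- Inf
  best_pos <- NA_integer_
  for (p in seq_len(L)) {
    k <- min(m, L - p + 1L)
    is_full <- k == m
    is_terminal <- (p + k - 1L) == L
    if (!is_full && !(is_terminal && k >= min_overlap)) next
    err <- 0L
    for (j in seq_len(k)) {
      if (s_chars[p + j - 1L] != a_chars[j] || s_chars[p + j - 1L] == "N")
        err <- err + 1L
    }
    if (err <= floor(max_error_rate * k) && err < best_err) {
      best_err <- err
      best_pos <- p - 1L
    }
  }
  best_pos
}

# Naive substring scan: enumerate every offset of every reference and test
# string equality.
oracle_substring_hits <- function(refs, query) {
  L <- nchar(query)
  hits <- list()
  for (id in names(refs)) {
    n <- nchar(refs[[id]])
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    subs <- substring(refs[[id]], starts, starts + L - 1L)
    off <- which(subs == query) - 1L
    if (length(off))
      hits[[id]] <- data.frame(ref_id = id, offset = off,
                               stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(ref_id = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$ref_id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random reads for the trimming property tests: a mixture of adapter-bearing
# reads (with random mutations in the adapter region), adapter-free reads
# and reads with N bases.
random_trim_reads <- function(n, adapter, max_len = 50L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    kind <- sample(c("clean", "mutated", "none", "n_bases"), 1L,
                   prob = c(0.4, 0.3, 0.2, 0.1))
    ins_len <- sample(0:35, 1L)
    ins <- paste(sample(bases, ins_len, replace = TRUE), collapse = "")
    if (kind == "none") {
      L <- sample(15:max_len, 1L)
      return(paste(sample(bases, L, replace = TRUE), collapse = ""))
    }
    ad <- adapter
    if (kind %in% c("mutated", "n_bases")) {
      a <- strsplit(ad, "")[[1L]]
      nmut <- sample(0:3, 1L)
      pos <- sample(seq_along(a), min(nmut, length(a)))
      a[pos] <- sample(if (kind == "n_bases") c(bases, "N") else bases,
                       length(pos), replace = TRUE)
      ad <- paste(a, collapse = "")
    }
    full <- paste0(ins, ad,
                   paste(sample(bases, max_len, replace = TRUE),
                         collapse = ""))
    substr(full, 1L, sample(20:max_len, 1L))
  }, character(1))
}

# Small shared fixture: a reference bundle and cascade tiers.
tiny_bundle <- function(seed = 11L) {
  make_reference_bundle(
    seed = seed,
    n_per_class = c(miRNA_precursor = 6L, rRNA = 1L, tRNA = 3L,
                    SNORD = 3L, SNORA = 2L, scaRNA = 1L, snRNA = 2L,
                    scRNA = 2L, piRNA = 8L, misc = 1L))
}

# Cached full-scale recovery benchmark shared by the acceptance tests
# (simulation + pipeline take about a minute; compute once).
benchmark_cache <- new.env(parent = emptyenv())
get_benchmark <- function() {
  if (is.null(benchmark_cache$res)) {
    bundle <- make_study_bundle(seed = 101L)
    design <- design_recovery_benchmark(bundle, seed = 102L)
    sim <- simulate_libraries(bundle, design, depth = 1e5, seed = 103L)
    res <- run_smallrna_pipeline(sim$reads, bundle)
    benchmark_cache$res <- list(bundle = bundle, design = design,
                                sim = sim, res = res)
  }
  benchmark_cache$res
}
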