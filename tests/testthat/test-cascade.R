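refs <- c(rna_a = "ACGTACGTACGTACGTACGT",
          rna_b = "TTTTACGTACGTAAAAAAAA",
          rna_c = "GGGGGGGGGGGGGGGGGGGG")

test_that("substring index answers whole-reference and absent queries", {
  idx <- build_index(refs)
  hit <- index_lookup(idx, refs[["rna_a"]])
  expect_equal(hit$ref_id[1], "rna_a")
  expect_equal(hit$offset[1], 0L)
  expect_equal(nrow(index_lookup(idx, "ACGTACGTACGTACGTTTTT")), 0L)
  expect_error(build_index(c(a = "ACGT", a = "GGCC")), "duplicate")
  expect_error(build_index(character(0)), "non-empty")
})

test_that("index equals the naive substring scan on random queries", {
  set.seed(41)
  b <- tiny_bundle()
  some <- bundle_sequences(b)[1:12]
  idx <- build_index(some)
  queries <- c(
    # real windows, windows spanning boundaries, and random absent strings
    vapply(1:600, function(i) {
      s <- some[[sample.int(length(some), 1)]]
      L <- sample(8:24, 1)
      p <- sample(nchar(s) - L, 1)
      substr(s, p, p + L - 1)
    }, character(1)),
    vapply(1:400, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(8:24, 1), TRUE),
            collapse = ""), character(1)))
  for (q in queries) {
    expect_equal(index_lookup(idx, q), oracle_substring_hits(some, q),
                 label = q)
  }
})

test_that("tier order and tie-breaks are deterministic", {
  tiers <- tier_config(
    rrna = c(rrna_1 = "AAAACCCCGGGGTTTTAAAACCCC"),
    ncrnadb = c(nc_a = "TGCATGCAAGGAGGTACGTT",
                nc_b = "CCTGCATGCAAGGAGGTA",
                mir_x = "AAAACCCCGGGGTTTTACGT"),
    pirna = c(pi_1 = "GATTACAGATTACAGATTACA"))

  # shared rRNA / ncRNA read is excluded by the rRNA tier
  r <- assign_read("AAAACCCCGGGGTTTT", tiers)
  expect_equal(r$status, "rRNA_excluded")
  expect_equal(r$tier, "rRNA")

  # piRNA-only read reaches the last tier
  r <- assign_read("GATTACAGATTACA", tiers)
  expect_equal(r$status, "assigned")
  expect_equal(r$tier, "piRNA")

  # two ncRNAdb hits: lexicographically smallest ref_id, multimap recorded
  r <- assign_read("TGCATGCAAGGAGGTA", tiers)
  expect_equal(r$ref_id, "nc_a")
  expect_equal(r$start, 0L)
  expect_equal(r$multimap_count, 2L)

  # near-miss (one mismatch everywhere) stays unmapped
  r <- assign_read("TGCATGCAAGGAGGTC", tiers)
  expect_equal(r$status, "unmapped")
})

test_that("cascade report partitions reads and matches planted fractions", {
  b <- tiny_bundle()
  tiers <- bundle_tiers(b)
  rrna_seq <- bundle_sequences(b, "rRNA")[[1]]
  pre <- bundle_sequences(b, "miRNA_precursor")[[1]]
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    sequence = c(substring(rrna_seq, 1:10, 20:29),
                 substring(pre, 5:94, 26:115)),
    stringsAsFactors = FALSE)
  res <- run_cascade(reads, tiers)
  expect_equal(unname(res$report["rRNA_excluded"]), 10)
  expect_equal(unname(res$report["input"]), 100)
  expect_equal(sum(res$report[c("rRNA_excluded", "assigned_ncRNAdb",
                                "assigned_piRNA", "unmapped")]), 100)
  # assignment coordinates reproduce the read as a reference substring
  a <- res$assignments[res$assignments$status == "assigned", ]
  seqs <- bundle_sequences(b)
  expect_identical(unname(substr(seqs[a$ref_id], a$start + 1, a$end)),
                   unname(reads$sequence[match(a$read_id, reads$read_id)]))

  # all-noise input is 100% unmapped
  noise <- data.frame(read_id = "n1", sequence = strrep("AC", 10),
                      stringsAsFactors = FALSE)
  expect_equal(unname(run_cascade(noise, tiers)$report["unmapped"]), 1)
})

test_that("removing a later tier never changes earlier-tier assignments", {
  b <- tiny_bundle()
  design <- design_androgen_experiment(b, n_features = 20L, n_de = 4L,
                                       seed = 42L)
  sim <- simulate_libraries(b, design, depth = 3000, seed = 43L)
  reads <- trim_set(sim$reads$ev_ctrl)$reads
  full <- run_cascade(reads, bundle_tiers(b))$assignments
  no_pi <- tier_config(rrna = bundle_sequences(b, "rRNA"),
                       ncrnadb = bundle_sequences(
                         b, setdiff(unique(b$entries$class),
                                    c("rRNA", "piRNA"))))
  part <- run_cascade(reads, no_pi)$assignments
  early <- full$tier %in% c("rRNA", "ncRNAdb")
  expect_identical(full[early, ], part[early, ])
  expect_true(all(part$status[!early] == "unmapped"))
})
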