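# A hand-built hairpin: 10-nt flanks, arms of 22, loop of 15.
flank <- 10L; arm_len <- 22L; loop_len <- 15L
pre_len <- 2L * flank + 2L * arm_len + loop_len
mature2 <- data.frame(
  precursor_id = "mirX", arm = c("5p", "3p"),
  start = c(flank, flank + arm_len + loop_len),
  end = c(flank + arm_len, flank + 2L * arm_len + loop_len),
  name = c("syn-miR-X-5p", "syn-miR-X-3p"), stringsAsFactors = FALSE)
loop2 <- c(flank + arm_len, flank + arm_len + loop_len)

test_that("the (d5, d3) decision table is exhaustive and recovers offsets", {
  arm <- mature2[1, ]
  for (d5 in -5:5) for (d3 in -5:5) {
    cl <- classify_isomir(arm$start + d5, arm$end + d3, mature2, loop2,
                          pre_len)
    expect_equal(cl$d5, d5)
    expect_equal(cl$d3, d3)
    want <-
      if (d5 == 0 && d3 == 0) "canonical"
      else if (d5 == 0) if (d3 < 0) "shorter_3p" else "longer_3p"
      else if (d3 == 0) if (d5 > 0) "shorter_5p" else "longer_5p"
      else if (d5 > 0 && d3 > 0) "shifted_toward_3p"
      else if (d5 < 0 && d3 < 0) "shifted_toward_5p"
      else if (d5 > 0 && d3 < 0) "shorter_both"
      else "longer_both"
    expect_equal(cl$category, want)
    expect_equal(cl$matched_canonical, "syn-miR-X-5p")
  }
})

test_that("loop and flank products classify as stem-loop and trailer", {
  cl <- classify_isomir(loop2[1] + 1L, loop2[2] - 1L, mature2, loop2,
                        pre_len)
  expect_equal(cl$category, "stem_loop")
  cl <- classify_isomir(0L, 9L, mature2, loop2, pre_len)
  expect_equal(cl$category, "trailer")
  expect_error(classify_isomir(30L, 20L, mature2, loop2, pre_len),
               "no overlap")
})

test_that("single-arm precursors yield opposite-arm calls via mirroring", {
  m3 <- mature2[2, ]  # only the 3p arm is annotated
  regions <- precursor_regions(m3, loop2, pre_len)
  opp <- regions[regions$region == "opposite_arm", ]
  expect_equal(nrow(opp), 1L)
  expect_equal(opp$name, "syn-miR-X-5p")
  # the mirror of the 3p arm across the loop midpoint lands on the 5p side
  expect_lte(opp$end, loop2[1])
  cl <- classify_isomir(opp$start + 1L, opp$end - 1L, m3, loop2, pre_len)
  expect_equal(cl$category, "opposite_arm")
  expect_equal(cl$matched_canonical, "syn-miR-X-5p")
})

test_that("fragments locate on their precursor exactly as brute force", {
  set.seed(71)
  pre <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  for (i in 1:50) {
    L <- sample(15:25, 1); p <- sample(120 - L, 1)
    frag <- substr(pre, p, p + L - 1)
    loc <- locate_on_precursor(frag, pre)
    expect_true(loc$found)
    # leftmost occurrence by direct scan
    starts <- seq_len(120 - L + 1)
    want <- which(substring(pre, starts, starts + L - 1) == frag)
    expect_equal(loc$start, want[1] - 1L)
    expect_equal(loc$n_occurrences, length(want))
  }
  expect_false(locate_on_precursor("AAAAAAAAAAAAAAAAAAAAAAAA", pre)$found)
})

test_that("taxonomy summary partitions calls and rounds percentages", {
  calls <- data.frame(
    category = c(rep("canonical", 5), rep("shorter_3p", 3),
                 rep("longer_3p", 2), "opposite_arm", "trailer"),
    stringsAsFactors = FALSE)
  s <- summarize_isomirs(calls)
  expect_equal(s$n[s$category == "Total"], 12)
  expect_equal(s$n[s$category == "isomiRs"], 5)
  leaf <- !s$is_subtotal
  expect_equal(sum(s$n[leaf]), 12)
  expect_equal(s$pct[s$category == "canonical"], round(100 * 5 / 12))
  empty <- summarize_isomirs(calls[0, , drop = FALSE])
  expect_true(all(empty$n == 0))
})

test_that("only differentially expressed fragments are classified by default", {
  b <- tiny_bundle()
  design <- design_androgen_experiment(b, n_features = 25L, n_de = 8L,
                                       seed = 72L)
  sim <- simulate_libraries(b, design, depth = 3e4, seed = 73L)
  res <- run_smallrna_pipeline(sim$reads, b)
  de_ids <- res$expression$fragment_id[
    res$expression$de_ev %in% c("up", "down")]
  expect_true(all(res$isomir_calls$ev$fragment_id %in% de_ids))
  all_calls <- classify_isomirs(res$fragments, b, res$expression,
                                only_de = FALSE)
  expect_gte(nrow(all_calls), nrow(res$isomir_calls$ev))
})
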