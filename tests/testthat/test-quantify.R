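test_that("RPM scaling normalises each library to one million", {
  counts <- matrix(c(250000, 750000), nrow = 2,
                   dimnames = list(c("f1", "f2"), "lib"))
  expect_equal(unname(rpm_scale(counts, 1e6)[, 1]), c(250000, 750000))
  expect_equal(unname(rpm_scale(matrix(42, 1, 1), 42)[1, 1]), 1e6)
  set.seed(61)
  m <- matrix(rpois(40, 200), 10, 4,
              dimnames = list(sprintf("f%d", 1:10), sprintf("l%d", 1:4)))
  expect_equal(unname(colSums(rpm_scale(m))), rep(1e6, 4))
  expect_error(rpm_scale(m, c(0, 1, 1, 1)), "> 0")
})

test_that("inclusion needs >= 10 reads in at least one library", {
  m <- rbind(a = c(12, 0, 0, 0), b = c(9, 9, 9, 9), c = c(10, 0, 0, 0))
  expect_equal(unname(filter_included(m)), c(TRUE, FALSE, TRUE))
  # strict reading: >= 10 in every library
  expect_equal(unname(filter_included(m, strict = TRUE)),
               c(FALSE, FALSE, FALSE))
  expect_true(filter_included(rbind(c(10, 10, 10, 10)), strict = TRUE))
})

test_that("fold-change calls follow the 4-fold rule and are antisymmetric", {
  expect_equal(call_de(10, 40, pseudocount = 0)$de_status, "up")
  expect_equal(call_de(10, 40, pseudocount = 0)$linear_fc, 4)
  expect_equal(call_de(7, 7)$de_status, "unchanged")
  d <- call_de(8, 0, pseudocount = 1)
  expect_equal(d$linear_fc, 1 / 9)
  expect_equal(d$de_status, "down")

  set.seed(62)
  a <- runif(200, 0, 5000); b <- runif(200, 0, 5000)
  ab <- call_de(a, b); ba <- call_de(b, a)
  expect_equal(ab$linear_fc, 1 / ba$linear_fc)
  swap <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(swap[ab$de_status]), ba$de_status)
})

test_that("class summary reproduces the subtotal structure", {
  leaf <- data.frame(class = c("SNORD", "SNORA", "scaRNA"),
                     de = c(91, 38, 11))
  s <- class_summary(leaf)
  expect_equal(s$de[s$class == "sdRNA"], 140)
  empty <- class_summary(data.frame(class = character(), de = numeric()))
  expect_true(all(empty$de == 0))
  expect_error(class_summary(data.frame(class = "lncRNA", de = 1)),
               "unknown class")
})

test_that("expression table wires counts, flags and contrasts together", {
  counts <- matrix(c(100, 400, 5, 3, 90, 410, 2, 1500,
                     120, 380, 4, 900, 110, 390, 3, 95),
                   nrow = 4,
                   dimnames = list(c("fA", "fB", "fC", "fD"),
                                   c("cell_ctrl", "cell_dht",
                                     "ev_ctrl", "ev_dht")))
  cls <- c(fA = "miRNA", fB = "SNORD", fC = "piRNA", fD = "tRF")
  tab <- build_expression_table(counts, cls)
  expect_equal(tab$included, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tab$de_ev[tab$fragment_id == "fC"], "excluded")
  expect_true(all(tab$fc_ev > 0))
  s <- summarize_classes(tab, "ev")
  expect_equal(s$detected[s$class == "Total"], 3)
})

test_that("library summary reports GC and composition against truth", {
  b <- tiny_bundle()
  design <- design_androgen_experiment(b, n_features = 25L, n_de = 6L,
                                       seed = 63L)
  sim <- simulate_libraries(b, design, depth = 2e4, seed = 64L)
  tr <- trim_set(sim$reads$cell_ctrl)
  tr$reads$library <- "cell_ctrl"
  casc <- run_cascade(tr$reads, bundle_tiers(b))
  s <- summarize_library(tr$report, casc, tr$reads)
  # planted rRNA fraction: 5% of depth among ~96% retained reads
  expect_equal(s$rrna_reads / 2e4, 0.05, tolerance = 0.25)
  expect_gt(s$smallrna_pct, 70)
  expect_equal(sum(s$length_histogram), s$filtered_reads)
  expect_true(all(as.integer(names(s$length_histogram)) %in% 20:25))

  # all-GC reads give GC% = 100
  gg <- data.frame(read_id = "g", sequence = "GGGGCCCC",
                   stringsAsFactors = FALSE)
  expect_equal(100 * evcargo::gc_fraction(gg$sequence), 100)
})
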