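bundle <- tiny_bundle()
design <- design_androgen_experiment(bundle, n_features = 25L, n_de = 6L,
                                     seed = 21L)

test_that("identical seeds give byte-identical FASTQ and truth files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_libraries(bundle, design, depth = 2000, seed = 5L,
                           outdir = d1)
  s2 <- simulate_libraries(bundle, design, depth = 2000, seed = 5L,
                           outdir = d2)
  for (f in basename(s1$files)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every read is accounted for and traces to one origin", {
  sim <- simulate_libraries(bundle, design, depth = 5000, seed = 6L)
  for (lib in names(sim$reads)) {
    rr <- sim$reads[[lib]]
    expect_equal(nrow(rr), 5000)
    origin <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", rr$read_id)
    tab <- table(origin)
    feat_tab <- tab[grep("^feat", names(tab))]
    realized <- sim$truth[[paste0("realized_", lib)]]
    names(realized) <- sim$truth$feature_id
    realized <- realized[realized > 0]
    expect_equal(as.integer(feat_tab[names(realized)]),
                 unname(realized))
    # feature + contamination + noise + filter-fodder reads partition depth
    expect_equal(sum(tab), 5000)
  }
})

test_that("realized counts track expectations within binomial error", {
  sim <- simulate_libraries(bundle, design, depth = 5e4, seed = 7L)
  tr <- sim$truth
  for (lib in c("cell_ctrl", "cell_dht", "ev_ctrl", "ev_dht")) {
    e <- tr[[paste0("expected_", lib)]]
    r <- tr[[paste0("realized_", lib)]]
    sel <- e >= 50
    se <- sqrt(e[sel])  # binomial SE, p small
    expect_true(all(abs(r[sel] - e[sel]) <= 4 * se),
                label = paste("counts near expectation in", lib))
  }
  # planted >= 4-fold contrast is realized within 3 binomial SE
  de <- tr[tr$planted_de & tr$pool == "ev" &
             tr$expected_ev_ctrl >= 50 & tr$expected_ev_dht >= 50, ]
  ratio <- de$realized_ev_dht / de$realized_ev_ctrl
  se_log <- sqrt(1 / de$expected_ev_ctrl + 1 / de$expected_ev_dht)
  expect_true(all(abs(log(ratio) - log(de$fc)) <= 3 * se_log))
})

test_that("degenerate jitter gives identical termini for all feature reads", {
  sim <- simulate_libraries(bundle, design, depth = 3000, seed = 8L,
                            termini_jitter = c("0" = 1))
  rr <- sim$reads$ev_ctrl
  trm <- trim_set(rr)
  origin <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", trm$reads$read_id)
  feat_seq <- stats::setNames(sim$truth$sequence, sim$truth$feature_id)
  is_feat <- grepl("^feat", origin)
  expect_gt(sum(is_feat), 0)
  expect_identical(trm$reads$sequence[is_feat],
                   unname(feat_seq[origin[is_feat]]))
})

test_that("library length regimes match the planted supports", {
  sim <- simulate_libraries(bundle, design, depth = 2e4, seed = 9L)
  cell <- trim_set(sim$reads$cell_ctrl)$reads$sequence
  ev <- trim_set(sim$reads$ev_dht)$reads$sequence
  expect_true(all(nchar(cell) >= 20 & nchar(cell) <= 25))
  expect_true(all(nchar(ev) >= 16 & nchar(ev) <= 30))
})

test_that("jitter probabilities and feature bounds are validated", {
  expect_error(simulate_libraries(bundle, design, depth = 100, seed = 1L,
                                  termini_jitter = c("0" = 0.5)),
               "sum to 1")
  bad <- design
  bad$features$end[1] <- 10000L
  expect_error(simulate_libraries(bundle, bad, depth = 100, seed = 1L),
               "outside|too close")
})

test_that("particle simulation is deterministic and honours planted truth", {
  truth <- particle_truth_patients()
  p1 <- simulate_particles(truth, seed = 3L)
  p2 <- simulate_particles(truth, seed = 3L)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "p1.csv"); f2 <- file.path(d, "p2.csv")
  write_particle_csv(p1, f1); write_particle_csv(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(sum(n <- table(p1$group)["AdvPCa"]) > 0, TRUE)

  # zero planted rate leaves the spot empty
  t0 <- truth
  t0$rate[t0$group == "BPH" & t0$capture == "CD81"] <- 0
  p0 <- simulate_particles(t0, seed = 4L)
  expect_equal(sum(p0$group == "BPH" & p0$capture == "CD81"), 0L)

  # the planted modal 5-nm bin is recovered empirically
  cd9 <- filter_size_window(p1[p1$group == "AdvPCa" & p1$capture == "CD9", ])
  sf <- size_frequency(cd9)
  expect_equal(sf$bin[which.max(sf$count)], 55)
})

test_that("invalid particle truth is rejected", {
  truth <- particle_truth_patients()
  truth$p_PSMA[1] <- 1.5
  expect_error(simulate_particles(truth, seed = 1L), "positivity")
  truth <- particle_truth_patients()
  truth$size_mode[1] <- 300
  expect_error(simulate_particles(truth, seed = 1L), "size modes")
})
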