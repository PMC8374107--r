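mk_particles <- function(capture, n, cd9 = 0, cd63 = 0, psma = 0,
                         size = 55, subject = "s1", group = "BPH") {
  data.frame(subject_id = subject, group = group, capture = capture,
             size_nm = rep_len(size, n), ch_CD9 = rep_len(cd9, n),
             ch_CD63 = rep_len(cd63, n), ch_PSMA = rep_len(psma, n),
             dilution_factor = 1, stringsAsFactors = FALSE)
}

test_that("the sizing window is inclusive at both edges", {
  p <- mk_particles("CD9", 4, size = c(45, 50, 200, 200.5))
  f <- filter_size_window(p)
  expect_equal(f$size_nm, c(50, 200))
  expect_equal(nrow(filter_size_window(p[0, ])), 0L)
})

test_that("IgG background subtraction floors at zero per combination", {
  p <- rbind(mk_particles("CD9", 500, cd9 = 1),
             mk_particles("IgG", 20, cd9 = 1),
             mk_particles("IgG", 30, cd63 = 1))
  s <- count_subpopulations(p)
  cd9pos <- s[s$capture == "CD9" & s$combination == "CD9+CD63-PSMA-", ]
  expect_equal(cd9pos$raw, 500L)
  expect_equal(cd9pos$background, 20L)
  expect_equal(cd9pos$corrected, 480)
  # IgG exceeds raw on the CD63-only combination: floored at zero
  floorrow <- s[s$capture == "CD9" & s$combination == "CD9-CD63+PSMA-", ]
  expect_equal(floorrow$corrected, 0)
  # the 8 sign combinations partition the spot's particles (pre-subtraction)
  expect_equal(sum(s$raw[s$capture == "CD9"]), 500L)
  expect_error(count_subpopulations(mk_particles("CD9", 5)), "IgG")
})

test_that("detection combinations partition simulated spots exactly", {
  p <- simulate_particles(particle_truth_patients(),
                          n_subjects = c(BPH = 2, LPCa = 2, AdvPCa = 2),
                          seed = 81L)
  s <- count_subpopulations(p)
  for (sub in unique(s$subject_id)) {
    for (cap in unique(s$capture[s$subject_id == sub])) {
      sel <- s$subject_id == sub & s$capture == cap
      expect_equal(sum(s$raw[sel]),
                   sum(p$subject_id == sub & p$capture == cap))
      expect_true(all(s$corrected[sel] >= 0))
    }
  }
})

test_that("triple-positive recovery stays within Poisson error of truth", {
  truth <- particle_truth_patients()
  row <- truth$group == "AdvPCa" & truth$capture == "CD9"
  lam <- truth$rate[row] * truth$p_CD9[row] * truth$p_CD63[row] *
    truth$p_PSMA[row]
  p <- simulate_particles(truth[truth$group == "AdvPCa", ],
                          n_subjects = c(AdvPCa = 40), seed = 82L,
                          subject_cv = 0)
  s <- count_subpopulations(p)
  trip <- s[s$capture == "CD9" & s$combination == "CD9+CD63+PSMA+", ]
  expect_equal(nrow(trip), 40L)
  mean_raw <- mean(trip$raw)
  se <- sqrt(lam / 40)
  expect_lt(abs(mean_raw - lam), 3 * se)
})

test_that("size histograms use left-closed 5-nm bins summing to 100%", {
  p <- mk_particles("CD9", 4, size = c(50, 50, 55, 60))
  h <- size_frequency(p)
  expect_equal(h$bin, c(50, 55, 60))
  expect_equal(h$pct, c(50, 25, 25))
  expect_equal(sum(h$pct), 100)
  set.seed(83)
  pu <- mk_particles("CD9", 5000, size = runif(5000, 50, 100))
  hu <- size_frequency(pu)
  expect_equal(sum(hu$pct), 100)
  expect_true(max(hu$count) < 2 * min(hu$count))  # flat within noise
})

test_that("group comparisons behave at the null, the boundary and with effects", {
  # identical groups: H = 0, p = 1
  cnt <- data.frame(subject_id = sprintf("s%d", 1:6),
                    group = rep(c("a", "b"), each = 3), value = rep(1:3, 2))
  r <- compare_groups(cnt)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$degenerate)
  # all-identical values: degenerate flag
  cnt0 <- transform(cnt, value = 5)
  expect_true(compare_groups(cnt0)$degenerate)

  # null simulation: three groups from one distribution
  set.seed(84)
  p_null <- replicate(100, {
    x <- data.frame(subject_id = sprintf("s%d", 1:36),
                    group = rep(c("a", "b", "c"), each = 12),
                    value = rlnorm(36, 5, 0.4))
    compare_groups(x)$p_value
  })
  expect_gte(mean(p_null > 0.05), 0.90)

  # planted 3-fold shift at the cohort sizes is detected
  truth <- particle_truth_patients()
  p <- simulate_particles(truth, seed = 85L)
  s <- count_subpopulations(filter_size_window(p))
  cd9 <- subpop_marginal(s[s$capture == "CD9", ], "CD9+")
  r <- compare_groups(data.frame(subject_id = cd9$subject_id,
                                 group = cd9$group, value = cd9$corrected))
  expect_lt(r$p_value, 0.05)
  adv <- r$pairwise$p_adjusted[
    (r$pairwise$group1 == "AdvPCa" | r$pairwise$group2 == "AdvPCa") &
      (r$pairwise$group1 == "BPH" | r$pairwise$group2 == "BPH")]
  expect_lt(adv, 0.05)

  # treatment arms use ANOVA + Tukey
  set.seed(86)
  arms <- data.frame(subject_id = sprintf("s%d", 1:15),
                     group = rep(c("CSS", "CSS+DHT", "FBS"), each = 5),
                     value = c(rnorm(5, 10), rnorm(5, 30), rnorm(5, 11)))
  ra <- compare_groups(arms, design = "treatment_arms")
  expect_equal(ra$method, "anova")
  expect_lt(ra$p_value, 0.05)
  expect_true(any(ra$pairwise$p_adjusted < 0.05))
})
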