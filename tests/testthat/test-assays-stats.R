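test_that("MIC is the lowest no-growth concentration of a clean series", {
  conc <- c(1, 2, 4, 8, 16, 32, 64, 128)
  growth <- matrix(rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), 3),
                   nrow = 3, byrow = TRUE)
  res <- mic_call(conc, growth)
  expect_identical(res$mic, "8")
  expect_equal(res$value, 8)
  expect_length(res$flags, 0L)
})

test_that("growth at every concentration reports an above-range MIC", {
  conc <- c(1, 2, 4, 8, 16, 32, 64, 128)
  res <- mic_call(conc, matrix(TRUE, 2, 8))
  expect_identical(res$mic, ">128")
  expect_true(is.na(res$value))
})

test_that("replicate disagreement consolidates to an en-dash range", {
  conc <- c(1, 2, 4, 8, 16, 32, 64, 128)
  growth <- rbind(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),  # 16
                  c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))   # 32
  res <- mic_call(conc, growth)
  expect_identical(res$mic, "16–32")
  expect_equal(res$per_replicate, c(16, 32))
  expect_length(res$flags, 0L)
  # a two-step disagreement is flagged
  growth2 <- rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), # 8
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))   # 32
  expect_true(any(grepl("more than one dilution", mic_call(conc, growth2)$flags)))
})

test_that("non-monotone growth is flagged and called above the highest growth", {
  conc <- c(1, 2, 4, 8, 16, 32)
  res <- mic_call(conc, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(any(grepl("non-monotone", res$flags)))
  expect_equal(res$value, 8)
})

test_that("OD readings convert to growth via the threshold", {
  conc <- c(2, 4, 8)
  res <- mic_call(conc, od = matrix(c(0.5, 0.4, 0.01), 1))
  expect_identical(res$mic, "8")
})

test_that("an exponential-approach release trace plateaus within two minutes", {
  # tau = 0.5 min first-order approach after addition at t = 10 min
  t <- seq(0, 20, by = 0.05)
  sig <- ifelse(t < 10, 100, 100 + 50 * (1 - exp(-(t - 10) / 0.5)))
  res <- disc_summary(t, sig, addition_time = 10)
  expect_equal(res$baseline, 100)
  expect_lte(res$time_to_plateau, 2)
  expect_equal(res$release, 50, tolerance = 0.05)
  expect_length(res$flags, 0L)
})

test_that("a ramp without a plateau is flagged", {
  t <- seq(0, 20, by = 0.1)
  sig <- ifelse(t < 10, 100, 100 + 20 * (t - 10))
  res <- disc_summary(t, sig, addition_time = 10)
  expect_true("no plateau" %in% res$flags)
  expect_true(is.na(res$release))
})

test_that("an unstable baseline is flagged", {
  t <- seq(0, 20, by = 0.1)
  sig <- ifelse(t < 10, 100 + 10 * sin(t * 3), 150)
  res <- disc_summary(t, sig, addition_time = 10)
  expect_true("unstable baseline" %in% res$flags)
})

test_that("zone area subtracts the producer spot and rejects impossible inputs", {
  expect_equal(zone_area(120, 20), 100)
  expect_error(zone_area(10, 20), "exceeds")
})

test_that("competition abundance is the percentage of species A", {
  expect_equal(competition_abundance(43, 57), 43)
  expect_error(competition_abundance(0, 0), "no cells")
})

test_that("aspect ratio separates rods from cocci", {
  cells <- data.frame(length = c(2.5, 0.9, 1.6, 1.0),
                      width = c(0.8, 0.8, 0.8, 0.8))
  m <- classify_morphology(cells)
  expect_identical(m$rods, 2L)
  expect_identical(m$cocci, 2L)
  expect_equal(m$percent_cocci, 50)
})

test_that("the pooled t-test matches the textbook formula to six decimals", {
  a <- c(5.1, 4.9, 5.6, 4.7, 5.3)
  b <- c(6.0, 6.3, 5.8, 6.4, 6.1, 5.9)
  res <- ttest_groups(a, b)
  o <- oracle_student_t(a, b)
  expect_equal(res$t, o$t, tolerance = 1e-9)
  expect_equal(res$df, o$df)
  expect_lt(abs(res$p - o$p), 5e-7)
  expect_equal(res$mean_diff, mean(a) - mean(b))
})

test_that("null p-values are uniform over repeated simulation", {
  p <- with_seed(2024, vapply(seq_len(2000), function(i) {
    ttest_groups(rnorm(6), rnorm(6))$p
  }, numeric(1)))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # empirical type-I error near the nominal level
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("star bins follow the legend mapping with boundary conventions", {
  expect_identical(star_class(0.5), "ns")
  expect_identical(star_class(0.05), "ns")     # exactly .05 is not significant
  expect_identical(star_class(0.049), "*")
  expect_identical(star_class(0.01), "**")     # boundaries go to the stronger bin
  expect_identical(star_class(0.001), "***")
  expect_identical(star_class(1e-4), "****")
  expect_identical(star_class(1e-6), "****")
  expect_error(star_class(1.5))
})

test_that("degenerate equal constant groups return a null test result", {
  res <- ttest_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_identical(res$stars, "ns")
  expect_error(ttest_groups(1, c(1, 2)), "n >= 2")
})
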