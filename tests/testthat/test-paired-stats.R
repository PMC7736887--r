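# Exact Wilcoxon signed-rank, Hodges-Lehmann intervals, stratified
# summaries.

test_that("signed-rank statistic and exact p match hand enumeration", {
  w <- wilcoxonSignedRank(c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 15)
  expect_equal(w$p.value, 0.0625, tolerance = 1e-12)
  expect_true(w$exact)
})

test_that("perfectly symmetric differences give p = 1", {
  expect_equal(wilcoxonSignedRank(c(1, -1))$p.value, 1)
  res <- wilcoxonSignedRank(c(0, 0, 0))
  expect_equal(res$p.value, 1)
  expect_true(res$degenerate)
})

test_that("exact p equals full 2^n enumeration for n <= 12", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), 6)
    while (anyDuplicated(abs(d)) || any(d == 0)) d <- round(rnorm(n), 6)
    got <- wilcoxonSignedRank(d)
    expect_true(got$exact)
    expect_equal(got$p.value, oracle_wilcoxon_p(d), tolerance = 1e-12,
                 label = sprintf("case %d (n=%d)", i, n))
  }
})

test_that("ties and large n use the corrected normal approximation", {
  set.seed(7)
  cases <- list(c(1, -1, 2, 2, 3), round(rnorm(25), 1),
                c(0.5, 0.5, -0.5, 1, 2, -2, 3))
  for (d in cases) {
    got <- wilcoxonSignedRank(d)
    want <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE))$p.value
    expect_false(got$exact)
    expect_equal(got$p.value, want, tolerance = 1e-10)
  }
})

test_that("Walsh-average estimate matches hand enumeration", {
  hl <- hodgesLehmannCI(c(1, 2, 3))
  expect_equal(hl$estimate, 2)
  expect_equal(sort(dualPET:::walsh_averages(c(1, 2, 3))),
               c(1, 1.5, 2, 2, 2.5, 3))
})

test_that("symmetric differences give a zero Hodges-Lehmann estimate", {
  expect_equal(hodgesLehmannCI(c(-2, -1, 0, 1, 2))$estimate, 0)
})

test_that("CI endpoints are Walsh averages bracketing the estimate", {
  set.seed(12)
  d <- rnorm(10, 1)
  hl <- hodgesLehmannCI(d)
  w <- sort(dualPET:::walsh_averages(d))
  expect_true(hl$lo %in% w && hl$hi %in% w)
  expect_lte(hl$lo, hl$estimate)
  expect_gte(hl$hi, hl$estimate)
  expect_true(hl$attained)
})

test_that("tiny samples return the widest attainable interval, flagged", {
  hl <- hodgesLehmannCI(c(1, 2), level = 0.95)
  expect_false(hl$attained)
  expect_equal(c(hl$lo, hl$hi), range(dualPET:::walsh_averages(c(1, 2))))
})

test_that("HL interval coverage is conservative on shifted cohorts", {
  set.seed(31)
  hits <- 0L
  nsim <- 400
  for (i in seq_len(nsim)) {
    d <- rnorm(10) + 0.7
    hl <- hodgesLehmannCI(d)
    hits <- hits + (hl$lo <= 0.7 && hl$hi >= 0.7)
  }
  expect_gte(hits / nsim, 0.93)
})

test_that("modality comparison reproduces the n = 3 worked example", {
  db <- data.frame(case = c("a", "b", "c"), v = c(2, 3, 4))
  wb <- data.frame(case = c("a", "b", "c"), v = c(1, 1, 1))
  row <- compareModalities(db, wb)
  expect_equal(row$hl_difference, 2)
  expect_equal(row$p_value, 0.25, tolerance = 1e-12)
})

test_that("identical tables give zero estimates and degenerate p = 1", {
  db <- data.frame(case = letters[1:4], x = c(1, 2, 3, 4),
                   y = c(2, 2, 2, 2))
  rows <- compareModalities(db, db)
  expect_true(all(rows$hl_difference == 0))
  expect_true(all(rows$p_value == 1))
  expect_true(all(rows$degenerate))
})

test_that("comparison has one row per requested feature", {
  set.seed(2)
  db <- cbind(data.frame(case = sprintf("c%02d", 1:10)),
              as.data.frame(matrix(rnorm(200), 10,
                                   dimnames = list(NULL, featureNames()))))
  wb <- db
  wb[featureNames()] <- wb[featureNames()] + rnorm(200, 0.2)
  rows <- compareModalities(db, wb, features = featureNames())
  expect_equal(nrow(rows), 20L)
  expect_identical(rows$feature, featureNames())
})

test_that("unmatched case IDs are reported", {
  db <- data.frame(case = c("a", "b"), v = 1:2)
  wb <- data.frame(case = c("a", "z"), v = 1:2)
  expect_error(compareModalities(db, wb), "unmatched.*[bz]")
})

test_that("swapping modalities negates estimates and preserves p", {
  set.seed(14)
  db <- data.frame(case = sprintf("c%d", 1:9), v = rnorm(9, 2))
  wb <- data.frame(case = sprintf("c%d", 1:9), v = rnorm(9, 1))
  fwd <- compareModalities(db, wb)
  rev <- compareModalities(wb, db)
  expect_equal(rev$hl_difference, -fwd$hl_difference, tolerance = 1e-12)
  expect_equal(rev$ci_lo, -fwd$ci_hi, tolerance = 1e-12)
  expect_equal(rev$ci_hi, -fwd$ci_lo, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("stratified fold change reproduces the published worked example", {
  ref <- read.csv(system.file("extdata", "reference_uptake_medians.csv",
                              package = "dualPET"))
  ref <- ref[ref$metric == "SUL_peak", ]
  tab <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    data.frame(case = paste0(ref$stratum[i], c("_1", "_2")),
               modality = ref$modality[i],
               d_MRI_cm = if (ref$stratum[i] == "le2.5") 2.0 else 4.0,
               SUL_peak = ref$median[i])
  }))
  out <- stratifiedSummary(tab, cutoff = 2.5, metrics_cols = "SUL_peak")
  fc <- out$fold_change
  small <- fc$fold[grepl("<=", fc$stratum)]
  large <- fc$fold[grepl(">", fc$stratum)]
  expect_equal(round(small, 2), 2.71)
  expect_equal(round(large, 2), 1.58)
})

test_that("identical db and wb columns give unit fold changes", {
  tab <- data.frame(case = rep(c("a", "b"), each = 2),
                    modality = rep(c("db", "wb"), 2),
                    d_MRI_cm = c(2, 2, 4, 4), m = c(3, 3, 5, 5))
  out <- stratifiedSummary(tab, metrics_cols = "m")
  expect_true(all(out$fold_change$fold == 1))
})

test_that("empty strata are omitted with a warning", {
  tab <- data.frame(case = c("a", "a"), modality = c("db", "wb"),
                    d_MRI_cm = c(2, 2), m = c(3, 2))
  expect_warning(out <- stratifiedSummary(tab, metrics_cols = "m"),
                 "empty stratum")
  expect_true(all(grepl("<=", out$fold_change$stratum)))
})
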