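makeRecords <- function(mu0, mu2, mu24, group = "bacterial_feeder",
                        treatment = "PEITC") {
  n <- length(mu0)
  data.frame(
    replicate_id = rep(sprintf("r%d", seq_len(n)), 3),
    group = group, treatment = treatment,
    time_point_h = rep(c(0, 2, 24), each = n),
    mu = c(mu0, mu2, mu24))
}

test_that("time-course normalization is per replicate against time 0", {
  rec <- makeRecords(c(200, 100), c(150, 100), c(100, 25))
  norm <- normalizeTimecourse(rec)
  expect_equal(norm$percent_of_pretreatment[norm$time_point_h == 0],
               c(100, 100))
  r1 <- norm[norm$replicate_id == "r1", ]
  expect_equal(r1$percent_of_pretreatment[r1$time_point_h == 24], 50)
  r2 <- norm[norm$replicate_id == "r2", ]
  expect_equal(r2$percent_of_pretreatment[r2$time_point_h == 2], 100)
  expect_equal(r2$percent_of_pretreatment[r2$time_point_h == 24], 25)
})

test_that("replicates with zero pre-treatment mu are excluded with a warning", {
  rec <- makeRecords(c(200, 0), c(150, 10), c(100, 5))
  expect_warning(norm <- normalizeTimecourse(rec), "r2")
  expect_false("r2" %in% norm$replicate_id)
  expect_equal(sum(norm$replicate_id == "r1"), 3)
})

test_that("paired t-test agrees with the closed-form statistic", {
  before <- c(10, 12, 11, 13, 12)
  after <- c(8, 9, 7, 10, 9)
  got <- pairedTTest(before, after)
  ref <- oraclePairedT(before, after)
  expect_equal(got$t_statistic, ref$t, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  expect_equal(got$test, "paired_t")
  expect_equal(got$n, 5)

  same <- pairedTTest(before, before)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(pairedTTest(1, 2), "at least 2")
  expect_error(pairedTTest(c(1, 2), c(1, 2, 3)), "equal-length")
})

test_that("constant nonzero paired shift exercises the zero-variance path", {
  x <- c(5, 7, 9, 11)
  expect_warning(res <- pairedTTest(x, x + 3), "zero variance")
  expect_equal(res$p_value, 0)
  expect_true(is.infinite(res$t_statistic) && res$t_statistic > 0)
})

test_that("unpaired t-test matches the closed form and handles degeneracy", {
  set.seed(401)
  a <- round(runif(4, 10, 30), 1)
  b <- round(runif(4, 5, 25), 1)
  got <- unpairedTTest(a, b)
  ref <- oracleUnpairedT(a, b)
  expect_equal(got$t_statistic, ref$t, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p, tolerance = 1e-12)

  eq <- unpairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_warning(deg <- unpairedTTest(c(0, 0, 0, 0), c(1, 1, 1, 1)),
                 "zero variance")
  expect_equal(deg$p_value, 0)

  welch <- unpairedTTest(a, b, welch = TRUE)
  expect_equal(welch$p_value, stats::t.test(b, a)$p.value)

  expect_error(unpairedTTest(1, c(1, 2)), "at least 2")
})

test_that("a constant control series reports 100 percent and p = 1", {
  rec <- makeRecords(rep(150, 5), rep(150, 5), rep(150, 5),
                     treatment = "control")
  rep1 <- screeningReport(rec)
  expect_true(all(rep1$summary$mean_percent == 100))
  expect_true(all(rep1$comparisons$p_value == 1))
  expect_true(all(rep1$comparisons$t_statistic == 0))
})

test_that("single-replicate cells are reported without a test", {
  rec <- makeRecords(c(100), c(90), c(50))
  out <- screeningReport(rec)
  expect_equal(unique(out$summary$n), 1)
  expect_true(all(is.na(out$comparisons$p_value)))
  expect_equal(unique(out$comparisons$n), 1)
})

test_that("the report is a pure function of its records", {
  set.seed(402)
  rec <- rbind(
    makeRecords(runif(5, 100, 200), runif(5, 80, 150), runif(5, 20, 80)),
    makeRecords(runif(5, 100, 200), runif(5, 100, 200),
                runif(5, 100, 200), treatment = "control"))
  r1 <- screeningReport(rec)
  r2 <- screeningReport(rec[sample(nrow(rec)), ])
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$comparisons, r2$comparisons)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeResults(r1$summary, f1); writeResults(r2$summary, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("declining treated series test significant while control does not", {
  rec <- rbind(
    makeRecords(c(180, 200, 190, 210, 205), c(150, 160, 140, 170, 160),
                c(40, 55, 60, 45, 50)),
    makeRecords(c(180, 200, 190, 210, 205), c(178, 204, 186, 214, 200),
                c(182, 196, 195, 206, 210), treatment = "control"))
  out <- screeningReport(rec)
  peitc24 <- out$comparisons[grepl("PEITC:24h", out$comparisons$comparison), ]
  ctrl24 <- out$comparisons[grepl("control:24h", out$comparisons$comparison), ]
  expect_lt(peitc24$p_value, 0.01)
  expect_gt(ctrl24$p_value, 0.2)
})

test_that("volume-intensity correlation reproduces lm and cor.test", {
  set.seed(403)
  n <- 30
  nv <- runif(n, 100, 1500)
  mi <- 20 + 0.02 * nv + rnorm(n, 0, 5)
  got <- volumeIntensityCorrelation(nv, mi)
  fit <- lm(mi ~ nv)
  expect_equal(got$slope, unname(coef(fit)[2]))
  expect_equal(got$r_squared, summary(fit)$r.squared)
  expect_equal(got$pearson_r, unname(cor.test(nv, mi)$estimate))
  expect_equal(got$r_squared, got$pearson_r^2, tolerance = 1e-12)
})
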