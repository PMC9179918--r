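test_that("trimmed mean and winsorized variance match order-statistics
          arithmetic and a brute-force oracle", {
  s <- trimmedMeanStats(1:10, trim = 0.2)
  expect_equal(s$tmean, mean(3:8))        # = 5.5
  expect_equal(s$h, 6L)
  # trim = 0 reduces to the classical mean and variance
  x <- c(2.3, -1, 5, 0.4, 9)
  s0 <- trimmedMeanStats(x, trim = 0)
  expect_equal(s0$tmean, mean(x))
  expect_equal(s0$winvar, var(x))
  # brute-force agreement on random vectors
  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1))
    tr <- sample(c(0, 0.1, 0.2, 0.25), 1)
    b <- bruteTrimmedStats(x, tr)
    s <- trimmedMeanStats(x, tr)
    expect_equal(s$tmean, b$tmean)
    expect_equal(s$winvar, b$winvar)
    expect_equal(s$h, b$h)
  }
  expect_error(trimmedMeanStats(numeric(0)), "empty")
})

test_that("trimmed two-way ANOVA enforces its design contracts", {
  d <- makeOrdinalScoreDataset(scoreSimSpec(seed = 2L))
  expect_error(trimmedTwoWayAnova(d$value, rep("only", 54), d$time_days),
               "two levels")
  expect_error(trimmedTwoWayAnova(rep(3, 54), d$group, d$time_days),
               "degenerate")
  dd <- d[!(d$group == "CTR" & d$time_days == "24"), ]
  expect_error(trimmedTwoWayAnova(dd$value, dd$group, dd$time_days),
               "24.CTR")
})

test_that("with trim 0 the test reduces to the classical
          heteroscedastic factorial ANOVA", {
  set.seed(5)
  d <- makeOrdinalScoreDataset(scoreSimSpec(nPerCell = 8L,
                                            noise = "normal", seed = 5L))
  res <- trimmedTwoWayAnova(d$value, d$group, d$time_days, trim = 0)
  # independent computation from plain cell means/variances
  cells <- split(d$value, list(factor(d$time_days), factor(d$group)))
  m <- vapply(cells, mean, numeric(1))
  v <- vapply(cells, function(x) var(x) / length(x), numeric(1))
  cj <- cbind(diag(2), 0) - cbind(0, diag(2))
  CA <- kronecker(cj, matrix(1, 1, 3))
  Tm <- CA %*% diag(v) %*% t(CA)
  QA <- drop(t(CA %*% m) %*% solve(Tm) %*% (CA %*% m))
  expect_equal(res@qA, QA, tolerance = 1e-10)
})

test_that("Johansen p-values approach the chi-square tail for large
          cells", {
  set.seed(6)
  n <- 400
  g <- rep(c("a", "b"), each = 2 * n)
  t <- rep(rep(c("t1", "t2"), each = n), 2)
  v <- rnorm(4 * n)
  res <- trimmedTwoWayAnova(v, g, t, trim = 0.2)
  # with h ~ 240 per cell the adjustment term is negligible
  expect_equal(res@pA, 1 - pchisq(res@qA, 1), tolerance = 5e-3)
  expect_equal(res@pAB, 1 - pchisq(res@qAB, 1), tolerance = 5e-3)
})

test_that("bootstrap p-values agree with the analytic approximation", {
  eff <- matrix(0, 3, 3); eff[1, ] <- 1
  d <- makeOrdinalScoreDataset(scoreSimSpec(cellEffects = eff,
                                            noise = "normal", seed = 4L))
  a1 <- trimmedTwoWayAnova(d$value, d$group, d$time_days)
  a2 <- trimmedTwoWayAnova(d$value, d$group, d$time_days,
                           method = "bootstrap", nboot = 999L, seed = 2L)
  expect_lt(abs(a1@pA - a2@pA), 0.12)
  # seeded: reproducible
  a3 <- trimmedTwoWayAnova(d$value, d$group, d$time_days,
                           method = "bootstrap", nboot = 999L, seed = 2L)
  expect_identical(a2@pA, a3@pA)
})

test_that("noncentral-t power behaves at its limits and matches
          oracles", {
  expect_equal(powerTwoSampleT(12, 0), 0.05, tolerance = 1e-10)
  expect_equal(powerTwoSampleT(12, 0, alpha = 0.13), 0.13,
               tolerance = 1e-10)
  expect_gt(powerTwoSampleT(12, 8), 0.999999)
  # base-R implementation as an independent oracle
  expect_equal(powerTwoSampleT(12, 1.2),
               power.t.test(n = 12, delta = 1.2, sd = 1,
                            sig.level = 0.05)$power,
               tolerance = 1e-5)
  # Monte-Carlo oracle: simulate the two-sample t test directly
  set.seed(12)
  reps <- 1e5
  x <- matrix(rnorm(12 * reps), 12)
  y <- matrix(rnorm(12 * reps, mean = 1.2), 12)
  sp <- sqrt((11 * apply(x, 2, var) + 11 * apply(y, 2, var)) / 22)
  tstat <- (colMeans(y) - colMeans(x)) / (sp * sqrt(2 / 12))
  mc <- mean(abs(tstat) > qt(0.975, 22))
  expect_lt(abs(powerTwoSampleT(12, 1.2) - mc), 0.005)
  expect_error(powerTwoSampleT(12, 1, alpha = 1.2), "alpha")
})

test_that("effect-size solver inverts the power function", {
  d <- effectSizeFromPower(12)
  expect_equal(powerTwoSampleT(12, d), 0.8, tolerance = 1e-6)
  # identity on a grid of designs
  for (n in c(5, 12, 30)) for (dd in c(0.5, 1, 1.5)) {
    pw <- powerTwoSampleT(n, dd)
    expect_equal(effectSizeFromPower(n, power = pw), dd,
                 tolerance = 1e-6)
  }
  # as the target power approaches alpha, no effect is needed
  expect_lt(effectSizeFromPower(12, power = 0.0500001), 1e-3)
  expect_error(effectSizeFromPower(12, power = 0.04), "power")
})

test_that("descriptive summaries follow the median/min-max/IQR
          presentation", {
  expect_equal(descriptiveSummary(c(1, 2, 3, 4, 5))[["median"]], 3)
  expect_equal(descriptiveSummary(c(1, 2, 3, 4, 5))[["min"]], 1)
  expect_equal(descriptiveSummary(c(1, 2, 3, 4, 5))[["max"]], 5)
  s <- descriptiveSummary(7)
  expect_equal(unname(s[c("median", "min", "max")]), c(7, 7, 7))
  expect_equal(s[["iqr"]], 0)
  # packaged hyaluronic-acid fixture
  ha <- haSynovialFluid()
  cghnc <- ha$ha_ng_ml[ha$group == "CGH-NC"]
  expect_equal(sort(cghnc), sort(c(119.62, 68.57, 90.66)))
  expect_equal(descriptiveSummary(cghnc)[["median"]], 90.66)
  expect_error(descriptiveSummary(numeric(0)), "empty")
})

test_that("stage frequency tables conserve counts and track monotone
          effects", {
  one <- data.frame(subject_id = "S1", group = "CTR", time_days = "24",
                    variable = "macro", value = 2)
  tab <- stageFrequencyTable(one, "macro")
  expect_equal(sum(tab$counts), 1)
  d <- makeOrdinalScoreDataset(scoreSimSpec(noise = "ordinalized",
                                            seed = 3L))
  tab <- stageFrequencyTable(d, "score")
  expect_true(all(apply(tab$counts, c(2, 3), sum) == 6))
  expect_equal(sum(tab$counts), nrow(d))
  expect_true(all(abs(apply(tab$frequencies, c(2, 3), sum) - 1) < 1e-12))
  cont <- data.frame(subject_id = "S1", group = "CTR", time_days = "24",
                     variable = "ha", value = 53.21)
  expect_error(stageFrequencyTable(cont, "ha"), "ordinal")
  # planted monotone time effect: modal stage non-decreasing over time
  eff <- matrix(rep(c(0, 1.2, 2.4), each = 3), 3)
  hits <- unlist(lapply(1:100, function(s) {
    dd <- makeOrdinalScoreDataset(scoreSimSpec(cellEffects = eff,
                                               noise = "ordinalized",
                                               seed = s))
    tt <- stageFrequencyTable(dd, "score")$counts
    modal <- apply(tt, c(2, 3), function(col) which.max(col))
    apply(modal, 1, function(r) all(diff(r) >= 0))   # per group
  }))
  expect_gte(mean(hits), 0.9)
})
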