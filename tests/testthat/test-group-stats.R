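test_that("the 1.5 IQR rule with interpolated quartiles screens as hand-computed", {
  r <- iqrExclude(c(1:9, 100))
  expect_identical(r$excluded, 100)
  expect_identical(r$kept, as.numeric(1:9))
  # hand check of the bounds: Q1 = 3.25, Q3 = 7.75 by linear interpolation
  expect_equal(r$bounds, c(3.25 - 1.5 * 4.5, 7.75 + 1.5 * 4.5))
  const <- iqrExclude(rep(4.2, 8))
  expect_length(const$excluded, 0)
  # equivariance under sign flip
  x <- c(-40, rnorm(12), 40)
  set.seed(1)
  expect_equal(sort(-iqrExclude(-x)$excluded), sort(iqrExclude(x)$excluded))
  expect_warning(iqrExclude(c(1, 2, 3)), "fewer than 4")
})

test_that("Welch statistics match the textbook formulas and a reference implementation", {
  x <- c(5.1, 6.3, 4.8, 7.0, 5.5)
  y <- c(8.2, 7.9, 9.1, 6.8)
  out <- welchBH(list(a = x, b = y))
  # textbook Satterthwaite computation, written out
  se2 <- var(x) / 5 + var(y) / 4
  tHand <- (mean(x) - mean(y)) / sqrt(se2)
  dfHand <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  pHand <- 2 * pt(-abs(tHand), dfHand)
  expect_equal(out$t, tHand, tolerance = 1e-12)
  expect_equal(out$df, dfHand, tolerance = 1e-12)
  expect_equal(out$p_raw, pHand, tolerance = 1e-12)
  ref <- t.test(x, y)
  expect_equal(out$p_raw, unname(ref$p.value), tolerance = 1e-12)
  # degenerate equal constants: p = 1 by convention
  out0 <- welchBH(list(a = rep(2, 3), b = rep(2, 4)))
  expect_equal(out0$t, 0)
  expect_equal(out0$p_raw, 1)
})

test_that("BH adjustment follows the step-up rule", {
  # hand step-up oracle
  bhHand <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(p[o] * m / (m:1)))
    adj[order(o)]
  }
  expect_equal(bhHand(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(7)
    expect_equal(p.adjust(p, "BH"), bhHand(p), tolerance = 1e-14)
  }
  # the pipeline's adjusted values dominate the raw ones and are monotone
  # in raw-p rank
  groups <- split(rnorm(40, rep(c(0, 0.4, 1, 2), each = 10)),
                  rep(letters[1:4], each = 10))
  out <- welchBH(groups)
  expect_true(all(out$p_bh >= out$p_raw - 1e-15))
  o <- order(out$p_raw)
  expect_true(all(diff(out$p_bh[o]) >= -1e-15))
  expect_true(all(out$stars %in% c("ns", "*", "**", "***", "****")))
})

test_that("the trend test rejects nothing on constant data and respects step-down", {
  const <- williamsTrend(rep(3, 5), list(g1 = rep(3, 5), g2 = rep(3, 5)),
                         direction = "increasing", nMC = 2000, seed = 1)
  expect_true(all(const$tbar == 0))
  expect_false(any(const$rejected))
  # step-down coherence on a signal only in the top group is a prefix of
  # rejections from the top
  set.seed(42)
  ctrl <- rnorm(10)
  gs <- list(g1 = rnorm(10), g2 = rnorm(10), g3 = rnorm(10) + 4)
  out <- williamsTrend(ctrl, gs, "increasing", nMC = 20000, seed = 2)
  rej <- out$rejected[order(out$step, decreasing = TRUE)]  # top first
  if (any(!rej)) expect_true(all(!rej[which.min(rej):length(rej)]))
  expect_true(out$rejected[out$group == "g3"])
  expect_error(williamsTrend(rnorm(5), list()), "non-empty")
  expect_error(williamsTrend(rnorm(5), list(g = 1)), "at least 2")
})

test_that("the trend test attains its nominal size and has power, by Monte Carlo", {
  ns <- c(8L, 8L, 8L); n0 <- 8L
  dfPool <- sum(ns) + n0 - 4L
  null <- stGclamp:::.williamsNullSample(ns, n0, dfPool, 2e5, seed = 11)
  crit <- quantile(null[, 3], 0.95, names = FALSE)
  # size: 4000 null datasets, top-step rejection rate near 0.05
  set.seed(12)
  hits <- 0L
  for (i in 1:4000) {
    st <- stGclamp:::.williamsStats(rnorm(n0),
                                    lapply(ns, function(n) rnorm(n)))
    if (st$tbar[3] >= crit) hits <- hits + 1L
  }
  expect_gt(hits / 4000, 0.035)
  expect_lt(hits / 4000, 0.065)
  # power: 3 SD shift at the top dose, 300 datasets
  null3 <- stGclamp:::.williamsNullSample(c(10L, 10L, 10L), 10L, 36L,
                                          1e5, seed = 14)
  crit3 <- quantile(null3[, 3], 0.95, names = FALSE)
  set.seed(13)
  pow <- 0L
  for (i in 1:300) {
    st <- stGclamp:::.williamsStats(
      rnorm(10), list(rnorm(10, 1), rnorm(10, 2), rnorm(10, 3)))
    if (st$tbar[3] >= crit3) pow <- pow + 1L
  }
  expect_gt(pow / 300, 0.95)
})

test_that("Spearman correlation handles monotone data, sign flips and ties", {
  x <- c(1, 4, 9, 16, 25, 30, 41, 55, 70, 88, 100, 130)
  y <- sqrt(x) + 3
  s <- spearmanRank(x, y)
  expect_equal(s$rho, 1)
  s2 <- spearmanRank(rev(x), y)
  expect_equal(s2$rho, -s$rho)
  # tie-laden vectors against the rank-then-Pearson oracle and cor.test
  xt <- c(1, 1, 2, 2, 3, 3, 4, 4, 10, 10, 11, 12)
  yt <- c(2, 1, 1, 3, 2, 5, 4, 4, 9, 12, 10, 10)
  st <- spearmanRank(xt, yt)
  expect_equal(st$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
  expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(st$p, ct$p.value, tolerance = 1e-10)  # both t approximations
  # exact enumeration for small n agrees with the reference exact test
  xs <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  ys <- c(2, 3, 7, 1, 8, 4, 6)
  se <- spearmanRank(xs, ys)
  expect_identical(se$method, "exact permutation")
  ce <- cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(se$p, ce$p.value, tolerance = 1e-10)
  # undefined under zero rank variance
  su <- spearmanRank(rep(1, 5), 1:5)
  expect_true(is.na(su$rho))
})

test_that("the cohort comparison report assembles summaries, pairs and trends", {
  set.seed(5)
  spec <- cohortSpec(seed = 5L)
  rows <- list()
  for (gi in seq_len(nrow(spec$groups))) {
    for (m in seq_len(spec$groups$n[gi])) {
      d <- sampleMouse(spec$groups[gi, ], spec)
      rows[[length(rows) + 1L]] <- data.frame(
        group = spec$groups$label[gi],
        as.list(paramVector(d$params)))
    }
  }
  tab <- do.call(rbind, rows)
  design <- list(control = "CD14wk",
                 ordered = spec$groups$label[-1],
                 directions = c(k2 = "decreasing", k3 = "increasing",
                                k5 = "decreasing", k7 = "increasing"),
                 nMC = 2e4, seed = 9L)
  rep <- runGroupComparison(tab, design)
  expect_s4_class(rep, "GroupComparisonReport")
  expect_equal(nrow(rep@summaries), 6 * 10)
  expect_equal(nrow(rep@pairwise), 10 * choose(6, 2))
  expect_equal(nrow(rep@trend), 4 * 5)
  # on the true generator draws, every trended parameter is detected at
  # the oldest group
  top <- rep@trend[rep@trend$group == "HFD36wk", ]
  expect_true(all(top$rejected))
  # stochastic p-values carry their provenance
  expect_true(all(rep@trend$n_mc == 2e4))
  expect_true(all(rep@trend$mc_seed > 0))
  # export schema
  dir <- tempfile(); exportReportCSV(rep, dir)
  pw <- read.csv(file.path(dir, "pairwise.csv"))
  expect_true(all(c("parameter", "group_a", "group_b", "t", "df",
                    "p_raw", "p_bh", "stars") %in% names(pw)))
  tr <- read.csv(file.path(dir, "trend.csv"))
  expect_true(all(c("parameter", "group", "direction", "tbar", "p_mc",
                    "rejected") %in% names(tr)))
})

test_that("a single-group table yields summaries without tests", {
  tab <- data.frame(group = "only", k1 = rnorm(8, 10), k2 = rnorm(8, 1))
  rep <- runGroupComparison(tab, design = list(control = "only"),
                            parameters = c("k1", "k2"))
  expect_equal(nrow(rep@summaries), 2)
  expect_equal(nrow(rep@pairwise), 0)
  expect_equal(nrow(rep@trend), 0)
})

test_that("the BH family controls false positives over null cohorts", {
  # complete null: any BH rejection at level 0.05 occurs with probability
  # at most ~alpha per family
  set.seed(31)
  hits <- 0L
  for (i in 1:60) {
    groups <- split(rnorm(32), rep(1:4, each = 8))
    names(groups) <- letters[1:4]
    out <- welchBH(groups)
    if (any(out$p_bh < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 9)  # binomial(60, ~0.05) upper tail
})
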