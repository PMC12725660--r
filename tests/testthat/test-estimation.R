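test_that("the objective is zero at the generating parameters", {
  cfg <- fitConfig()
  expect_lt(rssObjective(cdParams(), cdRecordExact(), cfg), 1e-8)
  expect_lt(rssObjective(cdParams(), cdRecordRounded(), cfg), 1e-8)
})

test_that("perturbing one observation raises the objective by its squared normalized residual", {
  rec <- cdRecordExact()
  cfg <- fitConfig()
  base <- rssObjective(cdParams(), rec, cfg)
  delta <- 7.3
  rec2 <- rec
  rec2@glucoseValues[12] <- rec2@glucoseValues[12] + delta
  # the glucose stream enters twice: directly and through the derived
  # cumulative-uptake stream (doses minus glucose mass change)
  normG <- mean(abs(rec2@glucoseValues))
  agBase <- cumulativeUptake(rec)
  agPert <- cumulativeUptake(rec2)
  normA <- mean(abs(agPert))
  expected <- (delta / normG)^2 + sum(((agPert - agBase) / normA)^2)
  # correct for the change of normalization constants on the unperturbed
  # residuals (zero at truth), so the quadratic form is exact
  expect_equal(rssObjective(cdParams(), rec2, cfg) - base, expected,
               tolerance = 1e-6)
})

test_that("the objective matches a closed-form trajectory on a degenerate model", {
  # both uptake routes negligible, EGP negligible, insulin decoupled:
  # G stays at G0, I relaxes exponentially with rate k4
  p <- modelParameters(k1 = 1e-10, k2 = 1e-12, k3 = 1e-12, k4 = 0.03,
                       k5 = 1e-12, k6 = 1e-6, k7 = 100, k8 = 1e-5,
                       G0 = 150, I0 = 2, iBounds = c(1e-9, 20))
  gt <- glucoseGrid(); tj <- insulinGrid()
  gObs <- rep(150, length(gt))
  iObs <- 2 * exp(-0.03 * tj) * 1.05          # 5% off the closed form
  rec <- clampRecord("toy", "toy", 25, gt, gObs, tj, iObs,
                     gt[-1], rep(0, length(gt) - 1))
  cfg <- fitConfig()
  normI <- mean(abs(iObs))
  handRSS <- sum(((iObs - 2 * exp(-0.03 * tj)) / normI)^2)
  expect_equal(rssObjective(p, rec, cfg), handRSS, tolerance = 1e-5)
})

test_that("simulation failure yields the penalty, not an exception", {
  rec <- cdRecordExact()
  cfg <- fitConfig()
  bad <- paramVector(cdParams())
  bad[["k1"]] <- 1e280   # overflows the EGP term immediately
  expect_equal(rssObjective(bad, rec, cfg), cfg$penalty)
})

test_that("the evolutionary search solves a sphere problem and is seed-deterministic", {
  rec <- cdRecordExact()
  bounds <- defaultBounds(rec)
  xstar <- bounds[, 1] + 0.65 * (bounds[, 2] - bounds[, 1])
  sphere <- function(x) sum((x - xstar)^2)
  cfg <- fitConfig(bounds = bounds, populationSize = 100,
                   generations = 400, seed = 4L)
  gs <- globalSearch(rec, cfg, objective = sphere)
  expect_lt(max(abs(log10(gs$best) - xstar)), 1e-2)
  # best objective never worsens across generations (elitist tournament)
  expect_true(all(diff(gs$bestHistory) <= 0))
  gs2 <- globalSearch(rec, cfg, objective = sphere)
  expect_identical(gs$best, gs2$best)
  expect_identical(gs$population, gs2$population)
})

test_that("local refinement is a descent method and nails an exact start", {
  rec <- cdRecordExact()
  cfg <- fitConfig()
  fit <- localRefine(cdParams(), rec, cfg)
  expect_lt(fit@rss, 1e-10)
  start <- paramVector(cdParams()) * 1.15
  startRSS <- rssObjective(paramsFromVector(start), rec, cfg)
  fit2 <- localRefine(start, rec, cfg)
  expect_lte(fit2@rss, startRSS)
  # the stored RSS re-evaluates: the FitResult contract
  expect_equal(fit2@rss,
               rssObjective(fit2@params, rec, cfg), tolerance = 1e-10)
  expect_equal(fit2@rss, sum(unlist(fit2@residuals)^2), tolerance = 1e-10)
})

test_that("a flat, dose-free record is fitted without failure", {
  gt <- glucoseGrid(); tj <- insulinGrid()
  rec <- clampRecord("flat", "degenerate", 25, gt, rep(110, length(gt)),
                     tj, rep(0.5, length(tj)), gt[-1],
                     rep(0, length(gt) - 1))
  cfg <- fitConfig(populationSize = 16, generations = 12, seed = 2L)
  fit <- fitMouse(rec, cfg, identifiability = FALSE, nStarts = 1)
  expect_true(is(fit, "FitResult"))
  sim <- stGclamp:::.simForRecord(paramVector(fit@params), rec, cfg)
  expect_lt(max(abs(sim$G / 110 - 1)), 0.05)   # essentially basal
  expect_lt(max(abs(sim$I / 0.5 - 1)), 0.15)
})

test_that("the identifiability report flags the weakly determined parameters", {
  rec <- cdRecordExact()
  cfg <- fitConfig()
  cfg$bounds <- defaultBounds(rec)
  fit <- localRefine(cdParams(), rec, cfg)
  rep <- identifiabilityReport(fit, rec, cfg)
  expect_identical(rep$parameter,
                   c(paste0("k", 1:8), "G0", "I0"))
  sv <- attr(rep, "singularValues")
  expect_true(all(sv > 0) && all(diff(sv) <= 0))
  expect_true(all(is.finite(rep$relCIHalfWidth)))
  # on noise-free data at the optimum the G0/I0 scales are tight while the
  # EGP-suppression weight k8 is among the loosest
  expect_gt(rep$relCIHalfWidth[rep$parameter == "k8"],
            rep$relCIHalfWidth[rep$parameter == "G0"])
})
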