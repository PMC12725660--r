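test_that("a basal run stays at the fixed point", {
  p <- cdParams()
  pr <- infusionProtocol("fixed_schedule", bodyWeight = 25)
  traj <- simulateFixed(p, pr)
  st <- basalSteadyState(p)
  for (nm in c("G", "I", "stG"))
    expect_lt(max(abs(traj@states[, nm] / st[[nm]] - 1)), 1e-6)
})

test_that("a vanishing store capacity removes insulin-independent uptake", {
  p <- modelParameters(k1 = 6, k2 = 3.5e-3, k3 = 2e-4, k4 = 0.02,
                       k5 = 1.3e-4, k6 = 6e-3, k7 = 1e-10, k8 = 0.01,
                       G0 = 120, I0 = 0.4)
  traj <- runClamp(p, cdProtocol())
  expect_lt(max(traj@fluxes[, "flux5"]), 1e-6)
  expect_lt(max(traj@states[, "stG"]), 1e-10)
  fd <- decomposeFluxes(traj)
  expect_lt(max(fd@flux5Integrals), 1e-5)
})

test_that("glucose mass is conserved under every protocol mode", {
  p <- cdParams()
  trajClamp <- cdClampTraj()
  trajFixed <- simulateFixed(p, infusionProtocol("fixed_schedule",
                                                 bodyWeight = 25,
                                                 rateTimes = c(0, 30, 90),
                                                 rateValues = c(0.1, 0.3,
                                                                0.05)))
  trajIvgtt <- simulateIVGTT(p, infusionProtocol("ivgtt_bolus",
                                                 bodyWeight = 25))
  for (tr in list(trajClamp, trajFixed, trajIvgtt))
    expect_lt(massBalanceError(tr), 1e-6)
})

test_that("states remain in their physical ranges for random cohort draws", {
  spec <- cohortSpec(seed = 3L)
  set.seed(99)
  for (gi in c(1L, 4L, 6L)) {
    draw <- sampleMouse(spec$groups[gi, ], spec)
    pr <- infusionProtocol("clamp", bodyWeight = draw$bodyWeight,
                           initialRate = spec$groups$initialRate[gi])
    traj <- runClamp(draw$params, pr)
    k7 <- paramVector(draw$params)[["k7"]]
    expect_gt(min(traj@states[, "G"]), -1e-8)
    expect_gt(min(traj@states[, "I"]), -1e-8)
    expect_gt(min(traj@states[, "stG"]), -1e-8)
    expect_lt(max(traj@states[, "stG"]), k7 * (1 + 1e-8))
  }
})

test_that("stored fluxes reproduce the uptake derivative identically", {
  traj <- cdClampTraj()
  dAG <- traj@fluxes[, "flux2"] - traj@fluxes[, "flux1"] +
    traj@fluxes[, "flux5"]
  # same arithmetic path as the solver's RHS: recompute from states
  v <- paramVector(traj@params)
  G <- traj@states[, "G"]; I <- traj@states[, "I"]
  stG <- traj@states[, "stG"]
  expect_identical(dAG, v[["k2"]] * G * I -
                     v[["k1"]] / (1 + I + v[["k8"]] * G) +
                     v[["k5"]] * G * (v[["k7"]] - stG))
})

test_that("the clamp attains target and holds it within 5 percent", {
  traj <- cdClampTraj()
  expect_true(traj@metadata$attained)
  expect_lt(traj@metadata$attainmentTime, 20)
  target <- traj@metadata$target
  expect_equal(target, 320)
  g <- traj@states[match(glucoseGrid(), traj@times), "G"]
  post <- glucoseGrid() >= 10
  expect_lt(max(abs(g[post] - target)) / target, 0.05)
})

test_that("fast priming reaches target sooner than slow priming", {
  p <- cdParams()
  fast <- runClamp(p, infusionProtocol("clamp", bodyWeight = 25,
                                       initialRate = 4))
  slow <- cdClampTraj()
  expect_lt(fast@metadata$attainmentTime, slow@metadata$attainmentTime)
})

test_that("the lean-mouse infusion demand is biphasic", {
  traj <- cdClampTraj()
  rate <- traj@dosesPerInterval / diff(c(0, traj@doseTimes))
  tt <- traj@doseTimes
  midMin <- min(rate[tt > 20 & tt < 70])
  lastHour <- mean(rate[tt > 120])
  expect_lt(midMin, mean(rate[tt > 5 & tt <= 20]))  # dip after priming
  expect_gt(lastHour, midMin)                       # late insulin-driven rise
  # the minimum is interior to (20, 70)
  tMin <- tt[tt > 20 & tt < 70][which.min(rate[tt > 20 & tt < 70])]
  expect_gt(tMin, 20); expect_lt(tMin, 70)
})

test_that("clamped insulin follows the closed-form relaxation toward k3 G / k4", {
  traj <- cdClampTraj()
  v <- paramVector(traj@params)
  target <- traj@metadata$target
  tA <- traj@metadata$attainmentTime
  sel <- traj@times >= tA
  tt <- traj@times[sel]
  iSim <- traj@states[sel, "I"]
  iInf <- v[["k3"]] * target / v[["k4"]]
  iCf <- iInf + (iSim[1] - iInf) * exp(-v[["k4"]] * (tt - tA))
  gErr <- max(abs(traj@states[sel, "G"] - target))
  bound <- v[["k3"]] * gErr / v[["k4"]] + 1e-6
  expect_lt(max(abs(iSim - iCf)), bound)
  expect_true(all(diff(iSim) > -1e-10))  # monotone rise
})

test_that("a never-attained clamp records a warning instead of failing", {
  p <- cdParams()
  pr <- infusionProtocol("clamp", bodyWeight = 25, initialRate = 1e-4)
  traj <- runClamp(p, pr)
  expect_false(traj@metadata$attained)
  expect_match(traj@metadata$warning, "never attained")
})

test_that("IVGTT kinetics: peak timing, relaxation, and dose linearity", {
  p <- cdParams()
  pr <- infusionProtocol("ivgtt_bolus", bodyWeight = 25)
  traj <- simulateIVGTT(p, pr)
  g <- traj@states[, "G"]
  tPeak <- traj@times[which.max(g)]
  expect_gte(tPeak, 2); expect_lte(tPeak, 6)
  after <- traj@times > tPeak
  expect_true(all(diff(g[after]) < 1e-9))          # monotone return
  expect_gt(min(g[after]), 0)
  # zero bolus equals an unstimulated run from the same initial state
  pr0 <- infusionProtocol("ivgtt_bolus", bodyWeight = 25, bolusDose = 0)
  traj0 <- simulateIVGTT(p, pr0)
  v <- paramVector(p)
  init <- c(G = v[["G0"]], I = v[["I0"]], stG = 0, AG = 0)
  ref <- simulateFixed(p, infusionProtocol("fixed_schedule",
                                           bodyWeight = 25,
                                           totalDuration = 90),
                       init = init)
  common <- intersect(traj0@times, ref@times)
  expect_equal(traj0@states[match(common, traj0@times), "G"],
               ref@states[match(common, ref@times), "G"],
               tolerance = 1e-8)
  # doubling the bolus doubles the infused mass exactly
  pr2 <- infusionProtocol("ivgtt_bolus", bodyWeight = 25, bolusDose = 1.5)
  traj2 <- simulateIVGTT(p, pr2)
  expect_equal(sum(traj2@dosesPerInterval), 2 * sum(traj@dosesPerInterval),
               tolerance = 1e-12)
})

test_that("windowed flux integrals match a closed-form oracle on constant fluxes", {
  n <- 361
  tt <- seq(0, 180, length.out = n)
  fx <- matrix(2.5, n, 7, dimnames = list(NULL, stGclamp:::.FLUX_NAMES))
  fx[, "flux2"] <- 1.25
  st <- matrix(1, n, 4, dimnames = list(NULL, stGclamp:::.STATE_NAMES))
  traj <- new("Trajectory", times = tt, states = st, fluxes = fx,
              infusionRate = rep(0, n), doseTimes = numeric(0),
              dosesPerInterval = numeric(0),
              protocol = infusionProtocol("fixed_schedule"),
              params = cdParams(), metadata = list())
  fd <- decomposeFluxes(traj)
  expect_equal(fd@flux5Integrals, rep(25, 5), tolerance = 1e-12)
  expect_equal(fd@flux2Integrals, rep(12.5, 5), tolerance = 1e-12)
  expect_error(decomposeFluxes(traj, windowEnds = 300), "span")
})

test_that("solutions are stable under tolerance refinement", {
  p <- cdParams()
  pr <- cdProtocol()
  t1 <- runClamp(p, pr, rtol = 1e-8, atol = 1e-10)
  t2 <- runClamp(p, pr, rtol = 5e-9, atol = 5e-11)
  idx1 <- match(glucoseGrid(), t1@times)
  idx2 <- match(glucoseGrid(), t2@times)
  for (nm in c("G", "I", "stG"))
    expect_lt(max(abs(t1@states[idx1, nm] - t2@states[idx2, nm]) /
                  pmax(abs(t2@states[idx2, nm]), 1e-6)), 1e-4)
})

test_that("trajectory CSV export carries the documented schema", {
  tf <- tempfile(fileext = ".csv")
  exportTrajectoryCSV(cdClampTraj(), tf)
  d <- read.csv(tf)
  expect_identical(names(d),
                   c("time_min", "G_mgdl", "I_ngml", "stG", "AG",
                     paste0("flux", 1:6), "infusion_mg_per_min"))
  fd <- decomposeFluxes(cdClampTraj())
  tf2 <- tempfile(fileext = ".csv")
  exportFluxDecompositionCSV(fd, tf2)
  d2 <- read.csv(tf2)
  expect_identical(names(d2),
                   c("window_end_min", "flux5_integral", "flux2_integral"))
  expect_equal(d2$window_end_min, c(10, 20, 60, 120, 180))
})
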