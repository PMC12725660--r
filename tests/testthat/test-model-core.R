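test_that("flux evaluation matches the model equations at hand-checked points", {
  p <- modelParameters(k1 = 10, k2 = 0.005, k3 = 2e-4, k4 = 0.01,
                       k5 = 1.4e-4, k6 = 0.01, k7 = 250, k8 = 0.01,
                       G0 = 120, I0 = 0.4)
  # G = 0 annihilates every G-proportional flux; EGP sees only insulin
  fl <- evalFluxes(c(G = 0, I = 2, stG = 0), p, 0)
  expect_equal(unname(fl[c("flux2", "flux3", "flux5")]), c(0, 0, 0))
  expect_equal(unname(fl[["flux1"]]), 10 / 3)
  # full store shuts off insulin-independent uptake regardless of glucose
  fl2 <- evalFluxes(c(G = 400, I = 1, stG = 250), p, 0)
  expect_equal(unname(fl2[["flux5"]]), 0)
  # hand evaluation of the EGP term: k1/(1 + I + k8 G)
  fl3 <- evalFluxes(c(G = 100, I = 1, stG = 0), p, 0)
  expect_equal(unname(fl3[["flux1"]]), 10 / (1 + 1 + 0.01 * 100))
  expect_equal(unname(fl3[["flux2"]]), 0.005 * 100 * 1)
  expect_equal(unname(fl3[["influxG"]]), 0)
})

test_that("invalid states and infusions are rejected with named bounds", {
  p <- cdParams()
  expect_error(evalFluxes(c(G = -1, I = 0.4, stG = 0), p, 0), "G < 0")
  expect_error(evalFluxes(c(G = 100, I = -0.1, stG = 0), p, 0), "I < 0")
  expect_error(evalFluxes(c(G = 100, I = 0.4, stG = 1e9), p, 0), "k7")
  expect_error(evalFluxes(c(G = 100, I = 0.4, stG = 0), p, -1),
               "infusionRate")
})

test_that("the RHS assembles exactly from the fluxes", {
  p <- cdParams()
  st <- c(G = 250, I = 1.3, stG = 150, AG = 5)
  fl <- evalFluxes(st, p, 2.5)
  d <- evalRHS(st, p, 2.5)
  expect_identical(d[["dG"]],
                   fl[["flux1"]] - fl[["flux2"]] - fl[["flux5"]] +
                   fl[["influxG"]])
  expect_identical(d[["dI"]], fl[["flux3"]] - fl[["flux4"]])
  expect_identical(d[["dstG"]], fl[["flux5"]] - fl[["flux6"]])
  # uptake counts glucose leaving the blood; store consumption (flux6)
  # does not enter
  expect_identical(d[["dAG"]],
                   fl[["flux2"]] - fl[["flux1"]] + fl[["flux5"]])
})

test_that("pure EGP growth when both uptake routes are disabled", {
  p <- modelParameters(k1 = 10, k2 = 1e-12, k3 = 2e-4, k4 = 0.01,
                       k5 = 1e-14, k6 = 0.01, k7 = 250, k8 = 0.01,
                       G0 = 120, I0 = 0.4)
  for (I in c(0, 0.5, 5, 19)) {
    d <- evalRHS(c(G = 120, I = I, stG = 0), p, 0)
    expect_gt(d[["dG"]], 0)
  }
})

test_that("the basal steady state solves all three balances", {
  for (p in list(cdParams(), referenceParams("HFDold"))) {
    st <- basalSteadyState(p)
    v <- paramVector(p)
    expect_equal(st[["I"]], v[["k3"]] * st[["G"]] / v[["k4"]],
                 tolerance = 1e-9)
    d <- evalRHS(st, p, 0)
    expect_lt(max(abs(d[c("dG", "dI", "dstG")])), 1e-9 * max(1, v[["k1"]]))
  }
})

test_that("a dominant store-consumption rate empties the basal store", {
  base <- paramVector(cdParams())
  make <- function(k6) paramsFromVector(replace(base, "k6", k6))
  stGs <- vapply(c(0.01, 1, 100), function(k6)
    basalSteadyState(make(k6))[["stG"]], numeric(1))
  expect_true(all(diff(stGs) < 0))
  expect_lt(stGs[3], 1)
})

test_that("parameter objects validate and round-trip through JSON", {
  expect_error(modelParameters(k1 = -1, k2 = 0.005, k3 = 2e-4, k4 = 0.01,
                               k5 = 1e-4, k6 = 0.01, k7 = 250, k8 = 0.01,
                               G0 = 120, I0 = 0.4), "positive")
  expect_error(modelParameters(k1 = 1, k2 = 0.005, k3 = 2e-4, k4 = 0.01,
                               k5 = 1e-4, k6 = 0.01, k7 = 250, k8 = 0.01,
                               G0 = 500, I0 = 0.4), "bounds")
  # k8 = 0 is legal (pure insulin suppression of EGP)
  p0 <- modelParameters(k1 = 1, k2 = 0.005, k3 = 2e-4, k4 = 0.01,
                        k5 = 1e-4, k6 = 0.01, k7 = 250, k8 = 0,
                        G0 = 120, I0 = 0.4)
  expect_equal(paramVector(p0)[["k8"]], 0)

  tf <- tempfile(fileext = ".json")
  paramsToJSON(cdParams(), tf)
  p2 <- paramsFromJSON(tf)
  expect_equal(paramVector(p2), paramVector(cdParams()))
  writeLines('{"k1": 1, "bogus": 2}', tf)
  expect_error(paramsFromJSON(tf), "unknown")
  expect_error(paramsFromVector(c(k1 = 1)), "missing")
})
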