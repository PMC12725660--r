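#' Measurement schedules of the clamp protocol
#'
#' The blood glucose schedule samples at 0, 1, 2, 3, 5 min, every 5 min from
#' 10 to 70 min, and every 10 min from 80 to 180 min (29 points); insulin is
#' sampled at 14 of those times; the IVGTT grid has 10 points over 90 min.
#'
#' @return Numeric vector of minutes.
#' @export
glucoseGrid <- function() c(0, 1, 2, 3, 5, seq(10, 70, by = 5),
                            seq(80, 180, by = 10))

#' @rdname glucoseGrid
#' @export
insulinGrid <- function() c(0, 1, 2, 3, 5, 10, 20, 30, 45, 60, 90, 120,
                            150, 180)

#' @rdname glucoseGrid
#' @export
ivgttGrid <- function() c(0, 1, 2, 3, 5, 10, 20, 30, 60, 90)

.checkState <- function(state, params) {
  v <- paramVector(params)
  if (any(!is.finite(state))) stop("state contains non-finite values")
  if (state[["G"]] < 0) stop("domain error: G < 0")
  if (state[["I"]] < 0) stop("domain error: I < 0")
  if (state[["stG"]] < 0) stop("domain error: stG < 0")
  if (state[["stG"]] > v[["k7"]] * (1 + 1e-12))
    stop("domain error: stG exceeds the store capacity k7")
  invisible(TRUE)
}

#' Evaluate the six model fluxes at one state
#'
#' Mass-transfer rates of the four-state model (all in concentration units
#' per minute): \code{flux1 = k1/(1 + I + k8*G)} (EGP), \code{flux2 =
#' k2*G*I} (insulin-dependent uptake), \code{flux3 = k3*G} (insulin
#' secretion), \code{flux4 = k4*I} (insulin clearance), \code{flux5 =
#' k5*G*(k7 - stG)} (insulin-independent uptake into the store),
#' \code{flux6 = k6*stG*I} (insulin-dependent store consumption).
#'
#' @param state named numeric vector with entries G, I, stG (AG optional).
#' @param params a \code{ModelParameters} object.
#' @param infusionRate exogenous glucose infusion, mg/dL/min (>= 0).
#' @return Named numeric vector flux1..flux6, influxG.
#' @examples
#' p <- referenceParams("CD")
#' evalFluxes(c(G = 120, I = 0.4, stG = 0), p, 0)
#' @export
evalFluxes <- function(state, params, infusionRate = 0) {
  .checkState(state, params)
  if (infusionRate < 0) stop("infusionRate must be >= 0")
  v <- paramVector(params)
  G <- state[["G"]]; I <- state[["I"]]; stG <- state[["stG"]]
  c(flux1 = v[["k1"]] / (1 + I + v[["k8"]] * G),
    flux2 = v[["k2"]] * G * I,
    flux3 = v[["k3"]] * G,
    flux4 = v[["k4"]] * I,
    flux5 = v[["k5"]] * G * (v[["k7"]] - stG),
    flux6 = v[["k6"]] * stG * I,
    influxG = infusionRate)
}

#' Evaluate the model right-hand side
#'
#' Assembles the four time derivatives from the fluxes:
#' \code{dG/dt = flux1 - flux2 - flux5 + influxG},
#' \code{dI/dt = flux3 - flux4},
#' \code{dstG/dt = flux5 - flux6},
#' \code{dAG/dt = flux2 - flux1 + flux5}. Note that cumulative uptake AG
#' counts glucose when it leaves the blood (flux2, flux5, net of EGP), not
#' when the store is consumed, so flux6 does not appear.
#'
#' @inheritParams evalFluxes
#' @return Named numeric vector dG, dI, dstG, dAG.
#' @export
evalRHS <- function(state, params, infusionRate = 0) {
  fl <- evalFluxes(state, params, infusionRate)
  c(dG = fl[["flux1"]] - fl[["flux2"]] - fl[["flux5"]] + fl[["influxG"]],
    dI = fl[["flux3"]] - fl[["flux4"]],
    dstG = fl[["flux5"]] - fl[["flux6"]],
    dAG = fl[["flux2"]] - fl[["flux1"]] + fl[["flux5"]])
}

#' Basal (zero-infusion) steady state of the model
#'
#' Solves the three algebraic balance equations (EGP = total uptake, insulin
#' secretion = clearance, store filling = store consumption) with no
#' exogenous infusion. At the root, \code{I = k3*G/k4} and \code{stG =
#' k5*G*k7 / (k5*G + k6*I)}; the remaining scalar equation in G is solved by
#' bisection on (0, Gmax].
#'
#' Note the root is the model's own fasting equilibrium and need not equal a
#' fitted mouse's observed (G0, I0): fits start trajectories at the
#' observed values.
#'
#' @param params a \code{ModelParameters} object.
#' @param gMax upper bracket for basal glucose (mg/dL).
#' @param tol absolute tolerance on each balance equation.
#' @return Named state vector (G, I, stG, AG = 0) with all three balances
#'   below \code{tol} in absolute value.
#' @export
basalSteadyState <- function(params, gMax = 1000, tol = 1e-9) {
  v <- paramVector(params)
  gbal <- function(G) {
    I <- v[["k3"]] * G / v[["k4"]]
    stG <- v[["k5"]] * G * v[["k7"]] / (v[["k5"]] * G + v[["k6"]] * I)
    v[["k1"]] / (1 + I + v[["k8"]] * G) - v[["k2"]] * G * I -
      v[["k5"]] * G * (v[["k7"]] - stG)
  }
  lo <- 1e-9
  if (gbal(lo) <= 0 || gbal(gMax) >= 0) {
    if (gbal(gMax) >= 0)
      stop("no basal steady state found in (0, ", gMax,
           "] mg/dL; widen gMax or revisit the parameter bounds")
  }
  root <- uniroot(gbal, c(lo, gMax), tol = .Machine$double.eps^0.75)$root
  G <- root
  I <- v[["k3"]] * G / v[["k4"]]
  stG <- v[["k5"]] * G * v[["k7"]] / (v[["k5"]] * G + v[["k6"]] * I)
  st <- c(G = G, I = I, stG = stG, AG = 0)
  resid <- evalRHS(st, params, 0)[c("dG", "dI", "dstG")]
  if (max(abs(resid)) > tol * max(1, v[["k1"]]))
    stop("basal steady-state residuals too large: ",
         paste(sprintf("%.3g", resid), collapse = ", "))
  st
}

#' Serialize / deserialize ModelParameters as JSON
#'
#' The JSON form is a flat mapping with exactly the keys k1..k8, G0, I0;
#' unknown keys are rejected on read.
#'
#' @param params a \code{ModelParameters} object.
#' @param path file path; for \code{paramsToJSON} with \code{path = NULL}
#'   the JSON string is returned.
#' @return \code{paramsFromJSON} returns a \code{ModelParameters}.
#' @export
paramsToJSON <- function(params, path = NULL) {
  js <- jsonlite::toJSON(as.list(paramVector(params)), auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname paramsToJSON
#' @param ... passed to \code{\link{paramsFromVector}}.
#' @export
paramsFromJSON <- function(path, ...) {
  x <- jsonlite::fromJSON(path)
  paramsFromVector(unlist(x), ...)
}
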