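#' @import methods
#' @importFrom stats approx cor median pnorm pt qnorm quantile rchisq rlnorm
#'   rnorm runif sd setNames var uniroot p.adjust
#' @importFrom utils read.csv write.csv head tail combn
#' @useDynLib stGclamp
NULL

.PARAM_NAMES <- c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "G0", "I0")
.STATE_NAMES <- c("G", "I", "stG", "AG")
.FLUX_NAMES  <- c("flux1", "flux2", "flux3", "flux4", "flux5", "flux6",
                  "influxG")

#' Model parameters for the glucose-store kinetic model
#'
#' Holds the eight rate constants of the four-state glucose regulation model
#' together with the initial (fasting) glucose and insulin levels, which are
#' treated as estimable parameters.
#'
#' The rate constants are phenomenological: \code{k1} scales endogenous
#' glucose production (EGP, mg/dL/min), suppressed by insulin and (via
#' \code{k8}) by glucose; \code{k2} drives insulin-dependent glucose uptake;
#' \code{k3}/\code{k4} are insulin secretion and clearance rate constants;
#' \code{k5} drives insulin-independent uptake into the transient glucose
#' store (glucose effectiveness); \code{k6} is the insulin-dependent
#' consumption of the store; \code{k7} is the store's capacity
#' (mg/dL-equivalent); \code{k8} (1/(mg/dL)) weights glucose in EGP
#' suppression and may be zero.
#'
#' @slot k1,k2,k3,k4,k5,k6,k7,k8 numeric(1) rate constants, see description.
#' @slot G0 numeric(1) initial/fasting blood glucose (mg/dL).
#' @slot I0 numeric(1) initial/fasting blood insulin (ng/mL).
#' @export
setClass("ModelParameters",
  representation(k1 = "numeric", k2 = "numeric", k3 = "numeric",
                 k4 = "numeric", k5 = "numeric", k6 = "numeric",
                 k7 = "numeric", k8 = "numeric", G0 = "numeric",
                 I0 = "numeric"))

setValidity("ModelParameters", function(object) {
  v <- paramVector(object)
  if (any(!is.finite(v)))
    return("all parameters must be finite")
  pos <- v[setdiff(.PARAM_NAMES, "k8")]
  if (any(pos <= 0))
    return(paste0("parameters must be strictly positive (k8 may be zero); ",
                  "offending: ",
                  paste(names(pos)[pos <= 0], collapse = ", ")))
  if (v[["k8"]] < 0) return("k8 must be >= 0")
  TRUE
})

#' Construct a ModelParameters object
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8 rate constants (see
#'   \code{\linkS4class{ModelParameters}}).
#' @param G0 initial/fasting blood glucose, mg/dL.
#' @param I0 initial/fasting blood insulin, ng/mL.
#' @param gBounds,iBounds physiological admissible ranges for \code{G0}
#'   (mg/dL) and \code{I0} (ng/mL); the defaults cover fasted through
#'   severely hyperglycemic mice.
#' @return A \code{ModelParameters} object.
#' @examples
#' p <- modelParameters(k1 = 10, k2 = 0.005, k3 = 2e-4, k4 = 0.01,
#'                      k5 = 1.4e-4, k6 = 0.01, k7 = 250, k8 = 0.01,
#'                      G0 = 120, I0 = 0.4)
#' paramVector(p)
#' @export
modelParameters <- function(k1, k2, k3, k4, k5, k6, k7, k8, G0, I0,
                            gBounds = c(40, 300), iBounds = c(0.05, 20)) {
  if (G0 < gBounds[1] || G0 > gBounds[2])
    stop("G0 = ", G0, " outside physiological bounds [",
         gBounds[1], ", ", gBounds[2], "] mg/dL")
  if (I0 < iBounds[1] || I0 > iBounds[2])
    stop("I0 = ", I0, " outside physiological bounds [",
         iBounds[1], ", ", iBounds[2], "] ng/mL")
  new("ModelParameters", k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
      k6 = k6, k7 = k7, k8 = k8, G0 = G0, I0 = I0)
}

#' Extract the parameters as a named numeric vector
#'
#' @param params a \code{ModelParameters} object.
#' @return Named numeric vector with entries k1..k8, G0, I0.
#' @export
paramVector <- function(params) {
  setNames(vapply(.PARAM_NAMES, function(nm) slot(params, nm), numeric(1)),
           .PARAM_NAMES)
}

#' Build ModelParameters from a named vector or list
#'
#' @param x named numeric vector or list with exactly the entries
#'   k1..k8, G0, I0 (order free); unknown names are rejected.
#' @param ... passed to \code{\link{modelParameters}} (e.g. bounds).
#' @return A \code{ModelParameters} object.
#' @export
paramsFromVector <- function(x, ...) {
  x <- unlist(x)
  unknown <- setdiff(names(x), .PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter names: ", paste(unknown, collapse = ", "))
  missing <- setdiff(.PARAM_NAMES, names(x))
  if (length(missing))
    stop("missing parameter names: ", paste(missing, collapse = ", "))
  do.call(modelParameters, c(as.list(x[.PARAM_NAMES]), list(...)))
}

setMethod("show", "ModelParameters", function(object) {
  v <- paramVector(object)
  cat("ModelParameters (glucose-store kinetic model)\n")
  cat("  rates:", paste(sprintf("%s=%.4g", names(v)[1:8], v[1:8]),
                        collapse = " "), "\n")
  cat(sprintf("  initial: G0=%.4g mg/dL  I0=%.4g ng/mL\n",
              v[["G0"]], v[["I0"]]))
})

#' Infusion protocol description
#'
#' Describes how exogenous glucose is delivered during a simulated
#' experiment: a closed-loop hyperglycemic clamp (\code{mode = "clamp"}), a
#' fixed piecewise-constant schedule (\code{"fixed_schedule"}), or an IVGTT
#' bolus (\code{"ivgtt_bolus"}). Rates are in uL/g/min of glucose solution,
#' as delivered by a syringe pump; the solution concentration (mg/uL)
#' converts them to mass rates, and the animal's circulating blood volume
#' converts mass rates into the model's concentration units.
#'
#' @slot mode one of "clamp", "fixed_schedule", "ivgtt_bolus".
#' @slot bodyWeight numeric(1), g.
#' @slot solutionConc numeric(1), mg glucose per uL of solution
#'   (0.25 for a 25\% solution, 0.15 for 15\%).
#' @slot initialRate numeric(1), uL/g/min priming rate (clamp mode).
#' @slot targetOffset numeric(1), mg/dL above fasting glucose (clamp mode).
#' @slot adjustmentTimes numeric, minutes at which the clamp controller may
#'   change the infusion rate (defaults to the glucose measurement grid).
#' @slot rateTimes,rateValues numeric, piecewise-constant schedule
#'   (fixed_schedule mode): rate \code{rateValues[i]} applies on
#'   \code{[rateTimes[i], rateTimes[i+1])}, the last value until the end.
#' @slot bolusDose numeric(1), g glucose per kg body weight (IVGTT).
#' @slot bolusDuration numeric(1), min over which the bolus is infused.
#' @slot totalDuration numeric(1), min.
#' @slot gainP,gainObs numeric(1), clamp controller gains (see
#'   \code{\link{runClamp}}).
#' @export
setClass("InfusionProtocol",
  representation(mode = "character", bodyWeight = "numeric",
                 solutionConc = "numeric", initialRate = "numeric",
                 targetOffset = "numeric", adjustmentTimes = "numeric",
                 rateTimes = "numeric", rateValues = "numeric",
                 bolusDose = "numeric", bolusDuration = "numeric",
                 totalDuration = "numeric", gainP = "numeric",
                 gainObs = "numeric"))

setValidity("InfusionProtocol", function(object) {
  if (!object@mode %in% c("clamp", "fixed_schedule", "ivgtt_bolus"))
    return("mode must be clamp, fixed_schedule or ivgtt_bolus")
  if (object@bodyWeight <= 0) return("bodyWeight must be > 0 g")
  if (object@solutionConc <= 0) return("solutionConc must be > 0 mg/uL")
  if (object@totalDuration <= 0) return("totalDuration must be > 0 min")
  if (any(object@rateValues < 0)) return("schedule rates must be >= 0")
  if (object@initialRate < 0) return("initialRate must be >= 0")
  if (object@bolusDose < 0) return("bolusDose must be >= 0")
  at <- object@adjustmentTimes
  if (length(at) && (any(diff(at) <= 0) || any(at < 0) ||
                     any(at > object@totalDuration)))
    return("adjustmentTimes must be strictly increasing within [0, totalDuration]")
  TRUE
})

#' Construct an InfusionProtocol
#'
#' @param mode "clamp", "fixed_schedule" or "ivgtt_bolus".
#' @param bodyWeight body weight, g.
#' @param solutionConc glucose solution concentration, mg/uL (default 0.25,
#'   i.e. a 25\% solution).
#' @param initialRate clamp priming rate, uL/g/min (default 0.15, the slow
#'   priming used for chow-fed mice).
#' @param targetOffset clamp target above fasting glucose, mg/dL
#'   (default 200).
#' @param adjustmentTimes minutes at which the clamp controller may adjust
#'   the rate; defaults to the glucose measurement grid.
#' @param rateTimes,rateValues piecewise-constant schedule for
#'   fixed_schedule mode (uL/g/min).
#' @param bolusDose IVGTT bolus, g/kg (default 0.75).
#' @param bolusDuration IVGTT bolus duration, min (default 3).
#' @param totalDuration experiment duration, min (default 180; 90 for
#'   IVGTT).
#' @param gainP,gainObs clamp controller gains, see \code{\link{runClamp}}.
#' @return An \code{InfusionProtocol} object.
#' @export
infusionProtocol <- function(mode = c("clamp", "fixed_schedule",
                                      "ivgtt_bolus"),
                             bodyWeight = 25, solutionConc = 0.25,
                             initialRate = 0.15, targetOffset = 200,
                             adjustmentTimes = NULL,
                             rateTimes = numeric(0),
                             rateValues = numeric(0),
                             bolusDose = 0.75, bolusDuration = 3,
                             totalDuration = NULL,
                             gainP = 0.8, gainObs = 1.0) {
  mode <- match.arg(mode)
  if (is.null(totalDuration))
    totalDuration <- if (mode == "ivgtt_bolus") 90 else 180
  if (is.null(adjustmentTimes))
    adjustmentTimes <- glucoseGrid()[glucoseGrid() <= totalDuration]
  if (mode == "ivgtt_bolus") solutionConc <- 0.15 * (solutionConc / 0.25)
  new("InfusionProtocol", mode = mode, bodyWeight = bodyWeight,
      solutionConc = solutionConc, initialRate = initialRate,
      targetOffset = targetOffset, adjustmentTimes = adjustmentTimes,
      rateTimes = rateTimes, rateValues = rateValues,
      bolusDose = bolusDose, bolusDuration = bolusDuration,
      totalDuration = totalDuration, gainP = gainP, gainObs = gainObs)
}

setMethod("show", "InfusionProtocol", function(object) {
  cat(sprintf("InfusionProtocol <%s>  BW=%.3g g  conc=%.3g mg/uL  %g min\n",
              object@mode, object@bodyWeight, object@solutionConc,
              object@totalDuration))
  if (object@mode == "clamp")
    cat(sprintf("  target = fasting + %g mg/dL, priming %.3g uL/g/min, %d adjustment times\n",
                object@targetOffset, object@initialRate,
                length(object@adjustmentTimes)))
  if (object@mode == "ivgtt_bolus")
    cat(sprintf("  bolus %.3g g/kg over %g min\n",
                object@bolusDose, object@bolusDuration))
})

#' One mouse's (measured or simulated) hyperglycemic clamp record
#'
#' @slot mouseId character(1) label.
#' @slot group character(1) group label (e.g. "CD14wk", "HFD28wk").
#' @slot bodyWeight numeric(1), g.
#' @slot glucoseTimes,glucoseValues numeric, min / mg/dL at the glucose
#'   measurement grid.
#' @slot insulinTimes,insulinValues numeric, min / ng/mL at the insulin
#'   measurement grid.
#' @slot doseTimes,doses numeric, minutes / mg of glucose administered in
#'   each interval (doses[i] was given over (doseTimes[i-1], doseTimes[i]],
#'   with doseTimes[0] = 0); doseTimes must be a subset of glucoseTimes.
#' @export
setClass("ClampRecord",
  representation(mouseId = "character", group = "character",
                 bodyWeight = "numeric",
                 glucoseTimes = "numeric", glucoseValues = "numeric",
                 insulinTimes = "numeric", insulinValues = "numeric",
                 doseTimes = "numeric", doses = "numeric"))

setValidity("ClampRecord", function(object) {
  chk <- function(t, v, nm, positive = TRUE) {
    if (length(t) != length(v))
      return(sprintf("%s: times and values differ in length", nm))
    if (length(t) && (any(diff(t) <= 0) || any(t < 0)))
      return(sprintf("%s: times must be sorted, non-negative", nm))
    if (positive && any(v <= 0))
      return(sprintf("%s: values must be > 0", nm))
    NULL
  }
  for (res in list(chk(object@glucoseTimes, object@glucoseValues, "glucose"),
                   chk(object@insulinTimes, object@insulinValues, "insulin"),
                   chk(object@doseTimes, object@doses, "doses",
                       positive = FALSE)))
    if (!is.null(res)) return(res)
  if (any(object@doses < 0)) return("doses must be >= 0")
  if (object@bodyWeight <= 0) return("bodyWeight must be > 0")
  if (length(object@doseTimes) &&
      !all(object@doseTimes %in% object@glucoseTimes))
    return("doseTimes must be a subset of glucoseTimes")
  TRUE
})

#' Construct a ClampRecord
#'
#' @param mouseId,group labels.
#' @param bodyWeight body weight, g.
#' @param glucoseTimes,glucoseValues glucose time course (min, mg/dL).
#' @param insulinTimes,insulinValues insulin time course (min, ng/mL).
#' @param doseTimes,doses per-interval administered glucose (min, mg);
#'   \code{doses[i]} was given over \code{(doseTimes[i-1], doseTimes[i]]}.
#' @return A \code{ClampRecord}.
#' @export
clampRecord <- function(mouseId, group, bodyWeight,
                        glucoseTimes, glucoseValues,
                        insulinTimes, insulinValues,
                        doseTimes, doses) {
  new("ClampRecord", mouseId = as.character(mouseId),
      group = as.character(group), bodyWeight = bodyWeight,
      glucoseTimes = as.numeric(glucoseTimes),
      glucoseValues = as.numeric(glucoseValues),
      insulinTimes = as.numeric(insulinTimes),
      insulinValues = as.numeric(insulinValues),
      doseTimes = as.numeric(doseTimes), doses = as.numeric(doses))
}

setMethod("show", "ClampRecord", function(object) {
  cat(sprintf("ClampRecord %s [%s]  BW=%.3g g\n", object@mouseId,
              object@group, object@bodyWeight))
  cat(sprintf("  %d glucose, %d insulin samples; %d dose intervals (total %.1f mg)\n",
              length(object@glucoseValues), length(object@insulinValues),
              length(object@doses), sum(object@doses)))
})

#' Dense simulated trajectory of the model
#'
#' @slot times numeric, min (strictly increasing dense grid).
#' @slot states matrix, columns G, I, stG, AG.
#' @slot fluxes matrix, columns flux1..flux6, influxG (per-time fluxes,
#'   mg/dL/min).
#' @slot infusionRate numeric, the piecewise-constant infusion f(t)
#'   (mg/dL/min) applying at each output time.
#' @slot doseTimes,dosesPerInterval numeric, interval-end times (min) and
#'   the glucose mass (mg) administered in each inter-measurement interval.
#' @slot protocol the InfusionProtocol that generated the run.
#' @slot params the ModelParameters used.
#' @slot metadata list (controller diagnostics, warnings, solver settings).
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", fluxes = "matrix",
                 infusionRate = "numeric", doseTimes = "numeric",
                 dosesPerInterval = "numeric", protocol = "ANY",
                 params = "ANY", metadata = "list"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (nrow(object@states) != n) return("states rows must match times")
  if (nrow(object@fluxes) != n) return("fluxes rows must match times")
  if (any(object@dosesPerInterval < -1e-12))
    return("dosesPerInterval must be >= 0")
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  st <- object@states
  cat(sprintf("Trajectory: %d points over [%g, %g] min\n",
              length(object@times), min(object@times), max(object@times)))
  cat(sprintf("  G %.4g..%.4g mg/dL  I %.3g..%.3g ng/mL  stG max %.4g  AG final %.4g\n",
              min(st[, "G"]), max(st[, "G"]), min(st[, "I"]), max(st[, "I"]),
              max(st[, "stG"]), st[nrow(st), "AG"]))
  if (length(object@dosesPerInterval))
    cat(sprintf("  total infused: %.1f mg over %d intervals\n",
                sum(object@dosesPerInterval),
                length(object@dosesPerInterval)))
  if (!is.null(object@metadata$warning))
    cat("  warning:", object@metadata$warning, "\n")
})

#' Coerce a Trajectory to a data.frame
#'
#' @param x a Trajectory.
#' @param ... unused.
#' @return data.frame with time_min, G_mgdl, I_ngml, stG, AG, flux1..flux6,
#'   infusion_mg_per_min (mass rate; uses the protocol's body weight).
#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) {
  vdl <- bloodVolume(x@protocol@bodyWeight)
  data.frame(time_min = x@times,
             G_mgdl = x@states[, "G"], I_ngml = x@states[, "I"],
             stG = x@states[, "stG"], AG = x@states[, "AG"],
             flux1 = x@fluxes[, "flux1"], flux2 = x@fluxes[, "flux2"],
             flux3 = x@fluxes[, "flux3"], flux4 = x@fluxes[, "flux4"],
             flux5 = x@fluxes[, "flux5"], flux6 = x@fluxes[, "flux6"],
             infusion_mg_per_min = x@infusionRate * vdl)
})

#' Windowed decomposition of glucose disposal fluxes
#'
#' @slot windowEnds numeric, window end times (min); each window is the 10
#'   preceding minutes.
#' @slot flux5Integrals,flux2Integrals numeric, 10-min integrals
#'   (mg/dL-equivalent) of insulin-independent (flux5) and
#'   insulin-dependent (flux2) uptake.
#' @slot stGTimes,stGSeries numeric, the store's trajectory on the dense
#'   grid.
#' @export
setClass("FluxDecomposition",
  representation(windowEnds = "numeric", flux5Integrals = "numeric",
                 flux2Integrals = "numeric", stGTimes = "numeric",
                 stGSeries = "numeric"))

setMethod("show", "FluxDecomposition", function(object) {
  cat("FluxDecomposition (10-min windows)\n")
  print(data.frame(window_end_min = object@windowEnds,
                   flux5_integral = object@flux5Integrals,
                   flux2_integral = object@flux2Integrals))
})

#' Result of fitting the model to one mouse
#'
#' @slot params the fitted \code{ModelParameters}.
#' @slot rss final residual sum of squares (normalized residuals).
#' @slot residuals list with per-stream residual vectors (G, I, AG).
#' @slot nEval number of objective evaluations used.
#' @slot converged logical(1).
#' @slot seed integer(1) seed used.
#' @slot cfgHash character(1) hash of the fit configuration.
#' @slot identifiability data.frame or NULL, per-parameter identifiability
#'   flags (see \code{\link{identifiabilityReport}}).
#' @export
setClass("FitResult",
  representation(params = "ANY", rss = "numeric", residuals = "list",
                 nEval = "numeric", converged = "logical", seed = "integer",
                 cfgHash = "character", identifiability = "ANY"))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: RSS = %.6g (%s, %d objective evaluations, seed %d)\n",
              object@rss,
              if (object@converged) "converged" else "not converged",
              as.integer(object@nEval), object@seed))
  show(object@params)
})

#' Group comparison report for fitted parameters
#'
#' @slot summaries data.frame of per-parameter, per-group box statistics
#'   (n, mean, se, q1, median, q3, outliers excluded).
#' @slot pairwise data.frame of Welch tests with BH adjustment and stars.
#' @slot trend data.frame of Williams-type step-down trend decisions.
#' @slot design list describing control group, group order and trend
#'   directions.
#' @export
setClass("GroupComparisonReport",
  representation(summaries = "data.frame", pairwise = "data.frame",
                 trend = "data.frame", design = "list"))

setMethod("show", "GroupComparisonReport", function(object) {
  cat(sprintf("GroupComparisonReport: %d parameters, %d groups\n",
              length(unique(object@summaries$parameter)),
              length(unique(object@summaries$group))))
  if (nrow(object@pairwise)) {
    sig <- object@pairwise[object@pairwise$p_bh < 0.05, , drop = FALSE]
    cat(sprintf("  %d/%d pairwise comparisons significant after BH\n",
                nrow(sig), nrow(object@pairwise)))
  }
  if (nrow(object@trend)) {
    rej <- object@trend[object@trend$rejected, , drop = FALSE]
    cat(sprintf("  trend rejections: %s\n",
                if (nrow(rej)) paste(sprintf("%s@%s", rej$parameter,
                                             rej$group), collapse = ", ")
                else "none"))
  }
})
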