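## Data-side formulas: circulating blood volume, cumulative glucose uptake
## from infusion records, tracer conversion for organ uptake, AUC windows.

#' Circulating blood volume of a mouse
#'
#' Computed as body weight times 72 mL of blood per kg of body weight,
#' returned in dL so it converts mg/dL concentrations into mg directly.
#'
#' @param bodyWeight body weight, g.
#' @return numeric, circulating blood volume in dL.
#' @examples
#' bloodVolume(25)   # 1.8 mL = 0.018 dL
#' @export
bloodVolume <- function(bodyWeight) {
  if (any(bodyWeight <= 0)) stop("bodyWeight must be > 0 g")
  (bodyWeight / 1000) * 72 / 100
}

#' Cumulative glucose uptake from a clamp record
#'
#' Data-side cumulative uptake at each glucose measurement time:
#' \deqn{AG(t_i) = \sum_{u \le i} [dose_u - (G(t_u) - G(t_{u-1})) V]}
#' with V the circulating blood volume in dL, AG(0) = 0. The doses are
#' already masses (mg); the blood-volume factor converts only the glucose
#' concentration difference into mass — the only unit-consistent reading of
#' the balance, and the one that matches the model's own mass balance.
#'
#' @param record a \code{\linkS4class{ClampRecord}}; doses must be aligned
#'   to the glucose grid.
#' @param missingDose policy when an inter-measurement interval has no
#'   recorded dose: "error" (default) or "zero" (treat as 0, with a
#'   warning).
#' @return Numeric vector of AG (mg) at \code{record@glucoseTimes}.
#' @export
cumulativeUptake <- function(record, missingDose = c("error", "zero")) {
  missingDose <- match.arg(missingDose)
  gt <- record@glucoseTimes
  gv <- record@glucoseValues
  doses <- setNames(rep(0, length(gt) - 1L), as.character(gt[-1]))
  have <- as.character(record@doseTimes)
  unmatched <- setdiff(have, names(doses))
  if (length(unmatched))
    stop("dose times not on the glucose grid: ",
         paste(unmatched, collapse = ", "))
  miss <- setdiff(names(doses), have)
  if (length(miss)) {
    msg <- paste("no dose recorded for interval(s) ending at",
                 paste(miss, collapse = ", "), "min")
    if (missingDose == "error") stop(msg) else warning(msg, "; treated as 0")
  }
  doses[have] <- record@doses
  vdl <- bloodVolume(record@bodyWeight)
  increments <- doses - diff(gv) * vdl
  unname(c(0, cumsum(increments)))
}

#' Convert tracer uptake into organ glucose uptake
#'
#' Proportional 2-deoxyglucose (2-DG) conversion: the glucose taken up by an
#' organ during the 10-minute tracer window is the glucose administered in
#' that window scaled by the fraction of administered tracer the organ
#' accumulated.
#'
#' @param glucoseAdministered10min glucose administered during the tracer
#'   window, mg.
#' @param dgUptake 2-DG accumulated in the organ, nmol.
#' @param dgAdministered 2-DG administered, nmol (default 5000, i.e. the
#'   5 umol co-administered dose).
#' @return Organ glucose uptake, mg.
#' @examples
#' organUptake(12, 500)   # 1.2 mg
#' @export
organUptake <- function(glucoseAdministered10min, dgUptake,
                        dgAdministered = 5000) {
  if (any(c(glucoseAdministered10min, dgUptake) < 0))
    stop("inputs must be >= 0")
  if (dgAdministered <= 0) stop("dgAdministered must be > 0")
  if (any(dgUptake > dgAdministered))
    warning("dgUptake exceeds dgAdministered; value returned but physically suspect")
  glucoseAdministered10min * dgUptake / dgAdministered
}

#' Area under a sampled curve over a window
#'
#' Trapezoidal rule with linear interpolation at window endpoints that fall
#' between samples.
#'
#' @param times,values the sampled curve.
#' @param window length-2 numeric, \code{c(a, b)} with a < b, inside the
#'   data span.
#' @return numeric(1), value x min.
#' @examples
#' aucWindow(0:10, rep(1, 11), c(0, 10))   # 10
#' @export
aucWindow <- function(times, values, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < min(times) || window[2] > max(times))
    stop(sprintf("window [%g, %g] outside data span [%g, %g]",
                 window[1], window[2], min(times), max(times)))
  .windowIntegral(times, values, window[1], window[2])
}
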