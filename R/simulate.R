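## Simulation engine: piecewise-constant infusion, stiff-capable integration
## with the compiled right-hand side, closed-loop clamp controller.

.rateToConc <- function(rateUlGMin, bodyWeight, solutionConc) {
  # uL/g/min * g * mg/uL = mg/min; divide by circulating blood volume (dL)
  rateUlGMin * bodyWeight * solutionConc / bloodVolume(bodyWeight)
}

# Integrate over one constant-rate segment. Returns the deSolve matrix.
.odeSegment <- function(y, times, kvec, rate, rtol, atol) {
  out <- deSolve::ode(y = y, times = times, func = "stg_derivs",
                      parms = c(kvec, rate), dllname = "stGclamp",
                      initfunc = "stg_init", jacfunc = "stg_jac",
                      jactype = "fullusr", nout = 7,
                      outnames = .FLUX_NAMES, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE solver failed at t = %.3f (state: %s)",
                 out[nrow(out), 1],
                 paste(sprintf("%.4g", out[nrow(out), 2:5]), collapse = ", ")))
  out
}

# Integrate a piecewise-constant infusion schedule.
# segments: data.frame(start, end, rate) contiguous, rate in mg/dL/min.
# Output at the union of a dense grid (denseBy) and extraTimes.
# Convention: the reported rate/fluxes at a boundary time belong to the
# segment beginning there (right-continuous f).
.integrateSegments <- function(params, init, segments, denseBy = 0.5,
                               extraTimes = numeric(0), rtol = 1e-8,
                               atol = 1e-10) {
  kvec <- paramVector(params)[1:8]
  y <- init[.STATE_NAMES]
  rows <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    t0 <- segments$start[s]; t1 <- segments$end[s]
    tt <- sort(unique(c(t0, t1, seq(t0, t1, by = denseBy),
                        extraTimes[extraTimes > t0 & extraTimes < t1])))
    out <- .odeSegment(y, tt, kvec, segments$rate[s], rtol, atol)
    y <- setNames(as.numeric(out[nrow(out), 2:5]), .STATE_NAMES)
    keep <- if (s == nrow(segments)) seq_len(nrow(out))
            else seq_len(nrow(out) - 1L)
    rows[[s]] <- cbind(out[keep, , drop = FALSE], rate = segments$rate[s])
  }
  m <- do.call(rbind, rows)
  states <- m[, 2:5, drop = FALSE]; colnames(states) <- .STATE_NAMES
  fluxes <- m[, 5 + seq_along(.FLUX_NAMES), drop = FALSE]
  colnames(fluxes) <- .FLUX_NAMES
  list(times = as.numeric(m[, 1]), states = states, fluxes = fluxes,
       rate = as.numeric(m[, "rate"]), finalState = y)
}

# Glucose mass (mg) infused in (a, b] given the segment table.
.infusedMass <- function(segments, vdl, a, b) {
  lo <- pmax(segments$start, a); hi <- pmin(segments$end, b)
  sum(pmax(hi - lo, 0) * segments$rate) * vdl
}

.dosesFromSegments <- function(segments, grid, vdl) {
  vapply(seq_along(grid)[-1], function(i)
    .infusedMass(segments, vdl, grid[i - 1], grid[i]), numeric(1))
}

.newTrajectory <- function(sim, segments, protocol, params, grid,
                           metadata = list()) {
  vdl <- bloodVolume(protocol@bodyWeight)
  doseT <- grid[-1]
  new("Trajectory", times = sim$times, states = sim$states,
      fluxes = sim$fluxes, infusionRate = sim$rate,
      doseTimes = doseT,
      dosesPerInterval = .dosesFromSegments(segments, grid, vdl),
      protocol = protocol, params = params,
      metadata = c(metadata, list(segments = segments)))
}

#' Simulate a fixed (open-loop) infusion schedule
#'
#' Integrates the four model ODEs under a piecewise-constant infusion
#' schedule with an adaptive stiff-capable solver (lsoda, analytic
#' Jacobian, rtol 1e-8 / atol 1e-10 by default). Pump rates (uL/g/min of
#' glucose solution) are converted to model units as rate x body weight x
#' solution concentration (mg/min), divided by the circulating blood volume
#' in dL.
#'
#' @param params a \code{ModelParameters}.
#' @param protocol an \code{InfusionProtocol} with mode "fixed_schedule";
#'   an empty schedule means no infusion.
#' @param init named state vector (G, I, stG, AG); default is the basal
#'   steady state of \code{params}.
#' @param denseBy output grid spacing, min.
#' @param rtol,atol solver tolerances.
#' @return A \code{\linkS4class{Trajectory}}.
#' @examples
#' p <- referenceParams("CD")
#' pr <- infusionProtocol("fixed_schedule", bodyWeight = 25)
#' traj <- simulateFixed(p, pr)   # basal run, stays at steady state
#' @export
simulateFixed <- function(params, protocol, init = NULL, denseBy = 0.5,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(protocol@mode == "fixed_schedule")
  if (is.null(init)) init <- basalSteadyState(params)
  tEnd <- protocol@totalDuration
  if (length(protocol@rateTimes)) {
    rt <- protocol@rateTimes; rv <- protocol@rateValues
    if (rt[1] > 0) { rt <- c(0, rt); rv <- c(0, rv) }
    segments <- data.frame(start = rt, end = c(rt[-1], tEnd),
                           rate = .rateToConc(rv, protocol@bodyWeight,
                                              protocol@solutionConc))
    segments <- segments[segments$end > segments$start, , drop = FALSE]
  } else {
    segments <- data.frame(start = 0, end = tEnd, rate = 0)
  }
  grid <- glucoseGrid()[glucoseGrid() <= tEnd]
  sim <- .integrateSegments(params, init, segments, denseBy,
                            extraTimes = c(grid, insulinGrid()),
                            rtol = rtol, atol = atol)
  .newTrajectory(sim, segments, protocol, params, grid,
                 metadata = list(rtol = rtol, atol = atol))
}

#' Run a closed-loop hyperglycemic clamp
#'
#' Holds blood glucose at \code{G0 + targetOffset} by titrating a
#' piecewise-constant glucose infusion, mimicking the experimental
#' procedure: a constant priming rate (\code{initialRate}) runs until
#' glucose first reaches the target (detected by bisection within the
#' measurement interval where the crossing occurs), after which the rate is
#' updated only at the adjustment times (by default the glucose measurement
#' schedule), using only the measured glucose values.
#'
#' The update rule is a discrete proportional rule with a finite-difference
#' demand observer: with measurement interval dt, error e = target - G, the
#' new rate is \code{max(0, gainObs * demandEstimate + gainP * e / dt)},
#' where \code{demandEstimate = previousRate - (G_k - G_{k-1}) / dt} is the
#' disposal rate implied by the last glucose change. With gainObs = 1 and
#' gainP in (0, 1] this is a damped deadbeat controller for the
#' near-integrator glucose dynamics and is deterministic, so synthetic
#' cohorts are exactly reproducible.
#'
#' @param params a \code{ModelParameters}.
#' @param protocol an \code{InfusionProtocol} with mode "clamp".
#' @param stG0 initial store: "zero" (default; the store is depleted after
#'   an overnight fast) or "basal" (the model's own basal steady-state
#'   store).
#' @param denseBy,rtol,atol see \code{\link{simulateFixed}}.
#' @return A \code{\linkS4class{Trajectory}}; metadata records the
#'   attainment time and a warning if the target was never reached.
#' @export
runClamp <- function(params, protocol, stG0 = c("zero", "basal"),
                     denseBy = 0.5, rtol = 1e-8, atol = 1e-10) {
  stopifnot(protocol@mode == "clamp")
  stG0 <- match.arg(stG0)
  v <- paramVector(params)
  target <- v[["G0"]] + protocol@targetOffset
  stG0v <- if (stG0 == "zero") 0 else basalSteadyState(params)[["stG"]]
  y <- c(G = v[["G0"]], I = v[["I0"]], stG = stG0v, AG = 0)
  kvec <- v[1:8]
  primeRate <- .rateToConc(protocol@initialRate, protocol@bodyWeight,
                           protocol@solutionConc)
  tEnd <- protocol@totalDuration
  adjust <- protocol@adjustmentTimes
  knots <- sort(unique(c(0, adjust, tEnd)))
  knots <- knots[knots <= tEnd]
  if (max(knots) < tEnd) knots <- c(knots, tEnd)

  segStart <- numeric(0); segEnd <- numeric(0); segRate <- numeric(0)
  rate <- primeRate
  attained <- FALSE; tAttain <- NA_real_
  gPrev <- v[["G0"]]; tPrev <- 0
  gLastMeas <- v[["G0"]]; tLastMeas <- 0
  dPrev <- NA_real_

  solveTo <- function(y, t0, t1, rate) {
    out <- .odeSegment(y, c(t0, t1), kvec, rate, rtol, atol)
    setNames(as.numeric(out[nrow(out), 2:5]), .STATE_NAMES)
  }

  for (i in seq_len(length(knots) - 1L)) {
    t0 <- knots[i]; t1 <- knots[i + 1L]
    if (!attained) {
      yEnd <- solveTo(y, t0, t1, rate)
      if (yEnd[["G"]] >= target) {
        # bisect for the crossing time within (t0, t1]
        lo <- t0; hi <- t1
        for (b in 1:40) {
          mid <- (lo + hi) / 2
          ymid <- solveTo(y, t0, mid, rate)
          if (ymid[["G"]] >= target) hi <- mid else lo <- mid
          if (hi - lo < 1e-6) break
        }
        tc <- hi
        segStart <- c(segStart, t0); segEnd <- c(segEnd, tc)
        segRate <- c(segRate, rate)
        y <- solveTo(y, t0, tc, rate)
        attained <- TRUE; tAttain <- tc
        gPrev <- y[["G"]]; tPrev <- tc
        # step down to the disposal rate implied by the priming ascent:
        # the ascent slope gives priming minus disposal
        ascent <- if (tc > tLastMeas)
          (y[["G"]] - gLastMeas) / (tc - tLastMeas) else 0
        rate <- max(0, rate - ascent)
        if (tc < t1) {
          segStart <- c(segStart, tc); segEnd <- c(segEnd, t1)
          segRate <- c(segRate, rate)
          y <- solveTo(y, tc, t1, rate)
        }
      } else {
        segStart <- c(segStart, t0); segEnd <- c(segEnd, t1)
        segRate <- c(segRate, rate)
        y <- yEnd
        gLastMeas <- y[["G"]]; tLastMeas <- t1
      }
    } else {
      # adjustment at t0 using the measured glucose only: demand observer
      # with linear trend anticipation plus a proportional correction
      dtPrev <- t0 - tPrev
      dtNext <- t1 - t0
      gNow <- y[["G"]]
      demand <- if (dtPrev > 0) rate - (gNow - gPrev) / dtPrev else rate
      slope <- if (!is.na(dPrev) && dtPrev > 0) (demand - dPrev) / dtPrev
               else 0
      # the demand estimate is centred on the previous interval's midpoint,
      # so extrapolate over half of each adjacent interval
      horizon <- 0.5 * (dtPrev + dtNext)
      err <- target - gNow
      rate <- max(0, protocol@gainObs * (demand + slope * horizon) +
                     protocol@gainP * err / dtNext)
      dPrev <- demand
      gPrev <- gNow; tPrev <- t0
      segStart <- c(segStart, t0); segEnd <- c(segEnd, t1)
      segRate <- c(segRate, rate)
      y <- solveTo(y, t0, t1, rate)
    }
  }

  segments <- data.frame(start = segStart, end = segEnd, rate = segRate)
  segments <- segments[segments$end > segments$start, , drop = FALSE]
  init <- c(G = v[["G0"]], I = v[["I0"]], stG = stG0v, AG = 0)
  grid <- glucoseGrid()[glucoseGrid() <= tEnd]
  sim <- .integrateSegments(params, init, segments, denseBy,
                            extraTimes = c(grid, insulinGrid(), tAttain),
                            rtol = rtol, atol = atol)
  meta <- list(target = target, attained = attained,
               attainmentTime = tAttain, stG0 = stG0,
               rtol = rtol, atol = atol)
  if (!attained)
    meta$warning <- sprintf("clamp target %.1f mg/dL never attained within %g min",
                            target, tEnd)
  .newTrajectory(sim, segments, protocol, params, grid, metadata = meta)
}

#' Simulate an intravenous glucose tolerance test (IVGTT)
#'
#' A glucose bolus (default 0.75 g/kg, 15\% solution) is infused at a
#' constant rate over \code{bolusDuration} minutes, then the infusion is
#' zero. Output is dense plus the IVGTT sampling grid
#' \{0,1,2,3,5,10,20,30,60,90\} min.
#'
#' @param params a \code{ModelParameters}.
#' @param protocol an \code{InfusionProtocol} with mode "ivgtt_bolus".
#' @param init named state vector; default starts at (G0, I0) with a
#'   depleted store.
#' @param stG0 "zero" or "basal", used when \code{init} is NULL.
#' @param denseBy,rtol,atol see \code{\link{simulateFixed}}.
#' @return A \code{\linkS4class{Trajectory}}.
#' @export
simulateIVGTT <- function(params, protocol, init = NULL,
                          stG0 = c("zero", "basal"), denseBy = 0.25,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(protocol@mode == "ivgtt_bolus")
  stG0 <- match.arg(stG0)
  v <- paramVector(params)
  if (is.null(init)) {
    stG0v <- if (stG0 == "zero") 0 else basalSteadyState(params)[["stG"]]
    init <- c(G = v[["G0"]], I = v[["I0"]], stG = stG0v, AG = 0)
  }
  vdl <- bloodVolume(protocol@bodyWeight)
  doseMg <- protocol@bolusDose * (protocol@bodyWeight / 1000) * 1000
  rate <- if (protocol@bolusDuration > 0)
    doseMg / protocol@bolusDuration / vdl else 0
  tEnd <- protocol@totalDuration
  segments <- data.frame(start = c(0, protocol@bolusDuration),
                         end = c(protocol@bolusDuration, tEnd),
                         rate = c(rate, 0))
  segments <- segments[segments$end > segments$start, , drop = FALSE]
  grid <- ivgttGrid()[ivgttGrid() <= tEnd]
  sim <- .integrateSegments(params, init, segments, denseBy,
                            extraTimes = grid, rtol = rtol, atol = atol)
  .newTrajectory(sim, segments, protocol, params, grid,
                 metadata = list(doseMg = doseMg, rtol = rtol, atol = atol))
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

.windowIntegral <- function(times, values, a, b) {
  if (a < min(times) - 1e-9 || b > max(times) + 1e-9)
    stop(sprintf("integration window [%g, %g] outside trajectory span [%g, %g]",
                 a, b, min(times), max(times)))
  inside <- times > a & times < b
  xs <- c(a, times[inside], b)
  ys <- c(approx(times, values, a)$y, values[inside],
          approx(times, values, b)$y)
  .trapz(xs, ys)
}

#' Decompose glucose disposal into windowed flux integrals
#'
#' Computes the 10-minute integrals of the insulin-independent uptake flux
#' (flux5, glucose effectiveness into the store) and the insulin-dependent
#' uptake flux (flux2) ending at each requested time, by trapezoidal
#' quadrature on the trajectory's dense grid, together with the store's
#' time course. This is the decomposition that separates the early,
#' insulin-independent phase of glucose disposal from the late
#' insulin-driven phase.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param windowEnds window end times, min (default 10, 20, 60, 120, 180).
#' @param windowWidth window width, min (default 10).
#' @return A \code{\linkS4class{FluxDecomposition}}.
#' @export
decomposeFluxes <- function(traj, windowEnds = c(10, 20, 60, 120, 180),
                            windowWidth = 10) {
  f5 <- vapply(windowEnds, function(e)
    .windowIntegral(traj@times, traj@fluxes[, "flux5"], e - windowWidth, e),
    numeric(1))
  f2 <- vapply(windowEnds, function(e)
    .windowIntegral(traj@times, traj@fluxes[, "flux2"], e - windowWidth, e),
    numeric(1))
  new("FluxDecomposition", windowEnds = windowEnds, flux5Integrals = f5,
      flux2Integrals = f2, stGTimes = traj@times,
      stGSeries = traj@states[, "stG"])
}

#' Mass-balance error of a simulated trajectory
#'
#' The model conserves glucose mass: at every time, cumulative infused
#' glucose (mg) equals the change in circulating glucose mass plus
#' cumulative uptake, \code{(G(t) - G(0)) * V + AG(t) * V} with V the
#' circulating blood volume in dL. Returns the maximum absolute discrepancy
#' relative to the larger of the two sides (bounded below by 1 mg to avoid
#' 0/0 at the start of a run).
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @return numeric(1), maximum relative discrepancy.
#' @export
massBalanceError <- function(traj) {
  segments <- traj@metadata$segments
  vdl <- bloodVolume(traj@protocol@bodyWeight)
  infused <- vapply(traj@times, function(t)
    .infusedMass(segments, vdl, 0, t), numeric(1))
  lhs <- (traj@states[, "G"] - traj@states[1, "G"] +
          traj@states[, "AG"]) * vdl
  max(abs(infused - lhs) / pmax(pmax(abs(infused), abs(lhs)), 1))
}

#' Export a trajectory or flux decomposition to CSV
#'
#' @param x a \code{Trajectory} or \code{FluxDecomposition}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
exportTrajectoryCSV <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportTrajectoryCSV
#' @export
exportFluxDecompositionCSV <- function(x, path) {
  stopifnot(is(x, "FluxDecomposition"))
  write.csv(data.frame(window_end_min = x@windowEnds,
                       flux5_integral = x@flux5Integrals,
                       flux2_integral = x@flux2Integrals),
            path, row.names = FALSE)
  invisible(path)
}
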