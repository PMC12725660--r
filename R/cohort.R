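## Synthetic mouse cohorts: per-group parameter distributions emulating
## chow-fed and high-fat-diet groups, closed-loop clamp simulation per
## mouse, measurement noise, and export in the 4-file CSV layout.

#' Reference parameter sets
#'
#' Documented fixture parameter sets used throughout the package. "CD" is a
#' lean, chow-fed-like mouse: modest fasting glucose/insulin, a sizeable
#' insulin-independent store that fills over roughly the first hour of a
#' clamp (producing the early insulin-independent disposal transient and
#' the biphasic infusion demand), and insulin-dependent uptake that
#' dominates the final hour. "HFDold" is an old, high-fat-diet-like mouse:
#' elevated fasting glucose and insulin, strong insulin secretion, weak
#' insulin-dependent uptake and weak glucose effectiveness, so the
#' infusion demand lacks the late insulin-driven rise.
#'
#' @param type "CD" or "HFDold".
#' @return A \code{\linkS4class{ModelParameters}}.
#' @export
referenceParams <- function(type = c("CD", "HFDold")) {
  type <- match.arg(type)
  switch(type,
    CD = modelParameters(k1 = 6, k2 = 3.5e-3, k3 = 2e-4, k4 = 0.02,
                         k5 = 1.3e-4, k6 = 6e-3, k7 = 600, k8 = 0.01,
                         G0 = 120, I0 = 0.4),
    # the oldest high-fat-diet group of the default cohort: the CD rates
    # scaled by that group's trend multipliers
    HFDold = modelParameters(k1 = 6 * 1.17, k2 = 3.5e-3 * 0.125,
                             k3 = 2e-4 * 1.45, k4 = 0.02 * 0.80,
                             k5 = 1.3e-4 * 0.267, k6 = 6e-3 * 0.10,
                             k7 = 600 * 1.73, k8 = 0.01 * 0.80,
                             G0 = 180, I0 = 2.5))
}

#' Cohort specification
#'
#' Builds the per-group specification for the synthetic cohort generator.
#' The default design has one chow-fed group and five
#' high-fat-diet groups of increasing time on diet, with group sizes 13,
#' 13, 16, 13, 10, 10; monotone multiplicative age trends on k2 (down), k3
#' (up), k5 (down) and k7 (up); rising body weight and fasting
#' glucose/insulin; the protocol constants of each group (priming rate,
#' target offset 200 mg/dL). Per-mouse parameters are drawn log-normally
#' around the group means; k7 additionally scales with the mouse's body
#' weight (heavier mice have a larger store), which induces the positive
#' k7 / body-weight correlation across the cohort.
#'
#' @param groups optional data.frame overriding the default group table
#'   (columns: label, n, bwMean, bwSD, fastG, fastGSD, fastI, fastISD,
#'   initialRate, and one column per rate constant k1..k8).
#' @param glucoseCV,insulinCV multiplicative measurement noise CVs
#'   (defaults 0.05 and 0.10, conventional glucometer / ELISA figures).
#' @param paramCV log-normal coefficient of variation of each rate
#'   constant between mice (default 0.18).
#' @param k7BWExponent elasticity of k7 with respect to body weight within
#'   a group (default 1).
#' @param seed integer seed stored with the spec.
#' @return A list of class "CohortSpec".
#' @export
cohortSpec <- function(groups = NULL, glucoseCV = 0.05, insulinCV = 0.10,
                       paramCV = 0.18, k7BWExponent = 1, seed = 1L) {
  stopifnot(glucoseCV >= 0, glucoseCV <= 0.5,
            insulinCV >= 0, insulinCV <= 0.5, paramCV >= 0)
  if (is.null(groups)) groups <- .defaultGroupTable()
  needed <- c("label", "n", "bwMean", "bwSD", "fastG", "fastGSD", "fastI",
              "fastISD", "initialRate", paste0("k", 1:8))
  missing <- setdiff(needed, names(groups))
  if (length(missing))
    stop("group table lacks columns: ", paste(missing, collapse = ", "))
  if (any(groups$n < 2)) stop("each group needs n >= 2")
  structure(list(groups = groups, glucoseCV = glucoseCV,
                 insulinCV = insulinCV, paramCV = paramCV,
                 k7BWExponent = k7BWExponent, seed = as.integer(seed)),
            class = "CohortSpec")
}

# Default group table: CD baseline from referenceParams("CD"), HFD groups
# as multiplicative departures. Trend multipliers (relative to CD):
#   k2 down, k3 up, k5 down, k7 up with time on diet; mild EGP rise (k1),
#   mild clearance decline (k4). Fasting glucose follows the reported
#   per-group clamp targets minus the 200 mg/dL offset.
.defaultGroupTable <- function() {
  cd <- paramVector(referenceParams("CD"))
  lab <- c("CD14wk", "HFD10wk", "HFD14wk", "HFD18wk", "HFD28wk", "HFD36wk")
  mult <- rbind(                # k1    k2    k3    k4    k5    k6    k7    k8
    CD14wk  = c(1.00, 1.000, 1.00, 1.00, 1.000, 1.00, 1.00, 1.00),
    HFD10wk = c(1.03, 0.850, 1.08, 0.95, 0.900, 0.70, 1.10, 0.96),
    HFD14wk = c(1.06, 0.650, 1.15, 0.92, 0.750, 0.45, 1.25, 0.92),
    HFD18wk = c(1.10, 0.450, 1.25, 0.88, 0.600, 0.30, 1.40, 0.88),
    HFD28wk = c(1.14, 0.250, 1.35, 0.84, 0.400, 0.15, 1.60, 0.84),
    HFD36wk = c(1.17, 0.125, 1.45, 0.80, 0.267, 0.10, 1.73, 0.80))
  ks <- sweep(mult, 2, cd[1:8], "*")
  colnames(ks) <- paste0("k", 1:8)
  data.frame(label = lab,
             n = c(13L, 13L, 16L, 13L, 10L, 10L),
             bwMean = c(27, 34, 40, 44, 48, 51),
             bwSD = c(2.0, 2.5, 3.0, 3.0, 3.5, 3.5),
             fastG = c(120, 180, 220, 230, 200, 180),
             fastGSD = c(8, 12, 15, 15, 14, 12),
             fastI = c(0.4, 0.8, 1.2, 1.6, 2.0, 2.5),
             fastISD = c(0.08, 0.16, 0.25, 0.3, 0.4, 0.5),
             initialRate = c(0.15, 0.1, 0.1, 0.1, 0.13, 0.13),
             ks, row.names = NULL)
}

#' Draw one mouse's parameters and body weight from a group spec
#'
#' Rate constants are log-normal around the group means with the spec's
#' between-mouse CV; k7 is additionally scaled by
#' \code{(BW / bwMean)^k7BWExponent}; fasting G0 and I0 are normal draws
#' truncated to the physiological bounds. Draws violating the bounds are
#' rejected and redrawn (at most 1000 attempts).
#'
#' @param groupRow one row of the spec's group table.
#' @param spec the \code{\link{cohortSpec}}.
#' @return list with \code{params} (\code{ModelParameters}) and
#'   \code{bodyWeight} (g). Uses the current RNG state.
#' @export
sampleMouse <- function(groupRow, spec) {
  sdlog <- sqrt(log(1 + spec$paramCV^2))
  for (attempt in seq_len(1000)) {
    bw <- rnorm(1, groupRow$bwMean, groupRow$bwSD)
    if (bw <= 5) next
    km <- as.numeric(groupRow[paste0("k", 1:8)])
    ks <- rlnorm(8, log(km) - sdlog^2 / 2, sdlog)
    ks[7] <- ks[7] * (bw / groupRow$bwMean)^spec$k7BWExponent
    g0 <- rnorm(1, groupRow$fastG, groupRow$fastGSD)
    i0 <- rnorm(1, groupRow$fastI, groupRow$fastISD)
    if (g0 < 40 || g0 > 300 || i0 < 0.05 || i0 > 20) next
    p <- tryCatch(modelParameters(k1 = ks[1], k2 = ks[2], k3 = ks[3],
                                  k4 = ks[4], k5 = ks[5], k6 = ks[6],
                                  k7 = ks[7], k8 = ks[8], G0 = g0,
                                  I0 = i0),
                  error = function(e) NULL)
    if (!is.null(p)) return(list(params = p, bodyWeight = bw))
  }
  stop("could not draw admissible parameters for group ", groupRow$label,
       " after 1000 attempts; revisit the spec")
}

#' Simulate one mouse's clamp record
#'
#' Runs the closed-loop clamp, then rebuilds the measured time courses by
#' replaying the recorded per-interval doses through the model — exactly
#' the forward model later used in fitting, where only the doses (not the
#' within-interval pump history) are known. Glucose is sampled at the
#' glucose grid and insulin at the insulin grid; multiplicative Gaussian
#' measurement noise is applied at the given CVs (drawn from the current
#' RNG state); doses are optionally rounded to 0.1 mg as a pump log would
#' be.
#'
#' @param params a \code{ModelParameters}.
#' @param protocol a clamp \code{InfusionProtocol}.
#' @param mouseId,group labels.
#' @param glucoseCV,insulinCV multiplicative noise CVs (0 = noise-free).
#' @param roundDoses round doses to 0.1 mg (default TRUE).
#' @param stG0 initial store, "zero" or "basal".
#' @return A \code{\linkS4class{ClampRecord}} with the clamp trajectory in
#'   \code{attr(, "trajectory")}; NULL if the clamp never attained target.
#' @export
simulateRecord <- function(params, protocol, mouseId = "m1",
                           group = "sim", glucoseCV = 0, insulinCV = 0,
                           roundDoses = TRUE, stG0 = "zero") {
  traj <- runClamp(params, protocol, stG0 = stG0)
  if (!isTRUE(traj@metadata$attained)) return(NULL)
  doses <- if (roundDoses) round(traj@dosesPerInterval, 1)
           else traj@dosesPerInterval
  gt <- glucoseGrid()
  rec0 <- clampRecord(mouseId, group, protocol@bodyWeight,
                      gt, rep(100, length(gt)),
                      insulinGrid(), rep(1, length(insulinGrid())),
                      traj@doseTimes, doses)
  cfg <- fitConfig(stG0 = stG0)
  sim <- .simForRecord(paramVector(params), rec0, cfg)
  gObs <- sim$G; iObs <- sim$I
  if (glucoseCV > 0)
    gObs <- pmax(gObs * (1 + glucoseCV * rnorm(length(gObs))), 1)
  if (insulinCV > 0)
    iObs <- pmax(iObs * (1 + insulinCV * rnorm(length(iObs))), 0.01)
  rec <- clampRecord(mouseId, group, protocol@bodyWeight, gt, gObs,
                     insulinGrid(), iObs, traj@doseTimes, doses)
  attr(rec, "trajectory") <- traj
  rec
}

#' Generate a complete synthetic cohort of clamp records
#'
#' For each mouse: draw parameters and body weight, run the closed-loop
#' hyperglycemic clamp (target = fasting + 200 mg/dL, the group's priming
#' rate), sample glucose at the glucose grid and insulin at the insulin
#' grid, apply multiplicative Gaussian measurement noise at the spec's
#' CVs, and round doses to 0.1 mg. Mice whose clamp never attains target
#' are redrawn (at most 5 retries, logged in the manifest).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param seed integer master seed (default: the spec's).
#' @return list with \code{records} (list of
#'   \code{\linkS4class{ClampRecord}}), \code{truth} (data.frame of true
#'   parameters per mouse), and \code{manifest} (seed, spec settings,
#'   retries).
#' @export
generateCohort <- function(spec, seed = spec$seed) {
  records <- list(); truthRows <- list(); retriesLog <- list()
  for (gi in seq_len(nrow(spec$groups))) {
    row <- spec$groups[gi, ]
    set.seed(deriveSeed(seed, paste0("group", row$label)))
    for (m in seq_len(row$n)) {
      id <- sprintf("%s_%02d", row$label, m)
      rec <- NULL
      for (try in 0:5) {
        draw <- sampleMouse(row, spec)
        prot <- infusionProtocol("clamp", bodyWeight = draw$bodyWeight,
                                 initialRate = row$initialRate,
                                 targetOffset = 200)
        rec <- simulateRecord(draw$params, prot, mouseId = id,
                              group = row$label,
                              glucoseCV = spec$glucoseCV,
                              insulinCV = spec$insulinCV)
        if (!is.null(rec)) break
        retriesLog[[length(retriesLog) + 1L]] <- id
      }
      if (is.null(rec))
        stop("mouse ", id, " never attained the clamp target after 5 redraws")
      records[[id]] <- rec
      truthRows[[id]] <- data.frame(mouse_id = id, group = row$label,
                                    body_weight_g = draw$bodyWeight,
                                    as.list(paramVector(draw$params)),
                                    attainment_min =
                                      attr(rec, "trajectory")@metadata$attainmentTime)
    }
  }
  list(records = records, truth = do.call(rbind, c(truthRows,
                                                   make.row.names = FALSE)),
       manifest = list(seed = seed, glucoseCV = spec$glucoseCV,
                       insulinCV = spec$insulinCV, paramCV = spec$paramCV,
                       k7BWExponent = spec$k7BWExponent,
                       nGroups = nrow(spec$groups),
                       retries = unlist(retriesLog),
                       package = as.character(utils::packageVersion("stGclamp"))))
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting: a small rolling hash of the stage label is
#' combined with the master seed modulo 2^31 - 1, so every stochastic
#' stage gets its own reproducible stream.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h) %% 2147483646 + 1)
}
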