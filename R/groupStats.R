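## Statistical layer: IQR outlier screening, pairwise Welch tests with
## Benjamini-Hochberg adjustment, Williams-type step-down trend tests with
## a Monte-Carlo null, Spearman rank correlation.

#' Exclude outliers by the 1.5 IQR rule
#'
#' Values below Q1 - 1.5 IQR or above Q3 + 1.5 IQR are excluded; quartiles
#' use linear interpolation of order statistics (\code{quantile} type 7).
#'
#' @param values numeric vector (>= 4 finite values for screening; fewer
#'   are returned unfiltered with a warning).
#' @return list with \code{kept}, \code{excluded} and the \code{bounds}.
#' @examples
#' iqrExclude(c(1:9, 100))$excluded   # 100
#' @export
iqrExclude <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    warning("fewer than 4 finite values; no outlier screening applied")
    return(list(kept = values, excluded = numeric(0),
                bounds = c(-Inf, Inf)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out <- values < bounds[1] | values > bounds[2]
  list(kept = values[!out], excluded = values[out], bounds = bounds)
}

.stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE)
}

.welchPair <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    # degenerate: no within-group variability
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf, df = nx + ny - 2,
                p = if (eq) 1 else 0))
  }
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Pairwise Welch tests with Benjamini-Hochberg adjustment
#'
#' Two-sided Welch t statistics with Satterthwaite degrees of freedom for
#' each requested pair, adjusted across the supplied family by the BH
#' step-up procedure, with significance stars at p < 0.05, 0.01, 0.001 and
#' 0.0001. When both groups have zero variance and equal means, p = 1 by
#' convention.
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param pairs two-column character matrix of group labels, or NULL for
#'   all pairs.
#' @return data.frame: group_a, group_b, t, df, p_raw, p_bh, stars.
#' @export
welchBH <- function(groups, pairs = NULL) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values")
  if (is.null(pairs)) {
    cmb <- combn(names(groups), 2)
    pairs <- t(cmb)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    w <- .welchPair(groups[[pairs[i, 1]]], groups[[pairs[i, 2]]])
    data.frame(group_a = pairs[i, 1], group_b = pairs[i, 2],
               t = w$t, df = w$df, p_raw = w$p)
  })
  out <- do.call(rbind, res)
  out$p_bh <- p.adjust(out$p_raw, method = "BH")
  out$stars <- as.character(.stars(out$p_bh))
  out
}

# Weighted maximum amalgamated mean of groups u..k (isotonic top value):
# max over u of the n-weighted mean of group means u..k. Equivalent to the
# top fitted value of the pool-adjacent-violators algorithm run on groups
# 1..k under a non-decreasing constraint.
.amalgTop <- function(means, ns, k) {
  best <- -Inf
  num <- 0; den <- 0
  for (u in k:1) {
    num <- num + ns[u] * means[u]
    den <- den + ns[u]
    best <- max(best, num / den)
  }
  best
}

# Trend statistics for control y0 and ordered treated groups ys (increasing
# alternative): tbar[k] = (amalgamated top mean of groups 1..k - control
# mean) / sqrt(s2 (1/nk + 1/n0)) with the pooled within-group variance.
.williamsStats <- function(y0, ys) {
  K <- length(ys)
  ns <- vapply(ys, length, 1L); n0 <- length(y0)
  means <- vapply(ys, mean, numeric(1)); m0 <- mean(y0)
  dfPool <- n0 + sum(ns) - (K + 1)
  s2 <- (sum((y0 - m0)^2) + sum(vapply(ys, function(y)
    sum((y - mean(y))^2), numeric(1)))) / dfPool
  tbar <- vapply(seq_len(K), function(k) {
    num <- .amalgTop(means, ns, k) - m0
    se <- sqrt(s2 * (1 / ns[k] + 1 / n0))
    if (se == 0) { if (abs(num) < 1e-300) 0 else sign(num) * Inf }
    else num / se
  }, numeric(1))
  list(tbar = tbar, ns = ns, n0 = n0, dfPool = dfPool, s2 = s2)
}

# Monte-Carlo sample of the null distribution of all K step statistics:
# group means ~ N(0, 1/n), pooled variance ~ chi^2_df / df (their exact
# normal-theory sampling distributions), so no per-observation simulation
# is needed. Returns an nMC x K matrix.
.williamsNullSample <- function(ns, n0, dfPool, nMC, seed) {
  K <- length(ns)
  set.seed(seed)
  simMeans <- matrix(rnorm(nMC * K, 0, rep(sqrt(1 / ns), each = nMC)),
                     nMC, K)
  simM0 <- rnorm(nMC, 0, sqrt(1 / n0))
  simS2 <- rchisq(nMC, dfPool) / dfPool
  out <- matrix(NA_real_, nMC, K)
  for (k in seq_len(K)) {
    num <- simMeans[, k] * ns[k]; den <- rep(ns[k], nMC)
    top <- num / den
    if (k > 1) for (u in (k - 1):1) {
      num <- num + simMeans[, u] * ns[u]; den <- den + ns[u]
      top <- pmax(top, num / den)
    }
    out[, k] <- (top - simM0) / sqrt(simS2 * (1 / ns[k] + 1 / n0))
  }
  out
}

#' Williams-type step-down trend test with a Monte-Carlo null
#'
#' Tests for a monotone change in group means with increasing dose (here:
#' age on diet) against a control, using the isotonic (amalgamated) mean of
#' the highest group: for step k the statistic is
#' \deqn{\bar t_k = (\hat M_k - \bar y_0) / \sqrt{s^2 (1/n_k + 1/n_0)}}
#' where \eqn{\hat M_k} is the pool-adjacent-violators amalgamated mean of
#' treated groups 1..k at position k, \eqn{\bar y_0} the control mean and
#' \eqn{s^2} the pooled within-group variance over all groups. Testing
#' steps down from the highest group and stops at the first non-rejection;
#' lower groups are then declared non-significant without testing.
#'
#' p-values come from a seeded Monte-Carlo of the joint null distribution
#' (group means and the pooled variance are simulated directly from their
#' normal-theory sampling distributions at the observed group sizes), which
#' replaces the classical critical-value tables, is valid at unequal group
#' sizes, and is reproducible by seed.
#'
#' @param control numeric vector, control group.
#' @param orderedGroups list of numeric vectors, ordered by dose (lowest
#'   first); each >= 2 values.
#' @param direction "increasing" or "decreasing" alternative.
#' @param alpha step-down rejection level (default 0.05).
#' @param nMC Monte-Carlo replicates (default 1e5).
#' @param seed integer seed for the null simulation.
#' @return data.frame (highest group first): group index/label, tbar, p_mc,
#'   rejected, tested; attributes "seed" and "nMC".
#' @export
williamsTrend <- function(control, orderedGroups,
                          direction = c("increasing", "decreasing"),
                          alpha = 0.05, nMC = 1e5, seed = 1L) {
  direction <- match.arg(direction)
  if (!length(orderedGroups)) stop("orderedGroups must be non-empty")
  if (length(control) < 2 ||
      any(vapply(orderedGroups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  labels <- names(orderedGroups)
  if (is.null(labels)) labels <- paste0("group", seq_along(orderedGroups))
  sgn <- if (direction == "decreasing") -1 else 1
  y0 <- sgn * control
  ys <- lapply(orderedGroups, function(y) sgn * y)
  K <- length(ys)
  st <- .williamsStats(y0, ys)
  tbar <- st$tbar
  tSim <- .williamsNullSample(st$ns, st$n0, st$dfPool, nMC, seed)
  pmc <- vapply(seq_len(K), function(k)
    (1 + sum(tSim[, k] >= tbar[k])) / (nMC + 1), numeric(1))

  rejected <- logical(K); tested <- logical(K)
  for (k in K:1) {
    tested[k] <- TRUE
    rejected[k] <- pmc[k] < alpha
    if (!rejected[k]) break
  }
  out <- data.frame(group = labels[K:1], step = K:1, tbar = tbar[K:1],
                    p_mc = pmc[K:1], tested = tested[K:1],
                    rejected = rejected[K:1], direction = direction)
  attr(out, "seed") <- seed
  attr(out, "nMC") <- nMC
  out
}

#' Spearman rank correlation with documented p-value conventions
#'
#' Rank correlation using average ranks for ties. The p-value uses the
#' t approximation \code{t = rho * sqrt((n-2)/(1-rho^2))} for n > 9 and an
#' exact two-sided permutation enumeration for n <= 9.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p}, \code{n}, \code{method}; if one
#'   variable has zero rank variance, rho and p are NA with a note.
#' @export
spearmanRank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "undefined (zero rank variance)"))
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2)) * sd(ry) * sqrt(n - 1)
    rhoPerm <- as.numeric(matrix(ry[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

#' Compare fitted parameters across mouse groups
#'
#' For each parameter column: outliers are screened per group by the 1.5
#' IQR rule, box statistics are computed, all pairwise Welch tests are BH
#' adjusted (one family per parameter), and for parameters with a
#' hypothesised monotone trend a Williams-type step-down test is run
#' against the control group in the design's direction.
#'
#' @param paramTable data.frame with a \code{group} column and parameter
#'   columns (as produced by \code{\link{fitCohort}}).
#' @param design list with \code{control} (label), \code{ordered}
#'   (character vector of non-control groups, lowest dose first),
#'   \code{directions} (named character vector, e.g.
#'   \code{c(k2 = "decreasing", k3 = "increasing", k5 = "decreasing",
#'   k7 = "increasing")}), and optionally \code{alpha}, \code{nMC},
#'   \code{seed}.
#' @param parameters which columns to analyse (default k1..k8, G0, I0
#'   intersected with the table's columns).
#' @return A \code{\linkS4class{GroupComparisonReport}}.
#' @export
runGroupComparison <- function(paramTable, design,
                               parameters = NULL) {
  stopifnot("group" %in% names(paramTable))
  if (is.null(parameters))
    parameters <- intersect(.PARAM_NAMES, names(paramTable))
  design$alpha <- design$alpha %||% 0.05
  design$nMC <- design$nMC %||% 1e5
  design$seed <- design$seed %||% 1L
  design$directions <- design$directions %||% character(0)
  groupsPresent <- unique(paramTable$group)
  orderAll <- c(design$control %||% groupsPresent[1],
                design$ordered %||% setdiff(groupsPresent,
                                            design$control))
  orderAll <- orderAll[orderAll %in% groupsPresent]

  sumRows <- list(); pairRows <- list(); trendRows <- list()
  for (p in parameters) {
    kept <- list()
    for (g in orderAll) {
      vals <- paramTable[paramTable$group == g, p]
      scr <- iqrExclude(vals)
      kept[[g]] <- scr$kept
      qs <- quantile(scr$kept, c(0.25, 0.5, 0.75), type = 7,
                     names = FALSE)
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        parameter = p, group = g, n = length(scr$kept),
        n_excluded = length(scr$excluded), mean = mean(scr$kept),
        se = sd(scr$kept) / sqrt(length(scr$kept)),
        q1 = qs[1], median = qs[2], q3 = qs[3])
    }
    if (length(orderAll) >= 2) {
      pw <- welchBH(kept)
      pw <- cbind(parameter = p, pw)
      pairRows[[length(pairRows) + 1L]] <- pw
      dirP <- design$directions[p]
      if (!is.na(dirP) && length(dirP) && !is.null(design$control) &&
          length(orderAll) >= 2) {
        treated <- kept[setdiff(orderAll, design$control)]
        tr <- williamsTrend(kept[[design$control]], treated,
                            direction = unname(dirP),
                            alpha = design$alpha, nMC = design$nMC,
                            seed = deriveSeed(design$seed,
                                              paste0("trend", p)))
        tr <- cbind(parameter = p, tr,
                    n_mc = attr(tr, "nMC"),
                    mc_seed = attr(tr, "seed"))
        trendRows[[length(trendRows) + 1L]] <- tr
      }
    }
  }
  emptyPW <- data.frame(parameter = character(0), group_a = character(0),
                        group_b = character(0), t = numeric(0),
                        df = numeric(0), p_raw = numeric(0),
                        p_bh = numeric(0), stars = character(0))
  emptyTR <- data.frame(parameter = character(0), group = character(0),
                        step = integer(0), tbar = numeric(0),
                        p_mc = numeric(0), tested = logical(0),
                        rejected = logical(0), direction = character(0),
                        n_mc = numeric(0), mc_seed = integer(0))
  new("GroupComparisonReport",
      summaries = do.call(rbind, sumRows),
      pairwise = if (length(pairRows)) do.call(rbind, pairRows)
                 else emptyPW,
      trend = if (length(trendRows)) do.call(rbind, trendRows)
              else emptyTR,
      design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a group comparison report as tidy CSVs
#'
#' Writes \code{summaries.csv}, \code{pairwise.csv} (parameter, group_a,
#' group_b, t, df, p_raw, p_bh, stars) and \code{trend.csv} (parameter,
#' group, direction, tbar, p_mc, rejected, replicate count and seed).
#'
#' @param report a \code{\linkS4class{GroupComparisonReport}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
exportReportCSV <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report@summaries, file.path(dir, "summaries.csv"),
            row.names = FALSE)
  write.csv(report@pairwise, file.path(dir, "pairwise.csv"),
            row.names = FALSE)
  write.csv(report@trend, file.path(dir, "trend.csv"), row.names = FALSE)
  invisible(dir)
}
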