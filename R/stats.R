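#' Shapiro-Wilk normality gate
#'
#' Parametric group comparisons are gated on a Shapiro-Wilk test of
#' normality; the gate passes when p > 0.05.
#'
#' @param sample numeric vector, 3 <= n <= 50.
#' @return list(W, p, pass).
#' @export
normalityGate <- function(sample) {
  n <- length(sample)
  if (n < 3)
    stop("insufficient data: normality test needs n >= 3", call. = FALSE)
  if (n > 50)
    stop("normality gate is specified for n <= 50", call. = FALSE)
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p = sw$p.value, pass = sw$p.value > 0.05)
}

#' Dunnett's many-to-one comparison against a reference
#'
#' Two-sided Dunnett-adjusted comparisons of each group mean against a
#' common reference (here typically the whole-section value), using the
#' pooled error of a one-way ANOVA across all groups. Adjusted p-values are
#' computed from the equicoordinate multivariate-t distribution over the
#' correlated contrasts.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param reference numeric vector of the reference group (n >= 2).
#' @param alpha significance level for flags (default 0.05).
#' @return data.frame(group, estimate, reference, statistic, pAdjusted,
#'   significant).
#' @export
dunnettVsReference <- function(groups, reference, alpha = 0.05) {
  if (length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, numeric(1))
  if (any(ns < 2) || length(reference) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  all <- c(groups, list(.ref = reference))
  N <- sum(vapply(all, length, numeric(1)))
  k <- length(groups)
  df <- N - (k + 1)
  s2 <- sum(vapply(all, function(g)
    sum((g - mean(g))^2), numeric(1))) / df
  if (s2 <= 0 || !is.finite(s2))
    stop("degenerate input: zero pooled variance", call. = FALSE)
  nr <- length(reference)
  mr <- mean(reference)
  mi <- vapply(groups, mean, numeric(1))
  se <- sqrt(s2 * (1 / ns + 1 / nr))
  tstat <- (mi - mr) / se
  # contrast correlations: rho_ij = (1/nr) / sqrt((1/ni+1/nr)(1/nj+1/nr))
  inv <- 1 / ns + 1 / nr
  corr <- outer(seq_len(k), seq_len(k), function(i, j)
    (1 / nr) / sqrt(inv[i] * inv[j]))
  diag(corr) <- 1
  padj <- vapply(tstat, function(t)
    1 - mvtnorm::pmvt(lower = rep(-abs(t), k), upper = rep(abs(t), k),
                      df = df, corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-4))[1],
    numeric(1))
  padj <- pmin(pmax(padj, 0), 1)
  data.frame(group = names(groups), estimate = unname(mi), reference = mr,
             statistic = unname(tstat), pAdjusted = unname(padj),
             significant = unname(padj < alpha))
}

#' Unpaired two-tailed t-test (pooled variance)
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return list(t, p, df). When both groups have zero variance and equal
#'   means the convention t = 0, p = 1 applies.
#' @export
ttestUnpaired <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    stop("degenerate input: zero variance with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Robust outlier flagging
#'
#' Surrogate for regression-based outlier removal on scalar replicate sets:
#' robust z-scores from the median and MAD, converted to two-sided normal
#' p-values and thresholded by Benjamini-Hochberg FDR control at level q.
#'
#' @param sample numeric vector (n >= 4 for flagging).
#' @param q FDR level (default 0.01).
#' @return logical vector of flags; with n < 4 no flagging is attempted and
#'   a warning is raised.
#' @export
flagOutliers <- function(sample, q = 0.01) {
  n <- length(sample)
  if (n < 4) {
    warning("n < 4: outlier flagging skipped")
    return(rep(FALSE, n))
  }
  med <- stats::median(sample)
  s <- stats::mad(sample)
  if (s == 0) return(sample != med)
  z <- (sample - med) / s
  p <- 2 * stats::pnorm(-abs(z))
  stats::p.adjust(p, method = "BH") < q
}

#' Method-validation report
#'
#' Tabulates the acceptance picture of a quantitation run: calibration
#' linearity (F-test p < 0.05, R^2, LOD, LLOQ), within-run and interday
#' accuracy/precision of the QC levels, the internal-standard response RSD
#' (flagged above 6 percent), and the QC pass rate within +/-10 percent of
#' nominal (flagged below 90 percent).
#'
#' @param curves list of \linkS4class{CalibrationCurve} objects.
#' @param qcRuns data.frame(day, nominal, measured) of QC replicates.
#' @param isResponses optional numeric vector of internal-standard responses
#'   across a run.
#' @return list(linearity, withinRun, interday, qcPassRate, qcPassFlag,
#'   isRsd, isFlag).
#' @export
validationReport <- function(curves, qcRuns, isResponses = NULL) {
  if (length(curves) < 1) stop("need at least one curve", call. = FALSE)
  if (length(unique(qcRuns$nominal)) < 2)
    stop("need at least two QC levels", call. = FALSE)
  linearity <- do.call(rbind, lapply(curves, function(cv)
    data.frame(analyte = cv@analyte, slope = cv@slope,
               rSquared = cv@rSquared, fTestP = cv@fTestP, lod = cv@lod,
               lloq = cv@lloq, accepted = cv@accepted)))
  rownames(linearity) <- NULL
  withinRun <- do.call(rbind, lapply(
    split(qcRuns, list(qcRuns$day, qcRuns$nominal), drop = TRUE),
    function(d) cbind(day = d$day[1],
                      qcEvaluate(d$measured, d$nominal[1]))))
  rownames(withinRun) <- NULL
  # interday: RSD of the day means per level
  interday <- do.call(rbind, lapply(split(qcRuns, qcRuns$nominal),
    function(d) {
      dm <- tapply(d$measured, d$day, mean)
      data.frame(nominal = d$nominal[1], nDays = length(dm),
                 biasPct = 100 * (mean(dm) - d$nominal[1]) / d$nominal[1],
                 rsdPct = 100 * stats::sd(dm) / mean(dm))
    }))
  rownames(interday) <- NULL
  within10 <- abs(qcRuns$measured - qcRuns$nominal) <= 0.10 * qcRuns$nominal
  qcPassRate <- mean(within10)
  isRsd <- if (is.null(isResponses)) NA_real_
           else 100 * stats::sd(isResponses) / mean(isResponses)
  list(linearity = linearity, withinRun = withinRun, interday = interday,
       qcPassRate = qcPassRate, qcPassFlag = qcPassRate < 0.90,
       isRsd = isRsd, isFlag = !is.na(isRsd) && isRsd > 6)
}
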