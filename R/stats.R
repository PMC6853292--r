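#' @include AllClasses.R utils.R
NULL

newComparison <- function(groups, x, y, statistic, statValue, pValue,
                          alpha, details = list()) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  methods::new("GroupComparison", groups = groups,
               n = c(length(x), length(y)),
               means = c(mean(x), mean(y)), sems = c(sem(x), sem(y)),
               statistic = statistic, statValue = statValue,
               pValue = pValue, alpha = alpha, details = details)
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s)\n", object@statistic))
  for (i in 1:2)
    cat(sprintf("  %-12s n = %2d, mean = %.4g +/- %.3g (SEM)\n",
                object@groups[i], object@n[i], object@means[i],
                object@sems[i]))
  lab <- if (object@statistic == "mann_whitney_u") "U" else "t"
  cat(sprintf("  %s = %.4g, two-sided p = %.4g (%s at alpha = %g)\n", lab,
              object@statValue, object@pValue,
              if (object@pValue <= object@alpha) "significant"
              else "not significant", object@alpha))
})

#' Compare surface-to-volume ratios between two groups
#'
#' Two-tailed Student's t test with pooled variance (the classical
#' equal-variance form; set \code{welch = TRUE} for the unequal-variance
#' alternative), as used to compare penetrating and fusing nerve bundles.
#'
#' @param pen,fus Numeric vectors of per-bundle S/V values (um^-1), one per
#'   group; each needs n >= 2.
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch correction instead of pooled variance.
#' @param groups Group names for the report.
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' compareSV(c(3.1, 3.4, 3.3), c(1.2, 1.5, 1.4))
#' @export
compareSV <- function(pen, fus, alpha = 0.05, welch = FALSE,
                      groups = c("penetrating", "fusing")) {
  if (length(pen) < 2L || length(fus) < 2L)
    stop("insufficient data: each group needs n >= 2")
  tt <- tryCatch(stats::t.test(pen, fus, var.equal = !welch),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both groups constant: t is undefined; equal means give p = 1 by
    # convention, unequal constant groups separate perfectly
    if (isTRUE(all.equal(mean(pen), mean(fus)))) {
      tval <- 0; p <- 1; df <- length(pen) + length(fus) - 2L
    } else {
      tval <- sign(mean(pen) - mean(fus)) * Inf; p <- 0
      df <- length(pen) + length(fus) - 2L
    }
  } else {
    tval <- unname(tt$statistic); p <- tt$p.value
    df <- unname(tt$parameter)
  }
  newComparison(groups, pen, fus, "student_t_two_tailed", tval, p, alpha,
                details = list(df = df, welch = welch))
}

# Exact (permutation) two-sided Mann-Whitney p by full enumeration of the
# C(n1 + n2, n1) group assignments; handles ties. Two-sided p is the
# doubled smaller tail, capped at 1.
mwEnumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  Us <- colSums(matrix(rk[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  pLow <- mean(Us <= U1)
  pHigh <- mean(Us >= U1)
  list(U = U1, p = min(1, 2 * min(pLow, pHigh)))
}

#' Compare basal-lamina pore diameters between two groups
#'
#' Mann-Whitney U test (Wilcoxon rank-sum). For combined n <= 20 the exact
#' two-sided p is computed by full enumeration of all group assignments
#' (valid under ties); larger samples use the normal approximation with tie
#' and continuity correction. The reported U is that of the first group;
#' U1 + U2 = n1 * n2 always.
#'
#' @param pen,fus Numeric vectors of pore diameters (um); each n >= 2.
#' @param alpha Significance level (default 0.05).
#' @param groups Group names for the report.
#' @return A \linkS4class{GroupComparison} (details carry \code{exact}).
#' @examples
#' comparePores(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
#' @export
comparePores <- function(pen, fus, alpha = 0.05,
                         groups = c("penetrating", "fusing")) {
  if (length(pen) < 2L || length(fus) < 2L)
    stop("insufficient data: each group needs n >= 2")
  n1 <- length(pen); n2 <- length(fus)
  if (n1 + n2 <= 20L) {
    e <- mwEnumerate(pen, fus)
    U <- e$U; p <- e$p; exact <- TRUE
  } else {
    wt <- suppressWarnings(stats::wilcox.test(pen, fus, exact = FALSE,
                                              correct = TRUE))
    U <- unname(wt$statistic); p <- wt$p.value; exact <- FALSE
  }
  newComparison(groups, pen, fus, "mann_whitney_u", U, p, alpha,
                details = list(exact = exact, U1 = U, U2 = n1 * n2 - U))
}

#' Fraction of observed nerve bundles that contain fusion
#'
#' Percentage of bundles classified \code{fusing_mixed}, reported to one
#' decimal place with half-away-from-zero rounding. With the reported
#' central-cornea counts (9 fusing bundles among 21) this gives 42.9;
#' truncation of the same ratio prints 42.8.
#'
#' @param results data.frame with a \code{phenotype} column (as returned by
#'   \code{\link{bundleMorphometry}} / \code{\link{measureCohort}}), or a
#'   character vector of phenotype calls.
#' @return Percentage in [0, 100], one decimal.
#' @examples
#' fusionFrequency(rep(c("fusing_mixed", "penetrating"), c(9, 12)))  # 42.9
#' @export
fusionFrequency <- function(results) {
  phen <- if (is.data.frame(results)) results$phenotype else results
  if (!length(phen)) stop("insufficient data: no bundles")
  roundHalfAway(100 * mean(phen == "fusing_mixed"), 1L)
}

#' Volume fraction of one compartment within a whole
#'
#' @param part Volume of the compartment of interest, um^3.
#' @param wholeParts Numeric vector of all compartment volumes making up
#'   the whole (include \code{part} itself), um^3.
#' @return \code{part / sum(wholeParts)}.
#' @examples
#' volumeFraction(75.42, c(75.42, 24.64))  # ~ 0.754, about three-fourths
#' @export
volumeFraction <- function(part, wholeParts) {
  if (any(c(part, wholeParts) < 0)) stop("volumes must be non-negative")
  tot <- sum(wholeParts)
  if (tot <= 0) stop("undefined: total volume is zero")
  part / tot
}
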