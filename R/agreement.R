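# Agreement statistics: two-way random-effects absolute-agreement ICC,
# reliability banding, and the 10 % suboptimal-ROI rule.

#' Two-way random-effects absolute-agreement ICC, single measures
#'
#' ICC(2,1) (McGraw & Wong's ICC(A,1)) from the two-way ANOVA
#' decomposition of an n-subjects x k-raters matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square. Absolute agreement penalizes
#' systematic rater offsets, unlike the consistency definition. Single
#' measures (not average measures) is used: individual assessments are
#' compared, and single measures is the conservative choice. The F test is
#' \eqn{MS_R / MS_E} and the confidence interval is the standard F-based
#' interval for ICC(A,1) with Satterthwaite degrees of freedom.
#'
#' @param ratings numeric n x k matrix, n >= 2 subjects (rows), k >= 2
#'   raters (columns), no missing cells (complete cases only: filter
#'   before calling).
#' @param confLevel confidence level for the interval (default 0.95).
#' @return an [IccResult-class].
#' @examples
#' m <- cbind(a = c(9, 6, 8, 7, 10, 6), b = c(2, 1, 4, 1, 5, 2))
#' iccAbsoluteAgreement(m)
#' @export
iccAbsoluteAgreement <- function(ratings, confLevel = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stopf("ratings matrix has missing cells: restrict to complete cases first")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stopf("need at least 2 subjects and 2 raters")

  grand <- mean(ratings)
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  SSR <- k * sum((rowM - grand)^2)            # subjects
  SSC <- n * sum((colM - grand)^2)            # raters
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST <= 0) stopf("degenerate ratings: zero total variance")
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  Fstat <- MSR / MSE
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)

  # F-based CI (McGraw & Wong 1996) with Satterthwaite df for the
  # denominator of the subject F ratio under absolute agreement
  alpha <- 1 - confLevel
  if (icc < 1 && MSE > 0) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    Fu <- qf(1 - alpha / 2, n - 1, v)
    Fl <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - Fu * MSE) /
      (Fu * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (Fl * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fl * MSR)
  } else {
    lo <- hi <- icc
  }

  new("IccResult", icc = icc,
      model = "two-way random effects, absolute agreement, single measures (ICC(2,1))",
      fstat = Fstat, df1 = df1, df2 = df2, pValue = p,
      ciLow = min(lo, icc), ciHigh = max(hi, icc),
      nSubjects = as.integer(n), nRaters = as.integer(k),
      confLevel = confLevel)
}

#' Reliability band of an ICC value
#'
#' The conventional interpretation bands: below 0.5 poor, 0.5 to 0.75
#' moderate, 0.75 to 0.9 good, 0.9 and above excellent. Intervals are
#' half-open upward, so each boundary belongs to the stronger band
#' (0.75 is "good", 0.90 is "excellent").
#'
#' @param icc finite ICC value(s).
#' @return character band label(s): "poor", "moderate", "good",
#'   "excellent".
#' @examples
#' classifyReliability(c(0.4, 0.6, 0.85, 0.95))
#' @export
classifyReliability <- function(icc) {
  if (any(!is.finite(icc))) stopf("ICC must be finite")
  as.character(cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
                   labels = c("poor", "moderate", "good", "excellent"),
                   right = FALSE))
}

#' Flag suboptimal ROI placements
#'
#' An algorithm ROI placement counts as suboptimal when its measured
#' perfusion deviates from the manual reference by strictly more than
#' 10 %: \eqn{|P_{alg} - P_{ref}| / P_{ref} > 0.10}. Pairs whose reference
#' is non-positive are excluded with a warning (the relative deviation is
#' undefined there).
#'
#' @param algorithmValues,referenceValues equal-length paired PU vectors.
#' @param threshold relative deviation threshold (default 0.10, strict).
#' @return list with \code{flags} (logical, NA for excluded pairs),
#'   \code{rate} (flagged fraction among evaluable pairs), \code{nFlagged}
#'   and \code{nEvaluable}.
#' @export
flagSuboptimal <- function(algorithmValues, referenceValues, threshold = 0.10) {
  if (length(algorithmValues) != length(referenceValues))
    stopf("paired value lists must have equal length")
  bad <- !is.na(referenceValues) & referenceValues <= 0
  if (any(bad))
    warnf("%d pair(s) with non-positive reference perfusion excluded", sum(bad))
  rel <- abs(algorithmValues - referenceValues) / referenceValues
  flags <- rel > threshold
  flags[bad] <- NA
  evaluable <- sum(!is.na(flags))
  list(flags = flags,
       rate = if (evaluable) sum(flags, na.rm = TRUE) / evaluable else NA_real_,
       nFlagged = sum(flags, na.rm = TRUE),
       nEvaluable = evaluable)
}
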