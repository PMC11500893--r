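# Robustness analytics: relative difference, inter-setting CV, ICC,
# Wilcoxon rank-sum and Benjamini-Hochberg adjustment.

#' Relative difference against the reference setting
#'
#' `(x - xRef) / xRef * 100`, in percent. Vectorised over `x`.
#'
#' @param x index value(s) at a non-reference setting.
#' @param xRef index value at the reference setting.
#' @return percent difference; `NA` with a warning when `xRef` is 0.
#' @examples
#' relativeDifference(12, 10)   # 20
#' relativeDifference(7.5, 10)  # -25
#' @export
relativeDifference <- function(x, xRef) {
  if (length(xRef) != 1L) stopf("'xRef' must be a single reference value")
  if (!is.finite(xRef) || xRef == 0) {
    warnf("relative difference undefined for a zero reference; returning NA")
    return(rep(NA_real_, length(x)))
  }
  (x - xRef) / xRef * 100
}

#' Inter-setting coefficient of variation
#'
#' Sample standard deviation over mean, in percent, of one radiomic index
#' across the imaging settings. Categories: low (< 10%), moderate
#' (10-25%), high (> 25%); for indices that can be negative the category is
#' judged on the magnitude.
#'
#' @param values numeric vector of one index across settings (>= 2 values).
#' @return list with `cv` (percent) and `category`.
#' @examples
#' interSettingCV(c(1, 1, 1, 1, 1, 1, 1, 3))  # 56.57%, high
#' @export
interSettingCV <- function(values) {
  if (length(values) < 2L) stopf("CV needs at least two values")
  if (anyNA(values)) {
    warnf("missing values in CV input; returning NA")
    return(list(cv = NA_real_, category = NA_character_))
  }
  m <- mean(values)
  if (m == 0) {
    warnf("zero mean: CV undefined; returning NA")
    return(list(cv = NA_real_, category = NA_character_))
  }
  cv <- stats::sd(values) / m * 100
  list(cv = cv, category = cvCategory(cv))
}

#' @rdname interSettingCV
#' @param cv CV value(s) in percent.
#' @export
cvCategory <- function(cv) {
  out <- ifelse(abs(cv) < 10, "low",
                ifelse(abs(cv) <= 25, "moderate", "high"))
  out[is.na(cv)] <- NA_character_
  out
}

#' Intraclass correlation coefficient (two-way mixed, absolute agreement)
#'
#' Computes `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from
#' the two-way ANOVA mean squares of a lesions x settings matrix: `MSR`
#' rows (lesions, the targets), `MSC` columns (settings, the raters), `MSE`
#' the residual; `n` lesions, `k` settings. Negative estimates are reported
#' as-is. Categories: excellent (> 0.9), good (0.75, 0.9], moderate
#' (0.5, 0.75], poor (<= 0.5).
#'
#' @param m numeric matrix, rows = lesions (n >= 2), columns = settings
#'   (k >= 2).
#' @return list with `icc`, `category` and the mean squares.
#' @examples
#' m <- rbind(c(1, 1.1), c(2, 2.1), c(3, 3.2))
#' iccAbsoluteAgreement(m)$icc
#' @export
iccAbsoluteAgreement <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stopf("ICC needs at least 2 lesions (rows) and 2 settings (columns)")
  if (anyNA(m)) {
    warnf("missing cells: ICC undefined; returning NA")
    return(list(icc = NA_real_, category = NA_character_,
                msr = NA_real_, msc = NA_real_, mse = NA_real_))
  }
  g <- mean(m)
  rMeans <- rowMeans(m)
  cMeans <- colMeans(m)
  ssr <- k * sum((rMeans - g)^2)
  ssc <- n * sum((cMeans - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(den) < .Machine$double.eps * max(1, abs(msr))) {
    warnf("degenerate matrix (no variance): ICC undefined; returning NA")
    return(list(icc = NA_real_, category = NA_character_,
                msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / den
  list(icc = icc, category = iccCategory(icc), msr = msr, msc = msc,
       mse = mse)
}

#' @rdname iccAbsoluteAgreement
#' @param icc ICC value(s).
#' @export
iccCategory <- function(icc) {
  out <- ifelse(icc > 0.9, "excellent",
                ifelse(icc > 0.75, "good",
                       ifelse(icc > 0.5, "moderate", "poor")))
  out[is.na(icc)] <- NA_character_
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact two-sided p-value by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the (mid-)ranks when both
#' samples have at most `exactLimit` observations (ties handled by
#' mid-ranks; p = doubled smaller tail, capped at 1); the normal
#' approximation with tie correction is used beyond.
#'
#' @param a,b numeric samples.
#' @param exactLimit maximum per-group size for the exact enumeration.
#' @return two-sided p-value.
#' @examples
#' wilcoxonRankSum(1:3, 4:6)  # exact 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 10L) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  if (max(n1, n2) <= exactLimit) {
    combos <- utils::combn(n1 + n2, n1)
    wAll <- colSums(matrix(r[combos], nrow = n1))
    tol <- sqrt(.Machine$double.eps)
    pLo <- mean(wAll <= w + tol)
    pHi <- mean(wAll >= w - tol)
    return(min(1, 2 * min(pLo, pHi)))
  }
  # normal approximation with tie correction
  nt <- n1 + n2
  ties <- table(r)
  mu <- n1 * (nt + 1) / 2
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) return(1)
  z <- (w - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values (monotone, capped at 1).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
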