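#' Exclude subject pairs with mismatched cardiac rhythms
#'
#' When two acquisitions of the same subject are compared, a heart-rate
#' (BPM = 60/Tc) difference above the threshold indicates the two records do
#' not sample the same rhythm and the pair is excluded.
#'
#' @param tcA,tcB numeric, per-subject cardiac periods (s) from methods A
#'   and B.
#' @param threshold relative BPM difference (percent of the pair mean) above
#'   which a subject is excluded; default 10.
#' @return list with integer vectors `kept` and `excluded` (subject indices).
#' @examples
#' bpmMismatchFilter(c(0.80, 0.80), c(0.80, 0.90))
#' @export
bpmMismatchFilter <- function(tcA, tcB, threshold = 10) {
  stopifnot(length(tcA) == length(tcB), all(tcA > 0), all(tcB > 0))
  bpmA <- 60 / tcA; bpmB <- 60 / tcB
  rel <- 100 * abs(bpmA - bpmB) / ((bpmA + bpmB) / 2)
  list(kept = which(rel <= threshold), excluded = which(rel > threshold))
}

#' Bland-Altman agreement on percentage differences
#'
#' Per-pair percentage difference `d_i = 100 (a_i - b_i) / mean(a_i, b_i)`;
#' the bias is `mean(d)` and the limits of agreement are
#' `mean(d) +/- 1.96 sd(d)`. Pairs with zero mean are dropped with a
#' warning.
#'
#' @param a,b paired numeric measurements (same parameter, two methods).
#' @return list with `meanDiff`, `loaLow`, `loaHigh` (percent), `d` (the
#'   per-pair percentage differences) and `n`.
#' @examples
#' blandAltmanPercent(c(10, 21, 29), c(11, 20, 31))
#' @export
blandAltmanPercent <- function(a, b) {
  stopifnot(length(a) == length(b))
  pm <- (a + b) / 2
  drop <- pm == 0
  if (any(drop)) {
    warning(sum(drop), " pair(s) with zero mean dropped")
    a <- a[!drop]; b <- b[!drop]; pm <- pm[!drop]
  }
  if (length(a) < 2L) stop("need at least 2 usable pairs")
  d <- 100 * (a - b) / pm
  m <- mean(d); s <- stats::sd(d)
  list(meanDiff = m, loaLow = m - 1.96 * s, loaHigh = m + 1.96 * s,
       d = d, n = length(d))
}

#' Correlation between paired parameter sets
#'
#' Pearson's correlation when both samples pass a Shapiro-Wilk normality
#' check (alpha = 0.05), Spearman's rank correlation otherwise.
#'
#' @param a,b paired numeric vectors, n >= 3.
#' @param alpha significance level of the normality gate.
#' @return list with `r`, `p` (two-sided) and `method` ("pearson" or
#'   "spearman").
#' @export
pairedCorrelation <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input")
  normal <- stats::shapiro.test(a)$p.value > alpha &&
    stats::shapiro.test(b)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(a, b, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}
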