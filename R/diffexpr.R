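# Two-library differential expression: floored reads-per-million
# normalization, log2 fold change (LL over HH), the Audic-Claverie exact
# test for unreplicated count comparisons, BH FDR and significance labels.

#' Normalized expression (reads per million, floored)
#'
#' \code{count / total * 1e6}, with results below \code{floor} (in
#' particular zero counts) replaced by the floor so log fold changes stay
#' defined.  The floor convention (0.01) matches the printed normalized
#' value reported for miRNAs absent from one library.
#'
#' @param count read count(s) of the miRNA.
#' @param total library total (candidate-miRNA reads), > 0.
#' @param floor minimum reported value (same units).
#' @return Normalized expression, vectorized over \code{count}.
#' @examples
#' normalizeStd(7, 7e6)          # 1
#' normalizeStd(0, 9059038)      # 0.01 (the floor)
#' @export
normalizeStd <- function(count, total, floor = 0.01) {
  if (any(total <= 0)) stop("library total must be > 0")
  if (any(count < 0)) stop("counts must be non-negative")
  std <- count / total * 1e6
  pmax(std, floor)
}

#' Log2 fold change, LL over HH
#'
#' @param stdHH,stdLL normalized expression in each library; both must be
#'   positive (use \code{\link{normalizeStd}}'s floor for zero counts).
#' @return \code{log2(stdLL / stdHH)}; antisymmetric under argument swap.
#' @examples
#' foldChange(0.0100, 14.8710)   # 10.5383
#' foldChange(32.3809, 1.4248)   # -4.5063
#' @export
foldChange <- function(stdHH, stdLL) {
  if (any(stdHH <= 0) || any(stdLL <= 0))
    stop("normalized expressions must be positive")
  log2(stdLL / stdHH)
}

#' Audic-Claverie exact p-value for two-library counts
#'
#' Given \code{x} reads in a library of \code{n1} total reads and \code{y}
#' in a library of \code{n2}, the posterior probability of observing
#' \code{y} given \code{x} is
#' \deqn{P(y|x) = (n2/n1)^y \frac{(x+y)!}{x!\,y!\,(1+n2/n1)^{x+y+1}}}
#' i.e. \code{y | x} is negative-binomial with size \code{x+1} and success
#' probability \code{n1/(n1+n2)}.  The two-sided p-value sums the smaller
#' tail (including \code{y}) and doubles it, capped at 1.
#'
#' @param x,y read counts in the two libraries (vectorized).
#' @param n1,n2 library totals.
#' @return Two-sided p-values in [0, 1].
#' @examples
#' exactCountPvalue(0, 0, 1e6, 1e6)     # 1
#' exactCountPvalue(0, 200, 1e6, 1e6)   # << 1e-20
#' @export
exactCountPvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  prob <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR with monotonicity enforcement, returned in input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return FDR-adjusted values.
#' @export
bhFdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance label from fold change and p-value
#'
#' \code{"**"} iff |log2FC| > 1 and p < 0.01; \code{"*"} iff |log2FC| > 1
#' and 0.01 <= p < 0.05; \code{""} otherwise.
#'
#' @param log2fc log2 fold change(s).
#' @param p p-value(s).
#' @return Character vector of labels.
#' @examples
#' labelSignificance(3.05183, 1.22e-27)   # "**"
#' labelSignificance(2.0, 0.03)           # "*"
#' labelSignificance(0.5, 1e-10)          # ""
#' @export
labelSignificance <- function(log2fc, p) {
  stopifnot(all(is.finite(log2fc)), all(is.finite(p)))
  out <- rep("", length(log2fc))
  big <- abs(log2fc) > 1
  out[big & p < 0.01] <- "**"
  out[big & p >= 0.01 & p < 0.05] <- "*"
  out
}

#' Differential expression table for two libraries
#'
#' Computes, per miRNA, the floored normalized expression in each library,
#' the log2 fold change (LL over HH, on the floored values), the
#' Audic-Claverie exact p-value, the BH FDR and the significance label.
#'
#' @param counts data.frame with columns \code{name}, \code{countHH},
#'   \code{countLL} (raw read counts).
#' @param nHH,nLL library totals (candidate-miRNA reads per library).
#' @param floor normalization floor.
#' @return A data.frame with columns name, stdHH, stdLL, log2FC, pvalue,
#'   fdr, label.
#' @export
diffExpression <- function(counts, nHH, nLL, floor = 0.01) {
  stopifnot(all(c("name", "countHH", "countLL") %in% names(counts)))
  stdHH <- normalizeStd(counts$countHH, nHH, floor)
  stdLL <- normalizeStd(counts$countLL, nLL, floor)
  lfc <- foldChange(stdHH, stdLL)
  p <- exactCountPvalue(counts$countHH, counts$countLL, nHH, nLL)
  data.frame(name = counts$name, stdHH = stdHH, stdLL = stdLL,
             log2FC = lfc, pvalue = p, fdr = bhFdr(p),
             label = labelSignificance(lfc, p),
             stringsAsFactors = FALSE)
}
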