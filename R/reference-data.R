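#' Bundled reference rows: top differentially expressed miRNAs in pMECs
#'
#' The ten miRNAs with the largest expression fold changes between primary
#' mammary epithelial cell libraries from a high- (HH) and a low- (LL)
#' milk-fat cow, as published for that two-library comparison: normalized
#' expression per library (reads per million, floored at 0.01), the printed
#' log2 fold change (LL over HH), the printed p-value and FDR, and the
#' significance label.  Used by examples and by the acceptance checks to
#' verify that the package's normalization, fold-change and labelling
#' arithmetic reproduces the published columns.
#'
#' @return A data.frame with columns name, stdHH, stdLL, foldChange,
#'   pvalue, fdr, label.
#' @examples
#' tab <- pmecTopTable()
#' all.equal(foldChange(tab$stdHH, tab$stdLL), tab$foldChange,
#'           tolerance = 1e-4)
#' @export
pmecTopTable <- function() {
  data.frame(
    name = c("bta-miR-124a", "bta-miR-224", "bta-miR-452", "bta-miR-877",
             "bta-miR-2344", "bta-miR-29b", "bta-miR-152", "bta-miR-30b-5p",
             "bta-miR-193a-3p", "bta-miR-33a"),
    stdHH = c(0.0100, 1.9114, 11.4682, 39.8015, 40.4761,
              588.2531, 1231.1490, 20.9127, 265.4560, 32.3809),
    stdLL = c(14.8710, 15.8505, 70.0808, 175.7807, 169.7254,
              97.5966, 189.5831, 1.8700, 20.2139, 1.4248),
    foldChange = c(10.5383, 3.05183, 2.6114, 2.1429, 2.0681,
                   -2.5915, -2.6991, -3.4833, -3.7151, -4.5063),
    pvalue = c(5.50e-43, 1.22e-27, 6.56e-100, 8.77e-197, 8.17e-182,
               0, 0, 1.68e-43, 0, 1.09e-80),
    fdr = c(0.0813, 0.2259, 0.3946, 0.2389, 0.8923,
            0.9213, 0.4573, 0.1364, 0.8523, 0.4039),
    label = rep("**", 10),
    stringsAsFactors = FALSE)
}
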