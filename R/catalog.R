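#' Reference catalog of validated sex-associated lung genes
#'
#' The 25 genes whose lung-tissue expression differs between males and
#' females in the discovery cohort and replicates with concordant direction
#' in all three validation cohorts. Fold changes follow the signed
#' convention: values > 1 mean higher expression in males, negative values
#' -r mean r-fold higher expression in females. RPS4Y1 is Y-linked, so its
#' fold change is measured against the background probe intensity in
#' females, who do not carry the gene; XIST drives X inactivation and is
#' strongly female-biased. Chromosome "X;Y" marks the pseudoautosomal
#' regions.
#'
#' @return A data.frame with columns `gene`, `entrez_id`, `chromosome`,
#'   `fold_change`, `fdr`.
#' @seealso [age_gene_catalog()], [default_truth_from_tables()]
#' @export
#' @examples
#' cat25 <- sex_gene_catalog()
#' table(cat25$chromosome)
sex_gene_catalog <- function() {
  df <- data.frame(
    gene = c("AOX1", "ARSD", "ATP6V1B1", "CD99", "CILP", "DDX3X", "EIF1AX",
             "EIF2S3", "GEMIN8", "HDHD1", "KAL1", "KDM6A", "OFD1",
             "OLFML2A", "PHGDH", "PRKX", "RPS4X", "RPS4Y1", "TRAPPC2",
             "TXLNG", "USP9X", "XIST", "ZBED1", "ZFX", "ZRSR2"),
    entrez_id = c(316L, 414L, 525L, 4267L, 8483L, 1654L, 1964L, 1968L,
                  54960L, 8226L, 3730L, 7403L, 8481L, 169611L, 26227L,
                  5613L, 6191L, 6192L, 6399L, 55787L, 8239L, 7503L, 9189L,
                  7543L, 8233L),
    chromosome = c("2", "X", "2", "X;Y", "15", "X", "X", "X", "X", "X",
                   "X", "X", "X", "9", "1", "X", "X", "Y", "X", "X", "X",
                   "X", "X;Y", "X", "X"),
    fold_change = c(1.397, -1.543, -1.352, 1.342, 1.397, -1.215, -1.336,
                    -1.231, -1.134, -1.586, -1.982, -1.514, -1.179,
                    -1.287, -1.170, -1.131, -1.369, 48.948, -1.171,
                    -1.184, -1.084, -12.561, 1.108, -1.382, -1.362),
    fdr = c(2.81e-04, 5.78e-50, 3.30e-04, 5.85e-22, 1.24e-02, 2.29e-04,
            1.34e-16, 1.39e-16, 1.20e-04, 1.75e-50, 1.75e-30, 4.96e-39,
            5.06e-04, 6.86e-03, 3.64e-02, 2.38e-03, 1.83e-09, 1.76e-249,
            1.72e-07, 7.33e-07, 2.15e-02, 1.14e-171, 3.91e-05, 3.14e-21,
            2.54e-16),
    stringsAsFactors = FALSE
  )
  df
}

#' Reference catalog of validated age-associated lung genes
#'
#' The 22 genes whose lung-tissue expression changes with age at surgery in
#' the discovery cohort and replicates with concordant direction in all
#' three validation cohorts. The estimate is the per-year slope of log2
#' expression; positive values mean higher expression in older individuals.
#' All 22 genes are autosomal.
#'
#' @return A data.frame with columns `gene`, `entrez_id`, `chromosome`,
#'   `estimate`, `fdr`.
#' @seealso [sex_gene_catalog()], [default_truth_from_tables()]
#' @export
age_gene_catalog <- function() {
  df <- data.frame(
    gene = c("AGR2", "CRYAB", "CXCL17", "CXCL9", "DIRAS3", "FANCE", "FMO3",
             "GSTA4", "ITGB5", "ITGBL1", "LCN2", "MGP", "PGM5", "PLCD3",
             "PTCHD4", "RCAN2", "RERGL", "SCARF2", "TC2N", "WISP2",
             "ZMAT3", "ZNF518B"),
    entrez_id = c(10551L, 1410L, 284340L, 4283L, 9077L, 2178L, 2328L,
                  2941L, 3693L, 9358L, 3934L, 4256L, 5239L, 113026L,
                  442213L, 10231L, 79785L, 91179L, 123036L, 8839L,
                  64393L, 85460L),
    chromosome = c("7", "11", "19", "4", "1", "6", "1", "6", "3", "13",
                   "9", "12", "9", "17", "6", "6", "12", "22", "14", "20",
                   "3", "4"),
    estimate = c(-0.01213, 0.013824, -0.00911, 0.028698, 0.008936,
                 -0.01075, 0.0131, -0.01173, 0.007076, 0.018297,
                 -0.02576, 0.00841, 0.009683, 0.005974, 0.003035,
                 0.015413, 0.022899, 0.009692, -0.00923, 0.026326,
                 0.016636, -0.00626),
    fdr = c(2.95e-02, 1.60e-03, 4.85e-02, 3.35e-02, 3.00e-03, 1.10e-03,
            1.44e-02, 4.80e-03, 4.19e-02, 1.21e-05, 3.78e-02, 4.97e-02,
            4.80e-02, 1.42e-02, 4.85e-02, 1.56e-04, 6.70e-03, 1.96e-02,
            3.78e-02, 9.02e-05, 1.84e-04, 4.07e-02),
    stringsAsFactors = FALSE
  )
  df
}
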