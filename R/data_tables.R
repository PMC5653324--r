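## Published reference tables shipped as plain code: the genome features of
## the 21 L. salivarius isolates (6 collected before the AGP ban, SBP; 15
## after, SAP) and the group-level crystal-violet biofilm dye measurements.
## These printed values are pipeline inputs for the statistics and
## quantification stages.

#' Genome features of the 21 L. salivarius isolates
#'
#' Draft-genome features of 6 pre-ban (SBP) and 15 post-ban (SAP) swine
#' intestinal isolates: genome size (Mbp), number of CDSs and GC%.
#'
#' @return data.frame with columns `strain`, `group`, `farm`,
#'   `genome_size`, `n_cds`, `gc_percent`.
#' @export
lsalivarius_features <- function() {
  data.frame(
    strain = c("KLA001", "KLA005", "KLA002", "KLA003", "KLA004", "KLA006",
               "KLF002", "KLF003", "KLF004", "KLF005", "KLF007", "KLW005",
               "KLW001", "KLW006", "KLW007", "KLW003", "KLW008", "KLW009",
               "KLW010", "KLW004", "KLW002"),
    group = c(rep("SBP", 6), rep("SAP", 15)),
    farm = c("A", "A", "B", "C", "D", "E",
             "G", "G", "G", "F", "F", "H", "H", "F", "F", "H", "F", "F",
             "F", "H", "H"),
    genome_size = c(2.27, 2.26, 2.26, 2.27, 2.26, 2.37,
                    2.18, 2.21, 2.12, 2.15, 2.22, 2.33, 2.09, 2.37, 2.39,
                    2.08, 2.03, 1.97, 2.14, 2.07, 2.39),
    n_cds = c(2171, 2177, 2175, 2169, 2180, 2265,
              2098, 2128, 2036, 2020, 2138, 1971, 2194, 1892, 1819, 2233,
              2011, 1961, 2148, 2185, 1982),
    gc_percent = c(32.83, 32.82, 32.82, 32.83, 32.83, 32.93,
                   32.81, 32.73, 32.71, 32.69, 32.9, 32.82, 33.04, 32.7,
                   32.75, 32.92, 32.88, 32.86, 32.67, 32.82, 32.82),
    stringsAsFactors = FALSE)
}

#' Group-level crystal-violet biofilm dye measurements
#'
#' Reported surface-bound dye masses (mean ± SD, μg) of the SBP and SAP
#' groups after 48 h and 72 h of static cultivation.
#'
#' @return data.frame with columns `group`, `timepoint_h`, `mean_ug`,
#'   `sd_ug`.
#' @export
biofilm_dye_reference <- function() {
  data.frame(
    group = c("SBP", "SBP", "SAP", "SAP"),
    timepoint_h = c(48, 72, 48, 72),
    mean_ug = c(3.79, 2.05, 40.25, 62.38),
    sd_ug = c(1.62, 0.57, 4.64, 4.72),
    stringsAsFactors = FALSE)
}
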