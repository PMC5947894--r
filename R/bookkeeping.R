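#' Inventory of the public GEO series behind the seven-state skin compendium
#'
#' The 24 NCBI GEO series from which the skin-state compendium this package
#' models was assembled, with each series' technology, sample origin, skin
#' states, number of high-quality samples retained and number of excluded
#' QC outliers. Useful as a realistic template for synthetic study
#' configurations and for sample bookkeeping.
#'
#' @return Data frame with columns `series`, `technology`, `origin`,
#'   `skin_states` (comma-separated, most frequent first),
#'   `high_quality_samples`, `excluded_outliers`.
#' @export
skin_series_inventory <- function() {
  tab <- data.frame(
    series = c("GSE2503", "GSE3189", "GSE6710", "GSE7553", "GSE13355",
               "GSE14905", "GSE15605", "GSE29359", "GSE30999", "GSE32407",
               "GSE32628", "GSE32924", "GSE36150", "GSE39612", "GSE42109",
               "GSE42677", "GSE45216", "GSE46517", "GSE52471", "GSE53223",
               "GSE53462", "GSE55664", "GSE66359", "GSE82105"),
    technology = c("Affymetrix", "Affymetrix", "Affymetrix", "Affymetrix",
                   "Affymetrix", "Affymetrix", "Affymetrix", "Illumina",
                   "Affymetrix", "Affymetrix", "Illumina", "Affymetrix",
                   "Affymetrix", "Affymetrix", "Affymetrix", "Affymetrix",
                   "Affymetrix", "Affymetrix", "Affymetrix", "Affymetrix",
                   "Illumina", "Illumina", "Affymetrix", "Affymetrix"),
    origin = c("Berlin (Deutschland)", "San Diego (USA)",
               "Berlin (Deutschland)", "Tampa (USA)", "Ann Arbor (USA)",
               "Gaithersburg (USA)", "Nashville (USA)",
               "New Lambton Heights (Australia)", "Spring House (USA)",
               "New York (USA)", "Leiden (Netherlands)", "New York (USA)",
               "Royal Oak (USA)", "Ann Arbor (USA)", "New York (USA)",
               "New York (USA)", "London (United Kingdom)", "Houston (USA)",
               "New York (USA)", "New York (USA)", "Suwon (South Korea)",
               "Philadelphia (USA)", "Turku (Finland)", "New York (USA)"),
    skin_states = c("SCC,NSK", "PRIMEL,NEV,NSK", "NSK", "BCC,PRIMEL,SCC,NSK",
                    "NSK", "NSK", "PRIMEL,NSK,METMEL", "METMEL", "NSK",
                    "NSK", "SCC", "NSK", "MCC", "MCC,SCC,BCC", "BCC", "SCC",
                    "SCC", "METMEL,PRIMEL,NSK,NEV", "NSK", "NEV,NSK",
                    "BCC,SCC,NSK", "NSK", "SCC", "METMEL,NSK"),
    high_quality_samples = c(10L, 66L, 12L, 44L, 57L, 20L, 46L, 75L, 74L,
                             10L, 14L, 7L, 10L, 28L, 10L, 10L, 28L, 78L,
                             10L, 14L, 25L, 10L, 8L, 12L),
    excluded_outliers = c(1L, 4L, 1L, 2L, 7L, 1L, 18L, 7L, 11L, 0L, 1L, 1L,
                          5L, 12L, 1L, 0L, 2L, 10L, 3L, 4L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  tab
}

#' Per-state sample counts of the skin compendium
#'
#' The number of retained high-quality samples per skin state in the
#' compendium inventoried by [skin_series_inventory()].
#'
#' @return Named integer vector over the 7 states.
#' @export
skin_state_counts <- function() {
  c(BCC = 43L, SCC = 84L, MCC = 33L, PRIMEL = 118L, METMEL = 118L,
    NSK = 250L, NEV = 32L)
}

#' Sample bookkeeping across quality control
#'
#' Tallies initial, excluded and retained sample counts, either from an
#' inventory table (columns `high_quality_samples`, `excluded_outliers`)
#' or from a list of QC reports plus their input bundles.
#'
#' @param inventory Data frame like [skin_series_inventory()].
#' @return Named integer vector `initial`, `excluded`, `retained`.
#' @export
sample_bookkeeping <- function(inventory = skin_series_inventory()) {
  retained <- sum(inventory$high_quality_samples)
  excluded <- sum(inventory$excluded_outliers)
  c(initial = retained + excluded, excluded = excluded, retained = retained)
}
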