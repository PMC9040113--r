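# The shipped study-population denominator fixture: the classic "Table 1"
# of an observational cohort — denominators and cause-specific death counts
# by cancer site and age group — for the motivating English survivor cohort
# of nine common cancers, together with the study-level totals it must
# reproduce.

#' Study-population denominator fixture
#'
#' Returns the transcribed study-population table of the motivating
#' survivor cohort: for each of 27 cancer-site by age-at-diagnosis cells,
#' the number of individuals, females, median (IQR) follow-up from cohort
#' entry, and deaths from cardiovascular disease, the primary cancer and
#' all cancers. Alongside, the published study-level totals: 104,028
#' individuals, 52,713 (50.7%) women, 7,091 cardiovascular deaths, 19,758
#' primary-cancer deaths and 25,666 all-cancer deaths. Summing the 27 rows
#' reproduces these totals exactly — a transcription-consistency surface
#' for [validate_margins()], and the source of the `"multisite"`
#' simulator preset's stratum sizes and female fractions.
#'
#' @return list with `margins` (27-row data frame: `site`, `age_group`,
#'   `individuals`, `female`, `female_pct`, `fu_median`, `fu_q1`, `fu_q3`,
#'   `cvd_deaths`, `primary_cancer_deaths`, `all_cancer_deaths`) and
#'   `totals` (named list of the printed study-level totals, plus
#'   `female_pct`).
#' @examples
#' fx <- fixture_table1()
#' sum(fx$margins$individuals) == fx$totals$individuals
#' @export
fixture_table1 <- function() {
  path <- system.file("extdata", "table1_margins.csv", package = "mortcross",
                      mustWork = TRUE)
  margins <- utils::read.csv(path, stringsAsFactors = FALSE)
  totals <- list(
    individuals = 104028,
    female = 52713,
    female_pct = 50.7,
    cvd_deaths = 7091,
    primary_cancer_deaths = 19758,
    all_cancer_deaths = 25666
  )
  list(margins = margins, totals = totals)
}
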