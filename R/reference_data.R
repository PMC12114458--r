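# Bundled reference results from a published five-disinfectant,
# 14-strain ESKAPEE suspension-test panel, used as comparator inputs for
# the agreement statistics and as worked-example data.

#' Suspension-test bactericidal concentrations for the bundled panel
#'
#' Median bactericidal concentrations (% v/v) achieving a >= 5-log10
#' reduction in viable counts, from quantitative suspension tests of five
#' commercial disinfectants (alcohol-, glutaraldehyde-, peroxide- and
#' chlorine-based) against 14 ESKAPEE-group strains (4 reference, 10
#' clinical).
#'
#' @return data frame with a `strain` column and one concentration column
#'   per disinfectant.
#' @export
suspension_mbc_panel <- function() {
  utils::read.csv(system.file("extdata", "suspension_mbc_panel.csv",
                              package = "cytocide"))
}

#' Cytometry-vs-suspension-test agreement counts for the bundled panel
#'
#' Per-disinfectant concordance of label-free cytometric MBC calls with the
#' standard suspension test over the 14-strain panel: exact categorical
#' agreement, and essential agreement within one and two doubling
#' dilutions.
#'
#' @return data frame with columns `disinfectant`, `n_strains`,
#'   `exact_agree`, `within_1_dilution`, `within_2_dilution`.
#' @export
fcm_agreement_counts <- function() {
  utils::read.csv(system.file("extdata", "fcm_agreement_counts.csv",
                              package = "cytocide"))
}
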