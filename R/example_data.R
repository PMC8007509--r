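#' Example dog-liver quantification results
#'
#' Regional DESI-MRM concentrations (ug/g tissue) of a drug candidate
#' (`cmpdA`) and its parent compound (`cmpdB`; `cmpdA` is also its
#' demethylated in-vivo metabolite) in three regions — bile-duct lesion,
#' connective tissue/blood vessel, liver parenchyma — of four dosed dog
#' livers, quantified against a mimetic-array calibration. Flags follow the
#' reporting conventions of such tables: `">ULOQ"` for regions above the
#' upper limit of quantification, `"ND"` for a compound not detected (the
#' undosed channel), and `n` gives the number of replicate ROIs behind each
#' mean and SD.
#'
#' Used by the worked examples to exercise [fold_differences()] and
#' [lcms_concordance()] on realistic printed-table input.
#'
#' @return data frame with columns `sample_id`, `dose_mg_kg`,
#'   `dosed_compound`, `compound`, `region`, `conc`, `sd`, `n`, `flag`.
#' @export
example_liver_quantification <- function() {
  read.csv(system.file("extdata", "liver_roi_concentrations.csv",
                       package = "qmsi"),
           stringsAsFactors = FALSE)
}

#' Example bulk LC-MS concentration ranges
#'
#' Whole-liver LC-MS concentration ranges (ug/g) matching the samples of
#' [example_liver_quantification()]; the sample whose MSI parenchyma value
#' exceeded the ULOQ is flagged and carries no range.
#'
#' @return data frame with columns `sample_id`, `low`, `high`, `flag`.
#' @export
example_lcms_ranges <- function() {
  read.csv(system.file("extdata", "liver_lcms_ranges.csv",
                       package = "qmsi"),
           stringsAsFactors = FALSE)
}
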