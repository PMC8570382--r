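#' Per-participant results from the original laboratory validation of the
#' method
#'
#' Overall accuracy and unweighted Cohen's kappa for each of the 15 infants
#' in the laboratory validation study of this classification method, under
#' both modelling regimes: individual models (within-infant chronological
#' 60/40 split) and group models (leave-one-subject-out). These published
#' summary values support reanalysis -- mean kappas, Landis-Koch bin counts
#' and the paired individual-vs-group comparison -- without access to the
#' raw recordings.
#'
#' @return data.frame with columns `participant`, `accuracy_individual`,
#'   `kappa_individual`, `accuracy_group`, `kappa_group`.
#' @examples
#' round(mean(labValidationResults()$kappa_individual), 2)
#' @export
labValidationResults <- function() {
  utils::read.csv(system.file("extdata", "lab_validation_results.csv",
                              package = "imupose", mustWork = TRUE))
}
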