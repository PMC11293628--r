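#' Published APOE-e4 leave-one-out summary statistics
#'
#' Leave-one-out fixed-effect meta-analysis results for the association of
#' the APOE e4 allele with Alzheimer disease across four population-based
#' studies (African American, East Asian, Hispanic, non-Hispanic White),
#' as published in the validation of the Meta-Reductive adjustment: each
#' row gives the combined effect (log odds ratio) and standard error of the
#' meta-analysis that excludes the named population. Together with
#' [reconstruct_from_loo()] this single-marker family is a complete,
#' self-contained real-data test of the removal algebra.
#'
#' @return A data.frame with columns `study` (the excluded population),
#'   `beta` and `se`.
#' @examples
#' loo <- apoe4_loo()
#' rec <- reconstruct_from_loo(loo$beta, loo$se, labels = loo$study)
#' # removing the African American study from the full meta-analysis
#' # reproduces the published leave-one-out row exactly
#' mra_remove(rec$meta, rec$studies[[1]])
#' @export
apoe4_loo <- function() {
  data.frame(
    study = c("African American", "East Asian", "Hispanic",
              "non-Hispanic White"),
    beta = c(1.189192599, 1.09385844, 1.215580078, 1.177899334),
    se = c(0.01671915, 0.017205134, 0.016903311, 0.026321213),
    stringsAsFactors = FALSE
  )
}
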