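#' Simulate multi-study GWAS summary statistics
#'
#' Generates per-study, per-marker effect sizes and standard errors with
#' the design used to certify the adjustment algebra: every beta is an
#' independent draw from Normal(`beta_mean`, `beta_sd`) and every SE an
#' independent draw from Uniform(`se_min`, `se_max`). Defaults are the
#' reference conditions: 10 studies of 10,000 markers, Normal(0, 1) betas,
#' SEs in \[0.1, 0.5\]. Betas are deliberately independent across studies
#' (no shared true effect): the identity being validated — removal of a
#' cohort reproduces the leave-one-out meta-analysis — is distribution-free,
#' so no generative signal model is needed or provided.
#'
#' Marker IDs are synthetic (`sim000001`, ...) and identical across studies;
#' each table carries constant synthetic alleles (effect A, other G) so the
#' tables pass allele harmonization unchanged. R's default Mersenne-Twister
#' stream is used; for each study in order, all betas are drawn first, then
#' all SEs, so a fixed `seed` reproduces byte-identical tables on any
#' platform.
#'
#' @param n_studies Number of studies (>= 2); default 10.
#' @param n_markers Markers per study (>= 1); default 10,000.
#' @param beta_mean,beta_sd Normal parameters for the effect sizes
#'   (defaults 0 and 1; `beta_sd > 0`).
#' @param se_min,se_max Uniform bounds for the standard errors
#'   (defaults 0.1 and 0.5; `0 < se_min < se_max`).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return A list of `n_studies` [sumstats] tables sharing marker IDs.
#' @examples
#' studies <- simulate_studies(n_studies = 3, n_markers = 10, seed = 42)
#' studies[[1]]
#' @export
simulate_studies <- function(n_studies = 10, n_markers = 10000,
                             beta_mean = 0, beta_sd = 1,
                             se_min = 0.1, se_max = 0.5, seed = NULL) {
  check_sim_config(n_studies, n_markers, beta_mean, beta_sd, se_min, se_max)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- sprintf("sim%06d", seq_len(n_markers))
  lapply(seq_len(n_studies), function(i) {
    beta <- stats::rnorm(n_markers, mean = beta_mean, sd = beta_sd)
    se <- stats::runif(n_markers, min = se_min, max = se_max)
    sumstats(data.frame(marker_id = ids,
                        effect_allele = "A", other_allele = "G",
                        beta = beta, se = se,
                        stringsAsFactors = FALSE),
             source_label = sprintf("simulated study %d", i))
  })
}

check_sim_config <- function(n_studies, n_markers, beta_mean, beta_sd,
                             se_min, se_max) {
  ok <- is.numeric(n_studies) && length(n_studies) == 1L && n_studies >= 2 &&
    is.numeric(n_markers) && length(n_markers) == 1L && n_markers >= 1 &&
    is.numeric(beta_mean) && is.finite(beta_mean) &&
    is.numeric(beta_sd) && beta_sd > 0 &&
    is.numeric(se_min) && is.numeric(se_max) &&
    se_min > 0 && se_min < se_max
  if (!ok) {
    stop(invalid_input(
      "invalid simulation config: need n_studies >= 2, n_markers >= 1, beta_sd > 0, 0 < se_min < se_max"
    ))
  }
  invisible(TRUE)
}
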