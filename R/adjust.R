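#' Remove a cohort's contribution from a meta-analysis table
#'
#' Table-level Meta-Reductive adjustment. Cohort alleles are harmonized
#' against the meta table (see [harmonize()]); for every matched marker the
#' cohort's contribution is removed with [mra_remove()], and the output
#' p-value is recomputed as a two-sided Wald test from the (adjusted or
#' unadjusted) beta and se. Markers that cannot be adjusted — absent from
#' the cohort, palindromic under the default policy, allele-incompatible, or
#' hitting the dominance guard — are emitted unadjusted and flagged; one bad
#' marker never aborts a genome-wide run. An adjustment record is produced
#' for every meta marker (no silent drops).
#'
#' @param meta [sumstats] table of the published meta-analysis. Its
#'   `n_studies` is unknown, so study counts are not tracked here.
#' @param cohort [sumstats] table of the overlapping cohort to remove.
#' @param palindromic Policy for A/T and C/G variants, passed to
#'   [harmonize()]: `"drop"` (default, emitted unadjusted) or `"keep"`.
#' @param missing Policy for meta markers absent from the cohort:
#'   `"emit"` (default; emitted unadjusted) or `"drop"` (removed from the
#'   output table; still present in the report).
#' @param eps Dominance guard threshold, see [mra_remove()].
#' @return A list with components
#'   \describe{
#'     \item{table}{[sumstats] table with adjusted `beta`/`se`, recomputed
#'       `p`, and columns `adjusted` and `removed_weight_fraction`.}
#'     \item{report}{data.frame of per-marker adjustment records:
#'       `marker_id`, `b_adj`, `se_adj`, `removed_weight_fraction`
#'       (`SE^2 * w_n`, in `[0, 1)`), `harmonization_action`, `adjusted`,
#'       `note`.}
#'   }
#' @examples
#' studies <- simulate_studies(n_studies = 3, n_markers = 5, seed = 1)
#' meta <- fema_table(studies)
#' adj <- adjust_table(meta, studies[[3]])
#' head(adj$report)
#' @export
adjust_table <- function(meta, cohort, palindromic = c("drop", "keep"),
                         missing = c("emit", "drop"), eps = 1e-12) {
  palindromic <- match.arg(palindromic)
  missing <- match.arg(missing)
  stopifnot(is.data.frame(meta), is.data.frame(cohort))
  validate_sumstats(meta)
  if (nrow(cohort)) validate_sumstats(cohort)

  h <- harmonize(meta, cohort, palindromic = palindromic)
  usable <- h$action %in% c("match", "flip") & !is.na(h$cohort_beta)

  W <- iv_weight(meta$se)
  b_adj <- meta$beta
  se_adj <- meta$se
  rwf <- rep(0, nrow(meta))
  note <- rep("", nrow(meta))
  adjusted <- rep(FALSE, nrow(meta))

  if (any(usable)) {
    w_n <- iv_weight(h$cohort_se[usable])
    frac <- w_n / W[usable]           # SE^2 * w_n, the removed-weight fraction
    ok <- (1 - frac) > eps
    dom <- which(usable)[!ok]
    use <- which(usable)[ok]
    if (length(dom)) {
      note[dom] <- "dominance"
    }
    if (length(use)) {
      W_adj <- W[use] - w_n[ok]
      b_adj[use] <- (meta$beta[use] * W[use] - h$cohort_beta[use] * w_n[ok]) / W_adj
      se_adj[use] <- sqrt(1 / W_adj)
      rwf[use] <- frac[ok]
      adjusted[use] <- TRUE
    }
  }

  report <- data.frame(
    marker_id = meta$marker_id,
    b_adj = b_adj, se_adj = se_adj,
    removed_weight_fraction = rwf,
    harmonization_action = h$action,
    adjusted = adjusted,
    note = note,
    stringsAsFactors = FALSE
  )

  out <- as.data.frame(meta)
  out$beta <- b_adj
  out$se <- se_adj
  out$p <- wald_stats(list(beta = b_adj, se = se_adj))$p
  out$adjusted <- adjusted
  out$removed_weight_fraction <- rwf
  if (missing == "drop") {
    out <- out[h$action != "cohort_missing", , drop = FALSE]
  }
  out <- sumstats(out, dialect = "canonical",
                  source_label = paste0(attr(meta, "source_label"), " [adjusted]"))
  list(table = out, report = report)
}

#' Fixed-effect meta-analysis of several summary-statistics tables
#'
#' Combines per-marker effect estimates across tables with [fema()]. All
#' tables must share the same marker universe; rows are aligned by marker
#' ID against the first table. Allele and position columns are inherited
#' from the first table; p-values are recomputed Wald tests.
#'
#' @param studies A list of two or more [sumstats] tables (one is allowed
#'   and returns its own estimates unchanged).
#' @return A [sumstats] table of combined estimates.
#' @export
fema_table <- function(studies) {
  if (inherits(studies, "sumstats")) studies <- list(studies)
  stopifnot(is.list(studies), length(studies) >= 1L)
  ref <- studies[[1L]]
  effs <- lapply(studies, function(s) {
    idx <- match(ref$marker_id, s$marker_id)
    if (any(is.na(idx))) {
      stop(invalid_input("studies do not share a common marker universe"))
    }
    study_effect(s$beta[idx], s$se[idx])
  })
  fit <- fema(effs)
  out <- as.data.frame(ref)[, c("marker_id", "chrom", "pos",
                                "effect_allele", "other_allele")]
  out$beta <- fit$beta
  out$se <- fit$se
  out$p <- wald_stats(fit)$p
  sumstats(out, dialect = "canonical",
           source_label = sprintf("FEMA of %d studies", length(studies)))
}
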