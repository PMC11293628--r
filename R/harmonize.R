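# Allele harmonization between a meta table and a cohort table.
#
# beta is signed with respect to the effect allele, so before the cohort's
# estimate can be subtracted from the meta-analysis the two tables must
# refer to the same allele. Matching is by marker ID + allele pair only;
# positions are never used (summary rows are the unit of operation).

.complement <- function(a) {
  ok <- grepl("^[ACGTacgt]+$", a)
  out <- a
  out[ok] <- chartr("ACGTacgt", "TGCAtgca", a[ok])
  out
}

.is_palindromic <- function(a1, a2) {
  ok <- !is.na(a1) & !is.na(a2) & grepl("^[ACGTacgt]$", a1) & grepl("^[ACGTacgt]$", a2)
  ok & toupper(a1) == toupper(.complement(a2))
}

#' Harmonize cohort alleles against a meta-analysis table
#'
#' For every marker of the meta table, decides how the cohort's effect
#' estimate relates to the meta effect allele:
#'
#' * `match` — same effect/other allele pair (directly, or after strand
#'   complementation): cohort beta used as is;
#' * `flip` — effect and other alleles swapped (directly or on the opposite
#'   strand): cohort beta sign-negated;
#' * `drop_palindromic` — A/T or C/G variant whose strand cannot be resolved
#'   from alleles alone (default policy drops these from adjustment);
#' * `drop_mismatch` — allele pairs incompatible even after strand
#'   complementation;
#' * `cohort_missing` — marker absent from the cohort.
#'
#' Allele comparison is case-insensitive. If the meta table carries no
#' allele columns while the cohort does, matching falls back to marker ID
#' only with a warning (`action = match`, flagged in the `id_only` column).
#'
#' @param meta,cohort [sumstats] tables.
#' @param palindromic `"drop"` (default) or `"keep"`; under `"keep"`
#'   palindromic variants are treated as ordinary matches/flips assuming
#'   both tables report the same strand.
#' @return A data.frame with one row per meta marker: `marker_id`,
#'   `cohort_beta` (sign-harmonized, `NA` when not usable), `cohort_se`,
#'   `action`, `id_only`.
#' @export
harmonize <- function(meta, cohort, palindromic = c("drop", "keep")) {
  palindromic <- match.arg(palindromic)
  stopifnot(is.data.frame(meta), is.data.frame(cohort))
  idx <- match(meta$marker_id, cohort$marker_id)
  present <- !is.na(idx)

  meta_has_alleles <- !all(is.na(meta$effect_allele))
  cohort_has_alleles <- !all(is.na(cohort$effect_allele))
  id_only <- FALSE
  if (!meta_has_alleles && cohort_has_alleles) {
    warning("meta table lacks allele columns; harmonizing on marker ID only",
            call. = FALSE)
    id_only <- TRUE
  }

  n <- nrow(meta)
  action <- rep("cohort_missing", n)
  c_beta <- rep(NA_real_, n)
  c_se <- rep(NA_real_, n)
  c_se[present] <- cohort$se[idx[present]]

  if (id_only || (!meta_has_alleles && !cohort_has_alleles)) {
    action[present] <- "match"
    c_beta[present] <- cohort$beta[idx[present]]
  } else {
    ea <- toupper(meta$effect_allele)
    oa <- toupper(meta$other_allele)
    cea <- toupper(cohort$effect_allele[idx])
    coa <- toupper(cohort$other_allele[idx])
    pal <- .is_palindromic(meta$effect_allele, meta$other_allele)

    same <- present & cea == ea & coa == oa
    swap <- present & cea == oa & coa == ea
    strand_same <- present & !same & !swap &
      toupper(.complement(cea)) == ea & toupper(.complement(coa)) == oa
    strand_swap <- present & !same & !swap &
      toupper(.complement(cea)) == oa & toupper(.complement(coa)) == ea

    is_match <- same | strand_same
    is_flip <- swap | strand_swap
    is_match[is.na(is_match)] <- FALSE
    is_flip[is.na(is_flip)] <- FALSE

    action[present] <- "drop_mismatch"
    action[is_match] <- "match"
    action[is_flip] <- "flip"
    c_beta[is_match] <- cohort$beta[idx[is_match]]
    c_beta[is_flip] <- -cohort$beta[idx[is_flip]]

    if (palindromic == "drop") {
      drop_pal <- present & pal & (is_match | is_flip)
      action[drop_pal] <- "drop_palindromic"
      c_beta[drop_pal] <- NA_real_
    }
  }

  data.frame(marker_id = meta$marker_id, cohort_beta = c_beta,
             cohort_se = c_se, action = action, id_only = id_only,
             stringsAsFactors = FALSE)
}
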