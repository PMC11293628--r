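# Leave-one-out validation: the removal algebra is exact, so removing study
# i from the full meta-analysis must reproduce a direct meta-analysis of the
# other k-1 studies. These tools prove that identity on any study collection
# and invert a published leave-one-out family back to per-study inputs.

#' Leave-one-out meta-analyses
#'
#' For each of the k studies, meta-analyzes the remaining k-1 with [fema()].
#' These re-fits are the ground truth the cohort-removal adjustment is
#' compared against.
#'
#' @param studies A list of k >= 2 [sumstats] tables sharing a marker
#'   universe, or a list of k [study_effect()] objects of equal length.
#' @return A list of k `"meta_effect"` objects; the i-th excludes study i.
#' @export
leave_one_out <- function(studies) {
  effs <- as_study_effects(studies)
  k <- length(effs)
  if (k < 2L) stop(invalid_input("leave-one-out requires at least 2 studies"))
  lapply(seq_len(k), function(i) fema(effs[-i]))
}

# normalize a list of sumstats tables or study_effects to aligned study_effects
as_study_effects <- function(studies) {
  stopifnot(is.list(studies))
  if (all(vapply(studies, inherits, logical(1L), "study_effect"))) {
    return(studies)
  }
  if (all(vapply(studies, inherits, logical(1L), "sumstats"))) {
    ref <- studies[[1L]]
    return(lapply(studies, function(s) {
      idx <- match(ref$marker_id, s$marker_id)
      if (any(is.na(idx))) {
        stop(invalid_input("studies do not share a common marker universe"))
      }
      study_effect(s$beta[idx], s$se[idx],
                   label = attr(s, "source_label"))
    }))
  }
  stop(invalid_input(
    "'studies' must be a list of sumstats tables or of study_effect objects"
  ))
}

#' Compare cohort removal against direct leave-one-out re-analysis
#'
#' Fits the full fixed-effect meta-analysis, removes each study in turn with
#' [mra_remove()], and compares every removal against the corresponding
#' [leave_one_out()] re-fit, per marker, in both beta and SE^2. Because the
#' removal is an algebraic identity — not an approximation — the comparison
#' must pass at the default tolerance on any valid input; a failure
#' indicates a formula or harmonization error, which is exactly what this
#' check exists to catch.
#'
#' @inheritParams leave_one_out
#' @param tol Relative tolerance for the pass/fail verdict (default 1e-8:
#'   comfortably above double-precision rounding at realistic weights,
#'   far below any printed GWAS precision).
#' @return An object of class `"mra_comparison"`: list with
#'   `n_markers_compared`, `max_abs_diff_beta`, `max_rel_diff_beta`,
#'   `max_abs_diff_se2`, `max_rel_diff_se2`, `pass`, `tol`, and
#'   `worst` (a data.frame of the worst-offending study/marker pairs).
#' @export
compare_mra_vs_loo <- function(studies, tol = 1e-8) {
  effs <- as_study_effects(studies)
  k <- length(effs)
  if (k < 2L) stop(invalid_input("comparison requires at least 2 studies"))
  full <- fema(effs)
  loo <- leave_one_out(effs)

  # beta is a signed estimate that crosses zero, where a pure relative
  # difference is ill-defined (machine-precision noise over a vanishing
  # reference); near zero it is measured on the estimate's own standard
  # error, its natural scale. se^2 is bounded away from zero, so a pure
  # relative difference applies.
  rel_beta <- function(x, ref, ref_se) abs(x - ref) / pmax(abs(ref), ref_se)
  rel <- function(x, ref) abs(x - ref) / abs(ref)
  worst <- data.frame()
  max_ab <- 0; max_rb <- 0; max_as <- 0; max_rs <- 0
  for (i in seq_len(k)) {
    adj <- mra_remove(full, effs[[i]])
    db <- abs(adj$beta - loo[[i]]$beta)
    rb <- rel_beta(adj$beta, loo[[i]]$beta, loo[[i]]$se)
    ds <- abs(adj$se^2 - loo[[i]]$se^2)
    rs <- rel(adj$se^2, loo[[i]]$se^2)
    max_ab <- max(max_ab, db); max_rb <- max(max_rb, rb)
    max_as <- max(max_as, ds); max_rs <- max(max_rs, rs)
    j <- which.max(pmax(rb, rs))
    worst <- rbind(worst, data.frame(
      excluded_study = i, marker = j,
      rel_diff_beta = rb[j], rel_diff_se2 = rs[j]
    ))
  }
  worst <- worst[order(-pmax(worst$rel_diff_beta, worst$rel_diff_se2)), ]
  structure(list(
    n_markers_compared = length(full$beta) * k,
    max_abs_diff_beta = max_ab, max_rel_diff_beta = max_rb,
    max_abs_diff_se2 = max_as, max_rel_diff_se2 = max_rs,
    pass = max_rb <= tol && max_rs <= tol,
    tol = tol,
    worst = utils::head(worst, 10L)
  ), class = "mra_comparison")
}

#' @export
print.mra_comparison <- function(x, ...) {
  cat("Cohort-removal vs leave-one-out comparison\n")
  cat(sprintf("  comparisons:            %d (study x marker)\n", x$n_markers_compared))
  cat(sprintf("  max |diff| beta:        %.3g (rel %.3g)\n",
              x$max_abs_diff_beta, x$max_rel_diff_beta))
  cat(sprintf("  max |diff| SE^2:        %.3g (rel %.3g)\n",
              x$max_abs_diff_se2, x$max_rel_diff_se2))
  cat(sprintf("  verdict at tol %.1e:    %s\n", x$tol,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Scatter the removal results against the leave-one-out ground truth
#'
#' Two panels — beta vs beta and SE^2 vs SE^2 — with the identity line;
#' with an exact implementation every point sits on the diagonal.
#'
#' @param x An `"mra_comparison"` is not enough to re-plot the raw values,
#'   so this method takes the original study list.
#' @param studies The study list that produced the comparison.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mra_comparison <- function(x, studies, ...) {
  effs <- as_study_effects(studies)
  full <- fema(effs)
  loo <- leave_one_out(effs)
  mb <- unlist(lapply(seq_along(effs), function(i) mra_remove(full, effs[[i]])$beta))
  lb <- unlist(lapply(loo, function(l) l$beta))
  ms <- unlist(lapply(seq_along(effs), function(i) mra_remove(full, effs[[i]])$se^2))
  ls <- unlist(lapply(loo, function(l) l$se^2))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(lb, mb, xlab = "leave-one-out beta", ylab = "adjusted beta",
                 main = "Effect sizes", ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(ls, ms, xlab = "leave-one-out SE^2", ylab = "adjusted SE^2",
                 main = "Squared standard errors", ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Reconstruct per-study inputs from published leave-one-out results
#'
#' Inverts the leave-one-out construction: given the k (beta, SE) pairs of
#' the meta-analyses that each exclude one study, recovers the k per-study
#' (beta, SE) inputs and the full-meta estimate. With `P_i = 1/se_loo_i^2`:
#' total precision `W = sum(P_i)/(k-1)`; per-study weight `w_i = W - P_i`;
#' weighted effect sum `S = sum(beta_loo_i * P_i)/(k-1)`; per-study
#' `beta_i = (S - beta_loo_i * P_i)/w_i`, `se_i = sqrt(1/w_i)`; full meta
#' `B = S/W`, `SE = sqrt(1/W)`. The linear system is exactly determined for
#' k >= 3; k = 2 is rejected because the total precision is unidentifiable
#' (each leave-one-out result *is* the other study, fixing no overall
#' scale).
#'
#' A family of pairs that did not come from a coherent fixed-effect
#' leave-one-out — e.g. one SE perturbed — yields a non-positive
#' reconstructed weight and is rejected.
#'
#' @param loo_beta,loo_se Numeric vectors of length k >= 3: the effect size
#'   and standard error of the meta-analysis excluding study i.
#' @param labels Optional study labels.
#' @return A list with `studies` (list of k [study_effect()]) and `meta`
#'   (the full `"meta_effect"`).
#' @examples
#' # leave-one-out family of the 3-study set (0.5,0.1),(0.2,0.2),(-0.1,0.5)
#' loo <- leave_one_out(list(study_effect(0.5, 0.1), study_effect(0.2, 0.2),
#'                           study_effect(-0.1, 0.5)))
#' rec <- reconstruct_from_loo(vapply(loo, `[[`, 1, "beta"),
#'                             vapply(loo, `[[`, 1, "se"))
#' rec$studies[[1]]$beta  # 0.5
#' @export
reconstruct_from_loo <- function(loo_beta, loo_se, labels = NULL) {
  k <- length(loo_beta)
  if (k < 3L || length(loo_se) != k) {
    stop(invalid_input(
      "need k >= 3 leave-one-out (beta, se) pairs of equal length; k = 2 leaves the system underdetermined"
    ))
  }
  P <- iv_weight(loo_se)
  if (any(!is.finite(loo_beta))) {
    stop(invalid_input("leave-one-out betas must be finite"))
  }
  W <- sum(P) / (k - 1)
  S <- sum(loo_beta * P) / (k - 1)
  w <- W - P
  if (any(w <= 0)) {
    stop(invalid_input(
      "inputs are not a coherent LOO family of a fixed-effect meta-analysis (reconstructed study weight <= 0)"
    ))
  }
  beta <- (S - loo_beta * P) / w
  studies <- lapply(seq_len(k), function(i) {
    study_effect(beta[i], sqrt(1 / w[i]),
                 label = if (is.null(labels)) NULL else labels[i])
  })
  list(studies = studies, meta = meta_effect(S / W, sqrt(1 / W), n_studies = k))
}
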