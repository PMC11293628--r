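#' Inverse-variance weight of an effect estimate
#'
#' The fixed-effect meta-analysis weight of a study is the precision of its
#' effect estimate: `w = 1/se^2`. Studies with smaller standard errors carry
#' more weight because they estimate the common effect more precisely.
#'
#' @param se Numeric vector of standard errors; every element must be finite
#'   and strictly positive.
#' @return Numeric vector of precisions `1/se^2`, in units of
#'   1/(effect-size units)^2.
#' @examples
#' iv_weight(c(1, 0.1, 0.5))  # 1, 100, 4
#' @export
iv_weight <- function(se) {
  if (!is.numeric(se) || length(se) == 0L) {
    stop(invalid_input("'se' must be a non-empty numeric vector"))
  }
  bad <- !is.finite(se) | se <= 0
  if (any(bad)) {
    stop(invalid_input(sprintf(
      "standard errors must be finite and > 0; offending value(s): %s",
      paste(utils::head(se[bad], 5L), collapse = ", ")
    )))
  }
  1 / se^2
}

#' Per-study effect estimates
#'
#' Container for one study's effect sizes and standard errors, scalar for a
#' single marker or vectors for a set of markers. Effect sizes are on an
#' additive scale (log odds ratio or linear-trait units); the derived weight
#' `1/se^2` is stored alongside.
#'
#' @param beta Numeric vector of effect sizes; must be finite.
#' @param se Numeric vector of standard errors, same length as `beta`;
#'   finite and strictly positive.
#' @param label Optional free-text study label.
#' @return An object of class `"study_effect"`: a list with elements
#'   `beta`, `se`, `weight` and `label`.
#' @examples
#' study_effect(0.5, 0.1, label = "cohort A")
#' @export
study_effect <- function(beta, se, label = NULL) {
  if (!is.numeric(beta) || !is.numeric(se)) {
    stop(invalid_input("'beta' and 'se' must be numeric"))
  }
  if (length(beta) != length(se)) {
    stop(invalid_input("'beta' and 'se' must have equal length"))
  }
  if (any(!is.finite(beta))) {
    stop(invalid_input(sprintf(
      "effect sizes must be finite; offending value(s): %s",
      paste(utils::head(beta[!is.finite(beta)], 5L), collapse = ", ")
    )))
  }
  w <- iv_weight(se)
  structure(
    list(beta = as.numeric(beta), se = as.numeric(se), weight = w,
         label = label),
    class = "study_effect"
  )
}

#' @export
print.study_effect <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("Study effect%s: %d marker(s)\n", lab, length(x$beta)))
  print(utils::head(data.frame(beta = x$beta, se = x$se, weight = x$weight)))
  invisible(x)
}

#' Combined meta-analysis effect
#'
#' Low-level constructor for a combined (meta-analysed) effect estimate.
#' Most users obtain one by fitting with [fema()] or by adjusting with
#' [mra_remove()]; the constructor exists so that a published meta-analysis
#' row (B, SE) can be wrapped directly, in which case the number of
#' contributing studies is typically unknown (`n_studies = NA`).
#'
#' @param beta Combined effect size(s) B.
#' @param se Combined standard error(s) SE; finite, > 0.
#' @param n_studies Number of contributing studies, or `NA` when unknown
#'   (published files rarely carry it).
#' @return An object of class `"meta_effect"`: list with `beta`, `se`,
#'   `precision` (`1/se^2`), `n_studies`.
#' @export
meta_effect <- function(beta, se, n_studies = NA_integer_) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop(invalid_input("'beta' must be finite numeric"))
  }
  w <- iv_weight(se)
  if (length(beta) != length(se)) {
    stop(invalid_input("'beta' and 'se' must have equal length"))
  }
  structure(
    list(beta = as.numeric(beta), se = as.numeric(se), precision = w,
         n_studies = as.integer(n_studies)),
    class = "meta_effect"
  )
}

#' Fit an inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study effect estimates under the fixed-effect model: a single
#' common true effect, each study weighted by its precision `w_i = 1/se_i^2`.
#' The combined estimate is the precision-weighted mean
#' \deqn{B = \sum_i \beta_i w_i / \sum_i w_i,\qquad SE^2 = 1/\sum_i w_i.}
#'
#' All studies must cover the same markers in the same order (element-wise
#' combination); use [leave_one_out()] / [adjust_table()] for keyed tables.
#'
#' @param studies A non-empty list of [study_effect()] objects (or a single
#'   `study_effect`).
#' @return An object of class `"meta_effect"`; see [meta_effect()].
#' @examples
#' fit <- fema(list(study_effect(0.5, 0.1),
#'                  study_effect(0.2, 0.2),
#'                  study_effect(-0.1, 0.5)))
#' coef(fit)         # 54.6/129
#' summary(fit)
#' @seealso [mra_remove()] to remove one study's contribution from the fit.
#' @export
fema <- function(studies) {
  if (inherits(studies, "study_effect")) studies <- list(studies)
  if (!is.list(studies) || length(studies) == 0L) {
    stop(invalid_input("'studies' must be a non-empty list of study_effect objects"))
  }
  if (!all(vapply(studies, inherits, logical(1L), "study_effect"))) {
    stop(invalid_input("every element of 'studies' must be a study_effect"))
  }
  m <- unique(vapply(studies, function(s) length(s$beta), integer(1L)))
  if (length(m) != 1L) {
    stop(invalid_input("all studies must cover the same number of markers"))
  }
  W <- 0
  S <- 0
  for (s in studies) {
    W <- W + s$weight
    S <- S + s$beta * s$weight
  }
  meta_effect(S / W, sqrt(1 / W), n_studies = length(studies))
}

#' Remove one cohort's contribution from a meta-analysis estimate
#'
#' The Meta-Reductive Approach (MRA): given the combined fixed-effect
#' estimate (B, SE) and the summary statistics (beta_n, se_n) of one
#' constituent cohort, algebraically removes that cohort so that the result
#' equals a re-meta-analysis of the remaining studies exactly:
#' \deqn{B_{adj} = B + \frac{SE^2 (B w_n - \beta_n w_n)}{1 - SE^2 w_n},
#'       \qquad SE^2_{adj} = \frac{SE^2}{1 - SE^2 w_n}.}
#'
#' Internally the computation uses the precision form
#' `B_adj = (B*W - beta_n*w_n) / (W - w_n)` with `W = 1/SE^2`, which is
#' algebraically identical (multiply numerator and denominator of the
#' displayed form by W) but avoids catastrophic cancellation when the cohort
#' carries nearly all of the weight (`SE^2 * w_n` close to 1).
#'
#' @param meta A [meta_effect()] (the published/combined estimate).
#' @param cohort A [study_effect()] for the cohort to remove, element-wise
#'   aligned with `meta`.
#' @param eps Dominance guard: removal requires `1 - SE^2 * w_n > eps`.
#'   Below this the cohort carries essentially all of the meta-analysis
#'   weight and the division amplifies numerical noise; default `1e-12`.
#' @return A `"meta_effect"` holding the adjusted B_adj, SE_adj, precision
#'   `1/SE^2 - w_n`, with `n_studies` decremented when known.
#' @examples
#' meta <- fema(list(study_effect(0.5, 0.1), study_effect(0.2, 0.2),
#'                   study_effect(-0.1, 0.5)))
#' mra_remove(meta, study_effect(-0.1, 0.5))  # B_adj = 0.44, SE_adj^2 = 0.008
#' @export
mra_remove <- function(meta, cohort, eps = 1e-12) {
  stopifnot(inherits(meta, "meta_effect"), inherits(cohort, "study_effect"))
  if (length(meta$beta) != length(cohort$beta)) {
    stop(invalid_input("'meta' and 'cohort' must cover the same markers"))
  }
  W <- meta$precision
  w_n <- cohort$weight
  # guard: 1 - SE^2 * w_n == (W - w_n)/W
  frac_left <- (W - w_n) / W
  if (any(frac_left <= eps)) {
    stop(dominance_error(
      "cohort dominates meta: the cohort carries essentially all of the meta-analysis weight (1 - SE^2*w_n <= eps); removal is undefined"
    ))
  }
  W_adj <- W - w_n
  b_adj <- (meta$beta * W - cohort$beta * w_n) / W_adj
  out <- meta_effect(b_adj, sqrt(1 / W_adj),
                     n_studies = if (is.na(meta$n_studies)) NA_integer_
                                 else meta$n_studies - 1L)
  out$precision <- W_adj  # exact, not recomputed from the rounded se
  out
}

#' Remove several cohorts' contributions in sequence
#'
#' Folds [mra_remove()] over a list of cohorts. Because the fixed-effect
#' sums are order-free, the result is independent of the removal order (up
#' to floating-point rounding) and equals a direct [fema()] of the
#' complementary study set.
#'
#' @inheritParams mra_remove
#' @param cohorts A (possibly empty) list of [study_effect()] objects.
#' @return A `"meta_effect"`; `meta` unchanged when `cohorts` is empty.
#' @export
mra_remove_sequential <- function(meta, cohorts, eps = 1e-12) {
  stopifnot(inherits(meta, "meta_effect"), is.list(cohorts))
  for (co in cohorts) meta <- mra_remove(meta, co, eps = eps)
  meta
}

#' Wald test statistics for a combined estimate
#'
#' Two-sided Wald normal test: `z = beta/se`,
#' `p = 2 * pnorm(-|z|)`. Input p-values carried in summary-statistics files
#' are never adjusted by this package, only replaced by this recomputation.
#'
#' @param effect A `"meta_effect"` (or anything with numeric `beta` and `se`).
#' @return A list with numeric vectors `z` and `p` (`p` in (0, 1]).
#' @export
wald_stats <- function(effect) {
  z <- effect$beta / effect$se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.meta_effect <- function(x, ...) {
  k <- if (is.na(x$n_studies)) "unknown number of" else x$n_studies
  cat(sprintf("Fixed-effect meta-analysis estimate (%s studies, %d marker(s))\n",
              k, length(x$beta)))
  print(utils::head(data.frame(beta = x$beta, se = x$se)))
  invisible(x)
}

#' @export
coef.meta_effect <- function(object, ...) object$beta

#' @export
summary.meta_effect <- function(object, ...) {
  ws <- wald_stats(object)
  out <- data.frame(beta = object$beta, se = object$se, z = ws$z, p = ws$p)
  structure(list(table = out, n_studies = object$n_studies),
            class = "summary.meta_effect")
}

#' @export
print.summary.meta_effect <- function(x, ...) {
  k <- if (is.na(x$n_studies)) "unknown number of" else x$n_studies
  cat(sprintf("Inverse-variance fixed-effect meta-analysis (%s studies)\n\n", k))
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat(sprintf("... %d more marker(s)\n", nrow(x$table) - 10L))
  invisible(x)
}

#' @export
confint.meta_effect <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = object$beta - q * object$se,
        upper = object$beta + q * object$se)
}

# classed conditions so callers can discriminate failure modes
invalid_input <- function(msg) {
  errorCondition(msg, class = c("metareduce_invalid_input", "metareduce_error"))
}

dominance_error <- function(msg) {
  errorCondition(msg, class = c("metareduce_dominance_error", "metareduce_error"))
}
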