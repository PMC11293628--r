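test_that("inverse-variance weights are 1/se^2 and reject invalid input", {
  expect_equal(iv_weight(1), 1)
  expect_equal(iv_weight(0.1), 100)
  expect_equal(iv_weight(0.5), 4)
  expect_equal(iv_weight(c(1, 0.1, 0.5)), c(1, 100, 4))
  # strictly decreasing in se
  se <- sort(exp(runif(50, log(1e-3), log(10))))
  expect_true(all(diff(iv_weight(se)) < 0))
  expect_error(iv_weight(0), class = "metareduce_invalid_input")
  expect_error(iv_weight(-0.1), class = "metareduce_invalid_input")
  expect_error(iv_weight(NaN), class = "metareduce_invalid_input")
  expect_error(iv_weight(Inf), class = "metareduce_invalid_input")
  # message names the offending value
  expect_error(iv_weight(-0.1), "-0.1")
})

test_that("study_effect enforces its invariants", {
  s <- study_effect(0.3, 0.2)
  expect_equal(s$weight, 1 / 0.2^2)
  expect_error(study_effect(NA_real_, 0.2), class = "metareduce_invalid_input")
  expect_error(study_effect(0.3, 0), class = "metareduce_invalid_input")
  expect_error(study_effect(c(1, 2), 0.1), class = "metareduce_invalid_input")
})

test_that("fixed-effect combination is the precision-weighted mean", {
  # single study is the identity
  m1 <- fema(list(study_effect(0.3, 0.2)))
  expect_equal(m1$beta, 0.3)
  expect_equal(m1$se, 0.2)
  expect_equal(m1$n_studies, 1L)

  # symmetric pair halves the variance
  m2 <- fema(list(study_effect(1, 1), study_effect(1, 1)))
  expect_equal(m2$beta, 1)
  expect_equal(m2$se^2, 0.5)

  # hand-computed 3-study weighted sum, w = (100, 25, 4)
  m3 <- fema(micro_studies())
  expect_equal(m3$beta, 54.6 / 129)
  expect_equal(m3$se^2, 1 / 129)
  expect_equal(m3$precision, 129)
  expect_equal(m3$n_studies, 3L)

  expect_error(fema(list()), class = "metareduce_invalid_input")
})

test_that("combination agrees with an independent fixed-effect fit", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(2:8, 1)
    b <- rnorm(k)
    se <- runif(k, 0.05, 0.8)
    fit <- fema(Map(study_effect, b, se))
    ref <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(fit$beta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(fit$se, ref$se, tolerance = 1e-10)
  }
})

test_that("removing one of two identical studies returns the other", {
  meta <- fema(list(study_effect(1, 1), study_effect(1, 1)))
  adj <- mra_remove(meta, study_effect(1, 1))
  expect_equal(adj$beta, 1)
  expect_equal(adj$se^2, 1)
  expect_equal(adj$n_studies, 1L)
})

test_that("removal reproduces the hand-derived 3-study result", {
  meta <- fema(micro_studies())
  adj <- mra_remove(meta, study_effect(-0.1, 0.5))
  expect_equal(adj$beta, 0.44)
  expect_equal(adj$se^2, 1 / 125)
  # equals direct combination of the remaining two studies
  direct <- fema(micro_studies()[1:2])
  expect_equal(adj$beta, direct$beta)
  expect_equal(adj$se, direct$se)
})

test_that("removal of the displayed-formula rendering matches the precision form", {
  # B_adj = B + SE^2*(B*w_n - beta_n*w_n) / (1 - SE^2*w_n), expanded as
  # printed, must agree with the internal cancellation-safe form
  set.seed(7)
  for (rep in 1:20) {
    studies <- rand_studies(sample(2:6, 1), se_lo = 0.05, se_hi = 2)
    meta <- fema(studies)
    co <- studies[[1]]
    B <- meta$beta; SE2 <- meta$se^2; wn <- co$weight; bn <- co$beta
    displayed <- B + SE2 * (B * wn - bn * wn) / (1 - SE2 * wn)
    adj <- mra_remove(meta, co)
    expect_equal(adj$beta, displayed, tolerance = 1e-9)
  }
})

test_that("removal refuses a dominating cohort", {
  meta <- fema(list(study_effect(0.3, 0.2)))
  expect_error(mra_remove(meta, study_effect(0.3, 0.2)),
               class = "metareduce_dominance_error")
  # near-total dominance also guarded
  meta2 <- fema(list(study_effect(0, 1e-6), study_effect(1, 1e6)))
  expect_error(mra_remove(meta2, study_effect(0, 1e-6 * (1 + 1e-14))),
               class = "metareduce_dominance_error")
})

test_that("removing a near-weightless cohort is the identity limit", {
  meta <- fema(micro_studies())
  adj <- mra_remove(meta, study_effect(5, 1e6))
  expect_equal(adj$beta, meta$beta, tolerance = 1e-6)
  expect_equal(adj$se, meta$se, tolerance = 1e-6)
})

test_that("sequential removal folds correctly and is order-independent", {
  studies <- micro_studies()
  meta <- fema(studies)
  # empty removal is the identity
  same <- mra_remove_sequential(meta, list())
  expect_equal(same$beta, meta$beta)
  expect_equal(same$se, meta$se)

  fwd <- mra_remove_sequential(meta, studies[c(2, 3)])
  expect_equal(fwd$beta, 0.5)
  expect_equal(fwd$se, 0.1)
  rev <- mra_remove_sequential(meta, studies[c(3, 2)])
  expect_lte(rel_diff(fwd$beta, rev$beta), 1e-12)
  expect_lte(rel_diff(fwd$se, rev$se), 1e-12)
})

test_that("Wald statistics are two-sided and symmetric in sign", {
  ws0 <- wald_stats(meta_effect(0, 1))
  expect_equal(ws0$z, 0)
  expect_equal(ws0$p, 1)

  ws <- wald_stats(meta_effect(0.44, sqrt(0.008)))
  expect_equal(ws$z, 0.44 / sqrt(0.008))
  expect_equal(ws$p, 8.683228e-07, tolerance = 1e-6)

  wneg <- wald_stats(meta_effect(-0.44, sqrt(0.008)))
  expect_equal(wneg$p, ws$p)
})

test_that("meta_effect methods summarise the fit", {
  fit <- fema(micro_studies())
  expect_equal(coef(fit), 54.6 / 129)
  s <- summary(fit)
  expect_s3_class(s, "summary.meta_effect")
  expect_equal(s$table$z, fit$beta / fit$se)
  ci <- confint(fit)
  expect_lt(ci[, "lower"], fit$beta)
  expect_gt(ci[, "upper"], fit$beta)
  expect_output(print(fit), "3 studies")
  expect_output(print(s), "meta-analysis")
})
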