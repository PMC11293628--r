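test_that("leave-one-out fits the complementary study set", {
  # two identical studies: each exclusion returns the other
  twin <- list(study_effect(1, 1), study_effect(1, 1))
  loo <- leave_one_out(twin)
  expect_equal(loo[[1]]$beta, 1)
  expect_equal(loo[[1]]$se, 1)
  expect_equal(loo[[2]]$beta, 1)

  # hand-computed: excluding study 3 of the micro set, w = (100, 25)
  loo3 <- leave_one_out(micro_studies())
  expect_equal(loo3[[3]]$beta, 0.44)
  expect_equal(loo3[[3]]$se^2, 0.008)

  expect_error(leave_one_out(list(study_effect(1, 1))),
               class = "metareduce_invalid_input")
})

test_that("leave-one-out accepts sumstats tables and aligns markers", {
  studies <- simulate_studies(n_studies = 3, n_markers = 20, seed = 4)
  loo <- leave_one_out(studies)
  direct <- fema_table(studies[-2])
  expect_equal(loo[[2]]$beta, direct$beta)
  expect_equal(loo[[2]]$se, direct$se)
})

test_that("removal matches leave-one-out on small and adversarial sets", {
  set.seed(21)
  # smallest valid case
  cmp2 <- compare_mra_vs_loo(rand_studies(2, 0.05, 2))
  expect_true(cmp2$pass)

  # one study carrying ~99.99% of the total weight still passes:
  # the precision-form computation does not cancel catastrophically
  heavy <- list(study_effect(0.5, 0.003), study_effect(-0.2, 1),
                study_effect(0.1, 2), study_effect(0.3, 3))
  cmp_h <- compare_mra_vs_loo(heavy)
  w <- vapply(heavy, `[[`, 1, "weight")
  expect_gt(max(w) / sum(w), 0.9999)
  expect_true(cmp_h$pass)
  expect_lte(cmp_h$max_rel_diff_beta, 1e-10)

  expect_error(compare_mra_vs_loo(list(study_effect(1, 1))),
               class = "metareduce_invalid_input")
})

test_that("comparison report fields are internally consistent", {
  studies <- simulate_studies(n_studies = 4, n_markers = 50, seed = 17)
  cmp <- compare_mra_vs_loo(studies, tol = 1e-8)
  expect_s3_class(cmp, "mra_comparison")
  expect_equal(cmp$n_markers_compared, 4 * 50)
  expect_identical(cmp$pass,
                   cmp$max_rel_diff_beta <= cmp$tol &&
                     cmp$max_rel_diff_se2 <= cmp$tol)
  expect_output(print(cmp), "PASS")
})

test_that("reconstruction inverts the leave-one-out construction", {
  studies <- micro_studies()
  loo <- leave_one_out(studies)
  rec <- reconstruct_from_loo(vapply(loo, `[[`, 1, "beta"),
                              vapply(loo, `[[`, 1, "se"))
  # recovers (0.5, 0.1), (0.2, 0.2), (-0.1, 0.5)
  for (i in 1:3) {
    expect_equal(rec$studies[[i]]$beta, studies[[i]]$beta, tolerance = 1e-12)
    expect_equal(rec$studies[[i]]$se, studies[[i]]$se, tolerance = 1e-12)
  }
  # intermediate quantities verified by hand: W = 129, P = (29, 104, 125)
  expect_equal(rec$meta$precision, 129, tolerance = 1e-12)
  expect_equal(rec$meta$beta, 54.6 / 129, tolerance = 1e-12)

  # feeding the reconstruction back reproduces the input pairs
  loo2 <- leave_one_out(rec$studies)
  for (i in 1:3) {
    expect_lte(rel_diff(loo2[[i]]$beta, loo[[i]]$beta), 1e-10)
    expect_lte(rel_diff(loo2[[i]]$se, loo[[i]]$se), 1e-10)
  }
})

test_that("reconstruction rejects k < 3 and incoherent families", {
  loo <- leave_one_out(micro_studies())
  b <- vapply(loo, `[[`, 1, "beta")
  s <- vapply(loo, `[[`, 1, "se")
  expect_error(reconstruct_from_loo(b[1:2], s[1:2]),
               class = "metareduce_invalid_input")
  # one SE inflated 10x is no longer a coherent leave-one-out family
  s_bad <- s; s_bad[1] <- s_bad[1] * 10
  expect_error(reconstruct_from_loo(b, s_bad), "not a coherent",
               class = "metareduce_invalid_input")
})

test_that("published four-population APOE4 family round-trips exactly", {
  loo <- apoe4_loo()
  rec <- reconstruct_from_loo(loo$beta, loo$se, labels = loo$study)
  back <- leave_one_out(rec$studies)
  for (i in 1:4) {
    expect_equal(back[[i]]$beta, loo$beta[i], tolerance = 1e-12)
    expect_equal(back[[i]]$se, loo$se[i], tolerance = 1e-12)
  }
  # removing the East Asian study reproduces its published row
  adj <- mra_remove(rec$meta, rec$studies[[2]])
  expect_equal(adj$beta, 1.09385844, tolerance = 1e-9)
})
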