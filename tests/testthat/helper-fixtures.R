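# shared fixture builders (everything is generated in code at test time)

# k random single-marker studies; SEs log-uniform over [se_lo, se_hi].
# The default span covers realistic GWAS summary statistics (weight ratios
# up to 1e4); removal accuracy degrades linearly in the removed-weight
# condition number, so pathological dominance is exercised by dedicated
# adversarial and guard tests rather than by these generators.
rand_studies <- function(k, se_lo = 0.01, se_hi = 1) {
  lapply(seq_len(k), function(i) {
    study_effect(stats::rnorm(1, sd = 2),
                 exp(stats::runif(1, log(se_lo), log(se_hi))))
  })
}

# the worked 3-study micro example
micro_studies <- function() {
  list(study_effect(0.5, 0.1), study_effect(0.2, 0.2),
       study_effect(-0.1, 0.5))
}

rel_diff <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.eps)

# signed effect estimates are compared on their own scale: |ref| when away
# from zero, the standard error when the estimate vanishes
rel_diff_beta <- function(x, ref, ref_se) abs(x - ref) / pmax(abs(ref), ref_se)

# write a small sumstats file in a given header convention
write_fixture <- function(df, headers, path = tempfile(fileext = ".tsv")) {
  names(df) <- headers
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_df <- function() {
  data.frame(
    snp = c("rs1", "rs2", "rs3"),
    a1 = c("A", "C", "T"),
    a2 = c("G", "T", "C"),
    beta = c(0.12, -0.05, 0.33),
    se = c(0.04, 0.1, 0.21),
    p = c(0.0027, 0.617, 0.116),
    stringsAsFactors = FALSE
  )
}
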