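# Shared fixtures built in code.

# Minimal harmonized-pairs table from raw vectors.
make_pairs <- function(bx, by, se_x = 0.01, se_y = 0.05,
                       ids = paste0("rs", seq_along(bx))) {
  data.frame(variant_id = ids, beta_exp = bx,
             se_exp = rep_len(se_x, length(bx)),
             beta_out = by, se_out = rep_len(se_y, length(bx)),
             stringsAsFactors = FALSE)
}

# A well-formed summary-statistics data.frame.
make_sumstats <- function(n = 5, chrom = "1", pos = seq(1e6, by = 1000,
                                                        length.out = n),
                          beta = rep(0.1, n), se = rep(0.02, n),
                          eaf = rep(0.3, n), nn = rep(1000, n),
                          ea = rep("A", n), oa = rep("G", n),
                          ids = paste0("rs", seq_len(n))) {
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), n = nn,
             stringsAsFactors = FALSE)
}

# One simulated gene region ready for estimator tests: independent
# instruments, known causal effect, optional noise.
make_region <- function(causal_beta = 0.3, k = 5, n_exp = 50000,
                        n_out = 50000, seed = 1, noise = TRUE,
                        pleiotropy_mode = "none", pleiotropy_sd = 0,
                        pleiotropy_mean = 0) {
  truth <- sim_truth(causal_beta = causal_beta,
                     pleiotropy_mode = pleiotropy_mode,
                     pleiotropy_sd = pleiotropy_sd,
                     pleiotropy_mean = pleiotropy_mean,
                     n_exposure = n_exp, n_outcome = n_out, seed = seed)
  ld <- simulate_ld_matrix(k, rep(1, k), 0)
  e <- simulate_qtl_sumstats(truth, ld, n_causal = k, seed = seed,
                             noise = noise, palindrome_frac = 0)
  o <- simulate_outcome_gwas(truth, e, ld, seed = seed + 1000000L,
                             noise = noise)
  harmonize(e, o)
}
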