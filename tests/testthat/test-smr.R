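# Build a QTL/GWAS table pair with prescribed z-scores at the top variant.
smr_tables <- function(z_qtl, z_gwas, k = 1) {
  qtl <- make_sumstats(k, beta = z_qtl * 0.02, se = rep(0.02, k))
  gwas <- make_sumstats(k, beta = z_gwas * 0.03, se = rep(0.03, k))
  list(qtl = qtl, gwas = gwas)
}

test_that("the SMR statistic matches the chi-square oracle", {
  # z_qtl = 10, z_gwas = 2: T = 400/104, p from chi-square(1)
  tb <- smr_tables(10, 2)
  rec <- smr_test(tb$qtl, tb$gwas)
  t_oracle <- 400 / 104
  expect_equal(rec$p_smr, pchisq(t_oracle, 1, lower.tail = FALSE))
  expect_equal(rec$p_smr, 0.0498, tolerance = 2e-3)
  expect_lt(rec$p_smr, 0.05)
  expect_equal(rec$b_smr, rec$b_gwas / rec$b_qtl)
  expect_equal(rec$se_smr, abs(rec$b_smr) * sqrt(1 / 100 + 1 / 4))
  # z_gwas = 0: T = 0, p = 1
  tb0 <- smr_tables(10, 0)
  expect_equal(smr_test(tb0$qtl, tb0$gwas)$p_smr, 1)
  # enormous z_qtl: p_smr approaches the GWAS p
  tbl <- smr_tables(1e4, 2)
  expect_equal(smr_test(tbl$qtl, tbl$gwas)$p_smr, 2 * pnorm(-2),
               tolerance = 1e-4)
  expect_error(smr_test(smr_tables(0, 2)$qtl, tb$gwas), "QTL beta is 0")
  expect_error(smr_test(make_sumstats(2, ids = c("a", "b")),
                        make_sumstats(2, ids = c("c", "d"))),
               "empty variant intersection")
})

test_that("T_smr is symmetric and bounded by its weaker leg", {
  set.seed(16)
  z1 <- rnorm(500, 0, 4); z2 <- rnorm(500, 0, 4)
  t_fun <- function(a, b) a^2 * b^2 / (a^2 + b^2)
  expect_equal(t_fun(z1, z2), t_fun(z2, z1))
  expect_true(all(t_fun(z1, z2) <= pmin(z1^2, z2^2) + 1e-12))
  # symmetry through the full record computation
  tb <- smr_tables(3, 7)
  tb_sw <- smr_tables(7, 3)
  expect_equal(smr_test(tb$qtl, tb$gwas)$p_smr,
               smr_test(tb_sw$qtl, tb_sw$gwas)$p_smr)
})

test_that("HEIDI returns 1 for identical ratios in perfect LD", {
  k <- 6
  ids <- paste0("rs", 1:k)
  r <- matrix(1, k, k, dimnames = list(ids, ids))
  qtl <- make_sumstats(k, beta = rep(0.5, k), se = rep(0.02, k))
  gwas <- make_sumstats(k, beta = rep(0.1, k), se = rep(0.03, k))
  h <- heidi_test(qtl, gwas, ld_matrix(r))
  expect_equal(h$p_heidi, 1)
  expect_equal(h$n_snps, k - 1)
})

test_that("HEIDI needs three eligible variants and ignores labels", {
  truth <- sim_truth(causal_beta = 0.3, seed = 17)
  ld <- simulate_ld_matrix(15, 15, 0.9)
  qtl <- simulate_qtl_sumstats(truth, ld, n_causal = 1, causal_idx = 8,
                               effect_sd = 0.4, seed = 17,
                               palindrome_frac = 0)
  gwas <- simulate_outcome_gwas(truth, qtl, ld, seed = 18)
  h <- heidi_test(qtl, gwas, ld)
  expect_gte(h$n_snps, 3)
  expect_true(h$p_heidi >= 0 && h$p_heidi <= 1)
  # relabeling non-top variants leaves p invariant
  perm <- c(1:7, 9:15, 8)  # move rows around; ids travel with rows
  h_perm <- heidi_test(qtl[perm, ], gwas[perm, ], ld)
  expect_equal(h_perm$p_heidi, h$p_heidi)
  # too few eligible variants: NA, not an error
  weak <- qtl; weak$pval <- rep(0.5, 15); weak$pval[8] <- 1e-20
  expect_true(is.na(heidi_test(weak, gwas, ld)$p_heidi))
})

test_that("linkage scenarios yield lower HEIDI p than shared-causal ones", {
  # paired simulation: same seeds, one vs two causal variants
  reps <- 40
  p_single <- p_double <- numeric(reps)
  for (i in seq_len(reps)) {
    truth <- sim_truth(causal_beta = 0.4, n_exposure = 50000,
                       n_outcome = 50000, seed = 100 + i)
    ld <- simulate_ld_matrix(20, 20, 0.85)
    q1 <- simulate_qtl_sumstats(truth, ld, n_causal = 1, causal_idx = 10,
                                b_true = c(rep(0, 9), 0.5, rep(0, 10)),
                                seed = 100 + i, palindrome_frac = 0)
    g1 <- simulate_outcome_gwas(truth, q1, ld, seed = 500 + i)
    p_single[i] <- heidi_test(q1, g1, ld)$p_heidi
    # linkage: expression driven by variant 10, outcome driven by variant 3
    q2 <- q1
    b_out <- c(rep(0, 2), 0.5, rep(0, 17))
    g2 <- g1
    marg <- as.numeric(unclass(ld) %*% b_out) * 0.4
    se_o <- g1$se
    g2$beta <- marg + (g1$beta - attr(g1, "beta_marginal_true"))
    g2$pval <- 2 * pnorm(-abs(g2$beta / g2$se))
    p_double[i] <- heidi_test(q2, g2, ld)$p_heidi
  }
  expect_lt(median(p_double, na.rm = TRUE), median(p_single, na.rm = TRUE))
})

test_that("three-step mediation verdict follows its three conditions", {
  ld <- simulate_ld_matrix(12, 12, 0.8)
  tr <- sim_truth(mediation_chain = c(b_meth_expr = -1,
                                      b_expr_outcome = -0.6),
                  n_exposure = 50000, n_outcome = 50000, seed = 19)
  reg <- simulate_mediation_region(tr, ld, n_causal = 1, effect_sd = 0.6,
                                   seed = 19, noise = FALSE)
  verdict <- three_step_smr(reg$eqtl, reg$mqtl, reg$gwas, ld)
  expect_true(verdict$verdict)
  # (-) * (-) = + must match the step-2 sign
  expect_true(verdict$sign_chain_consistent)
  expect_equal(sign(verdict$steps$b_smr), c(-1, 1, -1))

  # a top variant short of genome-wide significance fails condition 2
  weak_tr <- sim_truth(mediation_chain = c(b_meth_expr = -1,
                                           b_expr_outcome = -0.05),
                       n_exposure = 50000, n_outcome = 3000, seed = 20)
  weak <- simulate_mediation_region(weak_tr, ld, n_causal = 1,
                                    effect_sd = 0.6, seed = 20,
                                    noise = FALSE)
  v_weak <- three_step_smr(weak$eqtl, weak$mqtl, weak$gwas, ld)
  expect_false(v_weak$gw_significant)
  expect_false(v_weak$verdict)
})

test_that("protein/transcript consistency requires credible records", {
  rec <- function(b, p_smr = 0.01, p_heidi = 0.5) {
    data.frame(b_smr = b, p_smr = p_smr, p_heidi = p_heidi)
  }
  expect_true(protein_consistency(rec(0.3), rec(0.2)))
  expect_false(protein_consistency(rec(0.3), rec(-0.2)))
  weak <- protein_consistency(rec(0.3), rec(0.2, p_smr = 0.2))
  expect_false(weak)
  expect_match(attr(weak, "reason"), "protein")
  heidi_fail <- protein_consistency(rec(0.3, p_heidi = 0.005), rec(0.2))
  expect_false(heidi_fail)
  expect_match(attr(heidi_fail, "reason"), "HEIDI")
})
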