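bh_brute_force <- function(p) {
  # O(m^2) step-up: adj_i = min over j with p_j >= p_i of m * p_j / rank_j
  m <- length(p)
  rank_p <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (rank_p[j] >= rank_p[i]) m * p[j] / rank_p[j] else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

test_that("multiplicity adjustments match oracles", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bh"), 0.01)
  expect_equal(adjust_pvalues(0.01, "qvalue"), 0.01)
  p4 <- c(0.01, 0.02, 0.03, 0.8)
  expect_equal(adjust_pvalues(p4, "bh"), c(0.04, 0.04, 0.04, 0.8))
  expect_equal(min(1, 1403 * 0.01),
               adjust_pvalues(rep(0.01, 1403), "bonferroni")[1])
  expect_error(adjust_pvalues(numeric(0)), "empty")
  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")
  # BH equals the brute-force step-up on random inputs
  set.seed(13)
  for (i in 1:5) {
    p <- runif(30)^2
    expect_equal(adjust_pvalues(p, "bh"), bh_brute_force(p))
  }
})

test_that("q-values never exceed BH-adjusted values", {
  set.seed(14)
  p <- c(runif(150)^3, runif(150))  # mixture: some signal, some null
  q <- adjust_pvalues(p, "qvalue")
  bh <- adjust_pvalues(p, "bh")
  expect_true(all(q <= bh + 1e-12))
  pi0 <- estimate_pi0(p)
  expect_gt(pi0, 0)
  expect_lte(pi0, 1)
  # with few p-values pi0 falls back to 1 and q-values equal BH
  expect_equal(adjust_pvalues(p[1:10], "qvalue"),
               adjust_pvalues(p[1:10], "bh"))
})

test_that("direction consistency follows the sign rule", {
  aux <- c(egger = 0.2, weighted_median = 0.1, weighted_mode = 0.3,
           raps = 0.25, max_likelihood = 0.22)
  expect_true(direction_consistency(0.3, aux))
  aux_neg <- aux; aux_neg["egger"] <- -0.1
  expect_false(direction_consistency(0.3, aux_neg))
  # beta exactly 0 matches nothing
  aux0 <- aux; aux0["raps"] <- 0
  expect_false(direction_consistency(0.3, aux0))
  expect_false(direction_consistency(0, aux))
  # missing methods: strict fails, lenient skips
  aux_na <- aux; aux_na["weighted_mode"] <- NA
  expect_false(direction_consistency(0.3, aux_na, strict = TRUE))
  expect_true(direction_consistency(0.3, aux_na, strict = FALSE))
})

test_that("meta-analysis pools by inverse variance and gates on I2", {
  # closed-form pooling oracle: equal studies
  m <- meta_analyze(0.3, 0.1, 0.3, 0.1)
  expect_equal(m$beta, 0.3)
  expect_equal(m$se, 0.1 / sqrt(2))
  expect_equal(m$i_squared, 0)
  expect_equal(m$model, "fixed")
  # convexity: pooled estimate between study estimates
  m2 <- meta_analyze(0.2, 0.05, 0.5, 0.12)
  expect_gt(m2$beta, 0.2); expect_lt(m2$beta, 0.5)
  # forced heterogeneity selects the random-effects model
  m3 <- meta_analyze(0.4, 0.01, -0.4, 0.01)
  expect_gte(m3$i_squared, 50)
  expect_equal(m3$model, "random")
  expect_error(meta_analyze(0.3, 0.1, NA, 0.1), "two complete")
  expect_error(meta_analyze(0.3, -0.1, 0.2, 0.1), "standard errors")
})

test_that("meta-analysis agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(15)
  for (i in 1:4) {
    b <- rnorm(2, 0.2, 0.2); se <- runif(2, 0.05, 0.2)
    ours <- meta_analyze(b[1], se[1], b[2], se[2])
    fe <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(ours$q, as.numeric(fe$QE), tolerance = 1e-8)
    if (ours$model == "fixed") {
      expect_equal(ours$beta, as.numeric(fe$beta), tolerance = 1e-8)
      expect_equal(ours$se, as.numeric(fe$se), tolerance = 1e-8)
    } else {
      re <- metafor::rma(yi = b, sei = se, method = "DL")
      expect_equal(ours$beta, as.numeric(re$beta), tolerance = 1e-8)
      expect_equal(ours$se, as.numeric(re$se), tolerance = 1e-8)
    }
  }
})

test_that("discovery pipeline calls the causal gene and only it", {
  study <- simulate_study(n_genes = 8, causal_genes = 3, causal_beta = 0.5,
                          seed = 42)
  v <- discover_targets(study$genes, n_boot = 50, seed = 42)
  expect_equal(nrow(v), 8)
  expect_true(v$final_call[v$gene_id == "GENE3"])
  expect_false(any(v$final_call[v$gene_id != "GENE3"]))
  # determinism: identical seed reproduces the verdict table exactly
  v2 <- discover_targets(study$genes, n_boot = 50, seed = 42)
  expect_identical(v, v2)
})

test_that("opposite-sign replication kills a discovery hit via the meta p", {
  study <- simulate_study(n_genes = 4, causal_genes = 2, causal_beta = 0.5,
                          seed = 7)
  g <- study$genes
  # flip the replication cohort's effects for the causal gene
  g[["GENE2"]]$gwas_replication$beta <- -g[["GENE2"]]$gwas_replication$beta
  v <- discover_targets(g, n_boot = 50, seed = 7)
  row <- v[v$gene_id == "GENE2", ]
  expect_true(row$passed_bonferroni)   # discovery signal intact
  expect_false(row$final_call)
  expect_gte(row$meta_pval, 0.05)
})

test_that("a failing gene is isolated, not fatal", {
  study <- simulate_study(n_genes = 3, causal_genes = 1, seed = 3)
  g <- study$genes
  # move gene 2's annotation far away: no instruments in its cis window
  g[["GENE2"]]$annotation$start <- 9e8
  g[["GENE2"]]$annotation$end <- 9e8 + 1000
  v <- discover_targets(g, n_boot = 20, seed = 3)
  expect_equal(nrow(v), 3)
  expect_false(v$final_call[2])
  expect_match(v$error[2], "instrument")
  expect_true(v$final_call[1])
})
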