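# Synthetic summary-statistics generator with known causal truth.
#
# Everything is simulated directly on the summary-statistic scale: marginal
# QTL effects under block LD (beta_marginal = R %*% beta_true), outcome
# effects on the log-odds scale as causal_beta * exposure effect plus an
# optional per-variant direct (pleiotropic) effect, with sampling noise
# whose covariance follows the LD correlation. Exposure and outcome samples
# are treated as non-overlapping two-sample designs.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for one simulated gene region
#'
#' Houses the causal effect and nuisance structure a simulation is built
#' from, so recovery tests can compare estimates with truth.
#'
#' @param gene_id gene label
#' @param causal_beta effect of the exposure on the outcome, log-odds per SD
#'   of the (standardized) molecular exposure
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects with mean
#'   zero) or `"directional"` (non-zero mean direct effects)
#' @param pleiotropy_sd SD of per-variant direct variant-to-outcome effects
#' @param pleiotropy_mean mean of direct effects; must be 0 unless
#'   `pleiotropy_mode = "directional"`
#' @param mediation_chain optional named numeric vector
#'   `c(b_meth_expr = ..., b_expr_outcome = ...)` for methylation-mediation
#'   scenarios
#' @param n_exposure,n_outcome sample sizes of the two (non-overlapping)
#'   studies
#' @param seed integer seed associated with this truth record
#' @return object of class `sim_truth`
#' @export
sim_truth <- function(gene_id = "GENE1", causal_beta = 0,
                      pleiotropy_mode = c("none", "balanced", "directional"),
                      pleiotropy_sd = 0, pleiotropy_mean = 0,
                      mediation_chain = NULL,
                      n_exposure = 31684, n_outcome = 272412, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (pleiotropy_mode %in% c("none", "balanced") && pleiotropy_mean != 0)
    stop("pleiotropy_mean must be 0 unless mode is 'directional'")
  if (pleiotropy_mode == "none" && pleiotropy_sd != 0)
    stop("pleiotropy_sd must be 0 when mode is 'none'")
  if (n_exposure < 2 || n_outcome < 2) stop("sample sizes must be >= 2")
  if (!is.null(mediation_chain)) {
    if (!all(c("b_meth_expr", "b_expr_outcome") %in% names(mediation_chain)))
      stop("mediation_chain needs b_meth_expr and b_expr_outcome")
  }
  structure(list(gene_id = gene_id, causal_beta = causal_beta,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 mediation_chain = mediation_chain,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate a block-structured LD correlation matrix
#'
#' Within each block the correlation decays as AR(1): `r_ij = rho^|i-j|`;
#' across blocks it is exactly zero. The construction is deterministic.
#'
#' @param n_variants total number of variants
#' @param block_sizes integer vector summing to `n_variants`
#' @param rho within-block adjacent correlation, in (-1, 1)
#' @param variant_ids optional ids; default `snp1..snpN`
#' @return `ld_matrix`
#' @export
simulate_ld_matrix <- function(n_variants, block_sizes = n_variants,
                               rho = 0.8, variant_ids = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sum(block_sizes) != n_variants)
    stop("block sizes must sum to n_variants")
  if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_len(n_variants))
  r <- matrix(0, n_variants, n_variants,
              dimnames = list(variant_ids, variant_ids))
  offset <- 0L
  for (b in block_sizes) {
    idx <- offset + seq_len(b)
    r[idx, idx] <- rho^abs(outer(seq_len(b), seq_len(b), "-"))
    offset <- offset + b
  }
  ld_matrix(r)
}

# Assign alleles and effect-allele frequencies; a `palindrome_frac` fraction
# of variants is forced palindromic (A/T or C/G) with frequency near 0.5 to
# exercise the ambiguity filter downstream.
assign_alleles <- function(n, palindrome_frac) {
  non_pal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- stats::runif(n) < palindrome_frac
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    pair <- if (is_pal[i]) pal[[sample.int(4, 1)]] else non_pal[[sample.int(8, 1)]]
    ea[i] <- pair[1]; oa[i] <- pair[2]
  }
  eaf <- ifelse(is_pal, stats::runif(n, 0.45, 0.55), stats::runif(n, 0.05, 0.95))
  list(effect_allele = ea, other_allele = oa, eaf = eaf)
}

# Correlated sampling noise: L z scaled per-variant, cov = se_i se_j r_ij.
# Independent variants short-circuit the Cholesky factorization.
ld_noise <- function(ld, se) {
  r <- unclass(ld)
  if (all(r[lower.tri(r)] == 0)) return(stats::rnorm(nrow(r)) * se)
  ch <- chol(r + diag(1e-10, nrow(r)))
  as.numeric(crossprod(ch, stats::rnorm(nrow(r)))) * se
}

#' Simulate cis-QTL summary statistics for a molecular exposure
#'
#' True per-variant effects are drawn for `n_causal` randomly placed causal
#' variants (N(0, `effect_sd`^2), zero elsewhere); marginal effects are
#' `R %*% b_true` under the LD matrix `R`. The exposure is standardized, so
#' standard errors are `1/sqrt(n_exposure)` and sampling noise (optional)
#' has covariance `se_i se_j r_ij`. P-values come from the normal
#' approximation.
#'
#' @param truth `sim_truth`
#' @param ld `ld_matrix` for the region
#' @param n_causal number of causal variants (may be 0)
#' @param effect_sd SD of true causal per-allele effects
#' @param seed integer seed
#' @param noise simulate sampling noise? `FALSE` returns exact marginals
#' @param palindrome_frac fraction of variants forced palindromic
#' @param chrom,region_start chromosome label and 1-based start of the
#'   simulated region; variants are spaced 1 kb apart
#' @param causal_idx optional explicit indices of causal variants
#' @param b_true optional explicit vector of true per-variant effects
#'   (overrides `n_causal`/`effect_sd`)
#' @return summary-statistics data.frame with attributes
#'   `beta_marginal_true` (noise-free marginals), `b_true` and `truth`
#' @export
simulate_qtl_sumstats <- function(truth, ld, n_causal = 1, effect_sd = 0.15,
                                  seed = truth$seed, noise = TRUE,
                                  palindrome_frac = 0.1, chrom = "1",
                                  region_start = 1e6, causal_idx = NULL,
                                  b_true = NULL) {
  m <- nrow(ld)
  if (is.null(b_true) && n_causal > m) stop("n_causal exceeds n_variants")
  with_seed(seed, {
    if (is.null(b_true)) {
      b_true <- numeric(m)
      if (n_causal > 0) {
        if (is.null(causal_idx)) causal_idx <- sample.int(m, n_causal)
        b_true[causal_idx] <- stats::rnorm(n_causal, 0, effect_sd)
      }
    }
    beta_marg <- as.numeric(unclass(ld) %*% b_true)
    se <- rep(1 / sqrt(truth$n_exposure), m)
    al <- assign_alleles(m, palindrome_frac)
    beta <- beta_marg
    if (noise) beta <- beta + ld_noise(ld, se)
    out <- data.frame(
      variant_id = rownames(ld), chrom = chrom,
      pos = region_start + 1000 * (seq_len(m) - 1),
      effect_allele = al$effect_allele, other_allele = al$other_allele,
      eaf = al$eaf, beta = beta, se = se,
      pval = p_from_z(beta / se), n = truth$n_exposure,
      stringsAsFactors = FALSE)
    attr(out, "beta_marginal_true") <- beta_marg
    attr(out, "b_true") <- b_true
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate outcome GWAS summary statistics for a binary trait
#'
#' The marginal outcome effect of variant j is
#' `causal_beta * beta_exposure_j + (R alpha)_j` on the log-odds scale,
#' where `alpha` are per-variant direct (pleiotropic) effects drawn
#' according to the truth's pleiotropy mode, plus optional sampling noise.
#' Standard errors follow the case-control scale
#' `1/sqrt(n_outcome * phi * (1 - phi))` with case fraction `phi`.
#'
#' @param truth `sim_truth`
#' @param exposure_table table from [simulate_qtl_sumstats()]; its noise-free
#'   marginal effects (attribute) define the exposure side of the truth
#' @param ld `ld_matrix`; must match the exposure table's variants
#' @param seed integer seed
#' @param noise simulate sampling noise?
#' @param case_fraction case proportion `phi` of the outcome study
#' @return summary-statistics data.frame with attributes
#'   `beta_marginal_true`, `alpha` (direct effects) and `truth`
#' @export
simulate_outcome_gwas <- function(truth, exposure_table, ld,
                                  seed = truth$seed + 1L, noise = TRUE,
                                  case_fraction = 0.1) {
  m <- nrow(ld)
  if (!identical(exposure_table$variant_id, rownames(ld)))
    stop("variant sets of exposure table and LD matrix do not match")
  bx_true <- attr(exposure_table, "beta_marginal_true")
  if (is.null(bx_true)) bx_true <- exposure_table$beta
  with_seed(seed, {
    alpha <- switch(truth$pleiotropy_mode,
      none = numeric(m),
      balanced = stats::rnorm(m, 0, truth$pleiotropy_sd),
      directional = stats::rnorm(m, truth$pleiotropy_mean, truth$pleiotropy_sd))
    beta_marg <- truth$causal_beta * bx_true +
      as.numeric(unclass(ld) %*% alpha)
    v <- case_fraction * (1 - case_fraction)
    se <- rep(1 / sqrt(truth$n_outcome * v), m)
    beta <- beta_marg
    if (noise) beta <- beta + ld_noise(ld, se)
    out <- exposure_table[, c("variant_id", "chrom", "pos", "effect_allele",
                              "other_allele", "eaf")]
    out$beta <- beta
    out$se <- se
    out$pval <- p_from_z(beta / se)
    out$n <- truth$n_outcome
    attr(out, "beta_marginal_true") <- beta_marg
    attr(out, "alpha") <- alpha
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a methylation -> expression -> outcome mediation region
#'
#' Methylation marginal effects are generated first; expression effects are
#' `b_meth_expr` times the methylation effects (plus optional noise) and
#' outcome effects `b_expr_outcome` times the expression effects, so with
#' noise off the ratio of outcome to methylation marginals is exactly the
#' chain product at every variant.
#'
#' @param truth `sim_truth` with `mediation_chain` set
#' @param ld `ld_matrix`
#' @param n_causal,effect_sd,palindrome_frac passed to the methylation QTL
#'   stage
#' @param seed integer seed
#' @param noise simulate sampling noise in all three tables?
#' @param case_fraction case proportion for the outcome study
#' @return list with elements `mqtl`, `eqtl`, `gwas` (shared variants) and
#'   `truth`
#' @export
simulate_mediation_region <- function(truth, ld, n_causal = 1,
                                      effect_sd = 0.3, seed = truth$seed,
                                      noise = TRUE, palindrome_frac = 0,
                                      case_fraction = 0.1) {
  if (is.null(truth$mediation_chain)) stop("truth$mediation_chain must be set")
  b_me <- truth$mediation_chain[["b_meth_expr"]]
  b_eo <- truth$mediation_chain[["b_expr_outcome"]]
  m <- nrow(ld)
  mqtl <- simulate_qtl_sumstats(truth, ld, n_causal = n_causal,
                                effect_sd = effect_sd, seed = seed,
                                noise = noise,
                                palindrome_frac = palindrome_frac)
  meth_marg <- attr(mqtl, "beta_marginal_true")
  with_seed(seed + 1L, {
    expr_marg <- b_me * meth_marg
    se_e <- rep(1 / sqrt(truth$n_exposure), m)
    beta_e <- expr_marg
    if (noise) beta_e <- beta_e + ld_noise(ld, se_e)
    eqtl <- mqtl
    eqtl$beta <- beta_e
    eqtl$se <- se_e
    eqtl$pval <- p_from_z(beta_e / se_e)
    attr(eqtl, "beta_marginal_true") <- expr_marg
    out_marg <- b_eo * expr_marg
    v <- case_fraction * (1 - case_fraction)
    se_o <- rep(1 / sqrt(truth$n_outcome * v), m)
    beta_o <- out_marg
    if (noise) beta_o <- beta_o + ld_noise(ld, se_o)
    gwas <- mqtl
    gwas$beta <- beta_o
    gwas$se <- se_o
    gwas$pval <- p_from_z(beta_o / se_o)
    gwas$n <- truth$n_outcome
    attr(gwas, "beta_marginal_true") <- out_marg
    chain <- truth
    chain$chain_signs <- c(meth_expr = sign(b_me), expr_outcome = sign(b_eo),
                           meth_outcome = sign(b_me * b_eo))
    list(mqtl = mqtl, eqtl = eqtl, gwas = gwas, truth = chain)
  })
}

#' Simulate a multi-gene two-cohort study with known truth
#'
#' Convenience generator for pipeline-level tests: per gene, one LD region,
#' a cis-eQTL exposure table, and outcome GWAS tables for a discovery and an
#' independent replication cohort sharing the same causal truth.
#'
#' @param n_genes number of genes
#' @param causal_genes indices (or names) of genes given a non-zero causal
#'   effect
#' @param causal_beta causal effect for those genes (log-odds per SD)
#' @param n_variants,block_sizes,rho LD region layout per gene
#' @param n_causal causal eQTL variants per gene
#' @param effect_sd SD of true eQTL effects
#' @param n_exposure,n_discovery,n_replication sample sizes
#' @param case_fraction case proportion of both outcome cohorts
#' @param palindrome_frac fraction of palindromic variants
#' @param seed integer master seed; per-gene seeds are derived from it
#' @return list with `genes` (per gene: `annotation`, `ld`, `eqtl`,
#'   `gwas_discovery`, `gwas_replication`, `truth`) and `truth_table`
#' @export
simulate_study <- function(n_genes = 10, causal_genes = 1, causal_beta = 0.5,
                           n_variants = 30, block_sizes = c(10, 10, 10),
                           rho = 0.7, n_causal = 6, effect_sd = 0.15,
                           n_exposure = 100000, n_discovery = 100000,
                           n_replication = 100000, case_fraction = 0.1,
                           palindrome_frac = 0.05, seed = 1L) {
  genes <- vector("list", n_genes)
  names(genes) <- paste0("GENE", seq_len(n_genes))
  is_causal <- seq_len(n_genes) %in% causal_genes |
    names(genes) %in% causal_genes
  for (g in seq_len(n_genes)) {
    # per-gene seed, folded to stay within the 32-bit integer range
    gseed <- (as.integer(seed) %% 2000000L) * 1000L + g
    ids <- paste0("g", g, "_snp", seq_len(n_variants))
    ld <- simulate_ld_matrix(n_variants, block_sizes, rho, variant_ids = ids)
    truth_d <- sim_truth(gene_id = names(genes)[g],
                         causal_beta = if (is_causal[g]) causal_beta else 0,
                         n_exposure = n_exposure, n_outcome = n_discovery,
                         seed = gseed)
    region_start <- 1e6 * g
    eqtl <- simulate_qtl_sumstats(truth_d, ld, n_causal = n_causal,
                                  effect_sd = effect_sd, seed = gseed,
                                  palindrome_frac = palindrome_frac,
                                  chrom = "1", region_start = region_start)
    gwas_d <- simulate_outcome_gwas(truth_d, eqtl, ld, seed = gseed + 1L,
                                    case_fraction = case_fraction)
    truth_r <- truth_d
    truth_r$n_outcome <- n_replication
    gwas_r <- simulate_outcome_gwas(truth_r, eqtl, ld, seed = gseed + 2L,
                                    case_fraction = case_fraction)
    ann <- gene_annotation(names(genes)[g], "1",
                           start = region_start + 5000,
                           end = region_start + 1000 * (n_variants - 1) - 5000)
    genes[[g]] <- list(annotation = ann, ld = ld, eqtl = eqtl,
                       gwas_discovery = gwas_d, gwas_replication = gwas_r,
                       truth = truth_d)
  }
  truth_table <- data.frame(gene_id = names(genes),
                            causal_beta = ifelse(is_causal, causal_beta, 0),
                            stringsAsFactors = FALSE)
  list(genes = genes, truth_table = truth_table)
}
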