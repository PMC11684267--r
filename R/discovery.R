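# Gene-level discovery: multiplicity gates, direction robustness,
# replication, meta-analysis, and the end-to-end pipeline.

#' Estimate the null proportion pi0 from a p-value vector
#'
#' The lambda-grid estimator: `pi0(lambda) = mean(p > lambda) /
#' (1 - lambda)` on `lambda = 0.05, 0.10, ..., 0.95`, smoothed with a cubic
#' spline and read off at the largest lambda, clamped to (0, 1]. With fewer
#' than 20 p-values the estimate is unstable and 1 is returned
#' (conservative: q-values then equal BH).
#'
#' @param p p-values in (0, 1]
#' @return estimated null proportion in (0, 1]
#' @export
estimate_pi0 <- function(p) {
  m <- length(p)
  if (m < 20) return(1)
  lambda <- seq(0.05, 0.95, 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(1, max(pi0, 1 / m))
}

#' Multiplicity adjustment of p-values
#'
#' `bonferroni` and `bh` delegate to [stats::p.adjust()]; `qvalue` is the
#' FDR q-value `pi0_hat * BH`, with `pi0` estimated by [estimate_pi0()]
#' (so q-values are never larger than BH-adjusted values).
#'
#' @param p p-values in (0, 1]
#' @param method `"bonferroni"`, `"bh"` or `"qvalue"`
#' @return adjusted values, same length and order as `p`
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "qvalue")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  switch(method,
         bonferroni = stats::p.adjust(p, "bonferroni"),
         bh = stats::p.adjust(p, "BH"),
         qvalue = pmin(1, estimate_pi0(p) * stats::p.adjust(p, "BH")))
}

#' Direction agreement of auxiliary estimators with IVW
#'
#' `TRUE` iff the sign of every auxiliary causal estimate equals the sign
#' of the IVW estimate. A beta of exactly 0 has no direction and counts as
#' inconsistent. Missing auxiliary estimates (e.g. too few instruments)
#' fail the check under `strict = TRUE` (default) or are skipped otherwise.
#'
#' @param beta_ivw IVW (or Wald-ratio) estimate
#' @param beta_aux named numeric vector of auxiliary estimates
#' @param strict fail on missing auxiliary estimates?
#' @return logical
#' @export
direction_consistency <- function(beta_ivw, beta_aux, strict = TRUE) {
  if (is.na(beta_ivw) || sign(beta_ivw) == 0) return(FALSE)
  miss <- is.na(beta_aux)
  if (any(miss)) {
    if (strict) return(FALSE)
    beta_aux <- beta_aux[!miss]
  }
  if (!length(beta_aux)) return(!strict)
  all(sign(beta_aux) == sign(beta_ivw))
}

#' Two-study meta-analysis with I-squared-gated model choice
#'
#' Inverse-variance fixed-effect pooling of the two cohort estimates;
#' Cochran's Q on 1 df gives `I^2 = max(0, (Q - 1)/Q) * 100`. If
#' `I^2 < 50` the fixed-effects result is reported, otherwise
#' DerSimonian-Laird random effects.
#'
#' @param b1,se1 discovery estimate and SE
#' @param b2,se2 replication estimate and SE
#' @return list with `beta`, `se`, `pval`, `q`, `i_squared`, `model`
#' @export
meta_analyze <- function(b1, se1, b2, se2) {
  if (any(is.na(c(b1, se1, b2, se2)))) stop("meta-analysis requires two complete estimates")
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be > 0")
  b <- c(b1, b2); w <- 1 / c(se1, se2)^2
  beta_fe <- sum(w * b) / sum(w)
  q <- sum(w * (b - beta_fe)^2)
  i2 <- max(0, (q - 1) / q) * 100
  if (!is.finite(i2)) i2 <- 0
  if (i2 < 50) {
    beta <- beta_fe; se <- sqrt(1 / sum(w)); model <- "fixed"
  } else {
    tau2 <- max(0, (q - 1) / (sum(w) - sum(w^2) / sum(w)))
    w_r <- 1 / (1 / w + tau2)
    beta <- sum(w_r * b) / sum(w_r); se <- sqrt(1 / sum(w_r)); model <- "random"
  }
  list(beta = beta, se = se, pval = p_from_z(beta / se), q = q,
       i_squared = i2, model = model)
}

aux_methods <- c("egger", "weighted_median", "weighted_mode", "raps",
                 "max_likelihood")

fit_one_gene <- function(gene, window_bp, fdr, f_min, r2_threshold,
                         radial_alpha, n_boot, seed) {
  inst <- build_instruments(gene$eqtl, gene$annotation, gene$ld,
                            window_bp = window_bp, fdr = fdr, f_min = f_min,
                            r2_threshold = r2_threshold)
  if (!nrow(inst)) stop("no instruments survive filtering")
  harm_d <- harmonize(inst, gene$gwas_discovery)
  pairs_d <- kept_pairs(harm_d)
  if (!nrow(pairs_d)) stop("no harmonized pairs in discovery cohort")
  if (nrow(pairs_d) >= 3 && !is.null(radial_alpha)) {
    rad <- mr_radial(pairs_d, alpha = radial_alpha)
    drop <- pairs_d$variant_id %in% rad$outliers
    if (any(drop) && sum(!drop) >= 1) pairs_d <- pairs_d[!drop, , drop = FALSE]
  } else rad <- NULL
  fit_d <- mr_fit(pairs_d, n_boot = n_boot, seed = seed,
                  gene_id = gene$annotation$gene_id)
  harm_r <- harmonize(inst[inst$variant_id %in% pairs_d$variant_id, ,
                           drop = FALSE], gene$gwas_replication)
  pairs_r <- kept_pairs(harm_r)
  if (!nrow(pairs_r)) stop("no harmonized pairs in replication cohort")
  fit_r <- if (nrow(pairs_r) >= 2) mr_ivw(pairs_r) else mr_wald_ratio(pairs_r)
  loo_flag <- if (nrow(pairs_d) >= 3)
    any(mr_leave_one_out(pairs_d)$flagged) else NA
  list(fit_discovery = fit_d, fit_replication = fit_r, radial = rad,
       loo_flagged = loo_flag, k = nrow(pairs_d))
}

#' Run the full per-gene discovery pipeline over a study
#'
#' For every gene: instrument construction (cis window, FDR prefilter,
#' weak-instrument exclusion, LD clumping), harmonization against the
#' discovery GWAS, Radial-MR outlier removal with refit, the estimator
#' battery with sensitivity diagnostics, then — across genes — the three
#' multiplicity gates (Bonferroni, BH, q-value, all required below
#' `alpha`), the direction-consistency check, replication IVW in the
#' second cohort and the I-squared-gated meta-analysis. A gene's
#' `final_call` is `TRUE` iff all three gates pass, the five auxiliary
#' estimators agree in direction with IVW, and the meta-analysis p is
#' below `alpha`. One gene's failure (e.g. no surviving instruments) does
#' not abort the run; the gene is reported with `final_call = FALSE` and
#' the error message.
#'
#' @param genes named list, one element per gene, each with `annotation`,
#'   `ld`, `eqtl`, `gwas_discovery`, `gwas_replication` (the layout of
#'   [simulate_study()]`$genes`)
#' @param alpha significance level for gates and meta-analysis
#' @param window_bp,fdr,f_min,r2_threshold instrument-building parameters
#' @param radial_alpha Radial-MR outlier level (`NULL` disables removal)
#' @param gate_rule `"all"` (every multiplicity gate must pass) or `"any"`
#' @param strict_direction treatment of missing auxiliary estimators in the
#'   direction check
#' @param n_boot bootstrap replicates for median/mode SEs per gene
#' @param seed master seed; per-gene seeds are derived deterministically
#' @return data.frame of class `gene_verdicts`, one row per gene, with the
#'   discovery estimate, gate booleans, replication and meta-analysis
#'   columns and `final_call`
#' @export
discover_targets <- function(genes, alpha = 0.05, window_bp = 100000,
                             fdr = 0.05, f_min = 10, r2_threshold = 0.1,
                             radial_alpha = 0.05,
                             gate_rule = c("all", "any"),
                             strict_direction = TRUE, n_boot = 100,
                             seed = 1L) {
  gate_rule <- match.arg(gate_rule)
  stopifnot(length(genes) >= 1)
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, function(g) g$annotation$gene_id, character(1))
  fits <- vector("list", length(genes))
  errors <- rep(NA_character_, length(genes))
  for (i in seq_along(genes)) {
    fits[[i]] <- tryCatch(
      fit_one_gene(genes[[i]], window_bp, fdr, f_min, r2_threshold,
                   radial_alpha, n_boot, seed = seed + i),
      error = function(e) { errors[i] <<- conditionMessage(e); NULL })
  }
  rows <- lapply(seq_along(genes), function(i) {
    f <- fits[[i]]
    if (is.null(f))
      return(data.frame(gene_id = names(genes)[i], k = NA_integer_,
                        beta_ivw = NA_real_, se_ivw = NA_real_,
                        pval_ivw = NA_real_, q_pval = NA_real_,
                        egger_intercept_pval = NA_real_,
                        direction_consistent = FALSE,
                        beta_repl = NA_real_, se_repl = NA_real_,
                        pval_repl = NA_real_, meta_beta = NA_real_,
                        meta_se = NA_real_, meta_pval = NA_real_,
                        i_squared = NA_real_, meta_model = NA_character_,
                        loo_flagged = NA, error = errors[i],
                        stringsAsFactors = FALSE))
    p <- primary_row(f$fit_discovery)
    est <- f$fit_discovery$estimates
    aux <- stats::setNames(rep(NA_real_, length(aux_methods)), aux_methods)
    for (m in intersect(est$method, aux_methods))
      aux[m] <- est$beta[est$method == m]
    meta <- meta_analyze(p$beta, p$se, f$fit_replication$beta,
                         f$fit_replication$se)
    eg <- est[est$method == "egger", , drop = FALSE]
    data.frame(gene_id = names(genes)[i], k = p$k,
               beta_ivw = p$beta, se_ivw = p$se, pval_ivw = p$pval,
               q_pval = if ("q_pval" %in% names(p)) p$q_pval else NA_real_,
               egger_intercept_pval = if (nrow(eg)) eg$intercept_pval else NA_real_,
               direction_consistent = direction_consistency(p$beta, aux,
                                                            strict_direction),
               beta_repl = f$fit_replication$beta,
               se_repl = f$fit_replication$se,
               pval_repl = f$fit_replication$pval,
               meta_beta = meta$beta, meta_se = meta$se,
               meta_pval = meta$pval, i_squared = meta$i_squared,
               meta_model = meta$model, loo_flagged = f$loo_flagged,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$pval_ivw)
  out$bonferroni <- out$bh <- out$qvalue <- NA_real_
  if (any(ok)) {
    out$bonferroni[ok] <- adjust_pvalues(out$pval_ivw[ok], "bonferroni")
    out$bh[ok] <- adjust_pvalues(out$pval_ivw[ok], "bh")
    out$qvalue[ok] <- adjust_pvalues(out$pval_ivw[ok], "qvalue")
  }
  gates <- cbind(passed_bonferroni = out$bonferroni < alpha,
                 passed_bh = out$bh < alpha,
                 passed_qvalue = out$qvalue < alpha)
  gates[is.na(gates)] <- FALSE
  out <- cbind(out, gates)
  gate_ok <- if (gate_rule == "all") rowSums(gates) == 3 else rowSums(gates) > 0
  out$final_call <- gate_ok & out$direction_consistent &
    !is.na(out$meta_pval) & out$meta_pval < alpha
  rownames(out) <- NULL
  class(out) <- c("gene_verdicts", class(out))
  out
}
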