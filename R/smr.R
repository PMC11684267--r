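# Summary-data-based MR (SMR), the HEIDI linkage test, the three-step
# methylation mediation analysis, and transcript/protein direction
# consistency.

shared_region <- function(qtl, gwas) {
  shared <- intersect(qtl$variant_id, gwas$variant_id)
  if (!length(shared)) stop("empty variant intersection between QTL and GWAS")
  list(qtl = qtl[match(shared, qtl$variant_id), , drop = FALSE],
       gwas = gwas[match(shared, gwas$variant_id), , drop = FALSE],
       ids = shared)
}

#' SMR association test
#'
#' At the top QTL variant (smallest QTL p-value), the SMR effect is
#' `b_smr = b_gwas / b_qtl` with
#' `se_smr = |b_smr| * sqrt(1/z_qtl^2 + 1/z_gwas^2)`, and the test
#' statistic is `T_smr = z_qtl^2 * z_gwas^2 / (z_qtl^2 + z_gwas^2)`,
#' referred to chi-square with 1 df. The statistic is symmetric in the two
#' z-scores and never exceeds the weaker of them squared.
#'
#' @param qtl,gwas summary-statistics tables sharing (harmonized) variants
#' @param probe_id optional probe/gene/protein label for the record
#' @return one-row data.frame (`smr_record`): `probe_id`, `top_snp`,
#'   `b_qtl`, `se_qtl`, `p_qtl`, `b_gwas`, `se_gwas`, `p_gwas`, `b_smr`,
#'   `se_smr`, `p_smr`
#' @export
smr_test <- function(qtl, gwas, probe_id = NA_character_) {
  r <- shared_region(qtl, gwas)
  top <- which.min(r$qtl$pval)
  b_qtl <- r$qtl$beta[top]; se_qtl <- r$qtl$se[top]
  b_gwas <- r$gwas$beta[top]; se_gwas <- r$gwas$se[top]
  if (b_qtl == 0) stop("top-variant QTL beta is 0: SMR ratio undefined")
  z_qtl <- b_qtl / se_qtl; z_gwas <- b_gwas / se_gwas
  t_smr <- if (z_qtl == 0 && z_gwas == 0) 0 else
    z_qtl^2 * z_gwas^2 / (z_qtl^2 + z_gwas^2)
  b_smr <- b_gwas / b_qtl
  # z_gwas = 0 makes b_smr = 0; the delta-method SE then degenerates to the
  # first-order Wald-ratio form se_gwas / |b_qtl|
  se_smr <- if (z_gwas == 0) se_gwas / abs(b_qtl) else
    abs(b_smr) * sqrt(1 / z_qtl^2 + 1 / z_gwas^2)
  data.frame(probe_id = probe_id, top_snp = r$ids[top],
             b_qtl = b_qtl, se_qtl = se_qtl, p_qtl = r$qtl$pval[top],
             b_gwas = b_gwas, se_gwas = se_gwas, p_gwas = r$gwas$pval[top],
             b_smr = b_smr, se_smr = se_smr,
             p_smr = stats::pchisq(t_smr, 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (the SMR ratio is the same
#' at every variant in LD with the top one) from distinct causal variants
#' in linkage (ratios differ). For each eligible variant i (QTL p below
#' `p_qtl_threshold`, i.e. z^2 > ~10; top variant excluded; at most
#' `max_snps` strongest), `d_i = b_smr(i) - b_smr(top)`; the covariance of
#' `d` follows from the LD correlations and per-variant z-scores by the
#' delta method. The default test statistic is the sum of squared
#' standardized d's with a Satterthwaite (moment-matched scaled
#' chi-square) tail; `method = "quadform"` uses the quadratic form
#' `d' V^-1 d` (chi-square, m df) with an eigenvalue floor for
#' near-collinear LD. A high p supports a shared causal variant
#' (pleiotropy); a low p indicates linkage.
#'
#' @param qtl,gwas summary-statistics tables sharing harmonized variants
#' @param ld `ld_matrix` covering the shared variants
#' @param p_qtl_threshold eligibility threshold on the QTL p-value
#' @param min_snps minimum eligible variants; below it `p_heidi` is NA
#' @param max_snps cap on eligible variants (strongest QTL p first)
#' @param method `"satterthwaite"` or `"quadform"`
#' @param eig_floor eigenvalue floor used by `"quadform"`
#' @return list with `p_heidi` (NA when not estimable) and `n_snps` used
#' @export
heidi_test <- function(qtl, gwas, ld, p_qtl_threshold = 1.57e-3,
                       min_snps = 3, max_snps = 20,
                       method = c("satterthwaite", "quadform"),
                       eig_floor = 1e-8) {
  method <- match.arg(method)
  r <- shared_region(qtl, gwas)
  keep <- intersect(r$ids, rownames(ld))
  r$qtl <- r$qtl[match(keep, r$qtl$variant_id), , drop = FALSE]
  r$gwas <- r$gwas[match(keep, r$gwas$variant_id), , drop = FALSE]
  r$ids <- keep
  top <- which.min(r$qtl$pval)
  elig <- which(r$qtl$pval < p_qtl_threshold & seq_along(r$ids) != top)
  if (length(elig) > max_snps)
    elig <- elig[order(r$qtl$pval[elig])][seq_len(max_snps)]
  if (length(elig) < min_snps)
    return(list(p_heidi = NA_real_, n_snps = length(elig)))
  idx <- c(top, elig)
  z_q <- (r$qtl$beta / r$qtl$se)[idx]
  z_g <- (r$gwas$beta / r$gwas$se)[idx]
  b_smr <- (r$gwas$beta / r$qtl$beta)[idx]
  rr <- unclass(ld)[r$ids[idx], r$ids[idx], drop = FALSE]
  m <- length(idx)
  # cov(b_smr_i, b_smr_j) by the delta method, QTL and GWAS samples
  # independent, sampling correlation r_ij on both legs
  cov_smr <- outer(b_smr, b_smr) * rr *
    (outer(1 / z_g, 1 / z_g) + outer(1 / z_q, 1 / z_q))
  i_el <- 2:m
  v <- cov_smr[i_el, i_el, drop = FALSE] -
    matrix(cov_smr[i_el, 1], m - 1, m - 1) -
    t(matrix(cov_smr[i_el, 1], m - 1, m - 1)) + cov_smr[1, 1]
  d <- b_smr[i_el] - b_smr[1]
  if (method == "quadform") {
    e <- eigen((v + t(v)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, eig_floor)
    stat <- sum((crossprod(e$vectors, d))^2 / vals)
    p <- stats::pchisq(stat, df = m - 1, lower.tail = FALSE)
  } else {
    sd_d <- sqrt(pmax(diag(v), 1e-300))
    z_d <- d / sd_d
    cmat <- v / outer(sd_d, sd_d)
    cmat[!is.finite(cmat)] <- 0
    diag(cmat) <- 1
    stat <- sum(z_d^2)
    e_s <- m - 1
    var_s <- 2 * sum(cmat^2)
    a <- var_s / (2 * e_s)
    df <- 2 * e_s^2 / var_s
    p <- stats::pchisq(stat / a, df = df, lower.tail = FALSE)
  }
  list(p_heidi = p, n_snps = m - 1)
}

#' SMR with HEIDI for one probe
#'
#' Convenience wrapper returning the SMR record with `p_heidi` and
#' `n_heidi_snps` attached.
#'
#' @inheritParams smr_test
#' @inheritParams heidi_test
#' @return one-row data.frame
#' @export
smr_with_heidi <- function(qtl, gwas, ld, probe_id = NA_character_, ...) {
  rec <- smr_test(qtl, gwas, probe_id = probe_id)
  h <- heidi_test(qtl, gwas, ld, ...)
  rec$p_heidi <- h$p_heidi
  rec$n_heidi_snps <- h$n_snps
  rec
}

#' Three-step SMR methylation-mediation analysis
#'
#' Tests whether a gene's causal effect on the outcome is mediated by DNA
#' methylation in its region: (1) gene expression as exposure, outcome as
#' outcome; (2) CpG methylation as exposure, outcome as outcome; (3) CpG
#' methylation as exposure, gene expression as outcome. The candidate
#' passes (`verdict`) iff all three SMR p-values are below `p_smr_max`,
#' the top variants are genome-wide significant (`p < gw_threshold`) on
#' both legs of every step, and every available HEIDI p exceeds
#' `p_heidi_min`. The mediation sign chain — sign(step3) * sign(step1)
#' agreeing with sign(step2) — is reported alongside.
#'
#' @param gene_eqtl,cpg_mqtl,gwas summary-statistics tables over a shared
#'   region
#' @param ld `ld_matrix` for the region
#' @param p_smr_max SMR significance threshold, default 0.05
#' @param gw_threshold genome-wide significance threshold, default 5e-8
#' @param p_heidi_min HEIDI pass threshold, default 0.01
#' @param heidi_na `"fail"` (default, conservative) or `"pass"`: how an
#'   unestimable HEIDI p (too few eligible variants) counts
#' @param ... further arguments to [heidi_test()]
#' @return list of class `mediation_verdict`: `steps` (3-row data.frame),
#'   `gw_significant`, `heidi_pass`, `sign_chain_consistent`, `verdict`
#' @export
three_step_smr <- function(gene_eqtl, cpg_mqtl, gwas, ld, p_smr_max = 0.05,
                           gw_threshold = 5e-8, p_heidi_min = 0.01,
                           heidi_na = c("fail", "pass"), ...) {
  heidi_na <- match.arg(heidi_na)
  s1 <- smr_with_heidi(gene_eqtl, gwas, ld, probe_id = "gene_to_outcome", ...)
  s2 <- smr_with_heidi(cpg_mqtl, gwas, ld, probe_id = "cpg_to_outcome", ...)
  s3 <- smr_with_heidi(cpg_mqtl, gene_eqtl, ld, probe_id = "cpg_to_gene", ...)
  steps <- rbind(s1, s2, s3)
  smr_pass <- all(steps$p_smr < p_smr_max)
  gw_significant <- all(steps$p_qtl < gw_threshold) &&
    all(steps$p_gwas < gw_threshold)
  hp <- steps$p_heidi
  heidi_pass <- if (any(is.na(hp)))
    (heidi_na == "pass") && all(hp[!is.na(hp)] > p_heidi_min)
  else all(hp > p_heidi_min)
  sign_chain <- sign(s3$b_smr) * sign(s1$b_smr) == sign(s2$b_smr)
  structure(list(steps = steps, gw_significant = gw_significant,
                 heidi_pass = heidi_pass,
                 sign_chain_consistent = sign_chain,
                 verdict = smr_pass && gw_significant && heidi_pass),
            class = "mediation_verdict")
}

#' @export
print.mediation_verdict <- function(x, digits = 3, ...) {
  cat("Three-step SMR mediation analysis\n")
  print(data.frame(step = x$steps$probe_id,
                   b_smr = signif(x$steps$b_smr, digits),
                   p_smr = signif(x$steps$p_smr, digits),
                   p_heidi = signif(x$steps$p_heidi, digits)),
        row.names = FALSE)
  cat("genome-wide significant instruments:", x$gw_significant,
      "\nHEIDI pass:", x$heidi_pass,
      "\nsign chain consistent:", x$sign_chain_consistent,
      "\nverdict:", x$verdict, "\n")
  invisible(x)
}

#' Transcript/protein direction consistency
#'
#' A gene's causal evidence is considered cross-omics consistent when both
#' the transcript-level and protein-level SMR records are individually
#' credible (`p_smr < 0.05` and `p_heidi > 0.01`) and their SMR effects
#' have the same sign. If either record fails its own criteria the result
#' is `FALSE` with the reason in attribute `"reason"`.
#'
#' @param smr_transcript,smr_protein one-row SMR records with `p_heidi`
#' @param p_smr_max,p_heidi_min per-record credibility thresholds
#' @return logical with attribute `reason` when `FALSE`
#' @export
protein_consistency <- function(smr_transcript, smr_protein,
                                p_smr_max = 0.05, p_heidi_min = 0.01) {
  check_rec <- function(rec, label) {
    if (is.na(rec$p_smr) || rec$p_smr >= p_smr_max)
      return(paste0(label, " SMR p not significant"))
    if (is.na(rec$p_heidi) || rec$p_heidi <= p_heidi_min)
      return(paste0(label, " fails HEIDI"))
    NULL
  }
  reason <- c(check_rec(smr_transcript, "transcript"),
              check_rec(smr_protein, "protein"))
  if (length(reason)) return(structure(FALSE, reason = reason[1]))
  sign(smr_transcript$b_smr) == sign(smr_protein$b_smr)
}
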