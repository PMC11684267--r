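# Phenome-wide causal scan: one instrument set against many outcome traits
# with Bonferroni gating.

#' Phenome-wide MR scan of gene instrument sets across outcome traits
#'
#' For every gene x trait pair: harmonize the gene's instruments against
#' the trait GWAS, fit the primary estimator (IVW with multiplicative
#' random effects, Wald ratio at a single instrument), and flag
#' significance at `alpha / m`. By default `m` is the number of traits
#' requested (`strict_m = TRUE`), so traits that fail to scan still count
#' toward the correction; with `strict_m = FALSE`, `m` is the number of
#' traits scanned successfully. Per-trait failures are isolated and
#' reported, never fatal.
#'
#' When a gene's effect direction on the primary disease is supplied
#' (`gene_disease_sign`, e.g. the sign of its gout meta-analysis beta),
#' each significant trait association is labelled `beneficial` or
#' `adverse` for an intervention targeting the gene in the
#' disease-protective direction: pushing the exposure against the disease
#' sign changes the trait by `-sign(disease beta) * trait beta`, so a
#' trait association sharing the disease sign is beneficial (the trait
#' risk falls too), an opposite-sign association is adverse. Rows are left
#' unlabelled when the sign is not supplied.
#'
#' @param instruments per-gene exposure instrument table (needs
#'   `variant_id`, alleles, `eaf`, `beta`, `se`, `pval`, `n`)
#' @param traits named list of trait GWAS summary-statistics tables, or a
#'   manifest data.frame with columns `trait_id`, `path` and optionally
#'   `category`
#' @param alpha family-wise level before Bonferroni division, default 0.05
#' @param m_total override for the Bonferroni denominator (e.g. a fixed
#'   phenome size when scanning a subset)
#' @param strict_m count requested rather than successfully scanned traits
#' @param gene_disease_sign optional +1/-1 sign of the gene's effect on the
#'   primary disease
#' @param gene_id label for the output rows
#' @param categories optional named character vector trait_id -> category
#' @return data.frame sorted by p-value: one row per successfully scanned
#'   trait with estimator output, `significant`, and `direction_label`;
#'   attribute `m` holds the Bonferroni denominator, attribute `failures`
#'   any per-trait error messages
#' @export
phewas_scan <- function(instruments, traits, alpha = 0.05, m_total = NULL,
                        strict_m = TRUE, gene_disease_sign = NULL,
                        gene_id = "gene", categories = NULL) {
  if (is.data.frame(traits)) {
    stopifnot(all(c("trait_id", "path") %in% names(traits)))
    if ("category" %in% names(traits))
      categories <- stats::setNames(traits$category, traits$trait_id)
    paths <- stats::setNames(traits$path, traits$trait_id)
    traits <- lapply(paths, read_sumstats, trait_kind = "binary")
  }
  if (!length(traits)) stop("phewas_scan needs at least one trait")
  if (is.null(names(traits))) names(traits) <- paste0("trait", seq_along(traits))
  rows <- list(); failures <- character(0)
  for (tid in names(traits)) {
    res <- tryCatch({
      pairs <- kept_pairs(harmonize(instruments, traits[[tid]]))
      if (!nrow(pairs)) stop("no harmonized pairs")
      fit <- if (nrow(pairs) >= 2) mr_ivw(pairs) else mr_wald_ratio(pairs)
      data.frame(gene_id = gene_id, trait_id = tid,
                 trait_category = if (!is.null(categories) &&
                                      tid %in% names(categories))
                   categories[[tid]] else NA_character_,
                 method = fit$method, beta = fit$beta, se = fit$se,
                 pval = fit$pval, k = fit$k, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[tid] <- conditionMessage(res)
    else rows[[tid]] <- res
  }
  if (!length(rows)) stop("no trait scanned successfully")
  out <- do.call(rbind, rows)
  m <- if (!is.null(m_total)) m_total
       else if (strict_m) length(traits) else nrow(out)
  out$significant <- out$pval < alpha / m
  out$direction_label <- NA_character_
  if (!is.null(gene_disease_sign) && gene_disease_sign != 0) {
    lab <- ifelse(sign(out$beta) == sign(gene_disease_sign),
                  "beneficial", "adverse")
    out$direction_label[out$significant] <- lab[out$significant]
  }
  out <- out[order(out$pval), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "failures") <- failures
  out
}
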