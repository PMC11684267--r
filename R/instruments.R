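# Instrument construction: cis-window selection, instrument-strength
# statistics, significance prefilter, LD clumping.

#' Restrict summary statistics to a gene's cis window
#'
#' Keeps variants on the gene's chromosome with position inside
#' `[start - window_bp, end + window_bp]`, inclusive on both ends (1-based
#' coordinates).
#'
#' @param sumstats summary-statistics data.frame
#' @param gene one-row gene annotation (see [gene_annotation()])
#' @param window_bp flank size in base pairs, default 100 kb
#' @return subset of `sumstats`
#' @export
cis_window_filter <- function(sumstats, gene, window_bp = 100000) {
  stopifnot(nrow(gene) == 1)
  keep <- sumstats$chrom == gene$chrom &
    sumstats$pos >= gene$start - window_bp &
    sumstats$pos <= gene$end + window_bp
  out <- sumstats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of variance explained by a variant
#'
#' `PVE = beta^2 / (beta^2 + n * se^2)` from the variant's marginal effect,
#' standard error and sample size.
#'
#' @param beta,se,n marginal effect, standard error (> 0) and sample size
#' @return PVE in `[0, 1)`
#' @export
compute_pve <- function(beta, se, n) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(n <= 0)) stop("n must be > 0")
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F-statistic
#'
#' `F = ((n - k - 1) / k) * PVE / (1 - PVE)` with `k` the number of
#' instruments used (per-variant strength uses `k = 1`). Variants with
#' `F < 10` are conventionally excluded as weak.
#'
#' @param pve proportion of variance explained, in `[0, 1)`
#' @param n sample size; must exceed `k + 1`
#' @param k number of instruments, default 1
#' @return F-statistic (>= 0)
#' @export
compute_f_stat <- function(pve, n, k = 1) {
  if (any(pve < 0 | pve >= 1)) stop("pve must be in [0, 1)")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  (n - k - 1) / k * pve / (1 - pve)
}

#' Greedy LD clumping by p-value
#'
#' Retains the variant with the smallest p-value, removes every other
#' variant within `window_kb` of a retained variant whose squared
#' correlation with it is at least `r2_threshold`, and repeats. Ties on
#' p-value are broken by ascending position, then lexicographic id, so the
#' result does not depend on input row order.
#'
#' @param candidates summary-statistics data.frame (needs `variant_id`,
#'   `pos`, `pval`)
#' @param ld `ld_matrix` covering all candidates
#' @param r2_threshold squared-correlation threshold, default 0.1
#' @param window_kb clumping window in kb, default 10,000 (effectively
#'   region-wide for cis windows)
#' @return the retained subset, in the original column layout, ordered by
#'   ascending p-value
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.1, window_kb = 10000) {
  missing_ids <- setdiff(candidates$variant_id, rownames(ld))
  if (length(missing_ids))
    stop("variant(s) missing from LD matrix: ",
         paste(missing_ids, collapse = ", "))
  ord <- order(candidates$pval, candidates$pos, candidates$variant_id)
  x <- candidates[ord, , drop = FALSE]
  r2 <- unclass(ld)[x$variant_id, x$variant_id, drop = FALSE]^2
  keep <- logical(nrow(x))
  alive <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    prune <- alive & r2[i, ] >= r2_threshold &
      abs(x$pos - x$pos[i]) <= window_kb * 1000
    prune[i] <- FALSE
    alive[prune] <- FALSE
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a per-gene instrument set
#'
#' Applies, in order: the cis-window filter, a per-gene FDR (BH)
#' significance filter, per-variant PVE and F computation with exclusion of
#' weak instruments (`F < f_min`), and greedy LD clumping.
#'
#' @param sumstats exposure summary statistics
#' @param gene one-row gene annotation
#' @param ld `ld_matrix` for the region
#' @param window_bp cis flank, default 100 kb
#' @param fdr per-gene BH FDR threshold applied before clumping (`NULL`
#'   disables the prefilter)
#' @param f_min weak-instrument F cut-off; variants with `F < f_min` are
#'   excluded (strict inequality, so `F = f_min` is retained)
#' @param r2_threshold,window_kb clumping parameters
#' @return instrument table with added `gene_id`, `pve` and `f_stat`
#'   columns; zero rows if no variant survives
#' @export
build_instruments <- function(sumstats, gene, ld, window_bp = 100000,
                              fdr = 0.05, f_min = 10, r2_threshold = 0.1,
                              window_kb = 10000) {
  x <- cis_window_filter(sumstats, gene, window_bp)
  if (nrow(x) && !is.null(fdr))
    x <- x[stats::p.adjust(x$pval, "BH") < fdr, , drop = FALSE]
  x$pve <- compute_pve(x$beta, x$se, x$n)
  x$f_stat <- compute_f_stat(x$pve, x$n, k = 1)
  x <- x[x$f_stat >= f_min, , drop = FALSE]
  x <- ld_clump(x, ld, r2_threshold, window_kb)
  x$gene_id <- rep(gene$gene_id, nrow(x))
  rownames(x) <- NULL
  x
}
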