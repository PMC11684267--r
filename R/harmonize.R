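# Exposure/outcome harmonization: allele alignment, palindrome removal,
# Steiger directionality filtering.

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

is_palindromic <- function(a1, a2) paste(a1, a2, sep = "/") %in% PALINDROMIC

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every shared variant to the exposure's effect allele, so that
#' after harmonization both betas are signed for the same allele:
#' \itemize{
#'   \item alleles identical: record kept unchanged;
#'   \item alleles swapped (outcome effect/other equal exposure other/
#'     effect): the outcome beta is negated and its frequency replaced by
#'     `1 - eaf` (`action = "flipped"`);
#'   \item allele sets differing: record dropped
#'     (`action = "dropped_incompatible"`).
#' }
#' Optionally, ambiguous palindromic variants and variants failing the
#' Steiger directionality check are then dropped (see
#' [palindrome_filter()], [steiger_filter()]). Drops are recorded with a
#' reason, never raised as errors.
#'
#' @param exposure,outcome summary-statistics data.frames sharing
#'   `variant_id`s
#' @param palindrome_maf MAF threshold above which a palindromic variant is
#'   ambiguous and dropped (strict `>`); `NULL` disables the filter
#' @param steiger apply Steiger directionality filtering?
#' @return data.frame of class `harmonized_pairs`: one row per shared
#'   variant with `beta_exp`, `se_exp`, `n_exp`, `eaf_exp`, `beta_out`,
#'   `se_out`, `n_out`, `eaf_out`, `action`; rows with `action` starting
#'   `"dropped"` are excluded from analysis but retained in the table.
#'   Attribute `drop_counts` summarizes reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf = 0.42,
                      steiger = TRUE) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ei <- match(shared, exposure$variant_id)
  oi <- match(shared, outcome$variant_id)
  e <- exposure[ei, , drop = FALSE]
  o <- outcome[oi, , drop = FALSE]
  x <- data.frame(
    variant_id = shared,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, n_exp = e$n, eaf_exp = e$eaf,
    pval_exp = e$pval,
    beta_out = o$beta, se_out = o$se, n_out = o$n, eaf_out = o$eaf,
    pval_out = o$pval,
    action = rep("kept", length(shared)), stringsAsFactors = FALSE)
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  x$beta_out[swapped] <- -x$beta_out[swapped]
  x$eaf_out[swapped] <- 1 - x$eaf_out[swapped]
  x$action[swapped] <- "flipped"
  x$action[!same & !swapped] <- "dropped_incompatible"
  if (!is.null(palindrome_maf)) {
    live <- !startsWith(x$action, "dropped")
    amb <- live & palindrome_ambiguous(x, palindrome_maf)
    x$action[amb] <- "dropped_palindrome"
  }
  if (steiger) {
    live <- !startsWith(x$action, "dropped")
    st <- live & !steiger_keep(x)
    x$action[st] <- "dropped_steiger"
  }
  counts <- table(factor(x$action, levels = c("kept", "flipped",
    "dropped_palindrome", "dropped_incompatible", "dropped_steiger")))
  attr(x, "drop_counts") <- counts
  class(x) <- c("harmonized_pairs", class(x))
  x
}

# Ambiguity rule for palindromic variants: minor-allele frequency strictly
# above the threshold in either dataset (missing frequency on a palindromic
# variant is treated as ambiguous — conservative).
palindrome_ambiguous <- function(x, maf_threshold = 0.42) {
  pal <- is_palindromic(x$effect_allele, x$other_allele)
  maf_exp <- pmin(x$eaf_exp, 1 - x$eaf_exp)
  maf_out <- pmin(x$eaf_out, 1 - x$eaf_out)
  inter <- (is.na(maf_exp) | maf_exp > maf_threshold) |
    (is.na(maf_out) | maf_out > maf_threshold)
  pal & inter
}

# Steiger directionality: keep a variant unless it explains strictly more
# variance in the outcome than in the exposure (PVE comparison on both
# sides; the deterministic form of the test).
steiger_keep <- function(x) {
  if (any(is.na(x$n_exp)) || any(is.na(x$n_out)))
    stop("Steiger filtering requires sample sizes on both sides")
  pve_exp <- compute_pve(x$beta_exp, x$se_exp, x$n_exp)
  pve_out <- compute_pve(x$beta_out, x$se_out, x$n_out)
  !(pve_out > pve_exp)
}

#' Palindrome ambiguity filter
#'
#' Flags harmonized pairs whose allele pair is palindromic (A/T or C/G) and
#' whose minor-allele frequency is strictly greater than `maf_threshold` in
#' either dataset; such variants' strand cannot be resolved.
#'
#' @param pairs `harmonized_pairs` table
#' @param maf_threshold intermediate-frequency cut-off, default 0.42
#' @return logical vector, `TRUE` = keep
#' @export
palindrome_filter <- function(pairs, maf_threshold = 0.42) {
  !palindrome_ambiguous(pairs, maf_threshold)
}

#' Steiger directionality filter
#'
#' Drops variants that explain more variance in the outcome than in the
#' exposure (wrong causal direction), comparing per-variant PVE computed
#' from each side's beta, se and sample size. The inequality is strict, so
#' ties are kept.
#'
#' @param pairs `harmonized_pairs` table
#' @return logical vector, `TRUE` = keep
#' @export
steiger_filter <- function(pairs) steiger_keep(pairs)

#' Analysis-ready subset of a harmonized table
#' @param pairs `harmonized_pairs` table
#' @return rows whose action is `kept` or `flipped`
#' @export
kept_pairs <- function(pairs) {
  out <- pairs[!startsWith(pairs$action, "dropped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
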