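SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n")

#' Two-sided normal p-value from a z statistic
#' @param z numeric z statistic(s)
#' @return two-sided tail probability, never exactly 0 within double range
#' @keywords internal
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

#' Recompute a two-sided normal p-value from a point estimate and its 95% CI
#'
#' Reported effect estimates are often published as a beta with a 95%
#' confidence interval but a p-value rounded to few digits. This helper
#' recovers the two-sided normal p implied by the interval: the standard
#' error is `(upper - lower) / (2 * 1.96)` and the p-value is the two-sided
#' normal tail of `beta / se`.
#'
#' @param beta point estimate
#' @param lower,upper bounds of the 95% confidence interval
#' @return two-sided p-value implied by the normal approximation
#' @examples
#' p_from_ci(0.18, 0.03, 0.34)
#' @export
p_from_ci <- function(beta, lower, upper) {
  stopifnot(upper >= lower)
  se <- (upper - lower) / (2 * stats::qnorm(0.975))
  if (any(se <= 0)) stop("degenerate interval: upper must exceed lower")
  p_from_z(beta / se)
}

#' Validate a summary-statistics table
#'
#' Checks the schema used throughout the package: one row per variant with
#' identifier, chromosome, 1-based position, effect/other allele (A/C/G/T),
#' effect-allele frequency, beta, standard error, p-value and sample size.
#' Betas are per-allele effects: SD units for quantitative molecular traits,
#' log-odds for binary outcomes.
#'
#' @param x data.frame to validate
#' @param drop_invalid drop (with a message) rows with missing beta/se or
#'   non-positive se instead of erroring
#' @return the validated (possibly row-filtered) data.frame
#' @export
validate_sumstats <- function(x, drop_invalid = TRUE) {
  missing_cols <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    x[[col]] <- as.numeric(x[[col]])
  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup))
    stop("duplicated variant_id: ", paste(unique(dup), collapse = ", "))
  bad_allele <- !(x$effect_allele %in% c("A", "C", "G", "T")) |
    !(x$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop("non-ACGT allele for variant(s): ",
         paste(x$variant_id[bad_allele], collapse = ", "))
  if (any(x$effect_allele == x$other_allele))
    stop("effect_allele equals other_allele for variant(s): ",
         paste(x$variant_id[x$effect_allele == x$other_allele], collapse = ", "))
  drop <- is.na(x$beta) | is.na(x$se) | x$se <= 0
  if (any(drop)) {
    if (!drop_invalid)
      stop(sum(drop), " row(s) with missing beta/se or se <= 0")
    message("dropping ", sum(drop), " row(s) with missing beta/se or se <= 0")
    x <- x[!drop, , drop = FALSE]
  }
  if (any(x$eaf < 0 | x$eaf > 1, na.rm = TRUE))
    stop("eaf outside [0, 1]")
  if (any(x$pval <= 0 | x$pval > 1, na.rm = TRUE))
    stop("pval outside (0, 1]")
  rownames(x) <- NULL
  x
}

#' Read a tab-separated summary-statistics file
#'
#' Expects a header with the canonical column names (see
#' [validate_sumstats()]); `#`-prefixed lines are treated as comments. A
#' named `col_map` can rename non-standard headers, e.g.
#' `c(variant_id = "SNP", pval = "P")`.
#'
#' @param path file path
#' @param trait_kind `"quantitative"` (QTL exposure) or `"binary"` (case-
#'   control outcome); recorded as an attribute
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names
#' @return validated data.frame of variant records
#' @export
read_sumstats <- function(path, trait_kind = c("quantitative", "binary"),
                          col_map = NULL) {
  trait_kind <- match.arg(trait_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(x))
      if (!is.na(j)) names(x)[j] <- canon
    }
  }
  x <- validate_sumstats(x)
  attr(x, "trait_kind") <- trait_kind
  x
}

#' Write a summary-statistics table
#' @param x validated summary-statistics data.frame
#' @param path output path
#' @param comment optional metadata lines written as `#`-prefixed header
#' @export
write_sumstats <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x[, SUMSTATS_COLS], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct / validate an LD correlation matrix
#'
#' @param r square numeric matrix of pairwise correlations with variant ids
#'   as dimnames
#' @return object of class `ld_matrix` (a plain matrix with a class tag)
#' @export
ld_matrix <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(rownames(r)) && !is.null(colnames(r))) rownames(r) <- colnames(r)
  if (is.null(colnames(r)) && !is.null(rownames(r))) colnames(r) <- rownames(r)
  if (is.null(colnames(r))) stop("LD matrix needs variant ids as dimnames")
  asym <- max(abs(r - t(r)))
  if (asym >= 1e-8) stop("LD matrix asymmetric beyond tolerance (", signif(asym, 3), ")")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (max(abs(r)) > 1 + 1e-8) stop("|r| must not exceed 1")
  ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6) stop("LD matrix is not positive semi-definite")
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Read an LD matrix from a labelled square text matrix
#' @param path whitespace-delimited file, header row of variant ids
#' @return `ld_matrix`
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(x)
  rownames(m) <- colnames(m)
  ld_matrix(m)
}

#' Write an LD matrix as a labelled square text matrix
#' @param r `ld_matrix`
#' @param path output path
#' @export
write_ld_matrix <- function(r, path) {
  utils::write.table(unclass(r), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Gene annotation record(s)
#' @param gene_id gene label(s)
#' @param chrom chromosome label(s)
#' @param start,end 1-based inclusive gene bounds
#' @return data.frame with one row per gene
#' @export
gene_annotation <- function(gene_id, chrom, start, end) {
  if (any(start > end)) stop("start must be <= end")
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = as.numeric(start), end = as.numeric(end),
             stringsAsFactors = FALSE)
}
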