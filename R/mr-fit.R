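# Central model-fitting surface: mr_fit() and its S3 methods.

rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[, cols, drop = FALSE]
  })
  do.call(rbind, rows)
}

#' Fit the two-sample MR estimator battery to a harmonized instrument set
#'
#' The primary causal estimate follows the standard routing rule: with a
#' single instrument the Wald ratio is used; with two or more, the
#' inverse-variance weighted estimator under a multiplicative
#' random-effects model. The auxiliary estimators (MR-Egger, weighted
#' median, weighted mode, RAPS, maximum likelihood) rest on different
#' identifying assumptions and are fitted alongside when the instrument
#' count admits them; direction agreement across them is the usual
#' robustness check.
#'
#' @param pairs a `harmonized_pairs` table (dropped rows are excluded
#'   automatically) or any data.frame with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`
#' @param methods auxiliary estimators to fit alongside the primary one
#' @param n_boot parametric-bootstrap replicates for median/mode SEs
#' @param seed seed for bootstrap resampling
#' @param gene_id optional exposure label stored in the result
#' @return object of class `mr_fit` with components `estimates` (one row
#'   per fitted method), `primary` (method name of the headline estimate),
#'   `data` (the analysed pairs), `skipped` (methods not fitted and why)
#' @seealso [mr_ivw()], [mr_egger()], [mr_leave_one_out()], [mr_radial()]
#' @examples
#' set.seed(1)
#' k <- 5
#' bx <- runif(k, 0.1, 0.3)
#' pairs <- data.frame(beta_exp = bx, se_exp = 0.01,
#'                     beta_out = 0.3 * bx + rnorm(k, 0, 0.02),
#'                     se_out = 0.02)
#' fit <- mr_fit(pairs, n_boot = 50)
#' coef(fit)
#' @export
mr_fit <- function(pairs,
                   methods = c("egger", "weighted_median", "weighted_mode",
                               "raps", "max_likelihood"),
                   n_boot = 1000, seed = 1L, gene_id = NULL) {
  if (inherits(pairs, "harmonized_pairs")) pairs <- kept_pairs(pairs)
  check_pairs(pairs, 1, "mr_fit")
  k <- nrow(pairs)
  skipped <- character(0)
  rows <- list()
  if (k == 1) {
    rows$primary <- mr_wald_ratio(pairs)
    primary <- "wald_ratio"
    skipped <- stats::setNames(rep("needs k >= 2", length(methods)), methods)
  } else {
    rows$primary <- mr_ivw(pairs)
    primary <- "ivw_mre"
    for (m in methods) {
      res <- tryCatch(switch(m,
        egger = mr_egger(pairs),
        weighted_median = mr_weighted_median(pairs, n_boot, seed),
        weighted_mode = mr_weighted_mode(pairs, n_boot, seed),
        raps = mr_raps(pairs),
        max_likelihood = mr_max_likelihood(pairs),
        stop("unknown method: ", m)), error = function(e) e)
      if (inherits(res, "error")) skipped[m] <- conditionMessage(res)
      else rows[[m]] <- res
    }
  }
  est <- rbind_fill(rows)
  rownames(est) <- NULL
  structure(list(estimates = est, primary = primary, data = pairs,
                 skipped = skipped, gene_id = gene_id,
                 call = match.call()),
            class = "mr_fit")
}

primary_row <- function(object) {
  object$estimates[object$estimates$method == object$primary, , drop = FALSE]
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  p <- primary_row(x)
  cat("Two-sample MR fit", if (!is.null(x$gene_id)) paste0(" (", x$gene_id, ")"),
      "\n", sep = "")
  cat("Instruments: ", p$k, "; primary estimator: ", x$primary, "\n", sep = "")
  cat("Causal estimate (log-odds per SD exposure): ",
      format(p$beta, digits = digits), " (SE ",
      format(p$se, digits = digits), ", p = ",
      format(p$pval, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  crit <- ifelse(est$method == "egger",
                 stats::qt(1 - (1 - level) / 2, df = pmax(est$k - 2, 1)),
                 stats::qnorm(1 - (1 - level) / 2))
  out <- cbind(est$beta - crit * est$se, est$beta + crit * est$se)
  dimnames(out) <- list(est$method,
                        paste0(format(100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2)), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  p <- primary_row(object)
  object$data$beta_out - p$beta * object$data$beta_exp
}

#' @export
summary.mr_fit <- function(object, ...) {
  p <- primary_row(object)
  het <- if ("cochran_q" %in% names(object$estimates) && !is.na(p$cochran_q))
    c(Q = p$cochran_q, df = p$k - 1, pval = p$q_pval) else NULL
  eg <- object$estimates[object$estimates$method == "egger", , drop = FALSE]
  pleio <- if (nrow(eg))
    c(intercept = eg$egger_intercept, se = eg$intercept_se,
      pval = eg$intercept_pval) else NULL
  structure(list(fit = object, heterogeneity = het, pleiotropy = pleio),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  est <- x$fit$estimates
  cat("\nEstimates:\n")
  print(data.frame(method = est$method,
                   beta = signif(est$beta, digits),
                   se = signif(est$se, digits),
                   pval = signif(est$pval, digits),
                   k = est$k), row.names = FALSE)
  if (!is.null(x$heterogeneity))
    cat("\nCochran's Q = ", format(x$heterogeneity[["Q"]], digits = digits),
        " (df ", x$heterogeneity[["df"]], ", p = ",
        format(x$heterogeneity[["pval"]], digits = digits), ")\n", sep = "")
  if (!is.null(x$pleiotropy))
    cat("Egger intercept = ", format(x$pleiotropy[["intercept"]],
                                     digits = digits),
        " (p = ", format(x$pleiotropy[["pval"]], digits = digits), ")\n",
        sep = "")
  if (length(x$fit$skipped))
    cat("Not fitted:", paste(names(x$fit$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of a fitted MR model
#'
#' Outcome against exposure effects with +/- 1 SE error bars and one fitted
#' line per estimator (through the origin except MR-Egger).
#'
#' @param x `mr_fit` object
#' @param ... passed to `plot()`
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$beta_exp, d$beta_out,
                 xlab = "exposure effect (SD units)",
                 ylab = "outcome effect (log-odds)",
                 pch = 19, ...)
  graphics::segments(d$beta_exp, d$beta_out - d$se_out,
                     d$beta_exp, d$beta_out + d$se_out)
  graphics::segments(d$beta_exp - d$se_exp, d$beta_out,
                     d$beta_exp + d$se_exp, d$beta_out)
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    if (est$method[i] == "egger")
      graphics::abline(est$egger_intercept[i], est$beta[i], lty = i, col = i)
    else graphics::abline(0, est$beta[i], lty = i, col = i)
  }
  graphics::legend("topleft", legend = est$method, lty = seq_len(nrow(est)),
                   col = seq_len(nrow(est)), cex = 0.8, bty = "n")
  invisible(x)
}
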