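# Sensitivity diagnostics: leave-one-out, Radial MR outliers, MR-PRESSO.

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate k times, each time omitting one variant, and
#' flags omissions that flip the sign of the estimate or move it outside
#' the full-data 95% confidence interval.
#'
#' @param pairs harmonized table, k >= 3
#' @return data.frame with one row per omitted variant (`omitted`, `beta`,
#'   `se`, `pval`, `flagged`); attribute `full` holds the full-data IVW row
#' @export
mr_leave_one_out <- function(pairs) {
  check_pairs(pairs, 3, "leave_one_out")
  full <- mr_ivw(pairs)
  ci <- full$beta + c(-1, 1) * stats::qnorm(0.975) * full$se
  k <- nrow(pairs)
  rows <- lapply(seq_len(k), function(i) {
    fit <- mr_ivw(pairs[-i, , drop = FALSE])
    data.frame(omitted = if (!is.null(pairs$variant_id)) pairs$variant_id[i]
                         else as.character(i),
               beta = fit$beta, se = fit$se, pval = fit$pval,
               flagged = sign(fit$beta) != sign(full$beta) ||
                 fit$beta < ci[1] || fit$beta > ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Radial MR (IVW) outlier detection
#'
#' Fits radial IVW with modified second-order weights
#' `w_j = 1 / (se_out_j^2 / beta_exp_j^2 + beta^2 * se_exp_j^2 /
#' beta_exp_j^2)` (iterated to convergence in `beta`), computes the
#' per-variant contribution `Q_j = w_j (ratio_j - beta)^2` to Cochran's Q,
#' and flags variants whose `Q_j` exceeds the chi-square(1) quantile at
#' `alpha` (optionally Bonferroni-corrected over k).
#'
#' @param pairs harmonized table, k >= 3
#' @param alpha per-variant outlier level on chi-square(1), default 0.05
#' @param bonferroni divide `alpha` by k before thresholding?
#' @return list with `beta` (radial IVW estimate), `q` (total Q),
#'   `global_pval` (chi-square, k - 1 df), `q_contrib`, and `outliers`
#'   (variant ids or indices)
#' @export
mr_radial <- function(pairs, alpha = 0.05, bonferroni = FALSE) {
  check_pairs(pairs, 3, "radial")
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  ratio <- by / bx
  beta <- mr_ivw(pairs, random = FALSE)$beta
  for (i in 1:100) {
    w <- 1 / (sy^2 / bx^2 + beta^2 * sx^2 / bx^2)
    beta_new <- sum(w * ratio) / sum(w)
    if (abs(beta_new - beta) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  q_contrib <- w * (ratio - beta)^2
  q <- sum(q_contrib)
  k <- length(bx)
  thr_alpha <- if (bonferroni) alpha / k else alpha
  cut <- stats::qchisq(1 - thr_alpha, df = 1)
  ids <- if (!is.null(pairs$variant_id)) pairs$variant_id
         else as.character(seq_len(k))
  list(method = "radial", beta = beta, q = q,
       global_pval = stats::pchisq(q, k - 1, lower.tail = FALSE),
       q_contrib = stats::setNames(q_contrib, ids),
       outliers = ids[q_contrib > cut])
}

#' MR-PRESSO global and outlier tests
#'
#' The observed residual sum of squares (each variant's weighted squared
#' residual from the IVW fit excluding that variant) is compared with its
#' parametric null distribution, simulated from the fitted no-pleiotropy
#' model (`beta_out_j* ~ N(beta_loo_j * beta_exp_j, se_out_j^2)`,
#' `beta_exp_j* ~ N(beta_exp_j, se_exp_j^2)`). Per-variant outlier
#' p-values compare each observed residual with its own simulated
#' distribution and are Bonferroni-corrected over k.
#'
#' @param pairs harmonized table, k >= 4
#' @param n_sim number of null simulations (>= 1)
#' @param seed seed for the simulations
#' @param alpha outlier significance level before Bonferroni correction
#' @return list with `global_rss`, `global_pval`, `outlier_pvals`
#'   (Bonferroni-adjusted, capped at 1) and `outliers`
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = 1L, alpha = 0.05) {
  check_pairs(pairs, 4, "presso")
  if (n_sim < 1) stop("presso: n_sim must be >= 1")
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  k <- length(bx)
  w <- 1 / sy^2
  beta_loo <- vapply(seq_len(k), function(i) {
    sum((w * bx * by)[-i]) / sum((w * bx^2)[-i])
  }, numeric(1))
  res_obs <- w * (by - beta_loo * bx)^2
  rss_obs <- sum(res_obs)
  with_seed(seed, {
    sim <- matrix(0, n_sim, k)
    for (s in seq_len(n_sim)) {
      bx_s <- stats::rnorm(k, bx, sx)
      by_s <- stats::rnorm(k, beta_loo * bx, sy)
      beta_loo_s <- vapply(seq_len(k), function(i) {
        sum((w * bx_s * by_s)[-i]) / sum((w * bx_s^2)[-i])
      }, numeric(1))
      sim[s, ] <- w * (by_s - beta_loo_s * bx_s)^2
    }
    rss_sim <- rowSums(sim)
    global_pval <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)
    outlier_p <- vapply(seq_len(k), function(j) {
      (sum(sim[, j] >= res_obs[j]) + 1) / (n_sim + 1)
    }, numeric(1))
    outlier_p_adj <- pmin(1, outlier_p * k)
    ids <- if (!is.null(pairs$variant_id)) pairs$variant_id
           else as.character(seq_len(k))
    list(method = "presso", global_rss = rss_obs, global_pval = global_pval,
         outlier_pvals = stats::setNames(outlier_p_adj, ids),
         outliers = ids[outlier_p_adj < alpha])
  })
}
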