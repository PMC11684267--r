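# Two-sample MR estimators operating on harmonized exposure/outcome pairs.
#
# All estimators take a harmonized table (columns beta_exp, se_exp,
# beta_out, se_out; rows already filtered to analysable variants) and
# return a one-row data.frame with method, beta, se, pval, k plus
# method-specific diagnostics.

mr_result <- function(method, beta, se, pval, k, ...) {
  extra <- list(...)
  out <- data.frame(method = method, beta = beta, se = se, pval = pval,
                    k = k, stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

check_pairs <- function(pairs, k_min, method) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols))
    stop(method, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  if (nrow(pairs) < k_min)
    stop(method, " requires at least ", k_min, " variant(s), got ", nrow(pairs))
  invisible(pairs)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se_out / |beta_exp|` (the exposure-side uncertainty enters only at
#' second order and is ignored by default, the standard two-sample MR
#' convention).
#'
#' @param pairs harmonized table with exactly one analysable variant (if
#'   several rows are passed, the first is used)
#' @param second_order add the second-order exposure-uncertainty term to the
#'   delta-method SE?
#' @return one-row MR result data.frame
#' @export
mr_wald_ratio <- function(pairs, second_order = FALSE) {
  check_pairs(pairs, 1, "wald_ratio")
  bx <- pairs$beta_exp[1]; by <- pairs$beta_out[1]
  sx <- pairs$se_exp[1]; sy <- pairs$se_out[1]
  if (bx == 0) stop("wald_ratio undefined: exposure beta is 0")
  beta <- by / bx
  se <- sy / abs(bx)
  if (second_order) se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  mr_result("wald_ratio", beta, se, p_from_z(beta / se), 1L)
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Weighted least squares of outcome on exposure betas through the origin
#' with weights `1/se_out^2`; equivalently the inverse-variance pooled Wald
#' ratio. Under the multiplicative random-effects model the fixed-effect SE
#' is inflated by `max(1, sqrt(Q / (k - 1)))`, so overdispersion widens the
#' interval but underdispersion never narrows it. Cochran's Q and its
#' chi-square p-value (k - 1 df) are attached.
#'
#' @param pairs harmonized table, k >= 2
#' @param random multiplicative random effects (default) or plain fixed
#'   effects
#' @return one-row MR result with `cochran_q`, `q_pval`
#' @export
mr_ivw <- function(pairs, random = TRUE) {
  check_pairs(pairs, 2, "ivw")
  bx <- pairs$beta_exp; by <- pairs$beta_out; w <- 1 / pairs$se_out^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- sqrt(1 / sum(w * bx^2))
  k <- length(bx)
  q <- sum(w * (by - beta * bx)^2)
  phi <- if (random) max(1, sqrt(q / (k - 1))) else 1
  se <- se_fe * phi
  mr_result(if (random) "ivw_mre" else "ivw_fe", beta, se,
            p_from_z(beta / se), k,
            cochran_q = q, q_pval = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure betas with an
#' intercept, weights `1/se_out^2`, after orienting all variants to a
#' positive exposure effect (InSIDE parameterization). The slope is the
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect and its p-value is the pleiotropy test. Standard
#' errors use the multiplicative random-effects convention (residual SD
#' floored at 1) and t reference with k - 2 df.
#'
#' @param pairs harmonized table, k >= 3
#' @return one-row MR result with `egger_intercept`, `intercept_se`,
#'   `intercept_pval`
#' @export
mr_egger <- function(pairs) {
  check_pairs(pairs, 3, "egger")
  s <- sign(pairs$beta_exp)
  s[s == 0] <- 1
  bx <- abs(pairs$beta_exp); by <- pairs$beta_out * s
  w <- 1 / pairs$se_out^2
  k <- length(bx)
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1))
    stop("egger: singular design (no spread in exposure betas)")
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # floor residual SD at 1 (multiplicative random effects, no shrinkage)
  disp <- if (sm$sigma > 0) max(1, sm$sigma) / sm$sigma else 1
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] * disp
  int <- sm$coefficients["(Intercept)", "Estimate"]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] * disp
  mr_result("egger", slope, slope_se,
            2 * stats::pt(-abs(slope / slope_se), df = k - 2), k,
            egger_intercept = int, intercept_se = int_se,
            intercept_pval = 2 * stats::pt(-abs(int / int_se), df = k - 2))
}

# Interpolated weighted median of `r` with weights `w` (Bowden's
# percentile-interpolation rule).
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  n <- length(r)
  if (0.5 >= s[n]) return(r[n])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

boot_se <- function(pairs, point_fun, n_boot, seed) {
  if (n_boot < 1) return(NA_real_)
  k <- nrow(pairs)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, pairs$beta_exp, pairs$se_exp)
      by <- stats::rnorm(k, pairs$beta_out, pairs$se_out)
      point_fun(bx, by, pairs$se_out)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted median estimate
#'
#' Interpolated weighted median of the per-variant Wald ratios with
#' inverse-variance weights `beta_exp^2 / se_out^2`; consistent when at
#' least half the weight comes from valid instruments. SE by parametric
#' bootstrap (resampling betas from their sampling distributions).
#'
#' @param pairs harmonized table, k >= 3
#' @param n_boot bootstrap replicates for the SE (0 skips, SE = NA)
#' @param seed seed for the bootstrap
#' @return one-row MR result
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1L) {
  check_pairs(pairs, 3, "weighted_median")
  point <- function(bx, by, se_out)
    weighted_median_point(by / bx, bx^2 / se_out^2)
  beta <- point(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  se <- boot_se(pairs, point, n_boot, seed)
  mr_result("weighted_median", beta, se,
            if (is.na(se)) NA_real_ else p_from_z(beta / se), nrow(pairs))
}

# Mode of the weighted kernel-smoothed ratio density. Bandwidth is a
# Silverman-type rule on the weighted SD of the ratios; ties at the grid
# maximum are broken toward larger local weight mass, then smaller |x|.
weighted_mode_point <- function(r, w, bw_factor = 0.9) {
  w <- w / sum(w)
  mu <- sum(w * r)
  sd_w <- sqrt(sum(w * (r - mu)^2))
  k <- length(r)
  h <- bw_factor * k^(-1 / 5) * sd_w
  if (h <= 0) return(r[1])
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - r) / h)), numeric(1))
  top <- which(dens >= max(dens) - 1e-12 * max(dens))
  if (length(top) > 1) {
    mass <- vapply(grid[top], function(x) sum(w[abs(r - x) <= h]), numeric(1))
    top <- top[mass == max(mass)]
    top <- top[which.min(abs(grid[top]))]
  }
  grid[top[1]]
}

#' Weighted mode estimate
#'
#' Mode of the inverse-variance weighted, kernel-smoothed empirical density
#' of the per-variant Wald ratios; consistent when the largest group of
#' variants sharing a ratio are valid instruments (ZEMPA). SE by parametric
#' bootstrap.
#'
#' @param pairs harmonized table, k >= 3
#' @param n_boot bootstrap replicates for the SE (0 skips, SE = NA)
#' @param seed seed for the bootstrap
#' @param bw_factor bandwidth multiplier of the Silverman-type rule
#' @return one-row MR result
#' @export
mr_weighted_mode <- function(pairs, n_boot = 1000, seed = 1L, bw_factor = 0.9) {
  check_pairs(pairs, 3, "weighted_mode")
  point <- function(bx, by, se_out)
    weighted_mode_point(by / bx, bx^2 / se_out^2, bw_factor)
  beta <- point(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  se <- boot_se(pairs, point, n_boot, seed)
  mr_result("weighted_mode", beta, se,
            if (is.na(se)) NA_real_ else p_from_z(beta / se), nrow(pairs))
}

huber_psi <- function(t, c = 1.345) pmin(pmax(t, -c), c)

raps_score <- function(beta, bx, by, sx, sy, psi) {
  v <- sy^2 + beta^2 * sx^2
  t <- (by - beta * bx) / sqrt(v)
  dt <- (-bx * v - (by - beta * bx) * beta * sx^2) / v^1.5
  sum(psi(t) * dt)
}

#' Robust adjusted profile score (RAPS) estimate
#'
#' Solves the profile-score equation
#' `sum_j psi(t_j(beta)) * dt_j/dbeta = 0` with
#' `t_j(beta) = (beta_out_j - beta * beta_exp_j) /
#' sqrt(se_out_j^2 + beta^2 * se_exp_j^2)`, which accounts for measurement
#' error in the exposure betas. `psi` is the identity (simple profile
#' score) or a Huber function (robust, the default); the SE comes from the
#' sandwich of the estimating equation.
#'
#' @param pairs harmonized table, k >= 2
#' @param psi `"huber"` (default) or `"simple"`
#' @param huber_c Huber tuning constant
#' @return one-row MR result
#' @export
mr_raps <- function(pairs, psi = c("huber", "simple"), huber_c = 1.345) {
  check_pairs(pairs, 2, "raps")
  psi <- match.arg(psi)
  psi_fun <- if (psi == "huber") function(t) huber_psi(t, huber_c) else identity
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  f <- function(b) raps_score(b, bx, by, sx, sy, psi_fun)
  b0 <- mr_ivw(pairs, random = FALSE)$beta
  half <- max(1, 10 * abs(b0))
  lo <- b0 - half; hi <- b0 + half
  for (i in 1:12) {
    if (sign(f(lo)) != sign(f(hi))) break
    half <- half * 2; lo <- b0 - half; hi <- b0 + half
  }
  if (sign(f(lo)) == sign(f(hi)))
    stop("raps: no root of the profile score in the search bracket")
  beta <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  v <- sy^2 + beta^2 * sx^2
  dt <- (-bx * v - (by - beta * bx) * beta * sx^2) / v^1.5
  # model-based information: with t ~ N(0,1) under the fitted model,
  # Var(beta) = E[psi(Z)^2] / (E[psi'(Z)]^2 * sum (dt/dbeta)^2)
  if (psi == "huber") {
    cc <- huber_c
    delta1 <- 2 * stats::pnorm(cc) - 1
    delta2 <- delta1 - 2 * cc * stats::dnorm(cc) +
      2 * cc^2 * stats::pnorm(cc, lower.tail = FALSE)
  } else {
    delta1 <- 1; delta2 <- 1
  }
  se <- sqrt(delta2 / delta1^2) / sqrt(sum(dt^2))
  mr_result("raps", beta, se, p_from_z(beta / se), nrow(pairs))
}

#' Maximum-likelihood estimate
#'
#' Maximizes the bivariate-normal likelihood of the observed exposure and
#' outcome betas over the causal effect and the true per-variant exposure
#' effects; profiling out the latter reduces to minimizing
#' `sum_j (beta_out_j - beta * beta_exp_j)^2 / (se_out_j^2 + beta^2 *
#' se_exp_j^2)` (plus the log-variance terms). SE from the observed
#' information of the profile likelihood.
#'
#' @param pairs harmonized table, k >= 2
#' @return one-row MR result
#' @export
mr_max_likelihood <- function(pairs) {
  check_pairs(pairs, 2, "max_likelihood")
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  nll <- function(b) {
    v <- sy^2 + b^2 * sx^2
    0.5 * sum((by - b * bx)^2 / v + log(v))
  }
  b0 <- mr_ivw(pairs, random = FALSE)$beta
  half <- max(1, 10 * abs(b0))
  opt <- stats::optimize(nll, c(b0 - half, b0 + half), tol = 1e-12)
  beta <- opt$minimum
  if (min(beta - (b0 - half), (b0 + half) - beta) < 1e-6 * half)
    stop("max_likelihood: optimum at the boundary of the search interval")
  eps <- 1e-4 * max(1, abs(beta))
  info <- (nll(beta + eps) - 2 * nll(beta) + nll(beta - eps)) / eps^2
  if (!is.finite(info) || info <= 0)
    stop("max_likelihood: non-positive observed information")
  se <- 1 / sqrt(info)
  mr_result("max_likelihood", beta, se, p_from_z(beta / se), nrow(pairs))
}
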