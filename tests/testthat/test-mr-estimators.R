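test_that("Wald ratio and its delta-method SE", {
  expect_equal(mr_wald_ratio(make_pairs(0.5, 0))$beta, 0)
  w <- mr_wald_ratio(make_pairs(0.5, 0.1, se_y = 0.05))
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(mr_wald_ratio(make_pairs(-0.5, 0.1))$beta, -0.2)
  expect_error(mr_wald_ratio(make_pairs(0, 0.1)), "exposure beta is 0")
})

test_that("IVW matches the closed-form WLS oracle and routing rule", {
  # identical ratios and weights: estimate equals the ratio, Q = 0
  p_eq <- make_pairs(c(0.5, 0.25), c(0.1, 0.05), se_y = 0.05)
  fit <- mr_ivw(p_eq)
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$cochran_q, 0)
  # closed-form WLS oracle on unequal data
  set.seed(1)
  bx <- runif(6, 0.1, 0.4); by <- 0.3 * bx + rnorm(6, 0, 0.03)
  sy <- runif(6, 0.02, 0.06)
  p6 <- make_pairs(bx, by, se_y = sy)
  w <- 1 / sy^2
  beta_oracle <- sum(w * bx * by) / sum(w * bx^2)
  expect_equal(mr_ivw(p6)$beta, beta_oracle)
  q_oracle <- sum(w * (by - beta_oracle * bx)^2)
  expect_equal(mr_ivw(p6)$cochran_q, q_oracle)
  # multiplicative random effects never shrink below the fixed-effect SE
  expect_gte(mr_ivw(p6)$se, mr_ivw(p6, random = FALSE)$se)
  # k = 1 routes to the Wald ratio through mr_fit
  one <- make_pairs(0.5, 0.1, se_y = 0.05)
  fit1 <- mr_fit(one)
  expect_equal(fit1$primary, "wald_ratio")
  expect_equal(coef(fit1)[["wald_ratio"]], mr_wald_ratio(one)$beta)
  expect_error(mr_ivw(one), "at least 2")
})

test_that("Egger recovers an exact linear law and flags its intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.05 + 0.3 * bx
  fit <- mr_egger(make_pairs(bx, by, se_y = 0.04))
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.05, tolerance = 1e-10)
  # balanced pleiotropy: intercept estimate within 3 SE of 0
  h <- make_region(causal_beta = 0.3, k = 20, seed = 21,
                   pleiotropy_mode = "balanced", pleiotropy_sd = 0.01)
  eg <- mr_egger(kept_pairs(h))
  expect_lt(abs(eg$egger_intercept), 3 * eg$intercept_se)
  expect_error(mr_egger(make_pairs(rep(0.2, 4), 1:4 / 10)), "singular")
})

test_that("weighted median matches the brute-force oracle", {
  # equal weights, ratios {0.1, 0.2, 0.9} -> 0.2
  p3 <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9), se_y = 0.05)
  expect_equal(mr_weighted_median(p3, n_boot = 0)$beta, 0.2)
  # all ratios equal: estimate c, bootstrap spread ~ 0 as SEs -> 0
  pc <- make_pairs(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4) * 0.7,
                   se_x = 1e-10, se_y = 1e-10)
  fit <- mr_weighted_median(pc, n_boot = 50, seed = 3)
  expect_equal(fit$beta, 0.7)
  expect_lt(fit$se, 1e-6)
  # weight concentrating on one ratio pulls the estimate to it
  pw <- make_pairs(c(1, 1, 1), c(0.1, 0.5, 0.9),
                   se_y = c(1e-4, 1, 1))
  expect_equal(mr_weighted_median(pw, n_boot = 0)$beta, 0.1,
               tolerance = 1e-3)
  # independent oracle: the estimate inverts the piecewise-linear weighted
  # CDF through the mid-point percentiles at exactly 0.5
  set.seed(11)
  for (i in 1:5) {
    r <- rnorm(7); w <- runif(7, 0.5, 2)
    est <- mr_weighted_median(make_pairs(rep(1, 7), r, se_y = 1 / sqrt(w)),
                              n_boot = 0)$beta
    o <- order(r); rs <- r[o]; ws <- w[o] / sum(w)
    s <- cumsum(ws) - ws / 2
    expect_equal(approx(rs, s, xout = est)$y, 0.5, tolerance = 1e-9)
  }
})

test_that("weighted mode finds the majority cluster", {
  p4 <- make_pairs(rep(1, 4), c(0.2, 0.2, 0.2, 5), se_y = 0.05)
  expect_lt(abs(mr_weighted_mode(p4, n_boot = 0)$beta - 0.2), 0.1)
  # single cluster plus noise stays within the cluster span
  set.seed(5)
  r <- c(rnorm(8, 0.3, 0.02), 2)
  pk <- make_pairs(rep(1, 9), r, se_y = 0.05)
  est <- mr_weighted_mode(pk, n_boot = 0)$beta
  expect_gt(est, min(r[1:8]) - 0.05)
  expect_lt(est, max(r[1:8]) + 0.05)
})

test_that("RAPS coincides with IVW as exposure error vanishes", {
  set.seed(2)
  bx <- runif(8, 0.1, 0.4); by <- 0.3 * bx + rnorm(8, 0, 0.02)
  p <- make_pairs(bx, by, se_x = 1e-12, se_y = 0.04)
  raps <- mr_raps(p, psi = "simple")
  ivw <- mr_ivw(p, random = FALSE)
  expect_equal(raps$beta, ivw$beta, tolerance = 1e-6)
  expect_equal(raps$se, ivw$se, tolerance = 1e-4)
  # consistency: recover beta = 0.3 within 3 SE on noisy data
  h <- make_region(causal_beta = 0.3, k = 10, seed = 31)
  fit <- mr_raps(kept_pairs(h))
  expect_lt(abs(fit$beta - 0.3), 3 * fit$se)
})

test_that("Huber RAPS resists a gross outlier more than the simple score", {
  set.seed(3)
  bx <- runif(10, 0.1, 0.4)
  by <- 0.3 * bx + rnorm(10, 0, 0.01)
  by[1] <- by[1] + 0.5  # gross direct effect on one variant
  p <- make_pairs(bx, by, se_x = 0.005, se_y = 0.02)
  clean <- make_pairs(bx, 0.3 * bx, se_x = 0.005, se_y = 0.02)
  b_clean <- mr_raps(clean, psi = "simple")$beta
  b_simple <- mr_raps(p, psi = "simple")$beta
  b_huber <- mr_raps(p, psi = "huber")$beta
  expect_lt(abs(b_huber - b_clean), abs(b_simple - b_clean))
})

test_that("maximum likelihood agrees with IVW-FE limit and a grid search", {
  set.seed(4)
  bx <- runif(6, 0.1, 0.4); by <- 0.3 * bx + rnorm(6, 0, 0.02)
  p <- make_pairs(bx, by, se_x = 1e-12, se_y = 0.04)
  ml <- mr_max_likelihood(p)
  ivw <- mr_ivw(p, random = FALSE)
  expect_equal(ml$beta, ivw$beta, tolerance = 1e-6)
  expect_equal(ml$se, ivw$se, tolerance = 1e-4)
  # grid-search oracle with non-negligible exposure error
  p2 <- make_pairs(c(0.2, 0.35), c(0.09, 0.07), se_x = 0.03, se_y = 0.04)
  nll <- function(b) {
    v <- p2$se_out^2 + b^2 * p2$se_exp^2
    0.5 * sum((p2$beta_out - b * p2$beta_exp)^2 / v + log(v))
  }
  grid <- seq(-2, 2, by = 1e-4)
  b_grid <- grid[which.min(vapply(grid, nll, numeric(1)))]
  expect_equal(mr_max_likelihood(p2)$beta, b_grid, tolerance = 1e-3)
})

test_that("estimators are sign- and scale-equivariant", {
  h <- make_region(causal_beta = 0.25, k = 8, seed = 12)
  pairs <- kept_pairs(h)
  fit <- mr_fit(pairs, n_boot = 0, seed = 9)
  neg <- pairs; neg$beta_exp <- -neg$beta_exp
  fit_neg <- mr_fit(neg, n_boot = 0, seed = 9)
  expect_equal(coef(fit_neg), -coef(fit), tolerance = 1e-6)
  sc <- pairs; sc$beta_exp <- 2 * sc$beta_exp; sc$se_exp <- 2 * sc$se_exp
  fit_sc <- mr_fit(sc, n_boot = 0, seed = 9)
  expect_equal(coef(fit_sc), coef(fit) / 2, tolerance = 1e-6)
})
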