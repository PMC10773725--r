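test_that("KH z-test follows the normal quantiles and variance conventions", {
  n <- 400
  d <- rep(c(-1, 1), n / 2) * 0.3                       # dbar = 0, s > 0
  x <- toy_sitelik(rbind(rep(0, n), d))                 # tree2 - tree1 = d
  expect_equal(kh_pvalue(x, 1, 2), 0.5, tolerance = 1e-12)
  # dbar = 1.645 * s / sqrt(n)  ->  p ~= 0.05
  s <- sd(d)
  shift <- qnorm(0.95) * s / sqrt(n)
  x2 <- toy_sitelik(rbind(rep(0, n), d + shift))
  expect_equal(kh_pvalue(x2, 1, 2), 0.05, tolerance = 1e-6)
  # per-site variance flag rescales the z statistic by sqrt(n)
  expect_equal(kh_pvalue(x2, 1, 2, per_site_variance = TRUE),
               1 - pnorm(qnorm(0.95) / sqrt(n)), tolerance = 1e-9)
  # degenerate variance
  x3 <- toy_sitelik(rbind(rep(0, 10), rep(0.2, 10)))
  expect_equal(kh_pvalue(x3, 1, 2), 0)
  expect_equal(kh_pvalue(x3, 2, 1), 1)
  expect_equal(kh_pvalue(x3, 1, 1), 1)                  # the tree itself
})

test_that("KH bootstrap variant agrees with the normal-theory variant", {
  set.seed(17)
  n <- 500
  d <- rnorm(n, mean = 0.02, sd = 0.6)
  x <- toy_sitelik(rbind(rep(0, n), d))
  p_norm <- kh_pvalue(x, 1, 2)
  p_boot <- kh_pvalue(x, 1, 2, variant = "rell_bootstrap", B = 2e4, seed = 5)
  expect_within(p_boot, p_norm, 0.02)
})

test_that("KH over candidates scores the ML tree by convention or second-best", {
  fit <- make_small_fit(seed = 71, n = 300)
  p <- kh_pvalues(fit)
  expect_equal(p[fit$ml_index], 1)
  expect_true(all(p >= 0 & p <= 1))
  p2 <- kh_pvalues(fit, ml_tree = "second_best")
  expect_lt(p2[fit$ml_index], 1)
  expect_equal(p[-fit$ml_index], p2[-fit$ml_index])
})

test_that("chi-square P-values match the chi-bar mixtures at low df", {
  expect_within(chisq_pvalue(3.964, 1), 0.00486, 1e-5)
  expect_equal(round(chisq_pvalue(3.964, 1), 3), 0.005)
  expect_equal(chisq_pvalue(0, 1, low_df = TRUE), 0.5)
  expect_equal(chisq_pvalue(0, 1), 1)
  expect_equal(chisq_pvalue(3.8415 / 2, 1), 0.05, tolerance = 1e-4)
  expect_equal(chisq_pvalue(0, 0), 1)
  expect_equal(chisq_pvalue(1.3, 2, low_df = TRUE),
               pchisq(2.6, 1, lower.tail = FALSE) / 2 +
                 pchisq(2.6, 2, lower.tail = FALSE) / 2)
  expect_equal(chisq_pvalue(1.3, 3, low_df = TRUE), chisq_pvalue(1.3, 3))
  expect_error(chisq_pvalue(1, -1), "negative")
  # the low-df refinement is never more conservative
  for (y in c(0.1, 1, 4)) for (df in 1:2)
    expect_lte(chisq_pvalue(y, df, low_df = TRUE), chisq_pvalue(y, df))
})

test_that("chi-square df equals half the RF distance to the ML tree", {
  fit <- make_small_fit(seed = 72, n = 300)
  ml <- fit$candidates[[fit$ml_index]]
  p <- chisq_pvalues(fit)
  expect_equal(p[fit$ml_index], 1)
  i <- which(vapply(fit$candidates, function(t) rf_distance(t, ml), 0L) == 2)[1]
  expect_equal(p[i], chisq_pvalue(fit$loglik[fit$ml_index] - fit$loglik[i], 1))
})

test_that("RELL resampling has the right margins and determinism", {
  fit <- make_small_fit(seed = 73, n = 200)
  r1 <- rell_samples(fit, B = 500, r = 0.7, seed = 1)
  r2 <- rell_samples(fit, B = 500, r = 0.7, seed = 1)
  expect_identical(r1$sums, r2$sums)
  expect_equal(r1$ndraw, 140)
  # E[l_b(j)] = r * l(j)
  big <- rell_samples(fit, B = 4000, r = 0.5, seed = 2)
  expect_equal(rowMeans(big$sums) / 0.5, fit$loglik,
               tolerance = 0.02 * abs(mean(fit$loglik)))
  # single site: every bootstrap sum is ndraw * that site's value
  one <- toy_sitelik(matrix(c(-2, -3), 2, 1))
  rs <- rell_samples(one, B = 20, r = 3, seed = 3)
  expect_true(all(rs$sums == matrix(3 * c(-2, -3), 2, 20)))
})

test_that("SH P-values are centered, conservative and handle degenerate input", {
  same <- toy_sitelik(matrix(rep(c(-1.2, -0.8), each = 3), 3, 2, byrow = FALSE))
  expect_equal(sh_pvalues(same, B = 200, seed = 4), rep(1, 3))
  fit <- make_small_fit(seed = 74, n = 400)
  set.seed(6)
  p_sh <- sh_pvalues(fit, B = 2000)
  p_kh <- kh_pvalues(fit)
  expect_true(all(p_sh >= 0 & p_sh <= 1))
  expect_gte(p_sh[fit$ml_index], 0.95)
  # SH is the conservative correction: its sets contain the KH sets here
  expect_gte(sum(p_sh > 0.05), sum(p_kh > 0.05))
})

test_that("bootstrap proportions sum to one and split ties evenly", {
  one <- toy_sitelik(matrix(-(1:4), 1, 4))
  expect_equal(bp_support(one, B = 50, seed = 7), 1)
  twin <- toy_sitelik(matrix(rep(-(1:4), each = 2), 2, 4, byrow = FALSE))
  expect_equal(bp_support(twin, B = 64, seed = 8), c(0.5, 0.5))
  fit <- make_small_fit(seed = 75, n = 300)
  expect_equal(sum(bp_support(fit, B = 1000, seed = 9)), 1, tolerance = 1e-12)
})

test_that("BP of the ML tree grows with sequence length on resolved data", {
  mod <- study_model()
  tr <- study_tree(6, "positive", 0.1)
  cands <- enumerate_topologies(labs6)
  bp_ml <- vapply(c(100, 1000, 5000), function(n) {
    aln <- simulate_alignment(tr, mod, n, seed = 76)
    fit <- fit_topologies(aln, cands, mod)
    bp_support(fit, B = 1000, seed = 77)[fit$ml_index]
  }, numeric(1))
  expect_true(all(diff(bp_ml) >= 0))
  expect_gt(bp_ml[3], bp_ml[1])
})

test_that("AU follows the multiscale regression with its degenerate rules", {
  fit <- make_small_fit(seed = 78, n = 300)
  scales <- seq(0.5, 1.4, by = 0.1)
  # flat BP = 0.5 at every scale: d = c = 0, p = 0.5
  bp_flat <- matrix(0.5, 1, 10)
  one <- toy_sitelik(matrix(-(1:6), 1, 6))
  expect_equal(au_pvalues(one, bp_matrix = bp_flat)$p_au, 0.5, tolerance = 1e-9)
  # BP(r=1) = 0 forces p = 0 under the correction, not without it
  bp0 <- matrix(c(0.01, 0.008, 0.006, 0.005, 0.003, 0, 0, 0, 0, 0), 1)
  expect_equal(au_pvalues(one, bp_matrix = bp0)$p_au, 0)
  expect_gt(au_pvalues(one, bp_matrix = bp0, bp0_correction = FALSE)$p_au, 0)
  # fewer than 2 usable scales
  lone <- matrix(c(0, 0, 0, 0, 0, 0.2, 0, 0, 0, 0), 1)
  res <- au_pvalues(one, bp_matrix = lone, bp0_correction = FALSE)
  expect_true(res$degenerate)
  expect_equal(res$p_au, 0)
  # the fitted (d, c) solve the weighted normal equations (independent WLS)
  set.seed(10)
  au <- au_pvalues(fit, B = 2000)
  k <- order(abs(au$p_au - 0.5))[1]   # a well-behaved tree
  expect_false(is.na(au$d[k]))
})

test_that("AU coefficients reproduce an explicit weighted least-squares solve", {
  B <- 5000
  scales <- seq(0.5, 1.4, by = 0.1)
  bp <- matrix(c(0.35, 0.30, 0.28, 0.22, 0.20, 0.17, 0.15, 0.12, 0.10, 0.09), 1)
  one <- toy_sitelik(matrix(-(1:6), 1, 6))
  au <- au_pvalues(one, scales = scales, B = B, bp_matrix = bp)
  z <- qnorm(1 - bp[1, ])
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  W <- diag(B * dnorm(z)^2 / (bp[1, ] * (1 - bp[1, ])))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% z)   # normal equations
  expect_equal(c(au$d, au$c), as.numeric(beta), tolerance = 1e-8)
  expect_equal(au$p_au, 1 - pnorm(beta[1] - beta[2]), tolerance = 1e-8)
})

test_that("AU P-values are invariant to per-site constants shared across trees", {
  fit <- make_small_fit(seed = 79, n = 250)
  shift <- rnorm(ncol(fit$pattern_values))
  shifted <- fit
  shifted$pattern_values <- sweep(fit$pattern_values, 2, shift, "+")
  shifted$values <- shifted$pattern_values[, fit$pattern_index]
  set.seed(11); p1 <- au_pvalues(fit, B = 500)$p_au
  set.seed(11); p2 <- au_pvalues(shifted, B = 500)$p_au
  expect_equal(p1, p2)
})

test_that("topology_tests assembles all requested methods deterministically", {
  fit <- make_small_fit(seed = 80, n = 300)
  set.seed(12)
  res <- topology_tests(fit, methods = c("KH", "SH", "AU", "AUu", "chisq",
                                         "chisq_lowdf", "Bo", "Bom", "BH"),
                        B = 500, au_B = 500)
  expect_equal(nrow(res), 105)
  expect_true(all(c("p_KH", "p_SH", "p_AU", "p_AUu", "p_chisq", "p_Bo",
                    "p_Bom", "p_BH", "bp") %in% names(res)))
  expect_true(all(res$delta >= 0))
  expect_equal(res$p_AU[res$bp == 0], rep(0, sum(res$bp == 0)))
  set.seed(12)
  res2 <- topology_tests(fit, methods = c("KH", "SH", "AU", "AUu", "chisq",
                                          "chisq_lowdf", "Bo", "Bom", "BH"),
                         B = 500, au_B = 500)
  expect_identical(res, res2)
  expect_error(topology_tests(fit, methods = "KHns"), "unknown method")
})
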