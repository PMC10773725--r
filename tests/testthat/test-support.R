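test_that("aLRT cubic support reproduces the published arithmetic", {
  expect_equal(round(alrt_support(3.964, 0), 3), 0.993)
  expect_equal(round(alrt_support(0.597, 0), 3), 0.642)
  expect_equal(alrt_support(5, 5), 0.125)
  expect_error(alrt_support(1, 2), "not the ML")
})

test_that("aLRTc applies the (m-3) multiplicity correction, uncapped", {
  expect_equal(round(alrtc_support(0.642, 6), 3), -0.074)
  expect_equal(alrtc_support(1, 6), 1)
  expect_equal(alrtc_support(1, 24), 1)
  # through the full chain at delta = 3.964 (printed as aLRT 99.3 / aLRTc 97.8)
  expect_equal(round(alrtc_support(alrt_support(3.964, 0), 6), 3), 0.978)
})

test_that("confidence-set split support is one minus the worst surviving P-value", {
  fit <- make_small_fit(seed = 91, n = 300)
  ml <- fit$candidates[[fit$ml_index]]
  s <- ml$splits[1]
  has <- vapply(fit$candidates, function(t) s %in% t$splits, logical(1))
  pv <- rep(0, 105)
  expect_equal(split_support_from_pvalues(fit, pv, s), 1)
  pv[which(!has)[3]] <- 1
  expect_equal(split_support_from_pvalues(fit, pv, s), 0)
  pv[which(!has)] <- 0.25
  expect_equal(split_support_from_pvalues(fit, pv, s), 0.75)
  # undefined when every candidate contains the split
  sub <- site_loglik_matrix(fit$values[has, , drop = FALSE],
                            candidates = fit$candidates[has])
  expect_warning(out <- split_support_from_pvalues(sub, rep(0.5, sum(has)), s),
                 "undefined")
  expect_true(is.na(out))
})

test_that("four-taxon support ordering: chi-square >= Bonferroni >= aLRT", {
  # closed forms on a grid of log-likelihood differences: F* >= F*^2 >= F*^3
  for (delta in c(0, 0.1, 0.6, 2, 5, 10)) {
    sup_chisq <- 1 - chisq_pvalue(delta, 1, low_df = TRUE)
    sup_bonf <- 1 - (1 - (1 - chisq_pvalue(delta, 1, low_df = TRUE)))^2
    # Bonferroni support = 1 - [1 - (1-p)^2] = (1-p)^2 = F*^2
    sup_bonf <- (1 - chisq_pvalue(delta, 1, low_df = TRUE))^2
    sup_alrt <- alrt_support(delta, 0)
    expect_gte(sup_chisq + 1e-12, sup_bonf)
    expect_gte(sup_bonf + 1e-12, sup_alrt)
  }
})

test_that("aLRT supports come from the NNI alternatives of the ML tree", {
  fit <- make_small_fit(seed = 92, n = 500)
  sup <- alrt_supports(fit)
  expect_equal(nrow(sup), 3)
  ml <- fit$candidates[[fit$ml_index]]
  keys <- vapply(fit$candidates, function(t) paste(t$splits, collapse = "."),
                 character(1))
  for (k in seq_len(3)) {
    alts <- nni_alternatives(ml, sup$split[k])
    l2 <- max(vapply(alts, function(a)
      fit$loglik[match(paste(a$splits, collapse = "."), keys)], numeric(1)))
    expect_equal(sup$l2[k], l2)
    expect_equal(sup$alrt[k], alrt_support(max(fit$loglik), l2))
    expect_equal(sup$alrtc[k], alrtc_support(sup$alrt[k], 6))
  }
})

test_that("aLRT tree tests follow the published worked examples", {
  fit <- make_small_fit(seed = 93, n = 500)
  ml <- fit$candidates[[fit$ml_index]]
  # synthetic supports reproduce the printed arithmetic chains
  sup <- tibble::tibble(split = ml$splits, split_label = "",
                        l2 = NA_real_, alrt = c(0.642, 1, 1),
                        alrtc = alrtc_support(c(0.642, 1, 1), 6))
  tp <- alrt_tree_pvalues(fit, supports = sup)
  # the ML tree conflicts with nothing: p = 1, aLRTc report m - 3 = 3.000
  expect_equal(tp$p_alrt[fit$ml_index], 1)
  expect_equal(tp$p_alrtc[fit$ml_index], 3)
  # a tree clashing only with the 0.642 split: p = 0.358, aLRTc = 1.074
  clash <- which(vapply(seq_len(105), function(i) {
    t <- fit$candidates[[i]]
    !(sup$split[1] %in% t$splits) && all(sup$split[2:3] %in% t$splits)
  }, logical(1)))
  expect_gt(length(clash), 0)
  expect_equal(tp$p_alrt[clash], rep(1 - 0.642, length(clash)))
  expect_equal(tp$p_alrtc[clash], rep(3 * (1 - 0.642), length(clash)),
               tolerance = 1e-12)
  # with the delta = 3.964 support (99.3%) the chain gives 0.007 / 0.022
  sup2 <- sup; sup2$alrt[1] <- alrt_support(3.964, 0)
  tp2 <- alrt_tree_pvalues(fit, supports = sup2)
  expect_equal(round(tp2$p_alrt[clash[1]], 3), 0.007)
  expect_equal(round(tp2$p_alrtc[clash[1]], 3), 0.022)
})

test_that("aLRT confidence sets are dual to their split supports", {
  fit <- make_small_fit(seed = 94, n = 400)
  sup <- alrt_supports(fit)
  tp <- alrt_tree_pvalues(fit, supports = sup)
  for (alpha in c(0.01, 0.05, 0.2)) {
    in_set <- tp$p_alrt > alpha
    manual <- vapply(fit$candidates, function(t) {
      conf <- vapply(sup$split, topotest:::split_incompatible, logical(1), tt = t)
      all(sup$alrt[conf] < 1 - alpha)
    }, logical(1))
    expect_equal(in_set, manual)
  }
})

test_that("the split-support table spans methods with sane ranges", {
  fit <- make_small_fit(seed = 95, n = 400)
  set.seed(20)
  sup <- split_supports(fit, methods = c("KH", "chisq", "Bo"), B = 300)
  expect_equal(nrow(sup), 3)
  expect_true(all(c("KH", "chisq", "Bo", "aLRT", "aLRTc") %in% names(sup)))
  for (col in c("KH", "chisq", "Bo"))
    expect_true(all(sup[[col]] >= 0 & sup[[col]] <= 100))
  expect_true(all(sup$aLRT >= 12.5 & sup$aLRT <= 100))
  # split/tree duality for the chi-square column: a split supported at
  # >= 95 iff every candidate lacking it is rejected at alpha = 0.05
  p <- chisq_pvalues(fit)
  for (k in 1:3) {
    lacking <- !vapply(fit$candidates, function(t)
      sup$split[k] %in% t$splits, logical(1))
    expect_equal(sup$chisq[k] >= 95, all(p[lacking] <= 0.05))
  }
})
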