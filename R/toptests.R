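# ---- per-topology P-values from a site log-likelihood matrix -------------

#' Kishino-Hasegawa test of one topology against another
#'
#' One-sided z-test on the per-site log-likelihood differences
#' `d_i = l_i(tau') - l_i(tau)` of H0: `E[d_i] = 0` against HA:
#' `E[d_i] > 0`. The normal variant uses `P(Z > dbar)` with
#' `Var(dbar) = s^2/n` (`s^2` the sample variance of the `d_i`); the
#' bootstrap variant resamples the `d_i`, centers the bootstrap means at
#' zero and returns the upper tail proportion. A per-site variance reading
#' (`Var = s^2`) is available for sensitivity checks.
#'
#' @param x A `"site_loglik"`.
#' @param tau Index of the null topology.
#' @param tau_prime Index of the alternative (usually the ML tree).
#' @param variant `"normal"` or `"rell_bootstrap"`.
#' @param B Bootstrap replicates (bootstrap variant).
#' @param seed Optional seed for the bootstrap.
#' @param per_site_variance Use the literal per-site variance instead of
#'   the variance of the mean.
#' @return P-value in \[0, 1\].
#' @export
kh_pvalue <- function(x, tau, tau_prime, variant = c("normal", "rell_bootstrap"),
                      B = 10000, seed = NULL, per_site_variance = FALSE) {
  variant <- match.arg(variant)
  if (tau == tau_prime) return(1)
  d <- x$values[tau_prime, ] - x$values[tau, ]
  n <- length(d)
  if (n < 2) stop("KH test needs at least 2 sites")
  dbar <- mean(d)
  s <- sd(d)
  if (s == 0) return(if (dbar > 0) 0 else 1)
  if (variant == "normal") {
    se <- if (per_site_variance) s else s / sqrt(n)
    return(1 - pnorm(dbar / se))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  boot_means <- colMeans(matrix(d[idx], n, B))
  mean(boot_means - dbar > dbar)
}

#' KH P-values for every candidate against the ML tree
#'
#' The ML tree itself gets P-value 1 by default (no evidence against the
#' best tree); `ml_tree = "second_best"` instead tests it against the
#' second-ranked tree, mirroring the pairing some ML software reports.
#'
#' @inheritParams kh_pvalue
#' @param ml_tree `"one"` or `"second_best"`.
#' @return Numeric vector of P-values, one per candidate.
#' @export
kh_pvalues <- function(x, variant = "normal", B = 10000, seed = NULL,
                       ml_tree = c("one", "second_best"),
                       per_site_variance = FALSE) {
  ml_tree <- match.arg(ml_tree)
  ml <- x$ml_index
  p <- vapply(seq_len(n_trees(x)), function(i)
    kh_pvalue(x, i, ml, variant = variant, B = B, seed = seed,
              per_site_variance = per_site_variance), numeric(1))
  if (ml_tree == "second_best" && n_trees(x) >= 2) {
    second <- order(x$loglik, decreasing = TRUE)[2]
    p[ml] <- kh_pvalue(x, ml, second, variant = variant, B = B, seed = seed,
                       per_site_variance = per_site_variance)
  }
  p
}

#' Chi-square P-value for a log-likelihood difference
#'
#' `P(chisq_p > 2 * delta)`, where the degrees of freedom `p` equal the
#' number of edges that must be contracted to zero to reconcile the two
#' trees (half the Robinson-Foulds distance for binary trees). With zero
#' degrees of freedom the P-value is 1. The low-df refinement replaces the
#' bound by the known chi-bar-square mixtures for p = 1
#' (`P[chisq_1 > y]/2`) and p = 2 (`P[chisq_1 > y]/2 + P[chisq_2 > y]/2`);
#' larger p is unchanged.
#'
#' @param delta_loglik `l(tau') - l(tau)` (>= 0 when tau' is the ML tree).
#' @param df Nonnegative integer degrees of freedom.
#' @param low_df Apply the low degrees-of-freedom correction.
#' @return P-value in \[0, 1\].
#' @export
chisq_pvalue <- function(delta_loglik, df, low_df = FALSE) {
  if (df < 0) stop("negative degrees of freedom")
  y <- 2 * delta_loglik
  if (df == 0) return(if (y <= 0) 1 else 0)
  if (!low_df || df > 2) return(pchisq(y, df, lower.tail = FALSE))
  if (df == 1) return(pchisq(y, 1, lower.tail = FALSE) / 2)
  pchisq(y, 1, lower.tail = FALSE) / 2 + pchisq(y, 2, lower.tail = FALSE) / 2
}

# df of the 2-tree chi-square test: zero-length edges in the strict
# consensus of tau and tau', i.e. splits of tau' absent from tau
chisq_df <- function(tau, tau_prime) length(setdiff(tau_prime$splits, tau$splits))

#' Chi-square P-values for every candidate against the ML tree
#'
#' @param x A `"site_loglik"` with candidate topologies.
#' @param low_df Apply the low degrees-of-freedom correction.
#' @return Numeric vector of P-values.
#' @export
chisq_pvalues <- function(x, low_df = FALSE) {
  stopifnot(!is.null(x$candidates))
  ml <- x$candidates[[x$ml_index]]
  dl <- delta_loglik(x)
  vapply(seq_len(n_trees(x)), function(i)
    chisq_pvalue(dl[i], chisq_df(x$candidates[[i]], ml), low_df = low_df),
    numeric(1))
}

# ---- RELL bootstrap -------------------------------------------------------

#' RELL bootstrap log-likelihood sums
#'
#' Resampling of estimated log-likelihoods: each bootstrap replicate draws
#' `round(r * n)` sites uniformly with replacement (as multinomial weights
#' over the distinct site patterns) and sums each tree's site
#' log-likelihoods under those weights; all trees share the weights within
#' a replicate. No parameters are re-estimated.
#'
#' @param x A `"site_loglik"`.
#' @param B Number of bootstrap replicates.
#' @param r Resampled-length fraction (scale).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with `sums` (trees x B matrix), `B`, `r`, `ndraw`.
#' @export
rell_samples <- function(x, B = 10000, r = 1, seed = NULL) {
  stopifnot(B >= 1, r > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(x$values)
  ndraw <- as.integer(round(r * n))
  if (!is.null(x$pattern_values)) {
    W <- rell_weights_cpp(x$pattern_index, ncol(x$pattern_values),
                          ndraw, as.integer(B))
    sums <- x$pattern_values %*% W
  } else {
    W <- rell_weights_cpp(seq_len(n), n, ndraw, as.integer(B))
    sums <- x$values %*% W
  }
  list(sums = sums, B = as.integer(B), r = r, ndraw = ndraw)
}

#' Shimodaira-Hasegawa test P-values
#'
#' One shared RELL draw (scale 1) is used for all candidates. Each tree's
#' bootstrap log-likelihoods are centered at its own bootstrap mean — the
#' least-favourable configuration in which every candidate is equally good
#' — and the P-value for `tau` is the proportion of replicates in which
#' `max_j ltilde_b(j) - ltilde_b(tau)` exceeds the observed
#' `l(ML) - l(tau)`.
#'
#' @param x A `"site_loglik"` (at least 2 candidates).
#' @param B Bootstrap replicates.
#' @param seed Optional seed.
#' @param rell Optional precomputed [rell_samples()] at `r = 1` to reuse.
#' @return Numeric vector of P-values.
#' @export
sh_pvalues <- function(x, B = 10000, seed = NULL, rell = NULL) {
  stopifnot(n_trees(x) >= 2)
  if (is.null(rell)) rell <- rell_samples(x, B = B, r = 1, seed = seed)
  St <- rell$sums - rowMeans(rell$sums)
  cmax <- col_max_cpp(St)
  obs <- delta_loglik(x)
  # ties count toward the tail (bootstrap P-value convention): identical
  # candidates carry no evidence and must get P = 1, not 0
  vapply(seq_len(n_trees(x)), function(i)
    mean(cmax - St[i, ] >= obs[i]), numeric(1))
}

#' RELL bootstrap proportions
#'
#' `BP_r` for each candidate: the share of bootstrap replicates at scale
#' `r` in which that tree attains the largest resampled log-likelihood sum.
#' Exact ties split the count equally among the tied trees, so the
#' proportions always sum to 1.
#'
#' @inheritParams rell_samples
#' @param rell Optional precomputed [rell_samples()] to reuse.
#' @return Numeric vector of proportions summing to 1.
#' @export
bp_support <- function(x, B = 10000, r = 1, seed = NULL, rell = NULL) {
  if (is.null(rell)) rell <- rell_samples(x, B = B, r = r, seed = seed)
  as.numeric(col_argmax_share_cpp(rell$sums)) / rell$B
}

#' Approximately unbiased (AU) test P-values
#'
#' Multiscale RELL bootstrap: bootstrap proportions `BP_r` are computed at
#' several resampled-length fractions `r` bracketing 1, the probit
#' transforms `qnorm(1 - BP_r)` are regressed on `(sqrt(r), 1/sqrt(r))` by
#' weighted least squares (binomial-variance weights on the probit scale),
#' and the fitted signed distance `d` and curvature `c` give the P-value
#' `1 - pnorm(d - c)`. Scales with `BP_r = 0` carry no usable probit and
#' are excluded; `BP_r = 1` is clamped to `1 - 1/(2B)`. Because the probit
#' explodes as BP approaches 0, the test is numerically unstable for very
#' poorly supported trees; with `bp0_correction = TRUE` (the default and
#' the recommended reporting convention) the P-value is set to 0 whenever
#' the scale-1 bootstrap proportion is 0.
#'
#' @param x A `"site_loglik"`.
#' @param scales Resampling fractions; must bracket 1.
#' @param B Bootstrap replicates per scale.
#' @param seed Optional seed.
#' @param bp0_correction Force P = 0 when BP at scale 1 is 0.
#' @param bp_matrix Optional precomputed trees x scales BP matrix to reuse.
#' @return Tibble with one row per candidate: `p_au`, `bp` (scale-1 BP),
#'   `d`, `c`, `degenerate`.
#' @export
au_pvalues <- function(x, scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                       seed = NULL, bp0_correction = TRUE, bp_matrix = NULL) {
  stopifnot(min(scales) < 1, max(scales) >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bp_matrix)) {
    bp_matrix <- vapply(scales, function(r)
      bp_support(x, B = B, r = r), numeric(n_trees(x)))
  }
  i1 <- which.min(abs(scales - 1))
  out <- vapply(seq_len(n_trees(x)), function(i)
    au_fit_one(bp_matrix[i, ], scales, B, bp0 = bp_matrix[i, i1],
               bp0_correction = bp0_correction), numeric(4))
  tibble::tibble(p_au = out[1, ], d = out[2, ], c = out[3, ],
                 degenerate = out[4, ] > 0, bp = bp_matrix[, i1])
}

# returns c(p, d, c, degenerate)
au_fit_one <- function(bp, scales, B, bp0, bp0_correction) {
  if (bp0_correction && bp0 == 0) return(c(0, NA_real_, NA_real_, 0))
  usable <- bp > 0
  if (sum(usable) < 2)
    return(c(if (bp0 < 0.5) 0 else 1, NA_real_, NA_real_, 1))
  r <- scales[usable]
  b <- pmin(bp[usable], 1 - 1 / (2 * B))
  z <- qnorm(1 - b)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- B * stats::dnorm(z)^2 / (b * (1 - b))
  co <- unname(stats::lm.wfit(X, z, w)$coefficients)
  c(1 - pnorm(co[1] - co[2]), co[1], co[2], 0)
}

# ---- one-call summary -----------------------------------------------------

#' All topology tests at once
#'
#' Runs the requested tests on a site log-likelihood matrix and returns a
#' tidy per-candidate table. Methods: `"KH"`, `"SH"`, `"AU"` (BP = 0
#' corrected), `"AUu"` (uncorrected AU), `"chisq"`, `"chisq_lowdf"`,
#' `"Bo"` (Bonferroni vs the ML tree), `"Bom"` (Bonferroni with the
#' minimum P-value), `"BH"` (Benjamini-Hochberg), `"chisq_min"` /
#' `"chisq_lowdf_min"` / `"KH_min"` (uncorrected minimum P-value over the
#' compatible set), `"aLRT"` and `"aLRTc"` (support-derived tree tests;
#' binary candidates required). RELL draws are shared where scales and B
#' agree.
#'
#' @param x A `"site_loglik"` (with candidates for the structure-aware
#'   methods).
#' @param methods Character vector of method names.
#' @param B Bootstrap replicates for SH.
#' @param au_B Bootstrap replicates per AU scale.
#' @param au_scales AU resampling fractions.
#' @param seed Optional seed for all resampling.
#' @param low_df_base Use the low-df chi-square as the Bonferroni/BH base
#'   test.
#' @param newick Include a Newick string column for the candidates
#'   (disabled in bulk simulation loops where formatting 105 trees per
#'   replicate is measurable overhead).
#' @return A tibble: `tree` (index), `newick` (if candidates are present),
#'   `logL`, `delta`, then one `p_<method>` column per method (and `bp`
#'   when AU runs).
#' @export
topology_tests <- function(x, methods = c("KH", "SH", "AU", "chisq", "Bo"),
                           B = 10000, au_B = 10000,
                           au_scales = seq(0.5, 1.4, by = 0.1),
                           seed = NULL, low_df_base = FALSE, newick = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  known <- c("KH", "SH", "AU", "AUu", "chisq", "chisq_lowdf", "Bo", "Bom",
             "BH", "chisq_min", "chisq_lowdf_min", "KH_min", "aLRT", "aLRTc")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  out <- tibble::tibble(tree = seq_len(n_trees(x)),
                        logL = x$loglik, delta = delta_loglik(x))
  if (!is.null(x$candidates) && newick)
    out <- tibble::add_column(out,
      newick = vapply(x$candidates, format, character(1)), .after = "tree")

  rell1 <- NULL
  need_rell1 <- any(c("SH") %in% methods) ||
    (any(c("AU", "AUu") %in% methods) && au_B == B)
  if (need_rell1) rell1 <- rell_samples(x, B = B, r = 1)

  if ("KH" %in% methods) out$p_KH <- kh_pvalues(x)
  if ("SH" %in% methods) out$p_SH <- sh_pvalues(x, rell = rell1)
  if (any(c("AU", "AUu") %in% methods)) {
    bp_matrix <- vapply(au_scales, function(r) {
      if (abs(r - 1) < 1e-12 && !is.null(rell1) && rell1$B == au_B)
        bp_support(x, rell = rell1)
      else bp_support(x, B = au_B, r = r)
    }, numeric(n_trees(x)))
    if ("AU" %in% methods) {
      au <- au_pvalues(x, scales = au_scales, B = au_B,
                       bp_matrix = bp_matrix, bp0_correction = TRUE)
      out$p_AU <- au$p_au
      out$bp <- au$bp
    }
    if ("AUu" %in% methods) {
      auu <- au_pvalues(x, scales = au_scales, B = au_B,
                        bp_matrix = bp_matrix, bp0_correction = FALSE)
      out$p_AUu <- auu$p_au
      if (is.null(out$bp)) out$bp <- auu$bp
    }
  }
  if ("chisq" %in% methods) out$p_chisq <- chisq_pvalues(x)
  if ("chisq_lowdf" %in% methods) out$p_chisq_lowdf <- chisq_pvalues(x, low_df = TRUE)
  if ("Bo" %in% methods)
    out$p_Bo <- bonferroni_pvalues(x, mode = "ml", low_df = low_df_base)
  if ("Bom" %in% methods)
    out$p_Bom <- bonferroni_pvalues(x, mode = "minimum", low_df = low_df_base)
  if ("BH" %in% methods)
    out$p_BH <- bh_pvalues(x, low_df = low_df_base)
  if ("chisq_min" %in% methods)
    out$p_chisq_min <- minimum_pvalues(x, base_test = chisq_base_test(FALSE))
  if ("chisq_lowdf_min" %in% methods)
    out$p_chisq_lowdf_min <- minimum_pvalues(x, base_test = chisq_base_test(TRUE))
  if ("KH_min" %in% methods)
    out$p_KH_min <- minimum_pvalues(x, base_test = kh_base_test())
  if (any(c("aLRT", "aLRTc") %in% methods)) {
    sup <- alrt_supports(x)
    tp <- alrt_tree_pvalues(x, supports = sup)
    if ("aLRT" %in% methods) out$p_aLRT <- tp$p_alrt
    if ("aLRTc" %in% methods) out$p_aLRTc <- tp$p_alrtc
  }
  out
}
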