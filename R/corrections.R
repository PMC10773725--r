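# ---- selection-bias corrections ------------------------------------------
#
# Testing a topology tau against the data-selected ML tree inflates
# significance. The correction recasts the null as the strict consensus
# tau0 of tau and the ML tree, treats every candidate compatible with tau0
# as a potential alternative, and adjusts the 2-tree P-value for that
# multiplicity.

#' Chi-square 2-tree base test
#'
#' Returns a base-test closure `p(x, tau, tau_prime)` for use with the
#' Bonferroni / Benjamini-Hochberg corrections: the chi-square P-value at
#' statistic `2*(l(tau') - l(tau))` with degrees of freedom equal to the
#' number of zero-length edges in the strict consensus of the two trees.
#'
#' @param low_df Use the low degrees-of-freedom refinement.
#' @return A function `(x, tau, tau_prime) -> P-value`.
#' @export
chisq_base_test <- function(low_df = FALSE) {
  function(x, tau, tau_prime) {
    delta <- x$loglik[tau_prime] - x$loglik[tau]
    chisq_pvalue(delta, chisq_df(x$candidates[[tau]], x$candidates[[tau_prime]]),
                 low_df = low_df)
  }
}

#' KH 2-tree base test
#'
#' @inheritParams kh_pvalue
#' @return A function `(x, tau, tau_prime) -> P-value` applying the
#'   normal-theory KH z-test.
#' @export
kh_base_test <- function(per_site_variance = FALSE) {
  function(x, tau, tau_prime)
    kh_pvalue(x, tau, tau_prime, per_site_variance = per_site_variance)
}

# context for one tested topology: the consensus null and its compatible set
correction_context <- function(x, tau) {
  tau_hat <- x$ml_index
  tau0 <- strict_consensus(x$candidates[[tau]], x$candidates[[tau_hat]])
  list(tau = tau, tau_hat = tau_hat, tau0 = tau0,
       A = compatible_set(tau0, x$candidates, indices = TRUE))
}

#' Approximate Bonferroni-corrected P-values
#'
#' For each candidate `tau`, forms the strict consensus `tau0` with the ML
#' tree and the compatible set `A(tau0)`, then corrects the base-test
#' P-value for the `|A(tau0)|` implicit comparisons via the
#' independent-tests form `1 - (1 - p)^|A(tau0)|`, which is always a valid
#' probability (the raw product `|A| * p` is not). `mode = "ml"` (the
#' cheap default) uses `p = p(tau, ML tree)`; `mode = "minimum"` uses the
#' minimum base P-value over all alternatives in `A(tau0)` and is the less
#' conservative variant.
#'
#' @param x A `"site_loglik"` with candidate topologies.
#' @param mode `"ml"` or `"minimum"`.
#' @param base_test A 2-tree base test closure; default chi-square.
#' @param low_df Convenience switch for the default chi-square base.
#' @return Numeric vector of corrected P-values in \[0, 1\].
#' @export
bonferroni_pvalues <- function(x, mode = c("ml", "minimum"), base_test = NULL,
                               low_df = FALSE) {
  mode <- match.arg(mode)
  stopifnot(!is.null(x$candidates))
  if (is.null(base_test)) base_test <- chisq_base_test(low_df)
  vapply(seq_len(n_trees(x)), function(tau) {
    ctx <- correction_context(x, tau)
    p <- if (mode == "ml") base_test(x, tau, ctx$tau_hat)
         else min(vapply(ctx$A, function(tp) base_test(x, tau, tp), numeric(1)))
    1 - (1 - p)^length(ctx$A)
  }, numeric(1))
}

#' Benjamini-Hochberg corrected P-values
#'
#' `|A(tau0)| * min_k p_(k) / k` over the ordered base-test P-values
#' `p_(1) <= p_(2) <= ...` across the compatible set, capped at 1. Always
#' no larger than the minimum-mode Bonferroni value.
#'
#' @inheritParams bonferroni_pvalues
#' @return Numeric vector of corrected P-values in \[0, 1\].
#' @export
bh_pvalues <- function(x, base_test = NULL, low_df = FALSE) {
  stopifnot(!is.null(x$candidates))
  if (is.null(base_test)) base_test <- chisq_base_test(low_df)
  vapply(seq_len(n_trees(x)), function(tau) {
    ctx <- correction_context(x, tau)
    ps <- sort(vapply(ctx$A, function(tp) base_test(x, tau, tp), numeric(1)))
    min(1, length(ps) * min(ps / seq_along(ps)))
  }, numeric(1))
}

#' Uncorrected minimum P-value over the compatible set
#'
#' The raw `min` over `A(tau0)` of the 2-tree base test, with no
#' multiplicity adjustment — the quantity the Bonferroni correction
#' repairs. Exposed to quantify the selection-bias effect.
#'
#' @inheritParams bonferroni_pvalues
#' @return Numeric vector of P-values.
#' @export
minimum_pvalues <- function(x, base_test = NULL, low_df = FALSE) {
  stopifnot(!is.null(x$candidates))
  if (is.null(base_test)) base_test <- chisq_base_test(low_df)
  vapply(seq_len(n_trees(x)), function(tau) {
    ctx <- correction_context(x, tau)
    min(vapply(ctx$A, function(tp) base_test(x, tau, tp), numeric(1)))
  }, numeric(1))
}
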