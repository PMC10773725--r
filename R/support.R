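# ---- split support values -------------------------------------------------

#' aLRT support with the cubic correction
#'
#' `Fstar(2 * (l1 - l2))^3` where `Fstar(x) = 1/2 + P[chisq_1 <= x]/2`,
#' `l1` is the maximized log-likelihood of the ML tree and `l2` the better
#' of the two nearest-neighbor-interchange alternatives across the focal
#' split. Ranges over \[0.125, 1\]; 0.125 at `l1 = l2`.
#'
#' @param l1 Log-likelihood of the ML tree.
#' @param l2 Next-best log-likelihood among the two NNI alternatives
#'   (must not exceed `l1`).
#' @return Support value in \[0.125, 1\].
#' @export
alrt_support <- function(l1, l2) {
  if (any(l1 < l2)) stop("l1 < l2: the focal tree is not the ML resolution")
  fstar(2 * (l1 - l2))^3
}

fstar <- function(x) 0.5 + pchisq(x, df = 1) / 2

#' Multiplicity-corrected aLRT (aLRTc) support
#'
#' `1 - (m - 3) * (1 - aLRT)`: a Bonferroni adjustment over the `m - 3`
#' internal splits of a tree, so that accepting every split with aLRTc
#' support above `1 - alpha` controls the tree-level error at `alpha`.
#' Deliberately uncapped — values can be negative, signalling that the
#' corrected support is not itself a probability.
#'
#' @param alrt aLRT support value(s).
#' @param m Number of taxa (>= 4).
#' @return Corrected support (may be negative).
#' @export
alrtc_support <- function(alrt, m) {
  stopifnot(m >= 4)
  1 - (m - 3) * (1 - alrt)
}

#' Support for a split from confidence-set P-values
#'
#' The smallest level at which "every tree in the confidence set contains
#' the split" rejects is the largest P-value among candidates lacking the
#' split; support is one minus that. Requires at least one candidate
#' without the split, else the support is undefined (`NA` with a warning).
#'
#' @param x A `"site_loglik"` with candidates.
#' @param pvals Per-candidate P-values (same order as candidates).
#' @param s Canonical split mask.
#' @return Support in \[0, 1\], or `NA`.
#' @export
split_support_from_pvalues <- function(x, pvals, s) {
  has <- vapply(x$candidates, function(tt) s %in% tt$splits, logical(1))
  if (all(has)) {
    warning("every candidate contains the split; support undefined")
    return(NA_real_)
  }
  1 - max(pvals[!has])
}

#' aLRT supports for every split of the ML tree
#'
#' For each internal split of the ML candidate, finds the two
#' nearest-neighbor-interchange alternatives, takes their maximized
#' log-likelihoods (looked up among the fitted candidates, or re-optimized
#' from `aln` if absent), and applies the cubic aLRT formula plus the
#' aLRTc multiplicity correction.
#'
#' @param x A `"topo_fit"`/`"site_loglik"` with candidates; the ML
#'   candidate must be binary.
#' @param aln,model Optional alignment and model to refit NNI alternatives
#'   missing from the candidate set.
#' @return Tibble: `split` (mask), `split_label`, `l2`, `alrt`, `alrtc`.
#' @export
alrt_supports <- function(x, aln = NULL, model = NULL) {
  stopifnot(!is.null(x$candidates))
  ml <- x$candidates[[x$ml_index]]
  if (!is_binary(ml)) stop("aLRT supports require a binary ML tree")
  keys <- vapply(x$candidates, function(tt) paste(tt$splits, collapse = "."),
                 character(1))
  l1 <- x$loglik[x$ml_index]
  m <- length(ml$labels)
  rows <- lapply(ml$splits, function(s) {
    alts <- nni_alternatives(ml, s)
    ll <- vapply(alts, function(a) {
      i <- match(paste(a$splits, collapse = "."), keys)
      if (!is.na(i)) return(x$loglik[i])
      if (is.null(aln)) stop("NNI alternative not among candidates; ",
                             "supply 'aln' (and 'model') to refit")
      optimize_edge_lengths(a, aln, if (is.null(model)) x$model else model)$loglik
    }, numeric(1))
    l2 <- max(ll)
    a <- alrt_support(l1, l2)
    tibble::tibble(split = s, split_label = split_label(s, ml$labels),
                   l2 = l2, alrt = a, alrtc = alrtc_support(a, m))
  })
  dplyr::bind_rows(rows)
}

#' Tree-level P-values from aLRT split supports
#'
#' A tree conflicts with the ML tree through the ML splits incompatible
#' with it; let `M(tau)` be the maximum aLRT support among those. The
#' aLRT tree test has P-value `1 - M(tau)` and the multiplicity-corrected
#' (aLRTc) P-value `(m - 3) * (1 - M(tau))`, reported uncapped (the ML
#' tree itself has `M = 0`, hence aLRTc value `m - 3`); cap at 1 wherever
#' a probability is required.
#'
#' @param x A `"site_loglik"` with candidates.
#' @param supports Output of [alrt_supports()] (computed if `NULL`).
#' @return Tibble: `tree`, `M`, `p_alrt`, `p_alrtc`.
#' @export
alrt_tree_pvalues <- function(x, supports = NULL) {
  if (is.null(supports)) supports <- alrt_supports(x)
  ml <- x$candidates[[x$ml_index]]
  m <- length(ml$labels)
  M <- vapply(x$candidates, function(tt) {
    inc <- vapply(supports$split, function(s) split_incompatible(s, tt), logical(1))
    if (!any(inc)) 0 else max(supports$alrt[inc])
  }, numeric(1))
  tibble::tibble(tree = seq_along(x$candidates), M = M,
                 p_alrt = 1 - M, p_alrtc = (m - 3) * (1 - M))
}

# is split s incompatible with topology tt (i.e. no refinement of tt
# contains s)?
split_incompatible <- function(s, tt) {
  if (s %in% tt$splits) return(FALSE)
  m <- length(tt$labels)
  if (is_binary(tt)) return(TRUE)  # binary trees are maximal
  any(!vapply(tt$splits, splits_compatible, logical(1), b = s, m = m))
}

#' Split-support table across methods
#'
#' Support values for every internal split of the ML tree, one column per
#' testing method (confidence-set supports `1 - max P over trees lacking
#' the split`) plus the aLRT and aLRTc supports. Mirrors the customary
#' per-split reporting layout of ML phylogenetics software.
#'
#' @param x A `"topo_fit"`/`"site_loglik"` with candidates (binary ML
#'   tree).
#' @param tests Optional precomputed [topology_tests()] tibble; computed
#'   with `methods` otherwise.
#' @param methods Methods passed to [topology_tests()] when `tests` is
#'   `NULL`.
#' @param percent Report supports as percentages.
#' @param ... Passed to [topology_tests()].
#' @return Tibble: `split_label`, one column per method, `aLRT`, `aLRTc`.
#' @export
split_supports <- function(x, tests = NULL,
                           methods = c("SH", "KH", "AU", "chisq", "Bo"),
                           percent = TRUE, ...) {
  if (is.null(tests)) tests <- topology_tests(x, methods = methods, ...)
  pcols <- grep("^p_(?!aLRT)", names(tests), value = TRUE, perl = TRUE)
  # present columns in the requested method order (the customary layout)
  pcols <- c(intersect(paste0("p_", methods), pcols),
             setdiff(pcols, paste0("p_", methods)))
  ml <- x$candidates[[x$ml_index]]
  out <- tibble::tibble(split = ml$splits,
                        split_label = vapply(ml$splits, split_label,
                                             character(1), labels = ml$labels))
  for (pc in pcols) {
    sup <- vapply(ml$splits, function(s)
      split_support_from_pvalues(x, tests[[pc]], s), numeric(1))
    out[[sub("^p_", "", pc)]] <- sup
  }
  al <- alrt_supports(x)
  out$aLRT <- al$alrt[match(out$split, al$split)]
  out$aLRTc <- al$alrtc[match(out$split, al$split)]
  if (percent)
    out <- dplyr::mutate(out, dplyr::across(-c("split", "split_label"),
                                            ~ 100 * .x))
  out
}
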