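# ---- confidence sets and study metrics ------------------------------------

#' Confidence set of topologies
#'
#' Membership rule: a candidate belongs to the `(1 - alpha)` set iff its
#' P-value is strictly larger than `alpha`.
#'
#' @param pvals Per-candidate P-values.
#' @param alpha Level (default 0.05).
#' @return Integer indices of the member candidates.
#' @export
confidence_set <- function(pvals, alpha = 0.05) which(pvals > alpha)

#' Coverage over replicates (possibly several true trees)
#'
#' With zero-length edges in the generating tree, every binary resolution
#' compatible with its contraction is true; per-replicate coverage is the
#' fraction of those true trees inside the set, and the statistic averages
#' it over replicates (in percent).
#'
#' @param member Logical matrix, replicates x candidates (set membership).
#' @param true_idx Indices of the true candidates (non-empty).
#' @return Percentage in \[0, 100\].
#' @export
coverage_stat <- function(member, true_idx) {
  if (length(true_idx) == 0) stop("no true trees supplied")
  100 * mean(rowMeans(member[, true_idx, drop = FALSE]))
}

#' Mean and SD of confidence-set size over replicates
#'
#' @param member Logical matrix, replicates x candidates.
#' @return Named numeric: `mean`, `sd` (`sd` is `NA` for one replicate).
#' @export
mean_set_size_stat <- function(member) {
  sizes <- rowSums(member)
  c(mean = mean(sizes), sd = if (length(sizes) > 1) sd(sizes) else NA_real_)
}

#' Monte Carlo coverage / set-size study
#'
#' The full simulation loop: build the generating tree, enumerate all
#' binary candidates, then per replicate simulate an alignment, fit every
#' candidate, compute each requested method's P-values and record the
#' `(1 - alpha)` confidence sets. Everything is deterministic given
#' `seed`: replicate `i` reseeds the RNG at `seed + i`, so replicates are
#' independent of execution order.
#'
#' @param m Number of taxa (enumeration limit applies: 4..8).
#' @param setting Generating-tree setting, see [study_tree()].
#' @param internal_length Non-zero internal edge length of the generating
#'   tree.
#' @param terminal_length Terminal edge length.
#' @param n_sites Alignment length per replicate.
#' @param n_reps Number of simulated data sets.
#' @param methods Method names as in [topology_tests()].
#' @param alpha Test level.
#' @param model Substitution model used both to simulate and to fit
#'   (parameters are frozen, not re-estimated per topology).
#' @param B,au_B,au_scales Resampling settings for SH / AU.
#' @param seed Master seed (keep small; per-replicate seeds are
#'   `seed + 1 .. seed + n_reps`).
#' @param progress Print a dot every 10 replicates.
#' @return A `"study_result"`: see [tidy.study_result()].
#' @export
run_study <- function(m = 6, setting = "positive", internal_length = 0.1,
                      terminal_length = 0.1, n_sites = 1000, n_reps = 100,
                      methods = c("SH", "KH", "AU", "chisq", "Bo"),
                      alpha = 0.05, model = hky_model(kappa = 2,
                        base_freqs = c(0.1, 0.2, 0.3, 0.4), gamma_shape = 1,
                        n_rate_categories = 4),
                      B = 10000, au_B = 10000,
                      au_scales = seq(0.5, 1.4, by = 0.1),
                      seed = 1, progress = FALSE) {
  stopifnot(n_reps >= 1)
  tree <- study_tree(m, setting, internal_length, terminal_length)
  labels <- sort(tree$tip.label)
  candidates <- enumerate_topologies(labels)
  truth <- as_topology(tree, labels, collapse_zero = TRUE)
  true_idx <- compatible_set(truth, candidates, indices = TRUE)
  prepared <- prepare_engine_trees(candidates, labels)
  ntree <- length(candidates)

  member <- setNames(lapply(methods, function(m)
    matrix(NA, n_reps, ntree)), methods)
  failures <- 0L
  for (rep in seq_len(n_reps)) {
    set.seed(seed + rep)
    res <- tryCatch({
      aln <- simulate_alignment(tree, model, n_sites)
      fit <- fit_topologies(aln, candidates, model, prepared = prepared)
      topology_tests(fit, methods = methods, B = B, au_B = au_B,
                     au_scales = au_scales, newick = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning("replicate ", rep, " failed: ", conditionMessage(res))
      next
    }
    for (meth in methods)
      member[[meth]][rep, ] <- res[[paste0("p_", meth)]] > alpha
    if (progress && rep %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  ok <- stats::complete.cases(member[[methods[1]]])
  member <- lapply(member, function(mm) mm[ok, , drop = FALSE])

  n_correct <- length(true_idx)
  n_incorrect <- ntree - n_correct
  summary <- dplyr::bind_rows(lapply(methods, function(meth) {
    mm <- member[[meth]]
    sz <- mean_set_size_stat(mm)
    cov <- coverage_stat(mm, true_idx)
    avg_power <- if (n_incorrect > 0)
      mean(1 - mm[, -true_idx, drop = FALSE]) else NA_real_
    tibble::tibble(method = meth, coverage = cov,
                   mean_set_size = sz[["mean"]], sd_set_size = sz[["sd"]],
                   avg_power = avg_power)
  }))
  structure(list(
    summary = summary, member = member, true_idx = true_idx,
    n_correct = n_correct, n_incorrect = n_incorrect,
    n_reps = sum(ok), failures = failures,
    config = list(m = m, setting = setting,
                  internal_length = internal_length,
                  terminal_length = terminal_length, n_sites = n_sites,
                  n_reps = n_reps, methods = methods, alpha = alpha,
                  B = B, au_B = au_B, au_scales = au_scales, seed = seed)),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<study_result> m=%d %s tI=%g, n=%d sites, %d replicates\n",
              cfg$m, cfg$setting, cfg$internal_length, cfg$n_sites, x$n_reps))
  cat(sprintf("  %d true tree(s) of %d candidates\n", x$n_correct,
              x$n_correct + x$n_incorrect))
  df <- as.data.frame(x$summary)
  df$entry <- sprintf("%.0f/%.0f (%.0f)", df$coverage, df$mean_set_size,
                      ifelse(is.na(df$sd_set_size), 0, df$sd_set_size))
  print(df[, c("method", "coverage", "mean_set_size", "sd_set_size", "entry")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

# mean set size = NI - NI * avg power + NC * coverage (exact identity)
set_size_identity_gap <- function(x) {
  pw <- ifelse(is.na(x$summary$avg_power), 0, x$summary$avg_power)
  x$summary$mean_set_size -
    (x$n_incorrect - x$n_incorrect * pw +
       x$n_correct * x$summary$coverage / 100)
}
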