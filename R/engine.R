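# ---- site log-likelihood container ---------------------------------------

#' Site log-likelihood matrix
#'
#' The substrate of every topology test: a trees x sites matrix of per-site
#' log-likelihoods, with row sums the maximized log-likelihoods `l(tau)`.
#' The maximum-likelihood tree index is the row with the largest sum, ties
#' broken by lowest index. Usually produced by [fit_topologies()] or
#' [parse_sitelh()]; construct directly to score externally computed fits.
#'
#' @param values Numeric matrix (trees x sites).
#' @param candidates Optional list of `"topology"` objects, one per row;
#'   required by tests that use tree structure (chi-square df, Bonferroni,
#'   split supports).
#' @param pattern_values Optional compressed form: trees x patterns matrix.
#' @param pattern_weights,pattern_index Pattern counts and site -> pattern
#'   map matching `pattern_values`.
#' @return Object of class `"site_loglik"`.
#' @export
site_loglik_matrix <- function(values, candidates = NULL, pattern_values = NULL,
                               pattern_weights = NULL, pattern_index = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), all(is.finite(values)))
  if (!is.null(candidates)) stopifnot(length(candidates) == nrow(values))
  loglik <- rowSums(values)
  structure(list(values = values, loglik = loglik,
                 ml_index = which.max(loglik),
                 candidates = candidates,
                 pattern_values = pattern_values,
                 pattern_weights = pattern_weights,
                 pattern_index = pattern_index),
            class = "site_loglik")
}

#' @export
print.site_loglik <- function(x, ...) {
  cat(sprintf("<site_loglik> %d trees x %d sites; ML tree #%d (logL %.3f)\n",
              nrow(x$values), ncol(x$values), x$ml_index,
              x$loglik[x$ml_index]))
  invisible(x)
}

n_trees <- function(x) nrow(x$values)

# delta log-likelihoods l(ml) - l(tau), >= 0
delta_loglik <- function(x) max(x$loglik) - x$loglik

# ---- engine plumbing ------------------------------------------------------

# engine tree encoding: edge matrix with tip ids matched to 'labels' order,
# internal ids untouched (ape convention: tips 1..m, internals m+1..)
engine_tree <- function(phy, labels, lengths = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!setequal(phy$tip.label, labels))
    stop("tree tips do not match alignment taxa")
  edge <- phy$edge
  tip <- edge[, 2] <= length(labels)
  edge[tip, 2] <- match(phy$tip.label[edge[tip, 2]], labels)
  if (is.null(lengths)) lengths <- phy$edge.length
  if (is.null(lengths)) stop("tree has no edge lengths")
  if (any(lengths < 0)) stop("negative edge length")
  storage.mode(edge) <- "integer"
  list(edge = edge, length = as.numeric(lengths))
}

prepare_engine_trees <- function(candidates, labels, start_length = 0.1) {
  lapply(candidates, function(top) {
    phy <- as_phylo(top,
                    internal_lengths = rep(start_length, length(top$splits)),
                    terminal_lengths = rep(start_length, length(top$labels)))
    engine_tree(phy, labels)
  })
}

run_engine <- function(engine_trees, aln, model, optimise, max_cycles, tol) {
  pat <- compress_patterns(aln)
  tips <- pat$states - 1L
  res <- fit_trees_cpp(engine_trees, tips, pat$weights, model_for_engine(model),
                       optimise, as.integer(max_cycles), tol)
  res$pattern <- pat
  res
}

# ---- user-facing operations ----------------------------------------------

#' Per-site log-likelihoods of a fixed tree
#'
#' Pruning-algorithm site log-likelihoods under HKY+Gamma for a tree with
#' given edge lengths (no optimization). Sites with zero probability (e.g.
#' conflicting states across a path of total length 0) return `-Inf`.
#'
#' @param tree An ape `phylo` with edge lengths.
#' @param aln A `"dna_alignment"` over the same taxa.
#' @param model A `"subst_model"`.
#' @return Numeric vector of length `n_sites(aln)`, values `<= 0`.
#' @export
site_log_likelihoods <- function(tree, aln, model) {
  et <- engine_tree(tree, aln$labels)
  res <- run_engine(list(et), aln, model, FALSE, 0L, 0)
  v <- res$pattern_loglik[1, res$pattern$index]
  v[v <= -1e9] <- -Inf
  v
}

#' Maximum-likelihood edge lengths for one topology
#'
#' Optimizes all edge lengths (terminal and internal) of a topology by
#' cyclic per-edge Newton updates, holding the substitution model fixed.
#' Lengths are bounded to `[0, 10]`; the zero boundary is attained exactly
#' when the data support a contracted edge. Non-binary topologies
#' (consensus trees) are fitted as well.
#'
#' @param top A `"topology"` or a `phylo` (starting lengths taken from the
#'   tree if present).
#' @param aln A `"dna_alignment"`.
#' @param model A `"subst_model"`.
#' @param start_length Starting value for all edge lengths.
#' @param max_cycles Maximum optimization cycles over all edges.
#' @param tol Stop when a full cycle improves the log-likelihood by less
#'   than this.
#' @return List with elements `tree` (a `phylo` with optimized lengths),
#'   `loglik`, `site_loglik`, `converged`, and `cycles`.
#' @export
optimize_edge_lengths <- function(top, aln, model, start_length = 0.1,
                                  max_cycles = 100, tol = 1e-6) {
  phy <- if (inherits(top, "topology")) {
    as_phylo(top, rep(start_length, length(top$splits)),
             rep(start_length, length(top$labels)))
  } else top
  if (is.null(phy$edge.length)) phy$edge.length <- rep(start_length, nrow(phy$edge))
  et <- engine_tree(phy, aln$labels)
  res <- run_engine(list(et), aln, model, TRUE, max_cycles, tol)
  phy$edge.length <- res$lengths[[1]]
  list(tree = phy, loglik = res$loglik[1],
       site_loglik = res$pattern_loglik[1, res$pattern$index],
       converged = res$cycles[1] < max_cycles, cycles = res$cycles[1])
}

#' Fit every candidate topology and assemble the site log-likelihood matrix
#'
#' Optimizes edge lengths for each candidate under a fixed substitution
#' model and returns the trees x sites matrix of per-site log-likelihoods,
#' the maximized log-likelihoods and the ML tree index (ties broken by
#' lowest candidate index). Substitution parameters (kappa, gamma shape)
#' are not re-optimized per topology.
#'
#' @param aln A `"dna_alignment"`.
#' @param candidates List of `"topology"` objects sharing the alignment's
#'   taxa, e.g. from [enumerate_topologies()].
#' @param model A `"subst_model"`.
#' @param optimise If `FALSE`, score candidates at the starting lengths.
#' @inheritParams optimize_edge_lengths
#' @param prepared Internal: pre-built engine encodings of `candidates`
#'   (reused across replicates by [run_study()]).
#' @return A `"site_loglik"` object (subclass `"topo_fit"`) with fitted
#'   edge lengths in `$fitted_lengths`.
#' @export
fit_topologies <- function(aln, candidates, model, optimise = TRUE,
                           start_length = 0.1, max_cycles = 100, tol = 1e-6,
                           prepared = NULL) {
  stopifnot(length(candidates) >= 1)
  if (is.null(prepared))
    prepared <- prepare_engine_trees(candidates, aln$labels, start_length)
  res <- run_engine(prepared, aln, model, optimise, max_cycles, tol)
  x <- site_loglik_matrix(res$pattern_loglik[, res$pattern$index, drop = FALSE],
                          candidates = candidates,
                          pattern_values = res$pattern_loglik,
                          pattern_weights = res$pattern$weights,
                          pattern_index = res$pattern$index)
  x$fitted_lengths <- res$lengths
  x$cycles <- res$cycles
  x$model <- model
  class(x) <- c("topo_fit", class(x))
  x
}
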