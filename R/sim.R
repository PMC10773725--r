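# ---- study trees ----------------------------------------------------------

#' Caterpillar study trees with optional zero-length internal edges
#'
#' Builds the simulation trees used in the coverage experiments: a
#' caterpillar topology on `m` taxa whose internal edges, ordered along the
#' backbone, are set per `setting`. Terminal edges all get
#' `terminal_length`. Settings:
#' \describe{
#'   \item{`positive`}{all internal edges equal `internal_length`}
#'   \item{`one_zero`}{the first internal edge 0, the rest `internal_length`}
#'   \item{`two_separated_zero`}{internal edges 1 and 3 set to 0 (they do
#'     not share a node)}
#'   \item{`two_adjacent_zero`}{internal edges 1 and 2 set to 0 (they share
#'     a node)}
#'   \item{`star`}{no internal structure at all}
#' }
#' Which particular edges carry the zeros is immaterial to coverage and
#' set-size distributions, by exchangeability of taxon labels under the
#' simulation model.
#'
#' @param m Number of taxa (>= 4; >= 6 for the two-zero settings).
#' @param setting One of the strings above.
#' @param internal_length Length of the non-zero internal edges.
#' @param terminal_length Length of every terminal edge.
#' @param labels Taxon labels, default `t1..tm`.
#' @return An ape `phylo` with edge lengths.
#' @export
study_tree <- function(m = 6,
                       setting = c("positive", "one_zero",
                                   "two_separated_zero", "two_adjacent_zero",
                                   "star"),
                       internal_length = 0.1, terminal_length = 0.1,
                       labels = paste0("t", seq_len(m))) {
  setting <- match.arg(setting)
  stopifnot(m >= 4, length(labels) == m, internal_length >= 0)
  n_int <- m - 3L
  if (setting == "star")
    return(as_phylo(topology(labels), terminal_lengths = rep(terminal_length, m)))
  zero <- switch(setting,
    positive = integer(0),
    one_zero = 1L,
    two_separated_zero = c(1L, 3L),
    two_adjacent_zero = c(1L, 2L))
  if (length(zero) && max(zero) > n_int)
    stop("setting '", setting, "' is impossible with ", m,
         " taxa (needs at least ", max(zero) + 3L, ")")
  # caterpillar: internal split k groups taxa 1..(k+1) against the rest
  sides <- lapply(seq_len(n_int), function(k) labels[seq_len(k + 1L)])
  top <- topology(labels, sides)
  lens <- rep(internal_length, n_int)
  lens[zero] <- 0
  # topology() sorts splits by mask; map lengths accordingly
  masks <- vapply(sides, make_split, integer(1), labels = labels)
  lens <- lens[match(top$splits, masks)]
  as_phylo(top, internal_lengths = lens,
           terminal_lengths = rep(terminal_length, m))
}

# ---- sequence simulation --------------------------------------------------

#' Simulate a DNA alignment under HKY+Gamma
#'
#' Sites are i.i.d.: each draws a gamma rate category, a root state from
#' the stationary frequencies, and evolves down every edge with the HKY
#' transition probabilities scaled by the category rate. Identical seeds
#' give identical alignments.
#'
#' @param tree An ape `phylo` with edge lengths (zero lengths allowed).
#' @param model A `"subst_model"`.
#' @param n_sites Number of sites (>= 1).
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (so callers can manage reproducibility themselves).
#' @return A `"dna_alignment"` with the tree's tip labels, taxa in
#'   alphabetical tip-label order.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  K <- length(model$rates)
  cat_of_site <- if (K == 1L) rep(1L, n_sites) else
    sample.int(K, n_sites, replace = TRUE)
  nnode <- max(edge)
  states <- matrix(0L, nnode, n_sites)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = model$pi)
  # parent-before-child edge order
  ord <- order(match(edge[, 1], c(root, edge[, 2])))
  for (e in ord) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    if (len[e] == 0) { states[ch, ] <- states[p, ]; next }
    for (k in seq_len(K)) {
      P <- transition_matrix(model, len[e], model$rates[k])
      sites_k <- which(cat_of_site == k)
      if (!length(sites_k)) next
      ps <- states[p, sites_k]
      for (s in 1:4) {
        idx <- sites_k[ps == s]
        if (length(idx))
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  labels <- sort(tree$tip.label)
  dna_alignment(states[match(labels, tree$tip.label), , drop = FALSE], labels)
}
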