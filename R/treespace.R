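#' @useDynLib topotest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq pnorm qnorm qgamma pgamma rnorm runif sd var setNames
#' @importFrom rlang .data
NULL

# ---- split encoding -------------------------------------------------------
#
# A split (bipartition A|B of the taxa) is stored as an integer bitmask over
# the taxon order, bit i-1 for taxon i, canonicalised to the side NOT
# containing the first taxon (so bit 0 is always clear and A|B == B|A).
# Taxon order is fixed for the lifetime of an analysis.

full_mask <- function(m) bitwShiftL(1L, m) - 1L

canonical_mask <- function(mask, m) {
  if (bitwAnd(mask, 1L) != 0L) bitwAnd(bitwNot(mask), full_mask(m)) else mask
}

popcount <- function(mask) {
  n <- 0L
  while (any(mask > 0L)) {
    n <- n + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  n
}

mask_taxa <- function(mask, labels) labels[bitwAnd(bitwShiftR(mask, seq_along(labels) - 1L), 1L) == 1L]

#' Render a split as taxon-set notation
#'
#' @param mask Canonical split bitmask.
#' @param labels Taxon labels (order defines the encoding).
#' @return A string `"A,B|C,D"`, smaller side first.
#' @export
split_label <- function(mask, labels) {
  m <- length(labels)
  a <- mask_taxa(mask, labels)
  b <- setdiff(labels, a)
  paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
}

#' Construct a split bitmask from one side of a bipartition
#'
#' @param side Character vector of taxon labels on one side.
#' @param labels Full taxon label vector.
#' @return Canonical integer bitmask.
#' @export
make_split <- function(side, labels) {
  stopifnot(all(side %in% labels))
  mask <- sum(bitwShiftL(1L, match(side, labels) - 1L))
  k <- popcount(canonical_mask(as.integer(mask), length(labels)))
  if (k < 2L || k > length(labels) - 2L)
    stop("trivial split: both sides must contain at least 2 taxa")
  canonical_mask(as.integer(mask), length(labels))
}

splits_compatible <- function(a, b, m) {
  f <- full_mask(m)
  na <- bitwAnd(bitwNot(a), f); nb <- bitwAnd(bitwNot(b), f)
  bitwAnd(a, b) == 0L || bitwAnd(a, nb) == 0L ||
    bitwAnd(na, b) == 0L || bitwAnd(na, nb) == 0L
}

# ---- topology -------------------------------------------------------------

#' Create a topology from internal splits
#'
#' A topology is an unrooted tree shape over a fixed taxon set: a set of
#' pairwise-compatible nontrivial splits. With `m` taxa it holds at most
#' `m - 3` internal splits and is binary (fully resolved) when it holds
#' exactly that many; the star topology has none.
#'
#' @param labels Taxon labels (at least 4, unique; their order fixes the
#'   split encoding).
#' @param splits Integer vector of canonical split bitmasks (see
#'   [make_split()]), or a list of character vectors each giving one side.
#' @return An object of class `"topology"`.
#' @export
topology <- function(labels, splits = integer(0)) {
  stopifnot(is.character(labels), length(labels) >= 4L, !anyDuplicated(labels))
  m <- length(labels)
  if (is.list(splits)) splits <- vapply(splits, make_split, integer(1), labels = labels)
  splits <- sort(unique(as.integer(splits)))
  for (s in splits) {
    k <- popcount(s)
    if (bitwAnd(s, 1L) != 0L) stop("split masks must be canonical (bit of taxon 1 clear)")
    if (k < 2L || k > m - 2L) stop("trivial split in topology")
  }
  if (length(splits) > m - 3L) stop("too many internal splits for ", m, " taxa")
  if (length(splits) >= 2L) {
    for (i in seq_len(length(splits) - 1L))
      for (j in (i + 1L):length(splits))
        if (!splits_compatible(splits[i], splits[j], m))
          stop("incompatible splits: ", split_label(splits[i], labels), " vs ",
               split_label(splits[j], labels))
  }
  structure(list(labels = labels, splits = splits), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  m <- length(x$labels)
  kind <- if (length(x$splits) == m - 3L) "binary" else
    if (length(x$splits) == 0L) "star" else "partially resolved"
  cat(sprintf("<topology> %d taxa, %d internal split(s) (%s)\n",
              m, length(x$splits), kind))
  for (s in x$splits) cat("  ", split_label(s, x$labels), "\n", sep = "")
  invisible(x)
}

#' @export
format.topology <- function(x, ...) ape::write.tree(as_phylo(x))

is_binary <- function(top) length(top$splits) == length(top$labels) - 3L

same_taxa <- function(t1, t2) identical(t1$labels, t2$labels)

stop_if_taxa_mismatch <- function(t1, t2) {
  if (!same_taxa(t1, t2))
    stop("topologies are defined over different taxon sets / orders")
}

#' Strict consensus of two topologies
#'
#' Keeps exactly the internal splits present in both trees. Commutative,
#' associative and idempotent; the consensus of any tree with the star
#' topology is the star.
#'
#' @param t1,t2 `"topology"` objects over the same taxon set.
#' @return A `"topology"`.
#' @export
strict_consensus <- function(t1, t2) {
  stop_if_taxa_mismatch(t1, t2)
  topology(t1$labels, intersect(t1$splits, t2$splits))
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of internal splits. For two binary trees,
#' half this distance is the number of edges that must be contracted to
#' zero to turn one tree into the strict consensus — the degrees of freedom
#' of the chi-square topology test.
#'
#' @param t1,t2 `"topology"` objects over the same taxon set.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  stop_if_taxa_mismatch(t1, t2)
  length(setdiff(t1$splits, t2$splits)) + length(setdiff(t2$splits, t1$splits))
}

#' Candidates compatible with a (possibly unresolved) topology
#'
#' Returns which candidate trees contain every internal split of `t0` —
#' the set `A(tau0)` over which selection-bias corrections operate. Splits
#' are matched by their integer encodings, so the comparison is exact.
#'
#' @param t0 A `"topology"` (typically a strict consensus).
#' @param candidates List of `"topology"` objects over the same taxon set.
#' @param indices If `TRUE` return integer indices instead of the sublist.
#' @return Sublist of `candidates` (or their indices).
#' @export
compatible_set <- function(t0, candidates, indices = FALSE) {
  ok <- vapply(candidates, function(tt) {
    stop_if_taxa_mismatch(t0, tt)
    all(t0$splits %in% tt$splits)
  }, logical(1))
  if (indices) which(ok) else candidates[ok]
}

# ---- enumeration ----------------------------------------------------------

#' Enumerate all unrooted binary topologies
#'
#' Generates all `(2m-5)!!` binary shapes by stepwise taxon addition:
#' starting from the unique 3-taxon tree, taxon `k` is attached to each
#' edge of each partial tree in a fixed edge order, which makes the output
#' order deterministic and therefore suitable for lowest-index tie-breaking.
#'
#' @param labels Taxon labels; 4 to 8 of them (beyond 8 the catalogue grows
#'   too fast to enumerate; supply an explicit candidate list instead).
#' @return List of `"topology"` objects (3, 15, 105, 945 or 10395 of them).
#' @export
enumerate_topologies <- function(labels) {
  m <- length(labels)
  if (m < 4L || m > 8L)
    stop("enumeration supported for 4..8 taxa (got ", m,
         "); supply candidate topologies explicitly for larger problems")
  # edge list representation: tips 1..m, internal nodes m+1, ...
  # start: tips 1,2,3 joined at internal node m+1
  trees <- list(list(edge = cbind(c(m + 1L, m + 1L, m + 1L), 1:3), nnode = 1L))
  for (k in 4:m) {
    nxt <- vector("list", length(trees) * (2L * (k - 1L) - 3L))
    pos <- 0L
    for (tr in trees) {
      ne <- nrow(tr$edge)
      for (e in seq_len(ne)) {
        newnode <- m + tr$nnode + 1L
        edge <- rbind(tr$edge,
                      c(newnode, tr$edge[e, 2L]),
                      c(newnode, k))
        edge[e, 2L] <- newnode
        pos <- pos + 1L
        nxt[[pos]] <- list(edge = edge, nnode = tr$nnode + 1L)
      }
    }
    trees <- nxt
  }
  lapply(trees, function(tr) topology(labels, edgelist_splits(tr$edge, m)))
}

# canonical internal split masks from an edge matrix (parent, child),
# tips 1..m; parents are > m
edgelist_splits <- function(edge, m) {
  below <- integer(max(edge))
  below[1:m] <- bitwShiftL(1L, 0:(m - 1L))
  kids <- split(edge[, 2L], edge[, 1L])
  fill <- function(v) {
    if (v <= m) return(below[v])
    acc <- 0L
    for (c in kids[[as.character(v)]]) acc <- bitwOr(acc, fill(c))
    below[v] <<- acc
    acc
  }
  root <- setdiff(edge[, 1L], edge[, 2L])[1]
  fill(root)
  internal <- edge[, 2L] > m
  vapply(edge[internal, 2L], function(v) canonical_mask(below[v], m), integer(1))
}

# ---- NNI ------------------------------------------------------------------

# the four subtree blocks (A,B,C,D masks) around internal split s of a
# binary topology; s = A|B union C|D with split side X = A|B
edge_blocks <- function(top, s) {
  m <- length(top$labels)
  f <- full_mask(m)
  sides <- c(top$splits, bitwAnd(bitwNot(top$splits), f),
             bitwShiftL(1L, 0:(m - 1L)))
  pick2 <- function(X) {
    sub <- sides[bitwAnd(sides, X) == sides & sides != X & sides != 0L]
    a <- sub[which.max(vapply(sub, popcount, integer(1)))]
    b <- bitwAnd(X, bitwNot(a))
    if (!(b %in% sides)) stop("internal error: could not decompose edge blocks")
    c(a, b)
  }
  X <- s
  Y <- bitwAnd(bitwNot(s), f)
  list(AB = pick2(X), CD = pick2(Y))
}

#' Nearest-neighbor interchanges across one internal edge
#'
#' For an internal split written `AB|CD` (with `A`,`B`,`C`,`D` the four
#' subtrees meeting at the edge), returns the two alternative resolutions
#' `AC|BD` and `AD|BC`; all other splits are kept. Each neighbor is at
#' Robinson-Foulds distance 2 from the input tree.
#'
#' @param top A binary `"topology"`.
#' @param s Canonical mask of an internal split of `top`.
#' @return List of two `"topology"` objects.
#' @export
nni_alternatives <- function(top, s) {
  if (!is_binary(top)) stop("NNI requires a binary topology")
  if (!(s %in% top$splits)) stop("s is not an internal split of this topology")
  m <- length(top$labels)
  bl <- edge_blocks(top, s)
  keep <- setdiff(top$splits, s)
  alt <- function(x) topology(top$labels, c(keep, canonical_mask(x, m)))
  list(alt(bitwOr(bl$AB[1L], bl$CD[1L])),
       alt(bitwOr(bl$AB[1L], bl$CD[2L])))
}

# ---- conversion to/from ape ----------------------------------------------

#' Convert a topology to an ape \code{phylo}
#'
#' The tree is written rooted at the node adjacent to the first taxon (a
#' basal multifurcation in Newick terms), which is the conventional
#' representation of an unrooted tree. Optionally attaches edge lengths.
#'
#' @param top A `"topology"`.
#' @param internal_lengths Named or unnamed numeric vector of lengths for
#'   the internal splits, in the order of `top$splits` (default 0).
#' @param terminal_lengths Lengths for the terminal edges, in taxon order
#'   (default 0).
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(top, internal_lengths = NULL, terminal_lengths = NULL) {
  m <- length(top$labels)
  if (is.null(internal_lengths)) internal_lengths <- rep(0, length(top$splits))
  if (is.null(terminal_lengths)) terminal_lengths <- rep(0, m)
  stopifnot(length(internal_lengths) == length(top$splits),
            length(terminal_lengths) == m)
  ilen <- setNames(internal_lengths, as.character(top$splits))
  clades <- c(top$splits, bitwShiftL(1L, 1:(m - 1L)))  # no taxon-1 side
  nwk <- function(mask) {
    k <- popcount(mask)
    if (k == 1L) {
      i <- which(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L)
      return(sprintf("%s:%.10g", top$labels[i], terminal_lengths[i]))
    }
    sub <- clades[bitwAnd(clades, mask) == clades & clades != mask]
    # maximal proper subclades partition mask
    maxl <- sub[!vapply(sub, function(a)
      any(sub != a & bitwAnd(sub, a) == a), logical(1))]
    inner <- paste(vapply(maxl, nwk, character(1)), collapse = ",")
    len <- if (as.character(mask) %in% names(ilen)) ilen[[as.character(mask)]] else 0
    sprintf("(%s):%.10g", inner, len)
  }
  root_children <- clades[!vapply(clades, function(a)
    any(clades != a & bitwAnd(clades, a) == a), logical(1))]
  txt <- sprintf("(%s:%.10g,%s);", top$labels[1L], terminal_lengths[1L],
                 paste(vapply(root_children, nwk, character(1)), collapse = ","))
  ape::read.tree(text = txt)
}

#' Extract the topology of an ape \code{phylo}
#'
#' @param phy A `phylo` (rooted or unrooted; the root, if any, is ignored).
#' @param labels Taxon order to encode against; defaults to sorted tip
#'   labels. All analyses comparing topologies must share this order.
#' @param collapse_zero Treat internal edges with length `<= tol` as absent
#'   (used to contract the zero-length edges of a generating tree).
#' @param tol Zero-length tolerance.
#' @return A `"topology"`.
#' @export
as_topology <- function(phy, labels = NULL, collapse_zero = FALSE, tol = 1e-12) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(labels)) labels <- sort(phy$tip.label)
  if (!setequal(labels, phy$tip.label))
    stop("tip labels of the tree do not match 'labels'")
  m <- length(labels)
  edge <- phy$edge
  tipmap <- match(phy$tip.label, labels)
  below <- integer(max(edge))
  below[seq_len(m)] <- bitwShiftL(1L, tipmap - 1L)
  for (e in ape::postorder(phy))
    below[edge[e, 1L]] <- bitwOr(below[edge[e, 1L]], below[edge[e, 2L]])
  internal <- edge[, 2L] > ape::Ntip(phy)
  if (collapse_zero && !is.null(phy$edge.length))
    internal <- internal & phy$edge.length > tol
  masks <- vapply(edge[internal, 2L], function(v) canonical_mask(below[v], m), integer(1))
  k <- vapply(masks, popcount, integer(1))
  topology(labels, masks[k >= 2L & k <= m - 2L])
}
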