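# ---- site log-likelihood files --------------------------------------------
#
# The .sitelh dialect of mainstream ML software: a header line "ntrees
# nsites", then one record per tree — an optional identifier token followed
# by nsites log-likelihood values, possibly wrapped across lines. This is
# the import path for real-data analyses fitted under models the built-in
# engine does not cover (GTR+G, amino-acid models, ...).

#' Parse a site log-likelihood (.sitelh) file
#'
#' @param path File path.
#' @param candidates Optional list of `"topology"` objects matching the
#'   rows (enables structure-aware tests on imported likelihoods).
#' @return A `"site_loglik"`.
#' @export
parse_sitelh <- function(path, candidates = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  hdr_at <- which(keep)[1]
  hdr <- strsplit(trimws(lines[hdr_at]), "\\s+")[[1]]
  hn <- suppressWarnings(as.integer(hdr))
  if (length(hn) < 2 || anyNA(hn[1:2]))
    stop("line ", hdr_at, ": expected header 'ntrees nsites'")
  ntree <- hn[1]; n <- hn[2]
  toks <- character(0); tok_line <- integer(0)
  for (i in which(keep)[-1]) {
    tk <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    toks <- c(toks, tk); tok_line <- c(tok_line, rep(i, length(tk)))
  }
  vals <- matrix(NA_real_, ntree, n)
  names_out <- character(ntree)
  pos <- 1L
  for (t in seq_len(ntree)) {
    if (pos > length(toks))
      stop("header declares ", ntree, " trees but record ", t, " is missing")
    v <- suppressWarnings(as.numeric(toks[pos]))
    if (is.na(v)) { names_out[t] <- toks[pos]; pos <- pos + 1L }
    else names_out[t] <- paste0("tree", t)
    if (pos + n - 1L > length(toks))
      stop("line ", tok_line[min(length(toks), pos)],
           ": record ", t, " has fewer than ", n, " values")
    row <- suppressWarnings(as.numeric(toks[pos:(pos + n - 1L)]))
    if (anyNA(row))
      stop("line ", tok_line[pos + which(is.na(row))[1] - 1L],
           ": non-numeric token in record ", t)
    vals[t, ] <- row
    pos <- pos + n
  }
  if (pos <= length(toks))
    stop("line ", tok_line[pos], ": trailing data after the ", ntree,
         " declared records")
  x <- site_loglik_matrix(vals, candidates = candidates)
  x$tree_names <- names_out
  x
}

#' Write a site log-likelihood file
#'
#' @param x A `"site_loglik"`.
#' @param path Output path.
#' @param digits Significant digits (default keeps round-trip fidelity).
#' @return `path`, invisibly.
#' @export
write_sitelh <- function(x, path, digits = 12) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(x$values), ncol(x$values)), con)
  nm <- if (!is.null(x$tree_names)) x$tree_names
        else paste0("tree", seq_len(nrow(x$values)))
  for (i in seq_len(nrow(x$values)))
    writeLines(paste(nm[i], paste(formatC(x$values[i, ], digits = digits,
                                          format = "g"), collapse = " ")), con)
  invisible(path)
}

# ---- Newick candidate lists -----------------------------------------------

#' Read candidate topologies from a Newick file
#'
#' @param path File with one or more Newick trees.
#' @param labels Taxon order to encode against (default: sorted tips of
#'   the first tree).
#' @return List of `"topology"` objects.
#' @export
read_candidates <- function(path, labels = NULL) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(labels)) labels <- sort(trees[[1]]$tip.label)
  lapply(trees, as_topology, labels = labels)
}

#' Write topologies (or trees) to a Newick file
#'
#' @param x A `"topology"`, `phylo`, or list of either.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  if (inherits(x, c("topology", "phylo"))) x <- list(x)
  txt <- vapply(x, function(t)
    ape::write.tree(if (inherits(t, "topology")) as_phylo(t) else t),
    character(1))
  writeLines(txt, path)
  invisible(path)
}
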