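# ---- alignment container --------------------------------------------------

DNA_LEVELS <- c("A", "C", "G", "T")

#' DNA alignment
#'
#' A plain container: integer state matrix (taxa x sites, 1..4 coding
#' A,C,G,T) plus taxon labels. Ambiguity codes and gaps are not supported;
#' the likelihood engine requires fully determined states.
#'
#' @param x Character matrix (taxa x sites) of A/C/G/T (case-insensitive),
#'   or an integer matrix with values in 1..4.
#' @param labels Taxon labels; default rownames of `x`.
#' @return Object of class `"dna_alignment"`.
#' @export
dna_alignment <- function(x, labels = rownames(x)) {
  if (is.character(x)) {
    states <- matrix(match(toupper(x), DNA_LEVELS), nrow(x), ncol(x))
  } else {
    states <- x
    storage.mode(states) <- "integer"
  }
  if (anyNA(states) || any(states < 1L) || any(states > 4L))
    stop("alignment contains characters outside A/C/G/T")
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(states)))
  stopifnot(length(labels) == nrow(states), !anyDuplicated(labels))
  dimnames(states) <- NULL
  structure(list(labels = as.character(labels), states = states),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d taxa x %d sites\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Number of sites / taxa of an alignment
#' @param aln A `"dna_alignment"`.
#' @return Integer.
#' @export
n_sites <- function(aln) ncol(aln$states)

#' @rdname n_sites
#' @export
n_taxa <- function(aln) nrow(aln$states)

aln_chars <- function(aln) {
  m <- matrix(DNA_LEVELS[aln$states], nrow(aln$states), ncol(aln$states))
  rownames(m) <- aln$labels
  m
}

# unique site patterns: states (taxa x npat), counts, and site -> pattern map
compress_patterns <- function(aln) {
  key <- apply(aln$states, 2, paste, collapse = ".")
  idx <- match(key, unique(key))
  first <- which(!duplicated(key))
  list(states = aln$states[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, length(first))),
       index = idx)
}

# ---- readers / writers ----------------------------------------------------

#' Read a DNA alignment
#'
#' `read_fasta()` reads FASTA; `read_phylip()` reads relaxed sequential
#' PHYLIP (header `ntaxa nsites`, then whitespace-separated name and
#' sequence, possibly wrapped over several lines).
#'
#' @param path File path.
#' @return A `"dna_alignment"`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  labels <- sub("^>\\s*", "", trimws(lines[hdr]))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  to_alignment(labels, unname(seqs), path)
}

#' @rdname read_fasta
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2) stop("malformed PHYLIP header in ", path)
  m <- as.integer(hdr[1]); n <- as.integer(hdr[2])
  toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
  labels <- character(m); seqs <- character(m)
  i <- 1L
  for (t in seq_len(m)) {
    labels[t] <- toks[i]; i <- i + 1L
    while (nchar(seqs[t]) < n) {
      if (i > length(toks)) stop("truncated PHYLIP file: ", path)
      seqs[t] <- paste0(seqs[t], toks[i]); i <- i + 1L
    }
  }
  if (any(nchar(seqs) != n))
    stop("PHYLIP sequences do not match the stated length ", n)
  to_alignment(labels, seqs, path)
}

to_alignment <- function(labels, seqs, path) {
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences have unequal lengths in ", path)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  dna_alignment(mat, labels)
}

#' Write a DNA alignment
#'
#' @param aln A `"dna_alignment"`.
#' @param path Output path.
#' @param width Characters per sequence line (FASTA).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  ch <- aln_chars(aln)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(ch))) {
    writeLines(paste0(">", aln$labels[i]), con)
    s <- paste(ch[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_phylip <- function(aln, path) {
  ch <- aln_chars(aln)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(ch), ncol(ch)), con)
  for (i in seq_len(nrow(ch)))
    writeLines(paste(aln$labels[i], paste(ch[i, ], collapse = "")), con)
  invisible(path)
}
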