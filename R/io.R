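#' Read a FASTA file into a named character vector
#'
#' Identifiers are truncated at the first whitespace; duplicate identifiers
#' are an error.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("read_fasta: duplicate identifiers in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  stats::setNames(as.character(x), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Write / read a numeric matrix as CSV with row and column names
#'
#' @param m numeric matrix with dimnames.
#' @param path CSV path.
#' @export
write_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}

#' Read / write Newick trees
#'
#' Thin wrappers around the `ape` readers that fail with a clear message on
#' malformed input.
#'
#' @param path Newick file, or (for [read_newick()]) a Newick string.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(.as_phylo(path)), error = function(e)
    stop("read_newick: cannot parse '", path, "': ", conditionMessage(e)))
  if (is.null(tr)) stop("read_newick: cannot parse '", path, "'")
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object or an object with a `$newick`/`$phylo`
#'   component (e.g. an `exome_dendrogram`).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(.as_phylo(tree), file = path)
  invisible(path)
}
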