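#' BLOSUM62 substitution matrix with neutral unknowns
#'
#' Returns the published BLOSUM62 scores for the 20 standard residues plus
#' `X`, with every `X` score set to 0 so unknown residues neither reward nor
#' penalise the alignment (and never count as identities).
#'
#' @return a 21 x 21 integer matrix with residue dimnames.
#' @export
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      standard <- unlist(aa_groups(), use.names = FALSE)
      keep <- c(sort(standard), "X")
      m <- e$BLOSUM62[keep, keep]
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

#' Global protein alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh global alignment maximising the substitution
#' score minus affine gap costs: a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`.  Traceback ties prefer the diagonal,
#' then a gap in `b`, then a gap in `a`, so results are deterministic.
#'
#' @param a,b protein sequences (single strings, one-letter codes).
#' @param matrix substitution matrix with residue dimnames; defaults to
#'   [blosum62()].
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return a `protein_alignment`: list with `aligned_a`, `aligned_b`,
#'   `score`, `alignment_length`, `match_count` (identical-residue columns,
#'   `X` never counts), `gap_columns` (columns with a gap in either row) and
#'   `identity` = `match_count / (alignment_length - gap_columns)`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 12,
                         gap_extend = 2) {
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
    stop("global_align: both sequences must be non-empty strings")
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (!isTRUE(all.equal(unname(matrix), unname(t(matrix)))))
    stop("global_align: substitution matrix must be symmetric")
  res <- .nw_affine(toupper(a), toupper(b), matrix + 0, rownames(matrix),
                    gap_open, gap_extend)
  res$identity <- percent_identity(res)
  class(res) <- "protein_alignment"
  res
}

#' @export
print.protein_alignment <- function(x, width = 60, ...) {
  cat(sprintf("global alignment: score %g, length %d, %d matches, %d gap columns, identity %.4f\n",
              x$score, x$alignment_length, x$match_count, x$gap_columns,
              x$identity))
  for (k in seq(1, x$alignment_length, by = width)) {
    j <- min(k + width - 1, x$alignment_length)
    cat(substr(x$aligned_a, k, j), "\n", substr(x$aligned_b, k, j), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' Identity is the number of matching residues divided by the alignment
#' length minus the number of gap-containing columns; removing gapped
#' columns from the denominator keeps incomplete sequences from deflating
#' the identity.
#'
#' @param aln a `protein_alignment` or any list with `match_count`,
#'   `alignment_length` and `gap_columns`.
#' @return identity as a fraction in \[0, 1\]; `NA` when every column is
#'   gapped.
#' @export
percent_identity <- function(aln) {
  denom <- aln$alignment_length - aln$gap_columns
  if (denom <= 0) return(NA_real_)
  aln$match_count / denom
}

#' Protein divergence with a low-identity discard rule
#'
#' Divergence is `1 - identity`; pairs with identity below the threshold
#' are discarded (returned as `NA`) because such alignments mostly reflect
#' incomplete or non-orthologous sequence.
#'
#' @param identity numeric vector of identities in \[0, 1\].
#' @param threshold discard threshold (default 0.30).
#' @return numeric vector of divergences, `NA` where discarded or missing.
#' @export
divergence <- function(identity, threshold = 0.30) {
  stopifnot(all(identity >= 0 & identity <= 1, na.rm = TRUE))
  ifelse(is.na(identity) | identity < threshold, NA_real_, 1 - identity)
}

#' Per-gene protein divergence between two species
#'
#' Aligns the orthologous proteins of two species for each gene of a common
#' set and reports identity and divergence per gene.  Genes missing a
#' protein in either species, or falling below the identity threshold, are
#' reported with `NA` divergence.
#'
#' @param table_a,table_b finalised `species_table`s for the two species.
#' @param proteins_a,proteins_b named character vectors of protein
#'   sequences (names are protein accessions).
#' @param genes character vector of gene symbols (e.g. a
#'   `common_gene_set$symbols`); defaults to the symbols shared by the two
#'   tables.
#' @param min_identity discard threshold passed to [divergence()].
#' @inheritParams global_align
#' @return data frame with `gene_symbol`, `identity`, `divergence`.
#' @export
pairwise_divergence_track <- function(table_a, proteins_a, table_b,
                                      proteins_b, genes = NULL,
                                      matrix = blosum62(), gap_open = 12,
                                      gap_extend = 2, min_identity = 0.30) {
  if (is.null(genes))
    genes <- intersect(table_a$gene_symbol, table_b$gene_symbol)
  acc_a <- stats::setNames(table_a$protein_accession, table_a$gene_symbol)
  acc_b <- stats::setNames(table_b$protein_accession, table_b$gene_symbol)
  pa <- unname(proteins_a[acc_a[genes]])
  pb <- unname(proteins_b[acc_b[genes]])
  identity <- rep(NA_real_, length(genes))
  ok <- !is.na(pa) & !is.na(pb) & nzchar(pa) & nzchar(pb)
  for (i in which(ok)) {
    if (pa[i] == pb[i] && !grepl("X", pa[i], fixed = TRUE)) {
      identity[i] <- 1  # identical sequences align gaplessly to themselves
    } else {
      identity[i] <- global_align(pa[i], pb[i], matrix = matrix,
                                  gap_open = gap_open,
                                  gap_extend = gap_extend)$identity
    }
  }
  data.frame(gene_symbol = genes, identity = identity,
             divergence = divergence(identity, threshold = min_identity),
             stringsAsFactors = FALSE)
}
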