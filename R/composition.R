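#' Amino-acid groups by codon base composition
#'
#' The twenty standard residues split into three disjoint classes:
#' GARP (glycine, alanine, arginine, proline) are encoded by GC-rich codons,
#' FYMINK (phenylalanine, tyrosine, methionine, isoleucine, asparagine,
#' lysine) by AU-rich codons, and the remaining ten residues by "mixed"
#' codons.  Tryptophan sits in the mixed class: its single codon (UGG) is
#' neither GC- nor AU-rich.
#'
#' @return named list of character vectors `GARP`, `FYMINK`, `MIXED`.
#' @export
aa_groups <- function() {
  list(GARP = c("G", "A", "R", "P"),
       FYMINK = c("F", "Y", "M", "I", "N", "K"),
       MIXED = c("L", "S", "C", "H", "Q", "T", "V", "D", "E", "W"))
}

#' Classify residues into GC-usage groups
#'
#' @param residue character vector of one-letter residue codes.
#' @return character vector of `"GARP"`, `"FYMINK"`, `"MIXED"` or
#'   `"unclassified"` for non-standard codes (B, Z, X, U, `*`, ...).
#' @export
aa_group <- function(residue) {
  g <- aa_groups()
  lookup <- stats::setNames(rep(names(g), lengths(g)), unlist(g))
  out <- lookup[toupper(residue)]
  out[is.na(out)] <- "unclassified"
  unname(out)
}

#' GC content of nucleotide sequences
#'
#' Computes `100 * (G + C) / (A + C + G + T)`, case-insensitively.
#' Ambiguous IUPAC bases (N, R, Y, ...) and gaps are excluded from both the
#' numerator and the denominator, so assembly gaps do not bias the value.
#'
#' @param x character vector of nucleotide sequences (T or U).
#' @return numeric vector of GC percentages on the 0-100 scale; `NA` where a
#'   sequence has no unambiguous bases.
#' @export
gc_fraction <- function(x) {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  gc <- nchar(x) - nchar(gsub("[GC]", "", x))
  at <- nchar(x) - nchar(gsub("[AT]", "", x))
  denom <- gc + at
  ifelse(denom == 0, NA_real_, 100 * gc / denom)
}

#' Amino-acid usage of one protein
#'
#' Counts each residue, divides by the number of classified residues, and
#' sums the mole fractions within the GARP, FYMINK and mixed groups.  A
#' trailing stop symbol (`*`) is stripped; other non-standard residues are
#' excluded from the totals.
#'
#' @param protein a single protein sequence (one-letter codes).
#' @return list with `fractions` (named mole fractions over the 20 standard
#'   residues), `garp_percent`, `fymink_percent`, `mixed_percent` (0-100)
#'   and `n_classified`.
#' @export
aa_usage <- function(protein) {
  stopifnot(length(protein) == 1L)
  p <- toupper(sub("\\*+$", "", protein))
  if (!nzchar(p)) stop("aa_usage: empty protein sequence")
  g <- aa_groups()
  standard <- unlist(g, use.names = FALSE)
  res <- strsplit(p, "", fixed = TRUE)[[1L]]
  res <- res[res %in% standard]
  n <- length(res)
  if (n == 0L)
    return(list(fractions = stats::setNames(rep(NA_real_, 20), standard),
                garp_percent = NA_real_, fymink_percent = NA_real_,
                mixed_percent = NA_real_, n_classified = 0L))
  counts <- table(factor(res, levels = standard))
  frac <- as.numeric(counts) / n
  names(frac) <- standard
  list(fractions = frac,
       garp_percent = 100 * sum(frac[g$GARP]),
       fymink_percent = 100 * sum(frac[g$FYMINK]),
       mixed_percent = 100 * sum(frac[g$MIXED]),
       n_classified = n)
}

#' Per-gene composition metrics for one species
#'
#' Joins a finalised species table with its transcript and protein
#' sequences and returns one row per gene: transcript GC percent, group
#' usage percentages and the 20 per-residue mole fractions.  Genes whose
#' sequence is absent get `NA` metrics and are flagged in the
#' `missing_transcript` / `missing_protein` columns.
#'
#' @param table a finalised `species_table`.
#' @param transcripts named character vector of transcript sequences (names
#'   are transcript accessions), e.g. from [read_fasta()].
#' @param proteins named character vector of protein sequences (names are
#'   protein accessions).
#' @return data frame with columns `gene_symbol`, `species`, `gc_percent`,
#'   `garp_percent`, `fymink_percent`, `mixed_percent`, `frac_<residue>`
#'   for the 20 standard residues, and the missing flags.
#' @export
per_gene_metrics <- function(table, transcripts, proteins) {
  if (anyDuplicated(names(transcripts)))
    stop("per_gene_metrics: duplicate transcript identifiers")
  if (anyDuplicated(names(proteins)))
    stop("per_gene_metrics: duplicate protein identifiers")
  standard <- unlist(aa_groups(), use.names = FALSE)
  n <- nrow(table)
  tx <- unname(transcripts[table$transcript_accession])
  gc <- rep(NA_real_, n)
  gc[!is.na(tx)] <- gc_fraction(tx[!is.na(tx)])
  pr_acc <- if ("protein_accession" %in% names(table))
    table$protein_accession else rep(NA_character_, n)
  pr <- unname(proteins[pr_acc])
  usage <- matrix(NA_real_, nrow = n, ncol = 23,
                  dimnames = list(NULL, c("garp_percent", "fymink_percent",
                                          "mixed_percent",
                                          paste0("frac_", standard))))
  for (i in which(!is.na(pr) & nzchar(pr))) {
    u <- aa_usage(pr[i])
    usage[i, ] <- c(u$garp_percent, u$fymink_percent, u$mixed_percent,
                    u$fractions)
  }
  out <- data.frame(gene_symbol = table$gene_symbol,
                    species = table$species,
                    gc_percent = gc,
                    usage,
                    missing_transcript = is.na(tx),
                    missing_protein = is.na(pr),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
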