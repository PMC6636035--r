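#' Read a per-species gene table
#'
#' Reads a tab-separated gene table with one row per transcript entry.
#' Mandatory columns are `gene_symbol`, `chromosome`, `start`, `end`,
#' `strand` and `transcript_accession`; `protein_accession`,
#' `transcript_length`, `species` and `clade` are used when present.
#' Coordinates are 1-based and inclusive.
#'
#' @param path path to a TSV file with a header row.
#' @param species species name; overrides any `species` column.
#' @param clade clade label, one of `"fish"`, `"amphibia"`,
#'   `"non_avian_reptile"`, `"bird"`, `"mammal"`; overrides any `clade`
#'   column.
#' @return a `species_table`: a data frame of gene records with attributes
#'   `species` and `clade`.
#' @export
read_gene_table <- function(path, species = NULL, clade = NULL) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene_symbol", "chromosome", "start", "end", "strand",
                "transcript_accession")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols))
    stop("gene table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path)
  tbl$start <- suppressWarnings(as.numeric(tbl$start))
  tbl$end <- suppressWarnings(as.numeric(tbl$end))
  if ("transcript_length" %in% names(tbl))
    tbl$transcript_length <- suppressWarnings(as.numeric(tbl$transcript_length))
  as_species_table(tbl, species = species, clade = clade, source = path)
}

#' Validate a data frame of gene records as a species table
#'
#' @param tbl data frame with the gene-table columns (see
#'   [read_gene_table()]).
#' @inheritParams read_gene_table
#' @param source label used in error messages.
#' @return a `species_table` data frame.
#' @export
as_species_table <- function(tbl, species = NULL, clade = NULL,
                             source = "gene table") {
  if (nrow(tbl)) {
    mandatory <- c("gene_symbol", "chromosome", "start", "end", "strand",
                   "transcript_accession")
    bad <- which(Reduce(`|`, lapply(tbl[mandatory], function(x)
      is.na(x) | (is.character(x) & !nzchar(x)))))
    if (length(bad))
      stop(source, ": missing mandatory field(s) on row(s) ",
           paste(bad, collapse = ", "))
    tbl$strand <- chartr("−", "-", tbl$strand)
    badstrand <- which(!tbl$strand %in% c("+", "-"))
    if (length(badstrand))
      stop(source, ": invalid strand on row(s) ",
           paste(badstrand, collapse = ", "))
    badcoord <- which(tbl$start > tbl$end)
    if (length(badcoord))
      stop(source, ": start > end on row(s) ",
           paste(badcoord, collapse = ", "))
    if ("transcript_length" %in% names(tbl)) {
      badlen <- which(!is.na(tbl$transcript_length) & tbl$transcript_length <= 0)
      if (length(badlen))
        stop(source, ": non-positive transcript_length on row(s) ",
             paste(badlen, collapse = ", "))
    }
  }
  if (is.null(species))
    species <- if ("species" %in% names(tbl) && nrow(tbl))
      tbl$species[1] else NA_character_
  if (is.null(clade))
    clade <- if ("clade" %in% names(tbl) && nrow(tbl)) tbl$clade[1] else NA_character_
  if (!is.na(clade) && !clade %in% CLADES)
    stop(source, ": unknown clade label '", clade, "' (expected one of ",
         paste(CLADES, collapse = ", "), ")")
  tbl$species <- rep(species, length.out = nrow(tbl))
  tbl$clade <- rep(clade, length.out = nrow(tbl))
  structure(tbl, species = species, clade = clade,
            class = c("species_table", "data.frame"))
}

#' Keep protein-coding entries only
#'
#' Retains rows whose transcript accession carries a protein-coding RefSeq
#' prefix (`NM_` curated or `XM_` predicted mRNA); non-coding RNAs
#' (`NR_`/`XR_`) and accession-less rows are dropped.
#'
#' @param tbl a `species_table` or compatible data frame.
#' @return the filtered table.
#' @export
filter_protein_coding <- function(tbl) {
  keep <- grepl("^(NM_|XM_)", tbl$transcript_accession)
  out <- tbl[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the representative transcript for one gene
#'
#' Among entries sharing a gene symbol, keeps the one with the longest
#' transcript; ties are broken by the lexicographically smallest transcript
#' accession so the choice is reproducible.
#'
#' @param records data frame of records for a single gene symbol.
#' @return a one-row data frame.
#' @export
select_representative <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("select_representative: empty record list")
  if (length(unique(records$gene_symbol)) != 1L)
    stop("select_representative: records span more than one gene_symbol")
  len <- records$transcript_length
  if (is.null(len) || all(is.na(len)))
    stop("select_representative: transcript_length is required")
  ord <- order(-len, records$transcript_accession)
  records[ord[1L], , drop = FALSE]
}

#' Finalise a species table to one representative record per gene
#'
#' Applies the protein-coding filter and the longest-transcript rule.  When
#' the table lacks a `transcript_length` column, lengths are taken from the
#' supplied transcript sequences.
#'
#' @param tbl a `species_table`.
#' @param transcripts optional named character vector of transcript
#'   sequences (names are transcript accessions), used to fill in lengths.
#' @return a `species_table` with unique gene symbols, ordered by
#'   chromosome and start coordinate.
#' @export
finalize_species_table <- function(tbl, transcripts = NULL) {
  out <- filter_protein_coding(tbl)
  if (!"transcript_length" %in% names(out) ||
      anyNA(out$transcript_length)) {
    if (is.null(transcripts))
      stop("finalize_species_table: transcript_length column missing and no ",
           "transcript sequences supplied")
    out$transcript_length <- unname(nchar(transcripts)[out$transcript_accession])
    if (anyNA(out$transcript_length))
      stop("finalize_species_table: no sequence for transcript(s) ",
           paste(utils::head(out$transcript_accession[
             is.na(out$transcript_length)], 5), collapse = ", "))
  }
  if (nrow(out)) {
    pieces <- split(out, out$gene_symbol)
    out <- do.call(rbind, lapply(pieces, select_representative))
    out <- out[order(.chromosome_rank(out$chromosome), out$start), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, species = attr(tbl, "species"), clade = attr(tbl, "clade"),
            class = c("species_table", "data.frame"))
}

# numeric-aware chromosome ordering: chr1 < chr2 < chr10 < chrX
.chromosome_rank <- function(chr) {
  stripped <- sub("^chr", "", chr, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  order(order(is.na(num), num, stripped))
}

#' Match orthologs across species by gene symbol
#'
#' Matches every species' gene symbols against a finalised reference table,
#' case-insensitively, after applying an optional species-symbol alias map.
#' Symbols with no reference counterpart are dropped and reported.
#'
#' @param tables list of finalised `species_table`s (non-reference species).
#' @param reference the finalised reference `species_table`; its genome
#'   order defines the reference gene ranking.
#' @param alias_map optional data frame with columns `species_symbol` and
#'   `reference_symbol` mapping species-specific names (e.g. LOC numbers)
#'   onto reference symbols.
#' @return an `ortholog_matrix`: list with the reference order, the
#'   gene-by-species logical `presence` matrix, species clade labels, the
#'   reference coordinate frame, and the per-species unmatched-symbol report.
#' @export
match_orthologs <- function(tables, reference, alias_map = NULL) {
  if (anyDuplicated(reference$gene_symbol))
    stop("match_orthologs: reference table has duplicate gene symbols; ",
         "finalise it first")
  frame <- reference_order(reference)
  ref_syms <- frame$gene_symbol
  ref_upper <- toupper(ref_syms)
  alias <- character(0)
  if (!is.null(alias_map) && nrow(alias_map)) {
    if (!all(c("species_symbol", "reference_symbol") %in% names(alias_map)))
      stop("alias map needs columns species_symbol and reference_symbol")
    bad <- !toupper(alias_map$reference_symbol) %in% ref_upper
    if (any(bad))
      stop("alias map targets absent from reference order: ",
           paste(alias_map$reference_symbol[bad], collapse = ", "))
    alias <- stats::setNames(toupper(alias_map$reference_symbol),
                             toupper(alias_map$species_symbol))
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t)
      as.character(attr(t, "species")), "")
  species <- c(attr(reference, "species"), names(tables))
  if (anyDuplicated(species))
    stop("match_orthologs: duplicate species names")
  presence <- matrix(FALSE, nrow = length(ref_syms), ncol = length(species),
                     dimnames = list(ref_syms, species))
  presence[, 1L] <- TRUE
  unmatched <- stats::setNames(vector("list", length(tables)), names(tables))
  for (sp in names(tables)) {
    syms <- toupper(tables[[sp]]$gene_symbol)
    hit <- !is.na(match(syms, names(alias)))
    syms[hit] <- alias[syms[hit]]
    dup <- unique(syms[duplicated(syms)])
    dup <- dup[dup %in% ref_upper]
    if (length(dup))
      stop("match_orthologs: duplicate symbols in species '", sp,
           "' after aliasing: ", paste(dup, collapse = ", "))
    idx <- match(syms, ref_upper)
    presence[idx[!is.na(idx)], sp] <- TRUE
    unmatched[[sp]] <- sort(tables[[sp]]$gene_symbol[is.na(idx)])
  }
  clades <- stats::setNames(
    c(attr(reference, "clade"),
      vapply(tables, function(t) as.character(attr(t, "clade")), "")),
    species)
  structure(list(reference_order = ref_syms, presence = presence,
                 species = species, species_clade = clades,
                 reference_frame = frame, unmatched = unmatched),
            class = "ortholog_matrix")
}

#' @export
print.ortholog_matrix <- function(x, ...) {
  cat("ortholog matrix:", length(x$reference_order), "reference genes x",
      length(x$species), "species\n")
  cat("clades:", paste(sprintf("%s=%s", x$species, x$species_clade),
                       collapse = ", "), "\n")
  n_un <- vapply(x$unmatched, length, 0L)
  if (length(n_un))
    cat("unmatched symbols per species:",
        paste(sprintf("%s=%d", names(n_un), n_un), collapse = ", "), "\n")
  invisible(x)
}

#' Derive the common vertebrate gene set
#'
#' Keeps a reference gene when it is present in at least `min_count` species
#' belonging to the chosen clade group.  The defaults reproduce the
#' "present at least twice among fish, amphibia and non-avian reptiles"
#' rule used to define a typical vertebrate gene set.
#'
#' @param matrix an `ortholog_matrix`.
#' @param clade_group clade labels whose species are counted.
#' @param min_count minimum number of clade-group species carrying the gene.
#' @return a `common_gene_set`: list with `symbols` and the `rule` applied.
#' @export
build_common_set <- function(matrix,
                             clade_group = c("fish", "amphibia",
                                             "non_avian_reptile"),
                             min_count = 2) {
  stopifnot(inherits(matrix, "ortholog_matrix"))
  in_group <- matrix$species[matrix$species_clade %in% clade_group]
  if (min_count > length(in_group))
    stop("build_common_set: min_count (", min_count,
         ") exceeds the number of species in the clade group (",
         length(in_group), ")")
  counts <- rowSums(matrix$presence[, in_group, drop = FALSE])
  structure(list(symbols = matrix$reference_order[counts >= min_count],
                 rule = list(clade_group = clade_group,
                             min_count = min_count,
                             n_group_species = length(in_group))),
            class = "common_gene_set")
}

#' @export
print.common_gene_set <- function(x, ...) {
  cat("common gene set:", length(x$symbols), "genes (rule: >=",
      x$rule$min_count, "of", x$rule$n_group_species, "species in {",
      paste(x$rule$clade_group, collapse = ", "), "})\n")
  invisible(x)
}

#' Write a gene table as TSV
#'
#' @param tbl a `species_table` or compatible data frame.
#' @param path output path.
#' @export
write_gene_table <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
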