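# stage wrapper so failures name the pipeline stage that caused them
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full landscape pipeline on a directory of species files
#'
#' Expects, for every species, `<species>.tsv` (gene table),
#' `<species>_transcripts.fa` and `<species>_proteins.fa` in `input_dir`
#' (the layout written by [simulate_exomes()]).  Runs catalog matching,
#' common-set derivation, per-gene metrics, GC landscapes, the species
#' distance matrices and hierarchical clustering, writing every
#' intermediate table into `out_dir`.
#'
#' @param input_dir directory of per-species inputs.
#' @param out_dir output directory, created if needed.
#' @param reference reference species name (its genome defines the gene
#'   order); defaults to the alphabetically first species.
#' @param window sliding-window half-width in genes.
#' @param clade_group,min_count common-gene-set rule (see
#'   [build_common_set()]); `clade_group = NULL` uses every clade present.
#' @param metric which per-gene metric drives the landscapes
#'   (`"gc_percent"`, `"garp_percent"`, `"fymink_percent"` or
#'   `"mixed_percent"`).
#' @param distance,linkage clustering options (see [distance_matrix()] and
#'   [hierarchical_cluster()]).
#' @param divergence_pair optional character vector of two species names;
#'   when given, their per-gene protein divergence track is also computed
#'   and written.
#' @param gap_open,gap_extend,min_identity alignment options for the
#'   divergence track.
#' @param alias_map optional alias-map TSV path (columns `species_symbol`,
#'   `reference_symbol`).
#' @param reference_tree optional Newick file compared against the inferred
#'   dendrogram with [compare_trees()].
#' @return (invisibly) a list with the ortholog matrix, common set,
#'   metrics, landscapes, the `exome_phylogeny`, the optional divergence
#'   track and tree comparison, and the paths written.
#' @export
run_pipeline <- function(input_dir, out_dir, reference = NULL, window = 50,
                         clade_group = NULL, min_count = 2,
                         metric = "gc_percent",
                         distance = "euclidean", linkage = "average",
                         divergence_pair = NULL, gap_open = 12,
                         gap_extend = 2, min_identity = 0.30,
                         alias_map = NULL, reference_tree = NULL) {
  tsv <- list.files(input_dir, pattern = "\\.tsv$", full.names = FALSE)
  species <- sort(sub("\\.tsv$", "", tsv))
  if (length(species) < 2)
    stop("run_pipeline: need at least two species gene tables in ",
         input_dir)
  if (is.null(reference)) reference <- species[1L]
  if (!reference %in% species)
    stop("run_pipeline: reference species '", reference, "' not found")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- transcripts <- proteins <- stats::setNames(
    vector("list", length(species)), species)
  for (sp in species) {
    tables[[sp]] <- .stage(paste0("catalog:", sp), {
      tx <- read_fasta(file.path(input_dir, paste0(sp, "_transcripts.fa")))
      transcripts[[sp]] <- tx
      proteins[[sp]] <- read_fasta(file.path(input_dir,
                                             paste0(sp, "_proteins.fa")))
      finalize_species_table(
        read_gene_table(file.path(input_dir, paste0(sp, ".tsv")),
                        species = sp),
        transcripts = tx)
    })
  }

  amap <- if (!is.null(alias_map))
    utils::read.delim(alias_map, stringsAsFactors = FALSE) else NULL
  om <- .stage("orthologs", match_orthologs(
    tables[setdiff(species, reference)], tables[[reference]],
    alias_map = amap))
  if (is.null(clade_group))
    clade_group <- unique(stats::na.omit(om$species_clade))
  common <- .stage("common-set",
                   build_common_set(om, clade_group = clade_group,
                                    min_count = min_count))

  metrics <- landscapes <- stats::setNames(vector("list", length(species)),
                                           species)
  for (sp in species) {
    metrics[[sp]] <- .stage(paste0("metrics:", sp), {
      tbl <- tables[[sp]]
      tbl <- tbl[toupper(tbl$gene_symbol) %in% toupper(common$symbols), ,
                 drop = FALSE]
      per_gene_metrics(tbl, transcripts[[sp]], proteins[[sp]])
    })
    landscapes[[sp]] <- .stage(paste0("landscape:", sp), {
      v <- stats::setNames(metrics[[sp]][[metric]],
                           metrics[[sp]]$gene_symbol)
      landscape(v[!is.na(v)], om$reference_frame, w = window,
                species = sp, metric = metric)
    })
    utils::write.table(metrics[[sp]],
                       file.path(out_dir, paste0("metrics_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(landscapes[[sp]]),
                       file.path(out_dir, paste0("landscape_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  phylo <- .stage("tree", landscape_phylogeny(landscapes,
                                              distance = distance,
                                              linkage = linkage))
  write_matrix(phylo$correlation, file.path(out_dir, "correlation.csv"))
  write_matrix(phylo$distance, file.path(out_dir, "distance.csv"))
  write_matrix(heatmap_matrix(phylo$matrix, phylo$dendrogram$leaf_order),
               file.path(out_dir, "heatmap.csv"))
  writeLines(phylo$newick, file.path(out_dir, "tree.nwk"))

  div <- NULL
  if (!is.null(divergence_pair)) {
    stopifnot(length(divergence_pair) == 2,
              all(divergence_pair %in% species))
    a <- divergence_pair[1L]; b <- divergence_pair[2L]
    div <- .stage("divergence", pairwise_divergence_track(
      tables[[a]], proteins[[a]], tables[[b]], proteins[[b]],
      genes = intersect(common$symbols,
                        intersect(tables[[a]]$gene_symbol,
                                  tables[[b]]$gene_symbol)),
      gap_open = gap_open, gap_extend = gap_extend,
      min_identity = min_identity))
    utils::write.table(div, file.path(out_dir, sprintf(
      "divergence_%s_%s.tsv", a, b)), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  tree_cmp <- NULL
  if (!is.null(reference_tree))
    tree_cmp <- .stage("tree-compare",
                       compare_trees(phylo$dendrogram, reference_tree))

  # no timestamp in the log: artifacts must be checksum-reproducible
  writeLines(c(
    paste("exomescape", as.character(utils::packageVersion("exomescape"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("reference", reference),
    paste("species", paste(species, collapse = ",")),
    paste("window", window),
    paste("common_genes", length(common$symbols)),
    paste("distance", distance), paste("linkage", linkage)),
    file.path(out_dir, "run_info.txt"))

  invisible(list(orthologs = om, common = common, metrics = metrics,
                 landscapes = landscapes, phylogeny = phylo,
                 divergence = div, tree_comparison = tree_cmp,
                 out_dir = out_dir))
}
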