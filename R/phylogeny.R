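#' Species-by-gene landscape matrix
#'
#' Stacks the smoothed landscapes of several species into one matrix over
#' the genes present in every species (complete mode) or all genes seen in
#' any species with `NA`s (pairwise mode), columns ordered by reference
#' rank.
#'
#' @param landscapes named list of `exome_landscape` objects on the same
#'   reference order.
#' @param mode `"complete"` (default) or `"pairwise"`.
#' @return numeric matrix, species in rows, genes in columns.
#' @export
landscape_matrix <- function(landscapes, mode = c("complete", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(length(landscapes) >= 2, !is.null(names(landscapes)))
  genes <- if (mode == "complete")
    Reduce(intersect, lapply(landscapes, `[[`, "gene_symbol"))
  else
    unique(unlist(lapply(landscapes, `[[`, "gene_symbol")))
  ranks <- landscapes[[1L]]$rank[match(genes, landscapes[[1L]]$gene_symbol)]
  ranks[is.na(ranks)] <- Inf
  genes <- genes[order(ranks)]
  m <- t(vapply(landscapes, function(l)
    l$smoothed[match(genes, l$gene_symbol)], numeric(length(genes))))
  dimnames(m) <- list(names(landscapes), genes)
  m
}

#' Pairwise Pearson correlation between species landscapes
#'
#' @param m species-by-gene matrix from [landscape_matrix()].
#' @return S x S correlation matrix with unit diagonal and attribute
#'   `n_pairs` (number of unordered species pairs evaluated).
#' @export
correlation_matrix <- function(m) {
  stopifnot(nrow(m) >= 2, ncol(m) >= 3)
  zero_var <- apply(m, 1, stats::sd, na.rm = TRUE) == 0
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  if (any(zero_var)) {
    warning("correlation_matrix: zero-variance species: ",
            paste(rownames(m)[zero_var], collapse = ", "))
    r[zero_var, ] <- NA_real_
    r[, zero_var] <- NA_real_
  }
  diag(r) <- 1
  structure(r, n_pairs = nrow(m) * (nrow(m) - 1) / 2)
}

#' Euclidean (or correlation-based) distances between species landscapes
#'
#' @param m species-by-gene matrix without missing entries.
#' @param mode `"euclidean"` (default): `d(i,j) = sqrt(sum_g (m[i,g] -
#'   m[j,g])^2)`; or `"one-minus-r"`: `1 - Pearson r`.
#' @return symmetric S x S distance matrix with zero diagonal.
#' @export
distance_matrix <- function(m, mode = c("euclidean", "one-minus-r")) {
  mode <- match.arg(mode)
  if (anyNA(m))
    stop("distance_matrix: matrix has missing entries; use complete mode")
  d <- if (mode == "euclidean") as.matrix(stats::dist(m))
  else 1 - unclass(correlation_matrix(m))
  diag(d) <- 0
  attr(d, "n_pairs") <- NULL
  d
}

#' Hierarchical clustering of a species distance matrix
#'
#' Agglomerative clustering with the chosen linkage; the dendrogram is also
#' returned as an `ape` phylogeny and a Newick string with branch lengths
#' taken from the merge heights.
#'
#' @param d symmetric distance matrix with species dimnames.
#' @param linkage `"average"` (UPGMA, default), `"single"`, `"complete"` or
#'   `"ward"`.
#' @return an `exome_dendrogram`: list with the `hclust` object, the
#'   `phylo` tree, the `newick` string and the leaf order.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "single",
                                                "complete", "ward")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stop("hierarchical_cluster: distance matrix is not symmetric")
  if (any(diag(d) != 0))
    stop("hierarchical_cluster: distance matrix diagonal must be zero")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy), linkage = linkage,
                 leaf_order = hc$labels[hc$order]),
            class = "exome_dendrogram")
}

#' @export
print.exome_dendrogram <- function(x, ...) {
  cat("landscape dendrogram:", length(x$leaf_order), "species,",
      x$linkage, "linkage\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.exome_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, hang = -1, xlab = "", sub = "", ...)
  invisible(x)
}

.as_phylo <- function(t) {
  if (inherits(t, "phylo")) return(t)
  if (inherits(t, "exome_dendrogram")) return(t$phylo)
  if (is.character(t) && length(t) == 1L) {
    if (file.exists(t)) return(ape::read.tree(t))
    return(ape::read.tree(text = t))
  }
  stop("cannot interpret tree input of class ", paste(class(t), collapse = "/"))
}

#' Compare two trees over the same leaves
#'
#' Computes the unrooted Robinson-Foulds distance (number of bipartitions
#' present in one tree but not the other) and the Pearson correlation of
#' the two cophenetic distance matrices.
#'
#' @param t1,t2 trees as Newick strings, files, `phylo` objects or
#'   `exome_dendrogram`s.
#' @return list with `robinson_foulds` (integer) and `cophenetic_r`.
#' @export
compare_trees <- function(t1, t2) {
  p1 <- .as_phylo(t1); p2 <- .as_phylo(t2)
  extra1 <- setdiff(p1$tip.label, p2$tip.label)
  extra2 <- setdiff(p2$tip.label, p1$tip.label)
  if (length(extra1) || length(extra2))
    stop("compare_trees: leaf sets differ; only in tree 1: {",
         paste(extra1, collapse = ", "), "}; only in tree 2: {",
         paste(extra2, collapse = ", "), "}")
  rf <- if (length(p1$tip.label) <= 3) 0L else
    as.integer(ape::dist.topo(ape::unroot(p1), ape::unroot(p2),
                              method = "PH85"))
  c1 <- ape::cophenetic.phylo(p1)
  c2 <- ape::cophenetic.phylo(p2)[rownames(c1), colnames(c1)]
  r <- stats::cor(c1[lower.tri(c1)], c2[lower.tri(c2)])
  list(robinson_foulds = rf, cophenetic_r = r)
}

#' Reorder a landscape matrix to dendrogram leaf order
#'
#' Permutes the species rows of a landscape matrix into the given leaf
#' order (columns stay in reference gene order), ready to be written out
#' for heat-map display.
#'
#' @param m species-by-gene matrix.
#' @param species_order character vector of species, e.g. the `leaf_order`
#'   of an `exome_dendrogram`.
#' @return the row-permuted matrix.
#' @export
heatmap_matrix <- function(m, species_order) {
  if (!setequal(rownames(m), species_order))
    stop("heatmap_matrix: species_order does not match matrix rows")
  m[species_order, , drop = FALSE]
}

#' Landscapes to distance matrices, dendrogram and Newick tree
#'
#' Convenience wrapper running [landscape_matrix()],
#' [correlation_matrix()], [distance_matrix()] and
#' [hierarchical_cluster()] in one step.
#'
#' @inheritParams landscape_matrix
#' @inheritParams distance_matrix
#' @inheritParams hierarchical_cluster
#' @param distance distance mode, `"euclidean"` or `"one-minus-r"`.
#' @return an `exome_phylogeny`: list with `matrix`, `correlation`,
#'   `distance`, `dendrogram` and `newick`.
#' @export
landscape_phylogeny <- function(landscapes,
                                distance = c("euclidean", "one-minus-r"),
                                linkage = "average") {
  distance <- match.arg(distance)
  m <- landscape_matrix(landscapes, mode = "complete")
  corr <- correlation_matrix(m)
  d <- distance_matrix(m, mode = distance)
  dend <- hierarchical_cluster(d, linkage = linkage)
  structure(list(matrix = m, correlation = corr, distance = d,
                 dendrogram = dend, newick = dend$newick,
                 distance_mode = distance),
            class = "exome_phylogeny")
}

#' @export
print.exome_phylogeny <- function(x, ...) {
  cat("landscape phylogeny:", nrow(x$matrix), "species over", ncol(x$matrix),
      "shared genes\n")
  cat("distance:", x$distance_mode, "| linkage:", x$dendrogram$linkage,
      "|", attr(x$correlation, "n_pairs"), "species pairs\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.exome_phylogeny <- function(x, ...) {
  plot(x$dendrogram, main = "landscape dendrogram", ...)
  invisible(x)
}
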