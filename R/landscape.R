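#' Reference gene order
#'
#' Derives the linear reference ranking from a finalised species table:
#' genes are sorted by chromosome (numeric-aware) and start coordinate and
#' assigned contiguous ranks from 1.
#'
#' @param table a finalised `species_table` with unique gene symbols.
#' @return data frame `gene_symbol`, `chromosome`, `rank`, `midpoint`.
#' @export
reference_order <- function(table) {
  if (anyDuplicated(table$gene_symbol))
    stop("reference_order: duplicate gene symbols; finalise the table first")
  ord <- order(.chromosome_rank(table$chromosome), table$start)
  data.frame(gene_symbol = table$gene_symbol[ord],
             chromosome = table$chromosome[ord],
             rank = seq_along(ord),
             midpoint = (table$start[ord] + table$end[ord]) / 2,
             stringsAsFactors = FALSE)
}

#' Arrange per-gene values along a reference order
#'
#' @param values named numeric vector (names are gene symbols).
#' @param order a reference-order data frame from [reference_order()] (or
#'   the `reference_frame` of an `ortholog_matrix`).
#' @param drop_missing drop genes whose value is `NA` (default), so the
#'   sliding window runs over the nearest available neighbours.
#' @return data frame `gene_symbol`, `chromosome`, `rank`, `midpoint`,
#'   `value`, sorted by rank.
#' @export
order_genes <- function(values, order, drop_missing = TRUE) {
  unknown <- setdiff(names(values), order$gene_symbol)
  if (length(unknown))
    stop("order_genes: gene(s) absent from the reference order: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) ", ...")
  idx <- match(names(values), order$gene_symbol)
  out <- order[idx, , drop = FALSE]
  out$value <- unname(values)
  out <- out[order(out$rank), , drop = FALSE]
  if (drop_missing) out <- out[!is.na(out$value), , drop = FALSE]
  if (nrow(out) == 0L) warning("order_genes: no genes with data")
  rownames(out) <- NULL
  out
}

#' Sliding-window mean over an ordered series
#'
#' Position k receives the mean of positions `max(1, k - w)` to
#' `min(n, k + w)`: interior windows hold exactly `2w + 1` values
#' (101 genes at the default half-width of 50) and windows are truncated at
#' the ends of the series rather than dropped.
#'
#' @param values ordered numeric vector without `NA`.
#' @param w window half-width in genes (default 50).
#' @return numeric vector of the same length as `values`.
#' @export
sliding_window <- function(values, w = 50) {
  stopifnot(w >= 0, length(values) >= 1)
  if (anyNA(values))
    stop("sliding_window: values contain NA; remove missing genes first")
  n <- length(values)
  cs <- cumsum(c(0, values))
  lo <- pmax(1L, seq_len(n) - as.integer(w))
  hi <- pmin(n, seq_len(n) + as.integer(w))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Build a smoothed exome landscape
#'
#' Orders a per-gene metric on the reference gene ranking and smooths it
#' with the truncated sliding-window mean.  With `by_chromosome = TRUE` the
#' window never crosses a chromosome boundary.
#'
#' @inheritParams order_genes
#' @inheritParams sliding_window
#' @param by_chromosome restrict windows to single chromosomes.
#' @param species,metric optional labels stored with the landscape.
#' @return an `exome_landscape`: data frame `gene_symbol`, `chromosome`,
#'   `rank`, `midpoint`, `raw`, `smoothed` with attributes `w`, `species`,
#'   `metric`.
#' @export
landscape <- function(values, order, w = 50, by_chromosome = FALSE,
                      species = NULL, metric = NULL) {
  df <- order_genes(values, order, drop_missing = TRUE)
  names(df)[names(df) == "value"] <- "raw"
  if (nrow(df)) {
    if (by_chromosome) {
      sm <- unlist(lapply(split(df$raw, factor(df$chromosome,
                                               levels = unique(df$chromosome))),
                          sliding_window, w = w), use.names = FALSE)
    } else {
      sm <- sliding_window(df$raw, w = w)
    }
    df$smoothed <- sm
  } else df$smoothed <- numeric(0)
  structure(df, w = w, species = species, metric = metric,
            by_chromosome = by_chromosome,
            class = c("exome_landscape", "data.frame"))
}

#' @export
print.exome_landscape <- function(x, ...) {
  cat(sprintf("exome landscape%s%s: %d genes, window half-width %d\n",
              if (!is.null(attr(x, "species")))
                paste0(" of ", attr(x, "species")) else "",
              if (!is.null(attr(x, "metric")))
                paste0(" (", attr(x, "metric"), ")") else "",
              nrow(x), attr(x, "w")))
  if (nrow(x))
    cat(sprintf("smoothed range: %.3f .. %.3f\n", min(x$smoothed),
                max(x$smoothed)))
  invisible(x)
}

#' @export
plot.exome_landscape <- function(x, mode = c("rank", "physical"),
                                 col_raw = "grey80", col_smooth = "steelblue",
                                 ...) {
  mode <- match.arg(mode)
  ax <- landscape_axis(x, mode = mode)
  graphics::plot(ax$x, x$raw, pch = ".", col = col_raw,
                 xlab = if (mode == "rank") "gene rank" else "genomic position",
                 ylab = attr(x, "metric") %||% "value", ...)
  graphics::lines(ax$x, x$smoothed, col = col_smooth, lwd = 2)
  graphics::abline(v = attr(ax, "boundaries"), col = "grey60", lty = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plottable axis for a landscape
#'
#' Returns x-coordinates either as the gene rank or as the physical
#' midpoint offset by the cumulative span of preceding chromosomes, with
#' chromosome boundaries annotated.
#'
#' @param x an `exome_landscape`.
#' @param mode `"rank"` or `"physical"`.
#' @return data frame `gene_symbol`, `chromosome`, `x`, `smoothed`, with
#'   attribute `boundaries` (x positions where a new chromosome starts).
#' @export
landscape_axis <- function(x, mode = c("rank", "physical")) {
  mode <- match.arg(mode)
  chroms <- unique(x$chromosome)
  if (mode == "rank") {
    xx <- x$rank
    bounds <- vapply(chroms[-1], function(ch)
      min(x$rank[x$chromosome == ch]), 0)
  } else {
    if (!"midpoint" %in% names(x) || anyNA(x$midpoint))
      stop("landscape_axis: physical mode requires midpoint coordinates")
    spans <- vapply(chroms, function(ch) max(x$midpoint[x$chromosome == ch]), 0)
    offs <- stats::setNames(c(0, cumsum(spans))[seq_along(chroms)], chroms)
    xx <- x$midpoint + offs[x$chromosome]
    bounds <- unname(offs[-1])
  }
  structure(data.frame(gene_symbol = x$gene_symbol,
                       chromosome = x$chromosome, x = xx,
                       smoothed = x$smoothed, stringsAsFactors = FALSE),
            boundaries = unname(bounds))
}

#' Pearson correlation between two landscapes
#'
#' Restricts both landscapes to their shared genes and correlates the
#' smoothed (default) or raw per-gene values.
#'
#' @param a,b `exome_landscape` objects on the same reference order.
#' @param smoothed correlate smoothed values (`TRUE`, default) or raw
#'   per-gene values.
#' @return Pearson r with attribute `n` (genes used); `NA` when fewer than
#'   3 shared genes or a landscape has zero variance.
#' @export
landscape_correlation <- function(a, b, smoothed = TRUE) {
  common <- intersect(a$gene_symbol, b$gene_symbol)
  col <- if (smoothed) "smoothed" else "raw"
  va <- a[[col]][match(common, a$gene_symbol)]
  vb <- b[[col]][match(common, b$gene_symbol)]
  if (length(common) < 3) {
    warning("landscape_correlation: fewer than 3 shared genes")
    return(structure(NA_real_, n = length(common)))
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("landscape_correlation: zero variance")
    return(structure(NA_real_, n = length(common)))
  }
  structure(stats::cor(va, vb), n = length(common))
}
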