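#' Configuration for the synthetic exome simulator
#'
#' Bundles and validates the parameters of the synthetic multi-species
#' exome generator.  Defaults describe a desk-scale vertebrate-like study:
#' 2000 genes of 300 codons on 5 chromosomes, a 45% GC baseline with three
#' regional peaks, moderate GC/amino-acid coupling and a 4-leaf species
#' tree.
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes (contiguous rank blocks).
#' @param n_codons codons per gene (fixed length).
#' @param gc_baseline baseline GC target in percent.
#' @param peaks data frame with columns `center` (rank), `width` (Gaussian
#'   sd in ranks) and `amplitude` (percentage points) describing regional
#'   GC elevations.
#' @param kappa coupling in \[0, 1\] between the GC target and GARP
#'   sampling: `P(GARP) = 0.25 + kappa * (gc - 50) / 100`, with
#'   `P(FYMINK)` mirrored and mixed residues absorbing the rest.
#' @param tree species tree as a Newick string; branch lengths are
#'   expected substitutions per site.
#' @param clades optional named character vector of clade labels per tip;
#'   defaults to `"fish"` for every tip.
#' @param gbgc list of GC-biased gene-conversion episodes, each a list with
#'   `tips` (the clade of species affected), `from`/`to` (reference rank
#'   interval) and `bias` in \[0, 1\].
#' @param rearrangement_rate expected number of gene-block moves per
#'   branch.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   simulation byte for byte.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_chromosomes = 5,
                              n_codons = 300, gc_baseline = 45,
                              peaks = data.frame(
                                center = c(300, 1000, 1600),
                                width = c(120, 150, 100),
                                amplitude = c(12, 15, 10)),
                              kappa = 0.6,
                              tree = "((mam1:0.05,mam2:0.05):0.05,(rep1:0.05,rep2:0.05):0.05);",
                              clades = NULL, gbgc = list(),
                              rearrangement_rate = 1, seed = 1L) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, n_codons >= 1,
            gc_baseline > 0, gc_baseline < 100,
            kappa >= 0, kappa <= 1, rearrangement_rate >= 0)
  if (nrow(peaks)) {
    stopifnot(all(c("center", "width", "amplitude") %in% names(peaks)))
    if (any(peaks$center < 1 | peaks$center > n_genes))
      stop("simulation_config: peak centers must lie in [1, n_genes]")
    stopifnot(all(peaks$width > 0))
  }
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) stop("simulation_config: unparseable tree")
  if (is.null(clades)) clades <- stats::setNames(
    rep("fish", length(phy$tip.label)), phy$tip.label)
  if (!all(phy$tip.label %in% names(clades)))
    stop("simulation_config: clades must name every tip")
  if (!all(clades %in% CLADES))
    stop("simulation_config: unknown clade label(s)")
  for (ep in gbgc) {
    stopifnot(all(c("tips", "from", "to", "bias") %in% names(ep)))
    if (!all(ep$tips %in% phy$tip.label))
      stop("simulation_config: gbgc tips absent from tree")
    stopifnot(ep$from >= 1, ep$to <= n_genes, ep$from <= ep$to,
              ep$bias >= 0, ep$bias <= 1)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_codons = as.integer(n_codons),
                 gc_baseline = gc_baseline, peaks = peaks, kappa = kappa,
                 tree = tree, clades = clades, gbgc = gbgc,
                 rearrangement_rate = rearrangement_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# genetic-code bookkeeping: per residue, codons split by GC vs AT third base
.codon_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      code <- Biostrings::GENETIC_CODE
      code <- code[code != "*"]
      by_aa <- split(names(code), unname(code))
      sets <- list()
      for (aa in names(by_aa)) {
        third <- substr(by_aa[[aa]], 3, 3)
        sets[[paste0(aa, "G")]] <- by_aa[[aa]][third %in% c("G", "C")]
        sets[[paste0(aa, "A")]] <- by_aa[[aa]][third %in% c("A", "T")]
      }
      cache <<- list(code = code, by_aa = by_aa, sets = sets)
    }
    cache
  }
})

# vectorised sampler shared by simulate_cds() and simulate_reference():
# draws residues with GC-coupled group probabilities, then codons with
# GC-favouring third positions, for many genes at once
.sample_cds_block <- function(gc_target, n_codons, kappa) {
  g <- aa_groups()
  ct <- .codon_tables()
  G <- length(gc_target)
  N <- G * n_codons
  gc <- rep(gc_target, each = n_codons) / 100
  pg <- 0.25 + kappa * (gc - 0.5)
  pf <- 0.25 - kappa * (gc - 0.5)
  if (any(pg < 0 | pg > 1 | pf < 0 | pf > 1)) {
    warning("group probabilities clipped to [0, 1]")
    pg <- pmin(pmax(pg, 0), 1)
    pf <- pmin(pmax(pf, 0), 1 - pg)
  }
  u <- stats::runif(N)
  grp <- 1L + (u >= pg) + (u >= pg + pf)  # 1 GARP, 2 FYMINK, 3 MIXED
  members <- list(g$GARP, g$FYMINK, g$MIXED)
  res <- character(N)
  for (k in 1:3) {
    idx <- which(grp == k)
    res[idx] <- members[[k]][ceiling(stats::runif(length(idx)) *
                                       length(members[[k]]))]
  }
  use_gc <- stats::runif(N) < gc
  use_gc[res %in% c("M", "W")] <- TRUE  # single GC-ending codon only
  key <- paste0(res, ifelse(use_gc, "G", "A"))
  codon <- character(N)
  for (k in unique(key)) {
    set <- ct$sets[[k]]
    idx <- which(key == k)
    codon[idx] <- set[ceiling(stats::runif(length(idx)) * length(set))]
  }
  gene <- rep(seq_len(G), each = n_codons)
  list(cds = vapply(split(codon, gene), paste, "", collapse = ""),
       protein = vapply(split(res, gene), paste, "", collapse = ""))
}

#' Simulate one coding sequence under a GC target
#'
#' Amino acids are drawn with GC-coupled group probabilities
#' (`P(GARP) = 0.25 + kappa * (gc_target - 50) / 100`, `P(FYMINK)`
#' mirrored, mixed residues absorbing the rest; residues uniform within a
#' group), and the synonymous codon is chosen with a G/C third position
#' with probability `gc_target / 100`.
#'
#' @param gc_target target GC in percent, in (0, 100).
#' @param n_codons number of codons.
#' @param kappa GC/GARP coupling in \[0, 1\].
#' @param seed optional seed for standalone reproducibility.
#' @return list with `cds` (DNA string, no stop codons) and `protein`.
#' @export
simulate_cds <- function(gc_target, n_codons, kappa = 0.6, seed = NULL) {
  stopifnot(gc_target > 0, gc_target < 100, n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- .sample_cds_block(gc_target, n_codons, kappa)
  list(cds = unname(out$cds[1L]), protein = unname(out$protein[1L]))
}

# Gaussian-bump GC target curve, clipped to [25, 75]
.gc_target_curve <- function(config) {
  r <- seq_len(config$n_genes)
  target <- rep(config$gc_baseline, config$n_genes)
  if (nrow(config$peaks))
    for (i in seq_len(nrow(config$peaks)))
      target <- target + config$peaks$amplitude[i] *
        exp(-0.5 * ((r - config$peaks$center[i]) / config$peaks$width[i])^2)
  pmin(pmax(target, 25), 75)
}

.chromosome_blocks <- function(n_genes, n_chromosomes) {
  paste0("chr", cut(seq_len(n_genes), n_chromosomes, labels = FALSE))
}

# sequential gene coordinates along each chromosome, 1 kb intergenic spacing
.gene_coordinates <- function(chrom, len) {
  start <- integer(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start[idx] <- (seq_along(idx) - 1L) * (len + 1000L) + 1L
  }
  list(start = start, end = start + len - 1L)
}

#' Simulate the ancestral reference exome
#'
#' Lays `n_genes` genes over contiguous chromosome blocks, builds the GC
#' target curve (baseline plus Gaussian peaks, clipped to \[25, 75\]) and
#' samples every gene's coding sequence and protein under that target.
#'
#' @param config a [simulation_config()].
#' @param seed seed used before sampling; `NULL` leaves the RNG state
#'   untouched (used internally by [simulate_exomes()]).
#' @return an `exome_reference`: list with the ancestral `order` table,
#'   `cds` and `proteins` (named by gene symbol), the `gc_target` curve and
#'   a `truth` record of the planted peaks.
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  G <- config$n_genes
  symbols <- sprintf("G%05d", seq_len(G))
  target <- .gc_target_curve(config)
  chrom <- .chromosome_blocks(G, config$n_chromosomes)
  len <- 3L * config$n_codons
  coords <- .gene_coordinates(chrom, len)
  seqs <- .sample_cds_block(target, config$n_codons, config$kappa)
  order <- data.frame(gene_symbol = symbols, chromosome = chrom,
                      start = coords$start, end = coords$end, strand = "+",
                      transcript_accession = sprintf("NM_%06d", seq_len(G)),
                      protein_accession = sprintf("NP_%06d", seq_len(G)),
                      transcript_length = len, rank = seq_len(G),
                      stringsAsFactors = FALSE)
  structure(list(order = order,
                 cds = stats::setNames(unname(seqs$cds), symbols),
                 proteins = stats::setNames(unname(seqs$protein), symbols),
                 gc_target = stats::setNames(target, symbols),
                 truth = list(gc_target = target, peaks = config$peaks),
                 config = config),
            class = "exome_reference")
}

.BASES <- c("A", "C", "G", "T")

.translate_codons <- function(codons) {
  aa <- .codon_tables()$code[codons]
  aa[is.na(aa)] <- "*"
  unname(aa)
}

# one branch of sequence evolution: per-site substitution with probability
# 1 - exp(-len), replacement drawn from the stationary base frequencies pi;
# gBGC episodes add directed events at rate p * bias that set sites inside
# their rank interval to G or C.  Codons that would become stops revert.
.evolve_branch <- function(bases, len, pi, episodes) {
  p <- 1 - exp(-len)
  prev <- bases
  if (p > 0) {
    ev <- which(stats::runif(length(bases)) < p)
    if (length(ev))
      bases[ev] <- sample(.BASES, length(ev), replace = TRUE, prob = pi)
    for (ep in episodes) {
      s <- ep$sites
      ev2 <- s[stats::runif(length(s)) < p * ep$bias]
      if (length(ev2))
        bases[ev2] <- sample(c("G", "C"), length(ev2), replace = TRUE)
    }
  }
  changed <- which(bases != prev)
  if (length(changed)) {
    cod <- unique((changed - 1L) %/% 3L)
    p1 <- 3L * cod + 1L
    codons <- paste0(bases[p1], bases[p1 + 1L], bases[p1 + 2L])
    stopped <- which(.translate_codons(codons) == "*")
    for (i in stopped) {
      idx <- p1[i]:(p1[i] + 2L)
      bases[idx] <- prev[idx]
    }
  }
  bases
}

# random block move of contiguous genes within a gene-order vector
.rearrange_order <- function(ord, log_env, branch) {
  G <- length(ord)
  if (G < 3) return(ord)
  blocklen <- sample(5:50, 1L)
  blocklen <- min(blocklen, G - 1L)
  start <- sample(G - blocklen + 1L, 1L)
  block <- ord[start:(start + blocklen - 1L)]
  rest <- ord[-(start:(start + blocklen - 1L))]
  ins <- sample(length(rest) + 1L, 1L)
  log_env$log <- rbind(log_env$log,
                       data.frame(branch = branch, start = start,
                                  length = blocklen, insert_at = ins))
  append(rest, block, after = ins - 1L)
}

# edges of the subtree spanned by a set of tips, including the stem edge
.clade_edges <- function(phy, tips) {
  tip_idx <- match(tips, phy$tip.label)
  if (length(tip_idx) == 1L) return(which(phy$edge[, 2] == tip_idx))
  mrca <- ape::getMRCA(phy, tips)
  nodes <- mrca
  repeat {
    kids <- phy$edge[phy$edge[, 1] %in% nodes, 2]
    new <- setdiff(kids, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  which(phy$edge[, 2] %in% nodes)
}

#' Evolve species exomes along a tree
#'
#' Starting from the ancestral reference, applies per-site substitutions
#' along every branch (rate given by the branch length in expected
#' substitutions per site, replacements drawn from the ancestral base
#' frequencies so composition is stationary without bias), GC-biased gene
#' conversion inside the configured rank intervals, and random gene-block
#' rearrangements.  Each leaf emits a gene table plus transcript and
#' protein sequences.
#'
#' @param reference an `exome_reference` from [simulate_reference()].
#' @param config the same [simulation_config()].
#' @param seed seed used before evolving; `NULL` leaves the RNG state
#'   untouched.
#' @return list with per-species `tables`, `transcripts`, `proteins`
#'   (named by species) and a `truth` record (tree, rearrangement log,
#'   gBGC episodes).
#' @export
evolve_species <- function(reference, config, seed = config$seed + 1L) {
  stopifnot(inherits(reference, "exome_reference"))
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::read.tree(text = config$tree)
  G <- config$n_genes
  L <- 3L * config$n_codons
  bases0 <- strsplit(paste(reference$cds, collapse = ""), "")[[1L]]
  pi <- as.numeric(table(factor(bases0, levels = .BASES))) / length(bases0)
  # pre-resolve gBGC episodes to edges and site indices
  episodes_by_edge <- vector("list", nrow(phy$edge))
  for (ep in config$gbgc) {
    sites <- as.vector(outer(1:L, (ep$from:ep$to - 1L) * L, `+`))
    for (e in .clade_edges(phy, ep$tips))
      episodes_by_edge[[e]] <- c(episodes_by_edge[[e]],
                                 list(list(sites = sites, bias = ep$bias)))
  }
  root <- length(phy$tip.label) + 1L
  log_env <- new.env()
  log_env$log <- data.frame(branch = character(0), start = integer(0),
                            length = integer(0), insert_at = integer(0))
  out <- list()
  walk <- function(node, bases, ord) {
    kids <- which(phy$edge[, 1] == node)
    for (e in kids) {
      child <- phy$edge[e, 2]
      label <- if (child <= length(phy$tip.label))
        phy$tip.label[child] else paste0("node", child)
      b <- .evolve_branch(bases, phy$edge.length[e], pi,
                          episodes_by_edge[[e]])
      o <- ord
      if (config$rearrangement_rate > 0) {
        k <- stats::rpois(1L, config$rearrangement_rate)
        for (i in seq_len(k)) o <- .rearrange_order(o, log_env, label)
      }
      if (child <= length(phy$tip.label)) {
        out[[phy$tip.label[child]]] <<- list(bases = b, order = o)
      } else {
        walk(child, b, o)
      }
    }
  }
  walk(root, bases0, seq_len(G))
  symbols <- reference$order$gene_symbol
  species <- phy$tip.label
  tables <- transcripts <- proteins <- stats::setNames(
    vector("list", length(species)), species)
  for (i in seq_along(species)) {
    sp <- species[i]
    st <- out[[sp]]
    full <- paste(st$bases, collapse = "")
    cds <- substring(full, (seq_len(G) - 1L) * L + 1L, seq_len(G) * L)
    codons <- substring(full, seq(1L, G * L, 3L), seq(3L, G * L, 3L))
    aa <- .translate_codons(codons)
    prot <- vapply(split(aa, rep(seq_len(G), each = config$n_codons)),
                   paste, "", collapse = "")
    tx_acc <- sprintf("XM_%02d%06d", i, seq_len(G))
    pr_acc <- sprintf("XP_%02d%06d", i, seq_len(G))
    chrom <- .chromosome_blocks(G, config$n_chromosomes)
    coords <- .gene_coordinates(chrom, L)
    tbl <- data.frame(gene_symbol = symbols[st$order], chromosome = chrom,
                      start = coords$start, end = coords$end, strand = "+",
                      transcript_accession = tx_acc[st$order],
                      protein_accession = pr_acc[st$order],
                      transcript_length = L, stringsAsFactors = FALSE)
    tables[[sp]] <- as_species_table(tbl, species = sp,
                                     clade = unname(config$clades[sp]))
    transcripts[[sp]] <- stats::setNames(unname(cds), tx_acc)
    proteins[[sp]] <- stats::setNames(unname(prot), pr_acc)
  }
  list(tables = tables, transcripts = transcripts, proteins = proteins,
       truth = list(tree = config$tree,
                    rearrangements = log_env$log, gbgc = config$gbgc))
}

#' Simulate a complete multi-species exome dataset
#'
#' Runs [simulate_reference()] and [evolve_species()] under a single seed
#' and optionally writes the per-species gene tables (TSV), transcript and
#' protein FASTA files, the true tree and a ground-truth JSON record.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory.
#' @return an `exome_simulation`: list with `reference`, per-species
#'   `tables` / `transcripts` / `proteins`, `truth` and `config`.
#' @export
simulate_exomes <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  reference <- simulate_reference(config, seed = NULL)
  ev <- evolve_species(reference, config, seed = NULL)
  sim <- structure(list(reference = reference, tables = ev$tables,
                        transcripts = ev$transcripts,
                        proteins = ev$proteins,
                        truth = c(reference$truth, ev$truth),
                        config = config),
                   class = "exome_simulation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in names(sim$tables)) {
      write_gene_table(sim$tables[[sp]], file.path(out_dir,
                                                   paste0(sp, ".tsv")))
      write_fasta(sim$transcripts[[sp]],
                  file.path(out_dir, paste0(sp, "_transcripts.fa")))
      write_fasta(sim$proteins[[sp]],
                  file.path(out_dir, paste0(sp, "_proteins.fa")))
    }
    writeLines(config$tree, file.path(out_dir, "true_tree.nwk"))
    jsonlite::write_json(
      list(gc_target = unname(sim$reference$gc_target),
           peaks = sim$config$peaks,
           rearrangements = sim$truth$rearrangements,
           seed = config$seed),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
  }
  sim
}

#' @export
print.exome_simulation <- function(x, ...) {
  cat("simulated exome dataset:", x$config$n_genes, "genes x",
      length(x$tables), "species (", x$config$n_codons, "codons/gene )\n")
  cat("tree:", x$config$tree, "\n")
  cat("peaks:", nrow(x$config$peaks), "| kappa:", x$config$kappa,
      "| gBGC episodes:", length(x$config$gbgc),
      "| seed:", x$config$seed, "\n")
  invisible(x)
}
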