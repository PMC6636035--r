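# Independent brute-force oracles used across the suite.

# plain range mean at every position
bf_window_mean <- function(values, w) {
  n <- length(values)
  vapply(seq_len(n), function(k)
    mean(values[max(1, k - w):min(n, k + w)]), numeric(1))
}

# exhaustive enumeration of all global alignments (affine gap runs cost
# open + (len - 1) * ext), returning the maximal score
bf_align_score <- function(a, b, mat, gap_open = 12, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > na && j > nb) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, "D", acc + mat[A[i], B[j]])
    if (i <= na)
      rec(i + 1L, j, "U",
          acc - if (identical(prev, "U")) gap_extend else gap_open)
    if (j <= nb)
      rec(i, j + 1L, "L",
          acc - if (identical(prev, "L")) gap_extend else gap_open)
  }
  rec(1L, 1L, "", 0)
  best
}

# random protein over the 20 standard residues
random_protein <- function(n) {
  paste(sample(unlist(aa_groups(), use.names = FALSE), n, replace = TRUE),
        collapse = "")
}

# per-gene GC/GARP/FYMINK metrics straight from an exome_reference
reference_metrics <- function(ref) {
  garp <- fymink <- numeric(length(ref$proteins))
  for (i in seq_along(ref$proteins)) {
    u <- aa_usage(ref$proteins[[i]])
    garp[i] <- u$garp_percent
    fymink[i] <- u$fymink_percent
  }
  data.frame(gene_symbol = names(ref$cds),
             gc_percent = gc_fraction(ref$cds),
             garp_percent = garp, fymink_percent = fymink,
             stringsAsFactors = FALSE)
}

# GC landscapes for every species of a simulation, on the reference
# species' genome order
simulation_landscapes <- function(sim, reference, w = 50,
                                  metric = "gc_percent") {
  om <- match_orthologs(sim$tables[setdiff(names(sim$tables), reference)],
                        sim$tables[[reference]])
  lands <- lapply(names(sim$tables), function(sp) {
    m <- per_gene_metrics(sim$tables[[sp]], sim$transcripts[[sp]],
                          sim$proteins[[sp]])
    landscape(stats::setNames(m[[metric]], m$gene_symbol),
              om$reference_frame, w = w, species = sp, metric = metric)
  })
  names(lands) <- names(sim$tables)
  lands
}

# closed-form expected amino-acid difference probability between two
# leaves at equal branch length under the simulator's substitution model
# (per-site resampling from pi with prob 1 - exp(-len); codons that would
# become stops revert to the ancestral codon)
expected_pair_divergence <- function(ref_cds, branch_len, pi) {
  p <- 1 - exp(-branch_len)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  first <- substr(codons, 1, 1)
  second <- substr(codons, 2, 2)
  third <- substr(codons, 3, 3)
  anc <- unlist(lapply(ref_cds, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  anc_counts <- table(anc)
  site_tp <- function(a, b) (1 - p) * (a == b) + p * pi[b]
  total <- 0
  for (ac in names(anc_counts)) {
    pvec <- site_tp(substr(ac, 1, 1), first) *
      site_tp(substr(ac, 2, 2), second) *
      site_tp(substr(ac, 3, 3), third)
    names(pvec) <- codons
    stops <- code == "*"
    pvec[ac] <- pvec[ac] + sum(pvec[stops])
    pvec[stops] <- 0
    p_same <- sum(tapply(pvec, code, sum)^2)
    total <- total + anc_counts[[ac]] * (1 - p_same)
  }
  total / sum(anc_counts)
}

# minimal gene-table TSV written to a temp file
write_demo_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("gene_symbol", "chromosome", "start", "end", "strand",
                    "transcript_accession", "transcript_length"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
  path
}
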