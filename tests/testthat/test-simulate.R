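small_cfg <- function(...) {
  defaults <- list(n_genes = 200, n_codons = 60,
                   peaks = data.frame(center = 100, width = 30,
                                      amplitude = 12),
                   tree = "((a:0.05,b:0.05):0.03,(c:0.05,d:0.05):0.03);",
                   rearrangement_rate = 0.5, seed = 51)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(simulation_config, defaults)
}

test_that("configurations validate their invariants", {
  expect_error(simulation_config(kappa = 1.5), "kappa")
  expect_error(simulation_config(peaks = data.frame(center = 5000, width = 10,
                                                    amplitude = 5)),
               "peak centers")
  expect_error(simulation_config(gbgc = list(list(tips = "nope", from = 1,
                                                  to = 5, bias = 0.5))),
               "tips absent")
  expect_error(simulation_config(rearrangement_rate = -1))
})

test_that("the reference exome honours its GC target construction", {
  flat <- simulate_reference(small_cfg(peaks = data.frame(center = numeric(0),
                                                          width = numeric(0),
                                                          amplitude = numeric(0))))
  expect_true(all(flat$gc_target == flat$config$gc_baseline))
  ref <- simulate_reference(small_cfg())
  expect_equal(unname(which.max(ref$gc_target)), 100)  # peak center
  expect_equal(length(ref$cds), 200L)
  expect_true(all(nchar(ref$cds) == 180L))
  # no stop codons anywhere, proteins translate from the cds
  expect_false(any(grepl("\\*", ref$proteins)))
  codons <- substring(ref$cds[[1]], seq(1, 178, 3), seq(3, 180, 3))
  expect_identical(paste(unname(Biostrings::GENETIC_CODE[codons]),
                         collapse = ""),
                   unname(ref$proteins[[1]]))
})

test_that("simulations are byte-identical under a fixed seed", {
  s1 <- simulate_exomes(small_cfg())
  s2 <- simulate_exomes(small_cfg())
  expect_identical(s1$reference$cds, s2$reference$cds)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(lapply(s1$tables, as.data.frame),
                   lapply(s2$tables, as.data.frame))
  s3 <- simulate_exomes(small_cfg(seed = 52))
  expect_false(identical(s1$transcripts, s3$transcripts))
})

test_that("GC/GARP coupling follows the sampling law", {
  # kappa = 0: amino-acid usage decoupled from the GC target
  ref0 <- simulate_reference(small_cfg(n_genes = 600, n_codons = 150,
                                       kappa = 0, seed = 53))
  m0 <- reference_metrics(ref0)
  expect_lt(abs(stats::cor(ref0$gc_target, m0$garp_percent)), 0.15)
  # strong coupling at high GC: GARP fraction approaches 0.25 + kappa/2
  expect_warning(
    cds <- simulate_cds(gc_target = 99, n_codons = 5000, kappa = 1,
                        seed = 54),
    "clipped")
  u <- aa_usage(cds$protein)
  expect_lt(abs(u$garp_percent - 100 * (0.25 + 0.49)), 3)
  expect_lt(u$fymink_percent, 1)
})

test_that("zero branch lengths copy the ancestor to every leaf", {
  cfg <- small_cfg(tree = "((a:0,b:0):0,c:0);", rearrangement_rate = 0)
  sim <- simulate_exomes(cfg)
  ref_cds <- unname(sim$reference$cds)
  for (sp in names(sim$transcripts))
    expect_identical(unname(sim$transcripts[[sp]]), ref_cds)
  d <- pairwise_divergence_track(sim$tables$a, sim$proteins$a,
                                 sim$tables$b, sim$proteins$b)
  expect_true(all(d$divergence == 0))
})

test_that("base composition is stationary in expectation without bias", {
  cfg <- small_cfg(n_genes = 400, n_codons = 150,
                   tree = "(a:0.2,b:0.2);", rearrangement_rate = 0,
                   seed = 55)
  sim <- simulate_exomes(cfg)
  gc0 <- mean(gc_fraction(paste(sim$reference$cds, collapse = "")))
  for (sp in c("a", "b")) {
    gc1 <- gc_fraction(paste(sim$transcripts[[sp]], collapse = ""))
    expect_lt(abs(gc1 - gc0), 0.5)
  }
})

test_that("pairwise divergence matches the closed-form substitution expectation", {
  cfg <- small_cfg(n_genes = 250, n_codons = 200,
                   tree = "(a:0.15,b:0.15);", rearrangement_rate = 0,
                   seed = 56)
  sim <- simulate_exomes(cfg)
  d <- pairwise_divergence_track(sim$tables$a, sim$proteins$a,
                                 sim$tables$b, sim$proteins$b)
  bases <- strsplit(paste(sim$reference$cds, collapse = ""), "")[[1]]
  pi <- as.numeric(table(factor(bases, c("A", "C", "G", "T")))) / length(bases)
  names(pi) <- c("A", "C", "G", "T")
  expected <- expected_pair_divergence(sim$reference$cds, 0.15, pi)
  expect_lt(abs(mean(d$divergence, na.rm = TRUE) - expected), 0.015)
})

test_that("gBGC episodes raise GC inside their interval on the affected lineage", {
  cfg <- small_cfg(n_genes = 600, n_codons = 150,
                   tree = "(a:0.08,b:0.08);", rearrangement_rate = 0,
                   gbgc = list(list(tips = "a", from = 200, to = 400,
                                    bias = 0.9)),
                   peaks = data.frame(center = numeric(0),
                                      width = numeric(0),
                                      amplitude = numeric(0)),
                   seed = 57)
  sim <- simulate_exomes(cfg)
  om <- match_orthologs(sim$tables["b"], sim$tables$a)
  m <- per_gene_metrics(sim$tables$a, sim$transcripts$a, sim$proteins$a)
  gc <- stats::setNames(m$gc_percent, m$gene_symbol)[
    sim$reference$order$gene_symbol]
  inside <- mean(gc[200:400])
  outside <- mean(gc[-(200:400)])
  expect_gt(inside - outside, 1)
  # the unaffected lineage shows no such contrast
  mb <- per_gene_metrics(sim$tables$b, sim$transcripts$b, sim$proteins$b)
  gcb <- stats::setNames(mb$gc_percent, mb$gene_symbol)[
    sim$reference$order$gene_symbol]
  expect_lt(mean(gcb[200:400]) - mean(gcb[-(200:400)]), 1)
})

test_that("rearrangements permute gene order without touching sequences", {
  cfg <- small_cfg(rearrangement_rate = 3, seed = 58,
                   tree = "(a:0.0,b:0.0);")
  sim <- simulate_exomes(cfg)
  expect_gt(nrow(sim$truth$rearrangements), 0)
  ord_a <- sim$tables$a$gene_symbol
  expect_setequal(ord_a, sim$reference$order$gene_symbol)
  expect_false(identical(ord_a, sim$reference$order$gene_symbol))
  expect_identical(unname(sim$transcripts$a), unname(sim$reference$cds))
})
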