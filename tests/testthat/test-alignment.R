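test_that("worked alignment examples match the published BLOSUM62 scores", {
  aln <- global_align("MKTAY", "MKTAY")
  # sum of BLOSUM62 diagonal entries for M,K,T,A,Y: 5+5+5+4+7
  expect_equal(aln$score, 26)
  expect_equal(aln$match_count, 5L)
  expect_equal(aln$gap_columns, 0L)
  expect_equal(aln$identity, 1)

  one <- global_align("A", "A")
  expect_equal(one$score, 4)  # BLOSUM62 A/A
  expect_equal(one$identity, 1)

  gapped <- global_align("AAAA", "AA")
  expect_equal(gapped$match_count, 2L)
  expect_equal(gapped$gap_columns, 2L)
  expect_equal(gapped$identity, 1)  # 2 / (4 - 2)
  expect_equal(gapped$score,
               bf_align_score("AAAA", "AA", blosum62()))

  expect_error(global_align("", "AA"), "non-empty")
})

test_that("the DP aligner equals exhaustive enumeration on short sequences", {
  mat <- blosum62()
  alpha <- c("G", "A", "L", "K")
  # exhaustive over every pair up to length 3
  seqs <- unlist(lapply(1:3, function(n) {
    g <- do.call(expand.grid, rep(list(alpha), n))
    apply(g, 1, paste, collapse = "")
  }))
  for (a in seqs) for (b in seqs) {
    expect_equal(global_align(a, b, mat)$score, bf_align_score(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("aligner score/identity are symmetric and self-identity is exact", {
  set.seed(21)
  for (i in 1:15) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    ab <- global_align(a, b)
    ba <- global_align(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity, ba$identity)
    self <- global_align(a, a)
    expect_equal(self$identity, 1)
    expect_equal(divergence(self$identity), 0)
  }
})

test_that("aligner agrees with an independent affine-gap implementation", {
  skip_if_not_installed("Biostrings")
  set.seed(22)
  for (i in 1:10) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    ours <- global_align(a, b, gap_open = 12, gap_extend = 2)$score
    # Biostrings charges gapOpening + L * gapExtension per gap run; our
    # open = 12 / extend = 2 convention maps onto gapOpening = 10
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 2, type = "global", scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("X scores zero and never counts as a match", {
  m <- blosum62()
  expect_true(all(m["X", ] == 0) && all(m[, "X"] == 0))
  aln <- global_align("GXG", "GXG")
  expect_equal(aln$match_count, 2L)
  expect_equal(aln$score, 2 * m["G", "G"])
})

test_that("identity formula and the 30% discard rule behave as specified", {
  expect_equal(percent_identity(list(match_count = 90, alignment_length = 100,
                                     gap_columns = 0)), 0.90)
  expect_equal(percent_identity(list(match_count = 50, alignment_length = 60,
                                     gap_columns = 10)), 1.00)
  expect_true(is.na(percent_identity(list(match_count = 0,
                                          alignment_length = 5,
                                          gap_columns = 5))))
  expect_equal(divergence(0.89), 0.11)
  expect_equal(divergence(1.00), 0.00)
  expect_true(is.na(divergence(0.25)))  # below threshold: discarded
  expect_equal(divergence(c(0.5, 0.29, NA)), c(0.5, NA, NA))
  expect_error(divergence(1.2))
})

test_that("divergence tracks report one value per alignable ortholog pair", {
  mk <- function(sp, prot) {
    tbl <- as_species_table(data.frame(
      gene_symbol = names(prot), chromosome = "chr1",
      start = seq_along(prot) * 100, end = seq_along(prot) * 100 + 10,
      strand = "+",
      transcript_accession = sprintf("NM_%s%d", sp, seq_along(prot)),
      protein_accession = sprintf("NP_%s%d", sp, seq_along(prot)),
      transcript_length = 10, stringsAsFactors = FALSE),
      species = sp, clade = "fish")
    list(tbl = tbl, prot = stats::setNames(unname(prot),
                                           tbl$protein_accession))
  }
  pa <- c(g1 = "MKTAYIAKQR", g2 = "GGGGGGGGGG", g3 = "MKTAYIAKQR")
  pb <- c(g1 = "MKTAYIAKQR", g2 = "YYYYYYYYYY", g3 = "MKTWYIAKQR")
  a <- mk("a", pa); b <- mk("b", pb)
  d <- pairwise_divergence_track(a$tbl, a$prot, b$tbl, b$prot)
  d <- d[order(d$gene_symbol), ]
  expect_equal(d$divergence[d$gene_symbol == "g1"], 0)
  expect_true(is.na(d$divergence[d$gene_symbol == "g2"]))  # identity 0 < 0.30
  expect_equal(d$divergence[d$gene_symbol == "g3"], 0.1)
  # identical proteomes: all divergences zero
  d0 <- pairwise_divergence_track(a$tbl, a$prot, a$tbl, a$prot)
  expect_true(all(d0$divergence == 0))
})
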