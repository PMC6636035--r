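test_that("gene tables read, validate and reject bad rows by number", {
  p <- write_demo_table(c(
    "TP53\tchr17\t100\t500\t+\tNM_000546\t2512",
    "BRCA1\tchr17\t900\t1500\t-\tNM_007294\t7088",
    "ACTB\tchr7\t10\t90\t+\tNM_001101\t1852"))
  tbl <- read_gene_table(p, species = "human", clade = "mammal")
  expect_s3_class(tbl, "species_table")
  expect_equal(nrow(tbl), 3L)
  expect_identical(attr(tbl, "clade"), "mammal")

  empty <- write_demo_table(character(0))
  expect_equal(nrow(read_gene_table(empty, "h", "mammal")), 0L)

  bad <- write_demo_table(c(
    "TP53\tchr17\t100\t500\t+\tNM_000546\t2512",
    "BRCA1\tchr17\t1500\t900\t-\tNM_007294\t7088"))
  expect_error(read_gene_table(bad, "h", "mammal"), "row\\(s\\) 2")

  noheader <- tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tchromosome\tstart", "TP53\tchr17\t1"), noheader)
  expect_error(read_gene_table(noheader, "h", "mammal"), "missing column")

  expect_error(read_gene_table(p, "h", clade = "insect"), "unknown clade")
})

test_that("protein-coding filter keeps NM_/XM_ and drops non-coding RNAs", {
  p <- write_demo_table(c(
    "TP53\tchr1\t1\t10\t+\tNM_000546\t100",
    "RN7SK\tchr1\t20\t30\t+\tNR_001445\t100",
    "PRED1\tchr1\t40\t50\t+\tXM_012345\t100",
    "PREDNC\tchr1\t60\t70\t+\tXR_999999\t100"))
  tbl <- read_gene_table(p, "h", "mammal")
  kept <- filter_protein_coding(tbl)
  expect_setequal(kept$transcript_accession, c("NM_000546", "XM_012345"))
  expect_equal(nrow(filter_protein_coding(kept)), 2L)  # idempotent
  expect_equal(nrow(filter_protein_coding(tbl[0, ])), 0L)
})

test_that("representative selection takes the longest transcript with a deterministic tie-break", {
  recs <- data.frame(gene_symbol = "G1", chromosome = "chr1", start = 1,
                     end = 10, strand = "+",
                     transcript_accession = c("NM_3", "NM_1", "NM_2"),
                     transcript_length = c(1200, 3400, 800),
                     stringsAsFactors = FALSE)
  expect_identical(select_representative(recs)$transcript_accession, "NM_1")
  expect_identical(select_representative(recs[1, ])$transcript_accession,
                   "NM_3")
  tie <- recs
  tie$transcript_length <- c(1000, 1000, 500)
  expect_identical(select_representative(tie)$transcript_accession, "NM_1")
  expect_error(select_representative(recs[0, ]), "empty")
  # finalize = filter + select, and is idempotent
  p <- write_demo_table(c(
    "A\tchr1\t1\t10\t+\tNM_0002\t100",
    "A\tchr1\t1\t10\t+\tNM_0001\t300",
    "A\tchr1\t1\t10\t+\tNR_0003\t900",
    "B\tchr1\t50\t60\t+\tXM_0004\t200"))
  fin <- finalize_species_table(read_gene_table(p, "h", "mammal"))
  expect_equal(fin$transcript_accession, c("NM_0001", "XM_0004"))
  expect_equal(as.data.frame(finalize_species_table(fin)),
               as.data.frame(fin))
})

make_tbl <- function(species, clade, symbols) {
  as_species_table(data.frame(
    gene_symbol = symbols, chromosome = "chr1",
    start = seq_along(symbols) * 100, end = seq_along(symbols) * 100 + 50,
    strand = "+",
    transcript_accession = sprintf("NM_%s%03d", species, seq_along(symbols)),
    transcript_length = 100, stringsAsFactors = FALSE),
    species = species, clade = clade)
}

test_that("ortholog matching is case-insensitive, alias-aware and reports strays", {
  ref <- make_tbl("human", "mammal", c("TP53", "BRCA1", "ACTB"))
  a <- make_tbl("mouse", "mammal", c("Tp53", "Actb", "Zfp1"))
  b <- make_tbl("frog", "amphibia", c("LOC123", "actb"))
  amap <- data.frame(species_symbol = "LOC123", reference_symbol = "TP53",
                     stringsAsFactors = FALSE)
  om <- match_orthologs(list(mouse = a, frog = b), ref, alias_map = amap)
  expect_true(om$presence["TP53", "mouse"])
  expect_true(om$presence["TP53", "frog"])
  expect_false(om$presence["BRCA1", "frog"])
  expect_identical(om$unmatched$mouse, "Zfp1")
  expect_identical(om$reference_order, c("TP53", "BRCA1", "ACTB"))

  dup <- make_tbl("fishy", "fish", c("LOC123", "TP53"))
  expect_error(match_orthologs(list(fishy = dup), ref, alias_map = amap),
               "duplicate symbols")
  bad_map <- data.frame(species_symbol = "LOC9", reference_symbol = "NOPE")
  expect_error(match_orthologs(list(mouse = a), ref, alias_map = bad_map),
               "absent from reference")
})

test_that("common set applies the clade-group presence rule", {
  ref <- make_tbl("human", "mammal", c("A", "B", "C", "D"))
  fish1 <- make_tbl("fish1", "fish", c("A", "C", "D"))
  amph <- make_tbl("amph", "amphibia", c("A", "D"))
  mamm <- make_tbl("mamm", "mammal", c("B", "C", "D"))
  om <- match_orthologs(list(fish1 = fish1, amph = amph, mamm = mamm), ref)
  cs <- build_common_set(om, min_count = 2)
  # A: fish + amphibian = 2 -> kept; B: only mammals -> dropped
  expect_setequal(cs$symbols, c("A", "D"))
  expect_error(build_common_set(om, min_count = 3), "exceeds")

  # monotone in min_count
  n1 <- length(build_common_set(om, min_count = 1)$symbols)
  n2 <- length(build_common_set(om, min_count = 2)$symbols)
  expect_gte(n1, n2)

  # everything present everywhere -> common set is the whole reference
  all1 <- make_tbl("f1", "fish", c("A", "B", "C", "D"))
  all2 <- make_tbl("f2", "fish", c("A", "B", "C", "D"))
  om2 <- match_orthologs(list(f1 = all1, f2 = all2), ref)
  expect_identical(build_common_set(om2, clade_group = "fish",
                                    min_count = 2)$symbols,
                   om2$reference_order)
})
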