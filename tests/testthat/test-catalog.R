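test_that("loading a generic TSV indexes 3'UTR sites by (miRNA, gene) pair", {
  f <- write_tsv_lines(c(
    catalog_header,
    "miR-X\tgeneA\t\tchr1\t100\t107\t+\t3UTR\tstrong\tdb1",
    "miR-X\tgeneA\t\tchr1\t200\t207\t+\t3UTR\tstrong\tdb1",
    "miR-Y\tgeneA\t\tchr1\t300\t307\t+\t3UTR\tweak\tdb1"))
  cat <- load_catalog(f)
  expect_equal(site_count(cat, "miR-X", "geneA"), 2L)
  expect_equal(site_count(cat, "miR-Y", "geneA"), 1L)
  expect_equal(site_count(cat, "miR-Z", "geneA"), 0L)
  expect_equal(sum(cat$index$n_sites), 3L)
})

test_that("header-only files give an empty but valid catalog", {
  cat <- load_catalog(write_tsv_lines(catalog_header))
  expect_s3_class(cat, "cb_catalog")
  expect_equal(nrow(cat$index), 0L)
  expect_equal(nrow(enumerate_triads(cat)), 0L)
})

test_that("non-3'UTR sites are retained but never indexed", {
  f <- write_tsv_lines(c(
    catalog_header,
    "miR-X\tgeneA\t\tchr1\t100\t107\t+\tCDS\tstrong\tdb1"))
  cat <- load_catalog(f)
  expect_equal(nrow(cat$sites), 1L)
  expect_equal(nrow(cat$index), 0L)
  expect_equal(site_count(cat, "miR-X", "geneA"), 0L)
})

test_that("missing required columns and bad coordinates are reported, not swallowed", {
  f <- write_tsv_lines(c("mirna_id\tgene_id\tchrom\tstart",
                         "miR-X\tgeneA\tchr1\t10"))
  expect_error(load_catalog(f), "missing required column")
  f2 <- write_tsv_lines(c(
    catalog_header,
    "miR-X\tgeneA\t\tchr1\tabc\t107\t+\t3UTR\tstrong\tdb1",
    "miR-X\tgeneA\t\tchr1\t500\t400\t+\t3UTR\tstrong\tdb1",
    "miR-X\tgeneB\t\tchr2\t100\t107\t+\t3UTR\tstrong\tdb1"))
  expect_warning(cat <- load_catalog(f2), "unparseable")
  expect_equal(nrow(attr(cat, "row_errors")), 2L)
  expect_equal(site_count(cat, "miR-X", "geneB"), 1L)
})

test_that("rows lacking genomic positions are dropped with a logged count", {
  f <- write_tsv_lines(c(
    catalog_header,
    "miR-X\tgeneA\t\tchr1\t100\t107\t+\t3UTR\tstrong\tdb1",
    "miR-X\tgeneB\t\t\t\t\t+\t3UTR\tstrong\tdb1"))
  expect_message(cat <- load_catalog(f), "dropped 1 of 2")
  expect_equal(attr(cat, "n_dropped"), 1L)
  expect_equal(nrow(cat$sites), 1L)
})

test_that("database dialects convert 1-based inclusive coordinates", {
  f <- write_tsv_lines(c(
    paste(c("miRNA", "Target_Gene", "Chromosome", "Start", "End", "Strand",
            "Region", "Support_Type"), collapse = "\t"),
    "miR-X\tgeneA\tchr1\t101\t108\t+\t3UTR\tFunctional MTI"))
  cat <- load_catalog(f, dialect = "mirtarbase_like")
  expect_equal(cat$sites$start, 100L)
  expect_equal(cat$sites$end, 108L)
  expect_equal(cat$sites$evidence, "strong")
})

test_that("merge collapses duplicate and overlapping same-pair sites", {
  mk <- function(start, end, gene = "geneA", mir = "miR-X") {
    new_catalog(data.frame(mirna_id = mir, gene_id = gene, transcript_id = "",
                           chrom = paste0("chr_", gene), start = start,
                           end = end, strand = "+", region = "3UTR",
                           evidence = "strong", source_db = "x",
                           stringsAsFactors = FALSE), species = "mmu")
  }
  # exact duplicate -> one site
  expect_equal(site_count(merge_catalogs(mk(100, 107), mk(100, 107)), "miR-X", "geneA"), 1L)
  # overlap by >= 1 base -> union interval, one site
  m <- merge_catalogs(mk(100, 107), mk(105, 112))
  expect_equal(site_count(m, "miR-X", "geneA"), 1L)
  # disjoint -> two sites
  expect_equal(site_count(merge_catalogs(mk(100, 107), mk(200, 207)), "miR-X", "geneA"), 2L)
  # species mismatch refused
  b <- mk(100, 107); b$species <- "hsa"
  expect_error(merge_catalogs(mk(100, 107), b), "species mismatch")
})

test_that("sites on different transcripts pool to the gene level", {
  sites <- data.frame(
    mirna_id = "miR-X", gene_id = "geneA", transcript_id = c("tx1", "tx2"),
    chrom = "chr1", start = c(100L, 103L), end = c(107L, 110L), strand = "+",
    region = "3UTR", evidence = "strong", source_db = "x",
    stringsAsFactors = FALSE)
  expect_equal(site_count(new_catalog(sites, species = "mmu"), "miR-X", "geneA"), 1L)
})

test_that("index conservation: counts sum to the number of merged 3'UTR sites", {
  set.seed(11)
  for (i in 1:10) {
    cat <- random_catalog(n_pairs = 15)
    expect_equal(sum(cat$index$n_sites),
                 sum(vapply(unique(paste(cat$index$mirna_id, cat$index$gene_id, sep = "\r")),
                            function(key) {
                              p <- strsplit(key, "\r", fixed = TRUE)[[1]]
                              site_count(cat, p[1], p[2])
                            }, integer(1))))
  }
})

test_that("merge_catalogs is commutative and associative on the index", {
  set.seed(21)
  for (i in 1:8) {
    a <- random_catalog(n_pairs = 8)
    b <- random_catalog(n_pairs = 8)
    c3 <- random_catalog(n_pairs = 6)
    b$species <- c3$species <- a$species
    expect_equal(merge_catalogs(a, b)$index, merge_catalogs(b, a)$index)
    expect_equal(merge_catalogs(merge_catalogs(a, b), c3)$index,
                 merge_catalogs(a, merge_catalogs(b, c3))$index)
  }
})

test_that("re-indexing after merge is idempotent", {
  g <- generate_catalog(seed = 4)
  once <- merge_catalogs(g$catalog, g$catalog)
  twice <- merge_catalogs(once, g$catalog)
  expect_equal(once$index, g$catalog$index)
  expect_equal(twice$index, g$catalog$index)
})

test_that("generic TSV round-trips retained rows bit-exactly", {
  g <- generate_catalog(seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_catalog(g$catalog, f)
  back <- load_catalog(f, species = g$catalog$species)
  expect_equal(back$sites, g$catalog$sites)
  expect_equal(back$index, g$catalog$index)
  f2 <- tempfile(fileext = ".tsv")
  write_catalog(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("evidence restriction drops sites below the requested tiers", {
  f <- write_tsv_lines(c(
    catalog_header,
    "miR-X\tgeneA\t\tchr1\t100\t107\t+\t3UTR\tstrong\tdb1",
    "miR-X\tgeneA\t\tchr1\t200\t207\t+\t3UTR\tweak\tdb1"))
  expect_equal(site_count(load_catalog(f, min_evidence = "strong"), "miR-X", "geneA"), 1L)
  expect_equal(site_count(load_catalog(f), "miR-X", "geneA"), 2L)
})
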