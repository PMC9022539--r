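# builds a catalog directly from desired (mirna, gene) -> count pairs,
# with disjoint site intervals so counts equal multiplicities
catalog_from_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    starts <- 1000L * seq_len(counts$n[i])
    data.frame(mirna_id = counts$m[i], gene_id = counts$g[i], transcript_id = "",
               chrom = paste0("chr_", counts$g[i]), start = starts,
               end = starts + 7L, strand = "+", region = "3UTR",
               evidence = "strong", source_db = "t", stringsAsFactors = FALSE)
  })
  new_catalog(do.call(rbind, rows), species = "t")
}

cc <- function(...) {
  x <- list(...)
  data.frame(m = vapply(x, `[[`, "", 1), g = vapply(x, `[[`, "", 2),
             n = as.integer(vapply(x, `[[`, "", 3)), stringsAsFactors = FALSE)
}

test_that("the two site-count conditions select exactly the qualifying triads", {
  # qualifying: m1 has 3 on A, m2 has 1 on A and 2 on B, no m1 on B
  cat1 <- catalog_from_counts(cc(c("m1", "A", "3"), c("m2", "A", "1"), c("m2", "B", "2")))
  tr <- enumerate_triads(cat1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$regulator, "m1")
  expect_equal(tr$gene_a, "A")
  expect_equal(tr$secondary, "m2")
  expect_equal(tr$gene_b, "B")
  expect_equal(tr[, c("n_m1_on_a", "n_m2_on_a", "n_m2_on_b")],
               data.frame(n_m1_on_a = 3L, n_m2_on_a = 1L, n_m2_on_b = 2L))

  # tie on gene A counts violates strict "fewer"
  cat2 <- catalog_from_counts(cc(c("m1", "A", "2"), c("m2", "A", "2"), c("m2", "B", "2")))
  expect_equal(nrow(enumerate_triads(cat2)), 0L)

  # a single miRNA-1 site on gene B disqualifies it
  cat3 <- catalog_from_counts(cc(c("m1", "A", "3"), c("m2", "A", "1"),
                                 c("m2", "B", "2"), c("m1", "B", "1")))
  expect_equal(nrow(enumerate_triads(cat3)), 0L)

  # secondary without any gene-A site is not "in tandem"
  cat4 <- catalog_from_counts(cc(c("m1", "A", "3"), c("m2", "B", "2")))
  expect_equal(nrow(enumerate_triads(cat4)), 0L)
})

test_that("an absent regulator warns and returns an empty triad set", {
  cat1 <- catalog_from_counts(cc(c("m1", "A", "3"), c("m2", "A", "1"), c("m2", "B", "2")))
  expect_warning(tr <- enumerate_triads(cat1, regulator = "m9"), "no indexed")
  expect_equal(nrow(tr), 0L)
  expect_equal(nrow(enumerate_triads(cat1, regulator = "m1")), 1L)
})

test_that("enumeration equals the brute-force quadruple-loop oracle on random catalogs", {
  set.seed(101)
  for (i in 1:40) {
    cat <- random_catalog(n_mirnas = sample(3:8, 1), n_genes = sample(3:8, 1),
                          n_pairs = sample(6:20, 1))
    expect_identical(enumerate_triads(cat), brute_force_triads(cat))
  }
})

test_that("adding a binding site only removes triads through the two disqualifying routes", {
  set.seed(202)
  for (i in 1:25) {
    cat <- random_catalog(n_mirnas = 5, n_genes = 5, n_pairs = 10, cds_frac = 0)
    before <- enumerate_triads(cat)
    m <- sprintf("rm%02d", sample(5, 1)); g <- sprintf("rg%02d", sample(5, 1))
    extra <- data.frame(mirna_id = m, gene_id = g, transcript_id = "",
                        chrom = paste0("chr_", g), start = 99000L, end = 99007L,
                        strand = "+", region = "3UTR", evidence = "strong",
                        source_db = "t", stringsAsFactors = FALSE)
    after <- enumerate_triads(new_catalog(rbind(cat$sites, extra), species = "rand"))
    key <- function(x) paste(x$regulator, x$gene_a, x$secondary, x$gene_b)
    lost <- before[!key(before) %in% key(after), , drop = FALSE]
    if (nrow(lost) > 0) {
      # each lost triad must be explained: the new site was miRNA-1 on its
      # gene B, or raised the secondary's gene-A count to >= the regulator's
      explained <- (lost$regulator == m & lost$gene_b == g) |
        (lost$secondary == m & lost$gene_a == g & lost$n_m2_on_a + 1L >= lost$n_m1_on_a)
      expect_true(all(explained))
    }
  }
})

test_that("output order is deterministic and lexicographic", {
  g <- generate_catalog(seed = 31)
  tr <- enumerate_triads(g$catalog)
  expect_identical(tr, tr[order(tr$regulator, tr$gene_a, tr$secondary, tr$gene_b), ])
  expect_identical(tr, enumerate_triads(g$catalog))
})

test_that("pair prevalence counts distinct genes A, ignoring gene-B multiplicity", {
  triads <- data.frame(
    regulator = "m1", gene_a = c("A", "A", "D"), secondary = "m2",
    gene_b = c("B", "C", "B"), n_m1_on_a = 3L, n_m2_on_a = 1L, n_m2_on_b = 2L,
    stringsAsFactors = FALSE)
  pv <- pair_prevalence(triads)
  expect_equal(nrow(pv), 1L)
  expect_equal(pv$prevalence, 2L)
  expect_equal(nrow(pair_prevalence(triads[0, ])), 0L)
})

test_that("prevalence is conserved: totals never exceed distinct (regulator, gene A) pairs", {
  set.seed(303)
  for (i in 1:15) {
    cat <- random_catalog(n_mirnas = 7, n_genes = 7, n_pairs = 25)
    tr <- enumerate_triads(cat)
    pv <- pair_prevalence(tr)
    expect_lte(sum(pv$prevalence),
               nrow(unique(tr[, c("regulator", "gene_a", "secondary")])))
    if (nrow(pv) > 0) expect_true(all(pv$prevalence >= 1))
  }
})

test_that("the optional max-gap filter drops distant tandem pairs only", {
  sites <- rbind(
    data.frame(mirna_id = "m1", gene_id = "A", transcript_id = "", chrom = "chr_A",
               start = c(100L, 200L), end = c(107L, 207L), strand = "+",
               region = "3UTR", evidence = "strong", source_db = "t"),
    data.frame(mirna_id = "m2", gene_id = "A", transcript_id = "", chrom = "chr_A",
               start = 5000L, end = 5007L, strand = "+", region = "3UTR",
               evidence = "strong", source_db = "t"),
    data.frame(mirna_id = "m2", gene_id = "B", transcript_id = "", chrom = "chr_B",
               start = c(100L, 200L), end = c(107L, 207L), strand = "+",
               region = "3UTR", evidence = "strong", source_db = "t"))
  cat <- new_catalog(sites, species = "t")
  expect_equal(nrow(enumerate_triads(cat)), 1L)                 # no constraint
  expect_equal(nrow(enumerate_triads(cat, max_gap = 100)), 0L)  # gap ~4.8 kb
  expect_equal(nrow(enumerate_triads(cat, max_gap = 10000)), 1L)
})
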