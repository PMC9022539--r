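#' Generate a binding-site catalog with planted triads and decoys
#'
#' Builds a catalog whose exhaustive triad set is exactly a known planted
#' set. Planted triads share one regulator and use disjoint (gene A,
#' secondary, gene B) blocks, so no cross-combination can qualify. Decoy
#' interaction blocks each violate exactly one triad condition, giving a
#' dedicated negative control per rule:
#'
#' * `tie`: secondary has as many gene-A sites as the regulator (violates
#'   strict "fewer");
#' * `single_site_b`: gene B carries a single secondary site (violates
#'   the >= 2 rule);
#' * `m1_on_b`: gene B carries a regulator site (violates the exclusion
#'   rule);
#' * `no_m2_on_a`: the secondary has no site on gene A (violates the
#'   "in tandem" co-occurrence).
#'
#' Sites are laid on a fictitious genome with one chromosome per gene.
#' Whenever a pair needs `c` merged sites, `c + 1` raw rows are emitted
#' with two of them overlapping, so interval merging is exercised on
#' every pair. Deterministic for a fixed seed.
#'
#' @param n_mirnas,n_genes Catalog dimensions; background miRNAs/genes
#'   beyond the planted blocks receive non-qualifying single sites.
#' @param n_planted Number of planted triads.
#' @param decoy_profile Character vector of decoy classes to include (any
#'   of `"tie"`, `"single_site_b"`, `"m1_on_b"`, `"no_m2_on_a"`).
#' @param seed Integer RNG seed.
#' @param species Species tag for the catalog.
#' @return List with `catalog` (a `cb_catalog`) and `truth` (class
#'   `cb_synthetic_truth`): `planted_triads`, `decoys` (class and the
#'   condition each violates), `regulator`, `seed`, and the feature roles
#'   used by [generate_expression()].
#' @export
generate_catalog <- function(n_mirnas = 16, n_genes = 20, n_planted = 5,
                             decoy_profile = c("tie", "single_site_b",
                                               "m1_on_b", "no_m2_on_a"),
                             seed = 1L, species = "synthetic") {
  decoy_profile <- match.arg(decoy_profile, several.ok = TRUE,
                             choices = c("tie", "single_site_b", "m1_on_b", "no_m2_on_a"))
  # each planted triad consumes 1 secondary miRNA + 2 genes; decoys use
  # their own namespaces; the regulator is shared
  need_mirnas <- 1 + n_planted + 2 * length(decoy_profile)
  need_genes <- 2 * n_planted + 2 * length(decoy_profile)
  if (n_mirnas < need_mirnas || n_genes < need_genes)
    stop(sprintf("infeasible request: %d planted triads with %d decoy class(es) need >= %d miRNAs and >= %d genes",
                 n_planted, length(decoy_profile), need_mirnas, need_genes))
  set.seed(seed)

  mirnas <- sprintf("miR-%02d", seq_len(n_mirnas))
  genes <- sprintf("gene%02d", seq_len(n_genes))
  regulator <- mirnas[1]

  site_rows <- list()
  # emit `count` merged sites for a pair as count + 1 raw rows, two of
  # which overlap (positions jittered by seed for variety)
  emit <- function(mirna, gene, count, region = "3UTR") {
    base <- sample(50:150, 1)
    starts <- base + seq_len(count) * 100L
    starts <- c(starts, starts[1] + sample(1:5, 1))  # overlaps site 1
    data.frame(mirna_id = mirna, gene_id = gene, transcript_id = "",
               chrom = paste0("chr_", gene), start = starts,
               end = starts + 7L, strand = "+", region = region,
               evidence = sample(c("strong", "weak", "direct"), 1),
               source_db = "synthetic", stringsAsFactors = FALSE)
  }
  add <- function(...) site_rows[[length(site_rows) + 1L]] <<- emit(...)

  mi <- 2L; gi <- 1L
  planted <- list()
  for (p in seq_len(n_planted)) {
    m2 <- mirnas[mi]; ga <- genes[gi]; gb <- genes[gi + 1L]
    mi <- mi + 1L; gi <- gi + 2L
    n1a <- sample(2:4, 1)
    n2a <- sample(seq_len(n1a - 1L), 1)
    n2b <- sample(2:3, 1)
    add(regulator, ga, n1a)
    add(m2, ga, n2a)
    add(m2, gb, n2b)
    planted[[p]] <- data.frame(regulator = regulator, gene_a = ga,
                               secondary = m2, gene_b = gb,
                               n_m1_on_a = n1a, n_m2_on_a = n2a,
                               n_m2_on_b = n2b, stringsAsFactors = FALSE)
  }

  decoys <- list()
  for (cls in decoy_profile) {
    dm1 <- mirnas[mi]; dm2 <- mirnas[mi + 1L]
    da <- genes[gi]; db <- genes[gi + 1L]
    mi <- mi + 2L; gi <- gi + 2L
    violated <- switch(cls,
      tie = {
        add(dm1, da, 2); add(dm2, da, 2); add(dm2, db, 2)
        "secondary must have strictly fewer gene-A sites than the regulator"
      },
      single_site_b = {
        add(dm1, da, 3); add(dm2, da, 1); add(dm2, db, 1)
        "gene B must carry two or more secondary-miRNA sites"
      },
      m1_on_b = {
        add(dm1, da, 3); add(dm2, da, 1); add(dm2, db, 2); add(dm1, db, 1)
        "gene B must carry no regulator sites"
      },
      no_m2_on_a = {
        add(dm1, da, 3); add(dm2, db, 2)
        "secondary must co-occur with the regulator on gene A"
      })
    decoys[[cls]] <- list(class = cls, regulator = dm1, gene_a = da,
                          secondary = dm2, gene_b = db, violates = violated)
  }

  # background: leftover miRNAs each get one CDS site on a leftover gene
  # (never indexed) so catalog dimensions are honoured without new triads
  bg_m <- if (mi <= n_mirnas) mirnas[mi:n_mirnas] else character(0)
  bg_g <- if (gi <= n_genes) genes[gi:n_genes] else character(0)
  for (i in seq_along(bg_m)) {
    g <- bg_g[((i - 1) %% max(1, length(bg_g))) + 1]
    if (!is.na(g)) add(bg_m[i], g, 1, region = "CDS")
  }

  sites <- do.call(rbind, site_rows)
  catalog <- new_catalog(sites, species = species, merge_overlaps = TRUE)
  planted_df <- if (n_planted > 0) {
    pd <- do.call(rbind, planted)
    pd <- pd[order(pd$regulator, pd$gene_a, pd$secondary, pd$gene_b), , drop = FALSE]
    rownames(pd) <- NULL
    pd
  } else {
    data.frame(regulator = character(), gene_a = character(),
               secondary = character(), gene_b = character(),
               n_m1_on_a = integer(), n_m2_on_a = integer(),
               n_m2_on_b = integer(), stringsAsFactors = FALSE)
  }
  truth <- structure(
    list(planted_triads = planted_df, decoys = decoys, regulator = regulator,
         mirnas = mirnas, genes = genes, seed = seed,
         planted_mirnas = unique(c(regulator, planted_df$secondary)),
         planted_genes = unique(c(planted_df$gene_a, planted_df$gene_b))),
    class = "cb_synthetic_truth")
  list(catalog = catalog, truth = truth)
}

#' Generate differential-expression tables with planted effects
#'
#' Simulates the expression signature the coordinate-biogenesis model
#' expects: the regulator and every planted secondary miRNA upregulated
#' by `up_lfc`, every planted gene A / gene B downregulated by
#' `down_lfc`, and all remaining catalog features centred on zero.
#' P-values come from a two-group Welch t-test on simulated replicates
#' (default 3 vs 3) so the p-value / fold-change joint structure is
#' realistic; replicate measurement noise has a small fixed floor (sd
#' 0.05) so the test is defined even at `noise_sigma = 0`, where every
#' planted feature passes the default thresholds and background features
#' fail the fold-change rule.
#'
#' @param truth A `cb_synthetic_truth` from [generate_catalog()].
#' @param up_lfc Log2 fold change planted on upregulated miRNAs.
#' @param down_lfc Log2 magnitude planted on downregulated target genes.
#' @param noise_sigma Biological noise sd added to replicate measurements
#'   on the log2 scale.
#' @param n_reps Replicates per group for the t-model.
#' @param seed Integer RNG seed.
#' @return List with `mrna_de` and `mirna_de` data.frames
#'   (`feature_id`, `log2fc`, `pvalue`).
#' @export
generate_expression <- function(truth, up_lfc = 2, down_lfc = 1.5,
                                noise_sigma = 0, n_reps = 3, seed = 1L) {
  stopifnot(inherits(truth, "cb_synthetic_truth"))
  if (up_lfc <= 0 || down_lfc <= 0) stop("effect magnitudes must be positive")
  set.seed(seed)
  sd_rep <- noise_sigma + 0.05  # measurement floor keeps the t-test defined

  simulate_table <- function(features, effects) {
    rows <- lapply(seq_along(features), function(i) {
      ctrl <- stats::rnorm(n_reps, 8, sd_rep)
      case <- stats::rnorm(n_reps, 8 + effects[i], sd_rep)
      tt <- stats::t.test(case, ctrl)
      data.frame(feature_id = features[i],
                 log2fc = mean(case) - mean(ctrl),
                 pvalue = tt$p.value, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  mirnas <- truth$mirnas
  mirna_eff <- ifelse(mirnas %in% truth$planted_mirnas, up_lfc, 0)
  genes <- truth$genes
  gene_eff <- ifelse(genes %in% truth$planted_genes, -down_lfc, 0)

  list(mrna_de = simulate_table(genes, gene_eff),
       mirna_de = simulate_table(mirnas, mirna_eff))
}
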