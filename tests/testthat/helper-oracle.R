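# Independent oracles used by the property tests. Kept deliberately naive:
# the quadruple loop applies the triad conditions directly to site counts,
# and the hypergeometric tail is an explicit sum of binomial-coefficient
# products. Neither shares code with the implementation paths they check.

brute_force_triads <- function(catalog) {
  idx <- catalog$index
  mirnas <- sort(unique(idx$mirna_id))
  genes <- sort(unique(idx$gene_id))
  cnt_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(idx)))
    assign(paste(idx$mirna_id[i], idx$gene_id[i]), idx$n_sites[i], envir = cnt_env)
  cnt <- function(m, g) {
    v <- mget(paste(m, g), envir = cnt_env, ifnotfound = 0L)[[1]]
    v
  }
  rows <- list()
  for (m1 in mirnas) for (ga in genes) for (m2 in mirnas) for (gb in genes) {
    if (m1 == m2 || ga == gb) next
    n1a <- cnt(m1, ga)
    n2a <- cnt(m2, ga)
    n2b <- cnt(m2, gb)
    n1b <- cnt(m1, gb)
    if (n1a >= 2 && n2a >= 1 && n2a < n1a && n2b >= 2 && n1b == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = m1, gene_a = ga, secondary = m2, gene_b = gb,
        n_m1_on_a = n1a, n_m2_on_a = n2a, n_m2_on_b = n2b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(regulator = character(), gene_a = character(),
                      secondary = character(), gene_b = character(),
                      n_m1_on_a = integer(), n_m2_on_a = integer(),
                      n_m2_on_b = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$regulator, out$gene_a, out$secondary, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact enumeration of the upper hypergeometric tail via products of
# binomial coefficients (exactly representable in double for N <= 60).
exact_hyper_tail <- function(k, n, K, N) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random catalog with non-overlapping sites: counts are exactly the row
# multiplicities, so the brute-force oracle sees the intended numbers.
random_catalog <- function(n_mirnas = 6, n_genes = 6, n_pairs = 12,
                           max_sites = 4, cds_frac = 0.15) {
  mirnas <- sprintf("rm%02d", seq_len(n_mirnas))
  genes <- sprintf("rg%02d", seq_len(n_genes))
  pairs <- expand.grid(m = mirnas, g = genes, stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), min(n_pairs, nrow(pairs))), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cnt <- sample(max_sites, 1)
    region <- if (stats::runif(1) < cds_frac) "CDS" else "3UTR"
    starts <- 1000L * seq_len(cnt) + sample(0:50, 1)
    data.frame(mirna_id = pairs$m[i], gene_id = pairs$g[i], transcript_id = "",
               chrom = paste0("chr_", pairs$g[i]), start = starts,
               end = starts + 7L, strand = "+", region = region,
               evidence = "strong", source_db = "rand",
               stringsAsFactors = FALSE)
  })
  new_catalog(do.call(rbind, rows), species = "rand")
}

catalog_header <- paste(c("mirna_id", "gene_id", "transcript_id", "chrom",
                          "start", "end", "strand", "region", "evidence",
                          "source_db"), collapse = "\t")

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
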