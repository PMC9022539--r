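#' Enumerate coordinate-biogenesis triads
#'
#' A triad (regulator, gene A, secondary, gene B) is emitted when the two
#' site-count conditions hold on merged 3'UTR counts:
#'
#' * gene A carries two or more regulator (miRNA-1) sites in tandem with at
#'   least one secondary (miRNA-2) site, and strictly fewer miRNA-2 sites
#'   than miRNA-1 sites;
#' * gene B carries two or more miRNA-2 sites and no miRNA-1 sites.
#'
#' Self-pairs (regulator == secondary) and gene B == gene A are excluded.
#' "In tandem" imposes no distance constraint by default; `max_gap` (bases
#' between the closest regulator/secondary site pair on gene A) optionally
#' restricts it.
#'
#' @param catalog A `cb_catalog`.
#' @param regulator A miRNA id to use as miRNA-1, or `NULL` to enumerate
#'   over every miRNA in the catalog.
#' @param max_gap Optional maximum gap in bases between the nearest
#'   regulator and secondary site on gene A; `NULL` (default) disables the
#'   filter.
#' @return data.frame with columns `regulator`, `gene_a`, `secondary`,
#'   `gene_b`, `n_m1_on_a`, `n_m2_on_a`, `n_m2_on_b`, sorted
#'   lexicographically by (regulator, gene_a, secondary, gene_b).
#' @export
enumerate_triads <- function(catalog, regulator = NULL, max_gap = NULL) {
  stopifnot(inherits(catalog, "cb_catalog"))
  idx <- catalog$index
  empty <- data.frame(regulator = character(), gene_a = character(),
                      secondary = character(), gene_b = character(),
                      n_m1_on_a = integer(), n_m2_on_a = integer(),
                      n_m2_on_b = integer(), stringsAsFactors = FALSE)
  if (nrow(idx) == 0) return(empty)

  regs <- if (is.null(regulator)) unique(idx$mirna_id) else regulator
  if (!is.null(regulator) && !regulator %in% idx$mirna_id) {
    warning(sprintf("regulator '%s' has no indexed 3'UTR sites in this catalog", regulator))
    return(empty)
  }

  by_gene <- split(idx, idx$gene_id)       # miRNAs per gene
  by_mirna <- split(idx, idx$mirna_id)     # genes per miRNA

  rows <- list()
  for (m1 in regs) {
    m1_genes <- by_mirna[[m1]]
    genes_a <- m1_genes$gene_id[m1_genes$n_sites >= 2L]
    # genes whose 3'UTR carries any miRNA-1 site are ineligible as gene B
    m1_hit <- m1_genes$gene_id
    for (ga in sort(genes_a)) {
      n1 <- m1_genes$n_sites[m1_genes$gene_id == ga]
      on_a <- by_gene[[ga]]
      sec <- on_a[on_a$mirna_id != m1 & on_a$n_sites >= 1L & on_a$n_sites < n1, , drop = FALSE]
      if (nrow(sec) == 0) next
      for (j in seq_len(nrow(sec))) {
        m2 <- sec$mirna_id[j]
        if (!is.null(max_gap) &&
            .min_site_gap(catalog, m1, m2, ga) > max_gap) next
        m2_genes <- by_mirna[[m2]]
        gb <- m2_genes$gene_id[m2_genes$n_sites >= 2L]
        gb <- setdiff(gb, c(ga, m1_hit))
        if (length(gb) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          regulator = m1, gene_a = ga, secondary = m2, gene_b = sort(gb),
          n_m1_on_a = n1,
          n_m2_on_a = sec$n_sites[j],
          n_m2_on_b = m2_genes$n_sites[match(sort(gb), m2_genes$gene_id)],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$regulator, out$gene_a, out$secondary, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Smallest base gap between any regulator site and any secondary site on a
# gene's 3'UTR (0 when intervals touch or overlap).
.min_site_gap <- function(catalog, m1, m2, gene) {
  s <- catalog$sites
  s <- s[s$gene_id == gene & s$region == "3UTR", , drop = FALSE]
  a <- s[s$mirna_id == m1, , drop = FALSE]
  b <- s[s$mirna_id == m2, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  gaps <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
    max(0L, max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]))
  }))
  min(gaps)
}

#' Prevalence of coordinate-biogenesis miRNA pairs
#'
#' Counts, for each (regulator, secondary) pair, the number of distinct
#' genes A across which the pair co-occurs in the triad set. Multiplicity
#' in gene B is ignored. Prevalence ranks pairs: higher counts mark pairs
#' supported by more shared primary targets.
#'
#' @param triads data.frame as returned by [enumerate_triads()].
#' @return data.frame `regulator`, `secondary`, `prevalence`, sorted by
#'   descending prevalence then lexicographically.
#' @export
pair_prevalence <- function(triads) {
  empty <- data.frame(regulator = character(), secondary = character(),
                      prevalence = integer(), stringsAsFactors = FALSE)
  if (is.null(triads) || nrow(triads) == 0) return(empty)
  key <- unique(triads[, c("regulator", "secondary", "gene_a")])
  agg <- stats::aggregate(list(prevalence = rep(1L, nrow(key))),
                          by = list(regulator = key$regulator,
                                    secondary = key$secondary),
                          FUN = sum)
  agg$prevalence <- as.integer(agg$prevalence)
  agg <- agg[order(-agg$prevalence, agg$regulator, agg$secondary), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
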