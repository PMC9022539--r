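#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more query hits in a gene set, for a
#' hypergeometric draw of `n` genes from a universe of `N` genes of which
#' `K` belong to the set — the standard over-representation test. The tail
#' is inclusive, `P(X >= k)`, and evaluated through the stable log-space
#' distribution machinery of [stats::phyper()].
#'
#' @param k Query hits in the set.
#' @param n Query size (genes mappable to the background).
#' @param K Set size within the background.
#' @param N Background size.
#' @return `P(X >= k)`, a probability in (0, 1].
#' @examples
#' hypergeom_pvalue(15, 170, 253, 8900)  # ~9.57e-05
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (any(c(k, n, K, N) %% 1 != 0) || any(c(k, n, K, N) < 0))
    stop("k, n, K, N must be non-negative integers")
  if (any(K > N) || any(n > N)) stop("K and n must not exceed the background size N")
  if (any(k > pmin(n, K))) stop("k must not exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a gene-set collection against an explicit background
#'
#' Members outside the background universe are removed from each set;
#' empty or fully out-of-background sets are dropped. The background is
#' always an explicit input: whether it is an annotation universe or an
#' expressed-gene universe is a study design decision, not a default.
#'
#' @param sets Named list of character vectors of member gene ids, or the
#'   result of [read_gmt()].
#' @param background Character vector: the gene universe.
#' @param descriptions Optional named character vector of set
#'   descriptions (names matching `sets`).
#' @return An object of class `cb_geneset_collection`.
#' @export
gene_set_collection <- function(sets, background, descriptions = NULL) {
  if (length(background) == 0) stop("background gene universe must be non-empty")
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), background))
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 background = background),
            class = "cb_geneset_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set id, description, members...).
#' @return Named list of member vectors, with set descriptions attached as
#'   the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  # gmtPathways drops the description field; recover it for reporting
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(lines, function(x) if (length(x) >= 2) x[2] else "", character(1))
  names(desc) <- vapply(lines, `[`, character(1), 1)
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against every set in a collection. The query is
#' restricted to the background before testing (dropped genes are
#' reported via a message); only sets with at least one query hit are
#' tested; Benjamini-Hochberg adjustment is applied across the tested
#' sets.
#'
#' @param query_genes Character vector of query gene ids.
#' @param collection A `cb_geneset_collection`.
#' @param padj_method Only `"BH"` is supported.
#' @return data.frame with columns `set_id`, `description`, `k`, `n`,
#'   `K`, `N`, `gene_ratio`, `bg_ratio`, `pvalue`, `padj`, `genes`
#'   (slash-joined hits), sorted by ascending p-value.
#' @export
enrich <- function(query_genes, collection, padj_method = "BH") {
  stopifnot(inherits(collection, "cb_geneset_collection"))
  padj_method <- match.arg(padj_method, "BH")
  query <- unique(as.character(query_genes))
  mappable <- intersect(query, collection$background)
  n_lost <- length(query) - length(mappable)
  if (n_lost > 0)
    message(sprintf("enrich: %d query gene(s) absent from the background were dropped", n_lost))
  n <- length(mappable)
  N <- length(collection$background)

  res <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    hits <- intersect(mappable, members)
    k <- length(hits)
    if (k == 0) return(NULL)
    K <- length(members)
    data.frame(set_id = id,
               description = unname(collection$descriptions[id]),
               k = k, n = n, K = K, N = N,
               gene_ratio = sprintf("%d/%d", k, n),
               bg_ratio = sprintf("%d/%d", K, N),
               pvalue = hypergeom_pvalue(k, n, K, N),
               genes = paste(sort(hits), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(set_id = character(), description = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      gene_ratio = character(), bg_ratio = character(),
                      pvalue = numeric(), padj = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[order(res$pvalue, res$set_id), c("set_id", "description", "k", "n",
                                              "K", "N", "gene_ratio", "bg_ratio",
                                              "pvalue", "padj", "genes")]
  rownames(res) <- NULL
  res
}
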