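# Canonical column set of the generic binding-site TSV dialect.
.catalog_cols <- c("mirna_id", "gene_id", "transcript_id", "chrom", "start",
                   "end", "strand", "region", "evidence", "source_db")

# Column maps for database-style exports onto the generic schema.
# Both database dialects report 1-based inclusive coordinates.
.dialect_maps <- list(
  mirtarbase_like = c(mirna_id = "miRNA", gene_id = "Target_Gene",
                      transcript_id = "Target_Transcript", chrom = "Chromosome",
                      start = "Start", end = "End", strand = "Strand",
                      region = "Region", evidence = "Support_Type",
                      source_db = "Source"),
  tarbase_like = c(mirna_id = "mirna", gene_id = "geneName",
                   transcript_id = "transcript", chrom = "chromosome",
                   start = "start", end = "end", strand = "strand",
                   region = "region", evidence = "method",
                   source_db = "source")
)

.norm_evidence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[grepl("weak", x)] <- "weak"
  out[grepl("strong|functional mti$|^strong$", x) & !grepl("weak", x)] <- "strong"
  out[grepl("direct", x)] <- "direct"
  out[x %in% c("strong", "weak", "direct")] <- x[x %in% c("strong", "weak", "direct")]
  out
}

.norm_strand <- function(x) {
  x <- as.character(x)
  x[!x %in% c("+", "-")] <- "unknown"
  x
}

.norm_region <- function(x) {
  x <- toupper(gsub("['′]", "", as.character(x)))
  x[x %in% c("3UTR", "3-UTR", "3_UTR", "UTR3")] <- "3UTR"
  x[x %in% c("5UTR", "5-UTR", "5_UTR", "UTR5")] <- "5UTR"
  x[is.na(x) | x == ""] <- "3UTR"   # sources that omit region imply 3'UTR
  x[!x %in% c("3UTR", "5UTR", "CDS")] <- "unknown"
  x
}

#' Load a miRNA binding-site catalog
#'
#' Reads a tab-separated catalog of experimentally supported miRNA binding
#' sites and builds an indexed catalog object. Only sites annotated to the
#' 3'UTR enter the site-count index used by the coordinate-biogenesis
#' conditions; sites in other regions are retained for reporting.
#'
#' The generic dialect stores 0-based half-open coordinates; the
#' `mirtarbase_like` and `tarbase_like` dialects store 1-based inclusive
#' coordinates, converted at parse time. Rows without parseable genomic
#' positions are dropped and counted; rows with malformed (non-numeric or
#' inverted) coordinates are collected as row-level errors and reported via
#' a warning, never silently discarded.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect One of `"generic_tsv"`, `"mirtarbase_like"`,
#'   `"tarbase_like"`.
#' @param species Species tag carried on the catalog (e.g. `"mmu"`).
#' @param merge_overlaps Merge same-pair sites whose intervals overlap by at
#'   least one base on the same chromosome and strand into one site (the
#'   cross-database deduplication rule). Set `FALSE` to count raw rows.
#' @param min_evidence Optional evidence restriction: keep only sites whose
#'   evidence is in this character vector (levels: `strong`, `weak`,
#'   `direct`, `unknown`).
#' @return An object of class `cb_catalog`: a list with `sites` (data.frame
#'   of binding sites), `index` (data.frame `mirna_id`, `gene_id`,
#'   `n_sites` of merged 3'UTR sites), `species`, and `merge_overlaps`.
#'   Attributes `n_dropped` (rows without positions) and `row_errors`
#'   (malformed rows) record parse outcomes.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste(c("mirna_id","gene_id","transcript_id","chrom","start","end",
#'           "strand","region","evidence","source_db"), collapse = "\t"),
#'   "miR-X\tgeneA\t\tchr1\t100\t107\t+\t3UTR\tstrong\tdemo",
#'   "miR-X\tgeneA\t\tchr1\t200\t207\t+\t3UTR\tstrong\tdemo"), tsv)
#' cat <- load_catalog(tsv)
#' site_count(cat, "miR-X", "geneA")
#' @export
load_catalog <- function(path,
                         dialect = c("generic_tsv", "mirtarbase_like", "tarbase_like"),
                         species = "unknown",
                         merge_overlaps = TRUE,
                         min_evidence = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = c("NA", ""))
  if (dialect == "generic_tsv") {
    required <- setdiff(.catalog_cols, c("transcript_id", "region", "evidence", "source_db"))
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0)
      stop("catalog format error: missing required column(s): ",
           paste(missing, collapse = ", "))
    for (opt in setdiff(.catalog_cols, names(raw))) raw[[opt]] <- NA_character_
    df <- raw[, .catalog_cols]
    one_based <- FALSE
  } else {
    map <- .dialect_maps[[dialect]]
    required <- map[!names(map) %in% c("transcript_id", "region", "evidence", "source_db")]
    missing <- setdiff(unname(required), names(raw))
    if (length(missing) > 0)
      stop("catalog format error: missing required column(s): ",
           paste(missing, collapse = ", "))
    df <- data.frame(row.names = seq_len(nrow(raw)))
    for (std in names(map)) {
      src <- map[[std]]
      df[[std]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
    }
    one_based <- TRUE
  }

  n_in <- nrow(df)
  # rows lacking genomic positions are dropped (logged), per the
  # "had genomic binding positions listed" inclusion rule
  no_pos <- is.na(df$start) | is.na(df$end) | is.na(df$chrom)
  n_dropped <- sum(no_pos)
  df <- df[!no_pos, , drop = FALSE]

  start_num <- suppressWarnings(as.numeric(df$start))
  end_num <- suppressWarnings(as.numeric(df$end))
  bad <- is.na(start_num) | is.na(end_num)
  if (one_based) start_num <- start_num - 1  # to 0-based half-open
  bad <- bad | (!is.na(start_num) & !is.na(end_num) & start_num >= end_num)
  bad <- bad | is.na(df$mirna_id) | is.na(df$gene_id)
  row_errors <- data.frame(
    row = which(bad),
    mirna_id = df$mirna_id[bad],
    gene_id = df$gene_id[bad],
    start = df$start[bad],
    end = df$end[bad],
    stringsAsFactors = FALSE
  )
  if (nrow(row_errors) > 0)
    warning(sprintf("%d row(s) with unparseable or invalid coordinates were excluded; see attr(x, 'row_errors')",
                    nrow(row_errors)))
  df <- df[!bad, , drop = FALSE]
  df$start <- as.integer(start_num[!bad])
  df$end <- as.integer(end_num[!bad])
  df$strand <- .norm_strand(df$strand)
  df$region <- .norm_region(df$region)
  df$evidence <- .norm_evidence(df$evidence)
  df$source_db <- ifelse(is.na(df$source_db), dialect, df$source_db)
  df$transcript_id <- ifelse(is.na(df$transcript_id), "", df$transcript_id)
  rownames(df) <- NULL

  if (!is.null(min_evidence)) df <- df[df$evidence %in% min_evidence, , drop = FALSE]

  if (n_dropped > 0)
    message(sprintf("load_catalog: dropped %d of %d row(s) lacking genomic positions", n_dropped, n_in))

  cat <- new_catalog(df, species = species, merge_overlaps = merge_overlaps)
  attr(cat, "n_dropped") <- n_dropped
  attr(cat, "row_errors") <- row_errors
  cat
}

#' Construct a catalog from an in-memory site table
#'
#' @param sites data.frame with the generic-dialect columns (0-based
#'   half-open coordinates).
#' @param species Species tag.
#' @param merge_overlaps See [load_catalog()].
#' @return A `cb_catalog`.
#' @export
new_catalog <- function(sites, species = "unknown", merge_overlaps = TRUE) {
  stopifnot(all(c("mirna_id", "gene_id", "chrom", "start", "end") %in% names(sites)))
  for (opt in setdiff(.catalog_cols, names(sites))) {
    sites[[opt]] <- if (opt %in% c("strand", "region", "evidence")) "unknown" else ""
  }
  sites$region <- .norm_region(sites$region)
  if (nrow(sites) > 0 && any(sites$start >= sites$end))
    stop("invalid site interval: start must be < end (0-based half-open)")
  sites <- sites[, .catalog_cols]
  rownames(sites) <- NULL
  structure(
    list(sites = sites,
         index = .build_index(sites, merge_overlaps),
         species = species,
         merge_overlaps = merge_overlaps),
    class = "cb_catalog"
  )
}

# Merged-3'UTR-site index: the counts feeding the CB conditions. Sites on
# different transcripts of a gene are pooled to the gene before the
# interval union, so counts are gene-level.
.build_index <- function(sites, merge_overlaps = TRUE) {
  utr <- sites[sites$region == "3UTR", , drop = FALSE]
  if (nrow(utr) == 0) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  if (merge_overlaps) {
    key <- paste(utr$mirna_id, utr$gene_id, utr$chrom, utr$strand, sep = "\r")
    counts_by_key <- vapply(split(seq_len(nrow(utr)), key), function(idx) {
      ir <- IRanges::IRanges(start = utr$start[idx] + 1L, end = utr$end[idx])
      length(IRanges::reduce(ir))
    }, integer(1))
    parts <- do.call(rbind, strsplit(names(counts_by_key), "\r", fixed = TRUE))
    agg <- stats::aggregate(
      list(n_sites = as.integer(counts_by_key)),
      by = list(mirna_id = parts[, 1], gene_id = parts[, 2]),
      FUN = sum
    )
  } else {
    agg <- stats::aggregate(
      list(n_sites = rep(1L, nrow(utr))),
      by = list(mirna_id = utr$mirna_id, gene_id = utr$gene_id),
      FUN = sum
    )
  }
  agg <- agg[order(agg$mirna_id, agg$gene_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Merge two binding-site catalogs
#'
#' Pools the sites of two catalogs of the same species and re-derives the
#' merged-site index. Under the overlap-merge rule, two sites of the same
#' (miRNA, gene) pair overlapping by at least one base on the same
#' chromosome and strand collapse into one site spanning their union, so
#' duplicated records across source databases count once.
#'
#' @param a,b `cb_catalog` objects with matching species tags.
#' @return A merged `cb_catalog`.
#' @export
merge_catalogs <- function(a, b) {
  stopifnot(inherits(a, "cb_catalog"), inherits(b, "cb_catalog"))
  if (!identical(a$species, b$species))
    stop(sprintf("species mismatch: cannot merge '%s' catalog with '%s' catalog",
                 a$species, b$species))
  merge_overlaps <- a$merge_overlaps && b$merge_overlaps
  new_catalog(rbind(a$sites, b$sites), species = a$species,
              merge_overlaps = merge_overlaps)
}

#' Merged 3'UTR site count for a (miRNA, gene) pair
#'
#' @param catalog A `cb_catalog`.
#' @param mirna_id,gene_id Identifiers to query.
#' @return Non-negative integer; 0 for pairs absent from the 3'UTR index
#'   (including pairs whose only sites lie outside the 3'UTR).
#' @export
site_count <- function(catalog, mirna_id, gene_id) {
  stopifnot(inherits(catalog, "cb_catalog"))
  idx <- catalog$index
  hit <- idx$n_sites[idx$mirna_id == mirna_id & idx$gene_id == gene_id]
  if (length(hit) == 0) 0L else hit[[1]]
}

#' Write a catalog in the generic TSV dialect
#'
#' @param catalog A `cb_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "cb_catalog"))
  utils::write.table(catalog$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.cb_catalog <- function(x, ...) {
  cat(sprintf("cb_catalog [%s]: %d site(s), %d indexed 3'UTR pair(s), %d miRNA(s), %d gene(s)\n",
              x$species, nrow(x$sites), nrow(x$index),
              length(unique(x$index$mirna_id)), length(unique(x$index$gene_id))))
  invisible(x)
}
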