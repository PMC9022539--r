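#' Read a differential-expression table
#'
#' Expects a TSV with header `feature_id`, `log2fc`, `pvalue` and an
#' optional `padj` column. Fold changes are log2-scale.
#'
#' @param path TSV path.
#' @param use_padj Substitute the adjusted p-value column for `pvalue`
#'   when present.
#' @return data.frame with `feature_id`, `log2fc`, `pvalue`.
#' @export
read_expression <- function(path, use_padj = FALSE) {
  de <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(c("feature_id", "log2fc", "pvalue"), names(de))
  if (length(missing) > 0)
    stop("expression table missing column(s): ", paste(missing, collapse = ", "))
  if (use_padj) {
    if (!"padj" %in% names(de)) stop("use_padj = TRUE but no 'padj' column present")
    de$pvalue <- de$padj
  }
  .validate_de(de)
  de[, c("feature_id", "log2fc", "pvalue")]
}

.validate_de <- function(de) {
  if (any(!is.finite(de$log2fc)))
    stop("expression table contains non-finite log2fc values")
  if (any(is.na(de$pvalue) | de$pvalue < 0 | de$pvalue > 1))
    stop("expression table contains p-values outside [0, 1]")
  if (anyDuplicated(de$feature_id))
    stop("duplicate feature_id in expression table: ",
         paste(unique(de$feature_id[duplicated(de$feature_id)]), collapse = ", "))
  invisible(de)
}

#' Classify mRNA differential expression
#'
#' Symmetric linear-scale fold-change rule: a feature is `up` when its
#' linear fold change `2^log2fc` is at least `fc_threshold` and the
#' p-value passes, `down` when the fold change is at most
#' `1/fc_threshold` with a passing p-value, else `not_significant`.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param pvalue Numeric vector of p-values in \[0, 1\].
#' @param fc_threshold Linear fold-change threshold (> 1); default 1.5.
#' @param p_threshold P-value threshold; default 0.05.
#' @return Character vector with values `up`, `down`, `not_significant`.
#' @export
classify_mrna <- function(log2fc, pvalue, fc_threshold = 1.5, p_threshold = 0.05) {
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  .check_calls_input(log2fc, pvalue)
  lfc_cut <- log2(fc_threshold)
  sig <- pvalue <= p_threshold
  out <- rep("not_significant", length(log2fc))
  out[sig & log2fc >= lfc_cut] <- "up"
  out[sig & log2fc <= -lfc_cut] <- "down"
  out
}

#' Classify miRNA differential expression
#'
#' Sign rule: `up` when log fold change is positive with a passing
#' p-value, `down` when negative with a passing p-value, otherwise
#' `not_significant` (zero fold change is never significant).
#'
#' @inheritParams classify_mrna
#' @return Character vector with values `up`, `down`, `not_significant`.
#' @export
classify_mirna <- function(log2fc, pvalue, p_threshold = 0.05) {
  .check_calls_input(log2fc, pvalue)
  sig <- pvalue <= p_threshold
  out <- rep("not_significant", length(log2fc))
  out[sig & log2fc > 0] <- "up"
  out[sig & log2fc < 0] <- "down"
  out
}

.check_calls_input <- function(log2fc, pvalue) {
  if (length(log2fc) != length(pvalue)) stop("log2fc and pvalue lengths differ")
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  if (any(is.na(pvalue) | pvalue < 0 | pvalue > 1)) stop("pvalue must lie in [0, 1]")
  invisible(NULL)
}

.call_lookup <- function(features, de, classify) {
  out <- rep("unmeasured", length(features))
  hit <- match(features, de$feature_id)
  ok <- !is.na(hit)
  if (any(ok)) out[ok] <- classify(de$log2fc[hit[ok]], de$pvalue[hit[ok]])
  out
}

#' Contextualize triads with expression calls and confidence tiers
#'
#' Attaches up/down/not_significant/unmeasured calls for gene A, gene B,
#' the regulator, and the secondary miRNA to every triad, assigns a
#' confidence tier, and (in `down_down` mode) retains only triads
#' consistent with coordinated repression: both targets called down, the
#' secondary miRNA called up when a miRNA table is supplied, the regulator
#' assumed upregulated by study design when unmeasured. Triads whose
#' targets are unmeasured are dropped in `down_down` mode (conservative).
#'
#' Tiers: `high_confidence` when regulator and secondary are up with both
#' targets down, or the fully mirrored pattern; `low_confidence` when all
#' four features carry significant calls but not in the high-confidence
#' pattern; otherwise `unsupported`.
#'
#' @param triads data.frame from [enumerate_triads()].
#' @param mrna_de mRNA DE table (`feature_id`, `log2fc`, `pvalue`).
#' @param mirna_de Optional miRNA DE table in the same layout.
#' @param mode `"down_down"` (filtering) or `"full_pattern"` (annotate all
#'   triads with tiers, no filtering).
#' @param fc_threshold,p_threshold Thresholds passed to the classifiers.
#' @return Input triads with columns `call_gene_a`, `call_gene_b`,
#'   `call_regulator`, `call_secondary`, `tier` appended; in `down_down`
#'   mode only retained rows are returned.
#' @export
contextualize <- function(triads, mrna_de, mirna_de = NULL,
                          mode = c("down_down", "full_pattern"),
                          fc_threshold = 1.5, p_threshold = 0.05) {
  mode <- match.arg(mode)
  .validate_de(mrna_de)
  if (!is.null(mirna_de)) .validate_de(mirna_de)
  if (nrow(triads) == 0) {
    out <- triads
    out$call_gene_a <- character(0); out$call_gene_b <- character(0)
    out$call_regulator <- character(0); out$call_secondary <- character(0)
    out$tier <- character(0)
    return(out)
  }

  cls_m <- function(l, p) classify_mrna(l, p, fc_threshold, p_threshold)
  cls_mi <- function(l, p) classify_mirna(l, p, p_threshold)
  out <- triads
  out$call_gene_a <- .call_lookup(triads$gene_a, mrna_de, cls_m)
  out$call_gene_b <- .call_lookup(triads$gene_b, mrna_de, cls_m)
  if (is.null(mirna_de)) {
    out$call_regulator <- rep("unmeasured", nrow(out))
    out$call_secondary <- rep("unmeasured", nrow(out))
  } else {
    out$call_regulator <- .call_lookup(triads$regulator, mirna_de, cls_mi)
    out$call_secondary <- .call_lookup(triads$secondary, mirna_de, cls_mi)
  }

  if (mode == "down_down") {
    # the study design conditions on an upregulated CB regulator, so an
    # unmeasured regulator is assumed up rather than dropping the triad
    out$call_regulator[out$call_regulator == "unmeasured"] <- "up"
    keep <- out$call_gene_a == "down" & out$call_gene_b == "down"
    if (!is.null(mirna_de)) keep <- keep & out$call_secondary == "up"
    out <- out[keep, , drop = FALSE]
  }
  out$tier <- .assign_tier(out)
  rownames(out) <- NULL
  out
}

.assign_tier <- function(x) {
  if (nrow(x) == 0) return(character(0))
  sec <- x$call_secondary
  forward <- x$call_regulator == "up" & sec == "up" &
    x$call_gene_a == "down" & x$call_gene_b == "down"
  mirrored <- x$call_regulator == "down" & sec == "down" &
    x$call_gene_a == "up" & x$call_gene_b == "up"
  sig <- c("up", "down")
  all_sig <- x$call_regulator %in% sig & sec %in% sig &
    x$call_gene_a %in% sig & x$call_gene_b %in% sig
  out <- rep("unsupported", nrow(x))
  out[all_sig] <- "low_confidence"
  out[forward | mirrored] <- "high_confidence"
  out
}

#' Read a transcription-factor / regulatory edge list
#'
#' TSV with header `source_gene`, `target_gene` and optional `relation`.
#'
#' @param path TSV path.
#' @return data.frame `source_gene`, `target_gene`, `relation`.
#' @export
read_edges <- function(path) {
  e <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(c("source_gene", "target_gene"), names(e))
  if (length(missing) > 0)
    stop("edge table missing column(s): ", paste(missing, collapse = ", "))
  if (!"relation" %in% names(e)) e$relation <- "regulates"
  if (any(e$source_gene == e$target_gene))
    stop("regulatory edges must connect distinct genes")
  e[, c("source_gene", "target_gene", "relation")]
}

#' Exclude triads where gene A directly regulates gene B
#'
#' Removes triads with a known regulatory edge from gene A to gene B
#' (e.g. gene A is a transcription factor for gene B), so that the
#' expression change of the effector gene can be attributed to boosted
#' secondary-miRNA biogenesis rather than direct regulation. The filter is
#' directional by default.
#'
#' @param triads data.frame with `gene_a` and `gene_b` columns.
#' @param edges data.frame from [read_edges()] (or with the same columns).
#' @param bidirectional Also remove triads matched by an edge gene B ->
#'   gene A.
#' @return The retained triads; removal is the only modification.
#' @export
filter_direct_regulation <- function(triads, edges, bidirectional = FALSE) {
  if (nrow(triads) == 0 || is.null(edges) || nrow(edges) == 0) return(triads)
  hit <- paste(triads$gene_a, triads$gene_b) %in% paste(edges$source_gene, edges$target_gene)
  if (bidirectional)
    hit <- hit | paste(triads$gene_b, triads$gene_a) %in% paste(edges$source_gene, edges$target_gene)
  out <- triads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
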