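#' Signed linear fold change from log2 group means
#'
#' Converts a pair of log2 group means into the signed linear fold-change
#' convention used throughout: with r = 2^(numerator - denominator), the
#' result is r when r >= 1 and -1/r otherwise, so the magnitude is always
#' at least 1 and the sign encodes the direction of change. A ratio of
#' exactly 1 maps to +1.
#'
#' @param mean_log2_numerator,mean_log2_denominator Finite numeric vectors
#'   of log2 group means (recycled to common length).
#' @return Numeric vector of signed linear fold changes, |FC| >= 1.
#' @examples
#' signed_fold_change(4, 3)   # +2
#' signed_fold_change(3, 4)   # -2
#' signed_fold_change(3, 3)   # +1
#' @export
signed_fold_change <- function(mean_log2_numerator, mean_log2_denominator) {
  if (any(!is.finite(mean_log2_numerator)) ||
      any(!is.finite(mean_log2_denominator)))
    stop("log2 means must be finite")
  r <- 2 ^ (mean_log2_numerator - mean_log2_denominator)
  ifelse(r >= 1, r, -1 / r)
}

#' Row-wise Welch t-tests for a two-group comparison
#'
#' Vectorized Welch (unequal-variance) two-sided t-test across the rows of
#' a matrix. Rows where both groups are constant and equal get p = 1 by
#' convention so degenerate synthetic features flow through as
#' non-significant; constant-but-different rows get the smallest
#' representable positive p.
#'
#' @param values Numeric matrix (features x samples).
#' @param idx1,idx2 Column indices (or logical masks) of the two groups,
#'   each selecting at least 2 samples.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
row_welch_t <- function(values, idx1, idx2) {
  x <- values[, idx1, drop = FALSE]
  y <- values[, idx2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero pooled standard error: identical groups are null, distinct are
  # maximally significant (clamped into (0,1])
  zero <- se2 == 0
  if (any(zero)) p[zero] <- ifelse(m1[zero] == m2[zero], 1,
                                   .Machine$double.xmin)
  p <- pmin(p, 1)
  unname(p)
}

#' Two-group Welch t-test p-value
#'
#' Convenience scalar wrapper around [row_welch_t()] for two numeric
#' vectors; symmetric under group swap.
#'
#' @param values_group1,values_group2 Numeric vectors, length >= 2 each.
#' @return Two-sided p-value in (0, 1].
#' @export
two_group_t_test <- function(values_group1, values_group2) {
  if (length(values_group1) < 2L || length(values_group2) < 2L)
    stop("each group needs at least 2 values")
  m <- matrix(c(values_group1, values_group2), nrow = 1)
  row_welch_t(m, seq_along(values_group1),
              length(values_group1) + seq_along(values_group2))
}

#' Per-feature differential expression statistics
#'
#' Computes, for every feature of a two-group dataset, the group log2
#' means, the signed linear fold change (numerator over denominator) and
#' the Welch t-test p-value.
#'
#' @param dataset An [expression_dataset()].
#' @return A data.frame with columns `feature_id`, `mean_log2_numerator`,
#'   `mean_log2_denominator`, `signed_fold_change`, `p_value`.
#' @export
differential_expression <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  idx1 <- dataset$sample_groups == dataset$numerator
  idx2 <- dataset$sample_groups == dataset$denominator
  m1 <- rowMeans(dataset$values[, idx1, drop = FALSE])
  m2 <- rowMeans(dataset$values[, idx2, drop = FALSE])
  data.frame(
    feature_id = dataset$feature_ids,
    mean_log2_numerator = unname(m1),
    mean_log2_denominator = unname(m2),
    signed_fold_change = signed_fold_change(unname(m1), unname(m2)),
    p_value = row_welch_t(dataset$values, idx1, idx2),
    stringsAsFactors = FALSE)
}

#' Collapse probe-level results to gene level
#'
#' Maps probe identifiers to gene symbols and keeps, per gene, the probe
#' with the smallest p-value (ties: largest |fold change|, then
#' lexicographically smallest probe id). Probes absent from the mapping
#' are dropped.
#'
#' @param results Data.frame of per-probe statistics as returned by
#'   [differential_expression()].
#' @param probe_to_gene Named character vector, `names` = probe ids,
#'   values = gene ids; or a two-column data.frame (probe, gene).
#' @return Data.frame of the same shape keyed by normalized gene id, with
#'   an extra `probe_id` column recording the chosen representative.
#' @export
collapse_probes <- function(results, probe_to_gene) {
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2]]),
                                     as.character(probe_to_gene[[1]]))
  res <- results[results$feature_id %in% names(probe_to_gene), , drop = FALSE]
  if (nrow(res) == 0L) {
    out <- results[0, , drop = FALSE]
    out$probe_id <- character(0)
    return(out)
  }
  res$probe_id <- res$feature_id
  res$feature_id <- normalize_gene_ids(probe_to_gene[res$probe_id])
  ord <- order(res$feature_id, res$p_value, -abs(res$signed_fold_change),
               res$probe_id)
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(res$feature_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Canonical signature ordering: ascending p, ties by descending |FC|,
# then lexicographic gene id. Deterministic so the rank-based overlap
# scan downstream never depends on input order.
signature_order <- function(p_value, signed_fold_change, gene_id) {
  order(p_value, -abs(signed_fold_change), gene_id)
}

#' Build a differentially expressed gene signature
#'
#' Filters per-feature statistics to those passing strict fold-change and
#' p-value thresholds (|FC| > fc_threshold AND p < p_threshold, both
#' strict, matching the ">1.2" / "<0.05" selection convention of
#' commercial array analysis) and ranks them: ascending p-value, ties by
#' descending |FC|, then lexicographic gene id.
#'
#' @param dataset An [expression_dataset()], or a data.frame of
#'   per-feature statistics as returned by [differential_expression()]
#'   (e.g. after [collapse_probes()]).
#' @param fc_threshold Linear fold-change threshold, >= 1. Default 1.2;
#'   use 1.3 for comparisons where a tighter cut is wanted.
#' @param p_threshold Uncorrected p-value threshold in (0, 1]. Default 0.05.
#' @param name Signature name.
#' @param species Free-text species tag (e.g. "human", "mouse").
#' @return A `gene_signature`: list with `name`, `species`, `fc_threshold`,
#'   `p_threshold` and `entries`, a data.frame with columns `gene_id`,
#'   `direction` ("up"/"down"), `signed_fold_change`, `p_value`, `rank`.
#'   An empty signature (no feature passes) is legal.
#' @export
build_signature <- function(dataset, fc_threshold = 1.2, p_threshold = 0.05,
                            name = "signature", species = NA_character_) {
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]")
  de <- if (inherits(dataset, "expression_dataset"))
    differential_expression(dataset) else dataset
  stopifnot(all(c("feature_id", "signed_fold_change", "p_value") %in%
                  names(de)))
  keep <- abs(de$signed_fold_change) > fc_threshold &
    de$p_value < p_threshold
  de <- de[keep, , drop = FALSE]
  gene_id <- normalize_gene_ids(de$feature_id)
  if (anyDuplicated(gene_id))
    stop("duplicated gene ids in signature input: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         " (collapse probes first)")
  entries <- data.frame(
    gene_id = gene_id,
    direction = ifelse(de$signed_fold_change > 0, "up", "down"),
    signed_fold_change = de$signed_fold_change,
    p_value = de$p_value,
    stringsAsFactors = FALSE)
  gene_signature(entries, name = name, species = species,
                 fc_threshold = fc_threshold, p_threshold = p_threshold)
}

#' Construct a gene signature from an entry table
#'
#' Low-level constructor: validates entries, applies the canonical
#' ordering and assigns 1-based ranks.
#'
#' @param entries Data.frame with columns `gene_id`, `direction`,
#'   `signed_fold_change`, `p_value`.
#' @param name,species,fc_threshold,p_threshold Metadata carried on the
#'   object.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(entries, name = "signature",
                           species = NA_character_,
                           fc_threshold = NA_real_, p_threshold = NA_real_) {
  need <- c("gene_id", "direction", "signed_fold_change", "p_value")
  stopifnot(is.data.frame(entries), all(need %in% names(entries)))
  entries <- entries[, need, drop = FALSE]
  entries$gene_id <- normalize_gene_ids(entries$gene_id)
  if (anyDuplicated(entries$gene_id))
    stop("gene ids must be unique within a signature")
  if (!all(entries$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  bad <- (entries$direction == "up") != (entries$signed_fold_change > 0)
  if (any(bad))
    stop("direction inconsistent with fold-change sign for: ",
         paste(entries$gene_id[bad], collapse = ", "))
  ord <- signature_order(entries$p_value, entries$signed_fold_change,
                         entries$gene_id)
  entries <- entries[ord, , drop = FALSE]
  entries$rank <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  structure(list(name = name, species = species, entries = entries,
                 fc_threshold = fc_threshold, p_threshold = p_threshold),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", nrow(x$entries), " genes (",
      sum(x$entries$direction == "up"), " up, ",
      sum(x$entries$direction == "down"), " down)\n", sep = "")
  if (!is.na(x$fc_threshold))
    cat("  thresholds: |FC| > ", x$fc_threshold, ", p < ", x$p_threshold,
        "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) nrow(x$entries)

signature_genes <- function(sig) sig$entries$gene_id
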