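#' Two-group expression dataset
#'
#' Container for a log2-scale expression matrix together with a two-group
#' sample design and the orientation of the comparison. The numerator group
#' plays the role of "infant" (developmental comparisons) or "patient"
#' (disease comparisons); the denominator group is the adult / control
#' reference, so a positive fold change always means "higher in the
#' infant/patient group".
#'
#' @param values Numeric matrix of log2 expression intensities,
#'   features in rows, samples in columns. Column names must be sample ids.
#' @param feature_ids Character vector of unique, non-empty feature
#'   (probe or gene) identifiers, one per matrix row. Defaults to the
#'   matrix rownames.
#' @param sample_groups Named character vector (or two-column data.frame
#'   with columns `sample_id`, `group`) assigning every sample to exactly
#'   one of two group labels.
#' @param numerator,denominator The two group labels, in the orientation
#'   used for fold changes (numerator / denominator).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `feature_ids`, `sample_groups` (named character vector),
#'   `numerator`, `denominator`.
#' @examples
#' m <- matrix(rnorm(20, 7), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' grp <- setNames(c("infant", "infant", "adult", "adult"), colnames(m))
#' expression_dataset(m, sample_groups = grp,
#'                    numerator = "infant", denominator = "adult")
#' @export
expression_dataset <- function(values, feature_ids = rownames(values),
                               sample_groups, numerator, denominator) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.data.frame(sample_groups)) {
    if (!all(c("sample_id", "group") %in% names(sample_groups)))
      stop("sample_groups data.frame needs columns `sample_id` and `group`")
    sample_groups <- stats::setNames(as.character(sample_groups$group),
                                     as.character(sample_groups$sample_id))
  }
  if (is.null(feature_ids))
    stop("feature ids are required (rownames or `feature_ids`)")
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) must equal nrow(values)")
  if (anyDuplicated(feature_ids))
    stop("duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (any(!nzchar(feature_ids)))
    stop("feature ids must be non-empty strings")
  if (any(!is.finite(values)))
    stop("all expression values must be finite")

  if (is.null(colnames(values)))
    stop("`values` must have sample ids as column names")
  samples <- colnames(values)
  if (!all(samples %in% names(sample_groups)))
    stop("samples without a group label: ",
         paste(setdiff(samples, names(sample_groups)), collapse = ", "))
  sample_groups <- sample_groups[samples]

  labels <- unique(sample_groups)
  if (length(labels) != 2L)
    stop("exactly two group labels required, got: ",
         paste(labels, collapse = ", "))
  if (missing(numerator) || missing(denominator))
    stop("`numerator` and `denominator` group roles must be given")
  if (!numerator %in% labels || !denominator %in% labels ||
      numerator == denominator)
    stop("`numerator`/`denominator` must name the two distinct group labels")
  if (any(table(sample_groups) < 2L))
    stop("each group needs at least 2 samples")

  rownames(values) <- feature_ids
  structure(
    list(values = values, feature_ids = feature_ids,
         sample_groups = sample_groups,
         numerator = numerator, denominator = denominator),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$sample_groups)
  cat("expression_dataset: ", length(x$feature_ids), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  comparison: ", x$numerator, " (n=", tab[[x$numerator]], ") vs ",
      x$denominator, " (n=", tab[[x$denominator]], ")\n", sep = "")
  invisible(x)
}

#' Normalize gene identifiers
#'
#' Uppercases and strips surrounding whitespace so that identifiers join
#' reliably across datasets and orthologue tables.
#'
#' @param ids Character vector of gene or probe identifiers.
#' @return Normalized character vector.
#' @export
normalize_gene_ids <- function(ids) {
  toupper(trimws(as.character(ids)))
}
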