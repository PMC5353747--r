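#' Concordant bioset from a directional overlap
#'
#' Collects the genes changed in the same direction in both compared
#' signatures — the union of the (up, up) and (down, down) overlap sets —
#' with the shared direction recorded per gene. This is the "positively
#' correlated" gene set that downstream cell-type contribution analysis
#' partitions.
#'
#' @param directional A `directional_overlap` from
#'   [directional_decomposition()].
#' @param name Bioset name.
#' @param sources Optional character vector naming the two source
#'   comparisons.
#' @return A `concordant_bioset`: list with `name`, `sources` and
#'   `members`, a data.frame with columns `gene_id`, `direction`. An
#'   empty bioset is legal.
#' @export
derive_concordant_bioset <- function(directional, name = "bioset",
                                     sources = character(0)) {
  stopifnot(inherits(directional, "directional_overlap"))
  up <- directional$pairs$up_up$overlap_gene_ids
  down <- directional$pairs$down_down$overlap_gene_ids
  members <- data.frame(
    gene_id = c(up, down),
    direction = rep(c("up", "down"), c(length(up), length(down))),
    stringsAsFactors = FALSE)
  members <- members[order(members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(name = name, sources = sources, members = members),
            class = "concordant_bioset")
}

#' Construct a concordant bioset directly
#'
#' @param gene_id,direction Equal-length vectors of member genes and
#'   their shared direction ("up"/"down").
#' @param name,sources As in [derive_concordant_bioset()].
#' @return A `concordant_bioset`.
#' @export
concordant_bioset <- function(gene_id, direction, name = "bioset",
                              sources = character(0)) {
  gene_id <- normalize_gene_ids(gene_id)
  stopifnot(length(gene_id) == length(direction),
            all(direction %in% c("up", "down")),
            !anyDuplicated(gene_id))
  members <- data.frame(gene_id = gene_id, direction = direction,
                        stringsAsFactors = FALSE)
  members <- members[order(members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(name = name, sources = sources, members = members),
            class = "concordant_bioset")
}

#' @export
print.concordant_bioset <- function(x, ...) {
  cat("concordant_bioset '", x$name, "': ", nrow(x$members), " genes (",
      sum(x$members$direction == "up"), " up, ",
      sum(x$members$direction == "down"), " down)\n", sep = "")
  invisible(x)
}

#' @export
length.concordant_bioset <- function(x) nrow(x$members)

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (0.05 -> 0.1 at one decimal),
#' the convention used for reported contribution percentages; base R's
#' `round()` rounds halves to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Contribution percentage of a region or marginal count
#'
#' @param count Region or marginal gene count, `0 <= count <= bioset_size`.
#' @param bioset_size Total bioset size, > 0.
#' @return `100 * count / bioset_size`, rounded half-up to one decimal.
#' @examples
#' contribution_percentage(44, 141)  # 31.2
#' contribution_percentage(56, 231)  # 24.2
#' @export
contribution_percentage <- function(count, bioset_size) {
  if (any(bioset_size == 0)) stop("bioset_size must be > 0")
  if (any(count < 0) || any(count > bioset_size))
    stop("need 0 <= count <= bioset_size")
  round_half_up(100 * count / bioset_size, 1)
}

# gene ids of a directed set given as gene_signature, concordant_bioset,
# data.frame or character vector
directed_set_genes <- function(x) {
  if (inherits(x, "gene_signature")) return(signature_genes(x))
  if (inherits(x, "concordant_bioset")) return(x$members$gene_id)
  if (is.data.frame(x)) return(normalize_gene_ids(x$gene_id))
  normalize_gene_ids(x)
}

directed_set_directions <- function(x) {
  if (inherits(x, "gene_signature"))
    return(stats::setNames(x$entries$direction, x$entries$gene_id))
  if (inherits(x, "concordant_bioset"))
    return(stats::setNames(x$members$direction, x$members$gene_id))
  if (is.data.frame(x))
    return(stats::setNames(x$direction, normalize_gene_ids(x$gene_id)))
  stop("no direction information available")
}

#' Partition a bioset across three cell-type gene sets
#'
#' Assigns every bioset gene to exactly one of the 8 membership regions
#' of a three-set Venn diagram (the 7 intersection regions plus the
#' none-region) and reports region counts, per-set marginal counts, and
#' each region's percentage of the bioset size. Region names use the set
#' labels joined by "&"; genes in no set fall in region `"none"`. A gene
#' "specific to" one set is one in exactly one of the three sets.
#'
#' @param bioset A `concordant_bioset` (or character vector of gene ids).
#' @param set1,set2,set3 The three cell-type gene sets: `gene_signature`s,
#'   data.frames with a `gene_id` column, or character vectors. Ids must
#'   share the bioset's id space.
#' @param labels Character vector of length 3 naming the sets (default
#'   `c("FS", "AS", "OL")` for fast-spiking neurons, astrocytes,
#'   oligodendrocytes).
#' @return A `venn_partition`: list with `labels`, `bioset_size`,
#'   `regions` (named integer vector over the 8 regions), `marginals`
#'   (named integer vector, one per set), `percentages` (per-region, of
#'   bioset size), `marginal_percentages`, and `assignment` (data.frame
#'   gene_id / region).
#' @export
venn_partition <- function(bioset, set1, set2, set3,
                           labels = c("FS", "AS", "OL")) {
  stopifnot(length(labels) == 3, !anyDuplicated(labels))
  genes <- directed_set_genes(bioset)
  sets <- lapply(list(set1, set2, set3), directed_set_genes)
  inset <- vapply(sets, function(s) genes %in% s,
                  logical(length(genes)))
  if (length(genes) == 0L)
    inset <- matrix(logical(0), ncol = 3)

  region_name <- apply(inset, 1, function(b) {
    if (!any(b)) "none" else paste(labels[b], collapse = "&")
  })
  if (length(genes) == 0L) region_name <- character(0)

  all_regions <- c(labels,
                   paste(labels[1], labels[2], sep = "&"),
                   paste(labels[1], labels[3], sep = "&"),
                   paste(labels[2], labels[3], sep = "&"),
                   paste(labels, collapse = "&"),
                   "none")
  regions <- stats::setNames(integer(length(all_regions)), all_regions)
  tab <- table(region_name)
  regions[names(tab)] <- as.integer(tab)

  marginals <- stats::setNames(colSums(inset), labels)
  size <- length(genes)
  pct <- if (size > 0) contribution_percentage(regions, size) else
    stats::setNames(rep(NA_real_, length(regions)), names(regions))
  mpct <- if (size > 0) contribution_percentage(marginals, size) else
    stats::setNames(rep(NA_real_, 3), labels)

  structure(list(labels = labels, bioset_size = size,
                 regions = regions,
                 marginals = as.integer(marginals) |>
                   stats::setNames(labels),
                 percentages = pct, marginal_percentages = mpct,
                 assignment = data.frame(gene_id = genes,
                                         region = region_name,
                                         stringsAsFactors = FALSE)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition of ", x$bioset_size, " genes across ",
      paste(x$labels, collapse = "/"), ":\n", sep = "")
  for (nm in names(x$regions))
    cat(sprintf("  %-12s %4d (%s%%)\n", nm, x$regions[[nm]],
                format(x$percentages[[nm]])))
  cat("  marginals:", paste(sprintf("%s = %d (%s%%)", x$labels,
                                    x$marginals, x$marginal_percentages),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Direction concordance between a bioset and a cell-type signature
#'
#' Counts the genes shared between a concordant bioset and a directed
#' cell-type developmental signature, and how many of them change in the
#' same direction in both.
#'
#' @param bioset A `concordant_bioset`.
#' @param celltype_signature A `gene_signature` (or data.frame with
#'   `gene_id` and `direction` columns) in the same id space.
#' @return List with `n_shared` and `n_same_direction`
#'   (`n_same_direction <= n_shared`).
#' @export
direction_concordance <- function(bioset, celltype_signature) {
  bdir <- directed_set_directions(bioset)
  sdir <- directed_set_directions(celltype_signature)
  shared <- intersect(names(bdir), names(sdir))
  list(n_shared = length(shared),
       n_same_direction = sum(bdir[shared] == sdir[shared]))
}
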