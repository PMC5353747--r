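#' Orthologue table
#'
#' A (possibly many-to-many) relation between gene identifiers of two
#' species. Ids are normalized and duplicate pairs removed.
#'
#' @param gene_a,gene_b Character vectors of equal length: orthologous
#'   pairs, species A id in `gene_a`, species B id in `gene_b`.
#' @return An `ortholog_table`: data.frame with columns `gene_a`, `gene_b`.
#' @export
ortholog_table <- function(gene_a, gene_b) {
  if (length(gene_a) != length(gene_b))
    stop("gene_a and gene_b must have equal length")
  tab <- data.frame(gene_a = normalize_gene_ids(gene_a),
                    gene_b = normalize_gene_ids(gene_b),
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  rownames(tab) <- NULL
  class(tab) <- c("ortholog_table", "data.frame")
  tab
}

#' Map a gene signature across species
#'
#' Translates every signature gene through the orthologue table. A source
#' gene with several orthologues contributes all of them (each inheriting
#' the source fold change and p-value); when two source genes collide on
#' one target, the entry with the smallest p-value wins (ties broken by
#' the canonical signature ordering). Genes with no orthologue are
#' dropped, and the output is re-ranked.
#'
#' @param signature A `gene_signature`.
#' @param table An [ortholog_table()].
#' @param direction `"a_to_b"` (map `gene_a` ids to `gene_b`) or
#'   `"b_to_a"`.
#' @return A `gene_signature` in the target species' id space (possibly
#'   empty).
#' @export
map_signature <- function(signature, table, direction = c("a_to_b", "b_to_a")) {
  stopifnot(inherits(signature, "gene_signature"))
  direction <- match.arg(direction)
  if (nrow(table) == 0L) stop("orthologue table is empty")
  src <- if (direction == "a_to_b") table$gene_a else table$gene_b
  dst <- if (direction == "a_to_b") table$gene_b else table$gene_a

  ent <- signature$entries
  hit <- match(src, ent$gene_id)
  keep <- !is.na(hit)
  mapped <- ent[hit[keep], , drop = FALSE]
  mapped$gene_id <- dst[keep]
  # many-to-one collisions: minimum p wins (then |FC|, then id via the
  # canonical ordering)
  ord <- signature_order(mapped$p_value, mapped$signed_fold_change,
                         mapped$gene_id)
  mapped <- mapped[ord, , drop = FALSE]
  mapped <- mapped[!duplicated(mapped$gene_id), , drop = FALSE]
  mapped$rank <- NULL
  gene_signature(mapped,
                 name = paste0(signature$name, "_mapped"),
                 species = paste0("mapped_", direction),
                 fc_threshold = signature$fc_threshold,
                 p_threshold = signature$p_threshold)
}

#' Background gene universe for overlap tests
#'
#' The population of every hypergeometric overlap test: genes measured on
#' platform A that have at least one orthologue measured on platform B,
#' expressed in A's id space (`mode = "intersection"`, the default).
#' `mode = "union"` instead takes all platform-A genes with any
#' orthologue plus the A-side ids of orthologues of platform-B genes.
#'
#' @param platform_a_genes,platform_b_genes Character vectors of the gene
#'   ids measured on each platform.
#' @param table An [ortholog_table()] (`gene_a` = platform A's species).
#'   For a same-species comparison pass an identity table.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return A `universe` object: list with `members` (character vector)
#'   and `size`.
#' @export
build_universe <- function(platform_a_genes, platform_b_genes, table,
                           mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  a <- normalize_gene_ids(platform_a_genes)
  b <- normalize_gene_ids(platform_b_genes)
  a_with_measured_ortholog <-
    unique(table$gene_a[table$gene_b %in% b & table$gene_a %in% a])
  members <- if (mode == "intersection") {
    a_with_measured_ortholog
  } else {
    union(unique(table$gene_a[table$gene_a %in% a]),
          unique(table$gene_a[table$gene_b %in% b]))
  }
  if (length(members) == 0L)
    stop("empty gene universe: overlap tests are undefined")
  structure(list(members = sort(members), size = length(members)),
            class = "universe")
}

#' Fixed-size gene universe
#'
#' Constructs a universe directly from a membership set, for workflows
#' where the background is known (e.g. synthetic data where all genes are
#' measured on both platforms).
#'
#' @param members Character vector of gene ids.
#' @return A `universe` object.
#' @export
universe_from_members <- function(members) {
  members <- unique(normalize_gene_ids(members))
  if (length(members) == 0L) stop("empty gene universe")
  structure(list(members = sort(members), size = length(members)),
            class = "universe")
}

#' @export
print.universe <- function(x, ...) {
  cat("gene universe: N =", x$size, "\n")
  invisible(x)
}
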