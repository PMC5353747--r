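#' Upper tail of the hypergeometric overlap distribution
#'
#' Exact probability P(X >= k) that two sets of sizes `n1` and `n2`,
#' drawn without replacement from a universe of `N` genes, share at
#' least `k` members. This is the one-sided Fisher enrichment tail that
#' the running Fisher scan evaluates at every ranked prefix.
#'
#' @param k Observed overlap count.
#' @param n1,n2 Set sizes.
#' @param N Universe (background) size.
#' @return Tail probability in (0, 1].
#' @examples
#' hypergeometric_tail(1, 1, 1, 2)   # 0.5
#' hypergeometric_tail(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeometric_tail <- function(k, n1, n2, N) {
  if (any(c(k, n1, n2, N) < 0) || n1 > N || n2 > N || k > min(n1, n2))
    stop("inconsistent counts: need 0 <= k <= min(n1, n2) <= N")
  if (k <= max(0, n1 + n2 - N)) return(1)
  p <- stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Cutoff schemes for the running Fisher scan
#'
#' Builds the list of matched prefix-length pairs scanned by
#' [running_fisher()]. `"deciles"` takes 10 matched fractional cutoffs at
#' the deciles of the shorter signature (every rank when the shorter
#' signature has fewer than 10 entries); `"per-rank"` scans every rank of
#' the shorter signature.
#'
#' @param n_query,n_reference Signature sizes (after restriction to the
#'   universe).
#' @param scheme `"deciles"` or `"per-rank"`.
#' @return Integer matrix with columns `c_query`, `c_reference`, one row
#'   per cutoff pair; zero rows when either signature is empty.
#' @export
cutoff_pairs <- function(n_query, n_reference,
                         scheme = c("deciles", "per-rank")) {
  scheme <- match.arg(scheme)
  shorter <- min(n_query, n_reference)
  if (shorter == 0L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("c_query", "c_reference"))))
  n_cut <- if (scheme == "per-rank" || shorter < 10L) shorter else 10L
  fractions <- seq_len(n_cut) / n_cut
  cbind(c_query = as.integer(ceiling(fractions * n_query)),
        c_reference = as.integer(ceiling(fractions * n_reference)))
}

#' Running Fisher overlap test between two ranked signatures
#'
#' Rank-based overlap statistic between two gene signatures over a common
#' background universe: at each matched prefix cutoff pair the one-sided
#' hypergeometric enrichment tail of the prefix overlap is computed; the
#' smallest tail over the scan is Bonferroni-corrected by the number of
#' cutoffs scanned (capped at 1) to give the reported p-value. Overlap
#' counts and gene lists are reported at full signature length.
#'
#' @param query,reference `gene_signature` objects, ranked (as produced
#'   by [build_signature()] / [gene_signature()]).
#' @param universe A `universe` object; every signature gene must be a
#'   member.
#' @param cutoff_scheme `"deciles"` (default) or `"per-rank"`; see
#'   [cutoff_pairs()].
#' @return An `overlap_result`: list with `n_query`, `n_reference`,
#'   `n_overlap`, `universe_size`, `p_raw_best`, `n_cutoffs_scanned`,
#'   `p_final`, `overlap_gene_ids`, `cutoff_scheme`. Empty signatures are
#'   degenerate, not an error: `p_final = 1`, `n_overlap = 0`.
#' @export
running_fisher <- function(query, reference, universe,
                           cutoff_scheme = c("deciles", "per-rank")) {
  stopifnot(inherits(query, "gene_signature"),
            inherits(reference, "gene_signature"),
            inherits(universe, "universe"))
  cutoff_scheme <- match.arg(cutoff_scheme)
  qg <- signature_genes(query)
  rg <- signature_genes(reference)
  outside <- setdiff(c(qg, rg), universe$members)
  if (length(outside))
    stop("signature genes outside the universe (id spaces mismatched?): ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ...")

  overlap_genes <- intersect(qg, rg)
  res <- list(n_query = length(qg), n_reference = length(rg),
              n_overlap = length(overlap_genes),
              universe_size = universe$size,
              overlap_gene_ids = sort(overlap_genes),
              cutoff_scheme = cutoff_scheme)

  cuts <- cutoff_pairs(length(qg), length(rg), cutoff_scheme)
  if (nrow(cuts) == 0L) {
    res$p_raw_best <- 1
    res$n_cutoffs_scanned <- 0L
    res$p_final <- 1
    return(structure(res, class = "overlap_result"))
  }
  # prefix overlap at cutoff (c_q, c_r): genes in the top c_q of the
  # query whose reference rank is <= c_r
  ref_rank_of_query <- match(qg, rg)  # NA when absent from reference
  tails <- vapply(seq_len(nrow(cuts)), function(i) {
    c_q <- cuts[i, "c_query"]; c_r <- cuts[i, "c_reference"]
    k <- sum(ref_rank_of_query[seq_len(c_q)] <= c_r, na.rm = TRUE)
    hypergeometric_tail(k, c_q, c_r, universe$size)
  }, numeric(1))
  res$p_raw_best <- min(tails)
  res$n_cutoffs_scanned <- nrow(cuts)
  res$p_final <- min(1, res$p_raw_best * nrow(cuts))
  structure(res, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("running Fisher overlap: ", x$n_overlap, " shared genes (",
      x$n_query, " vs ", x$n_reference, ", N = ", x$universe_size, ")\n",
      "  p = ", format(x$p_final, digits = 3), " (best raw tail ",
      format(x$p_raw_best, digits = 3), " over ", x$n_cutoffs_scanned,
      " cutoffs, ", x$cutoff_scheme, ")\n", sep = "")
  invisible(x)
}

# restrict a signature to one direction, preserving relative order
restrict_direction <- function(signature, direction) {
  ent <- signature$entries[signature$entries$direction == direction, ,
                           drop = FALSE]
  ent$rank <- NULL
  gene_signature(ent,
                 name = paste0(signature$name, "_", direction),
                 species = signature$species,
                 fc_threshold = signature$fc_threshold,
                 p_threshold = signature$p_threshold)
}

#' Directional decomposition of a signature overlap
#'
#' Splits the overlap of two signatures into the four direction pairs —
#' (up, up), (down, down), (up, down), (down, up) — and runs a separate
#' running Fisher test for each pair against the full universe. The four
#' gene sets are disjoint and their counts sum to the undirected overlap.
#' The per-pair significance threshold is Bonferroni-corrected for the
#' four possible direction situations (alpha / 4).
#'
#' @inheritParams running_fisher
#' @param alpha Family-wise level for the directional threshold
#'   (default 0.05, giving the 0.05 / 4 = 0.0125 per-pair threshold).
#' @return A `directional_overlap`: list with `pairs` (named list of four
#'   `overlap_result`s keyed `"up_up"`, `"down_down"`, `"up_down"`,
#'   `"down_up"`), `counts` (named integer vector), `threshold`
#'   (alpha / 4), `n_overlap_total`.
#' @export
directional_decomposition <- function(query, reference, universe,
                                      cutoff_scheme = c("deciles", "per-rank"),
                                      alpha = 0.05) {
  cutoff_scheme <- match.arg(cutoff_scheme)
  combos <- list(up_up = c("up", "up"), down_down = c("down", "down"),
                 up_down = c("up", "down"), down_up = c("down", "up"))
  pairs <- lapply(combos, function(d)
    running_fisher(restrict_direction(query, d[1]),
                   restrict_direction(reference, d[2]),
                   universe, cutoff_scheme))
  counts <- vapply(pairs, function(p) p$n_overlap, integer(1))
  parent <- running_fisher(query, reference, universe, cutoff_scheme)
  structure(list(pairs = pairs, counts = counts,
                 threshold = bonferroni_threshold(alpha, 4L),
                 n_overlap_total = parent$n_overlap,
                 parent = parent),
            class = "directional_overlap")
}

#' @export
print.directional_overlap <- function(x, ...) {
  cat("directional overlap (", x$n_overlap_total, " shared genes):\n",
      sep = "")
  for (nm in names(x$pairs))
    cat(sprintf("  %-10s n = %3d  p = %s\n", nm, x$counts[[nm]],
                format(x$pairs[[nm]]$p_final, digits = 3)))
  cat("  directional threshold:", x$threshold, "\n")
  invisible(x)
}

#' Bonferroni per-comparison threshold
#'
#' @param alpha Family-wise significance level in (0, 1].
#' @param m Number of comparisons, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 4)  # 0.0125
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Classify the direction of a signature correlation
#'
#' Labels a directional overlap as a positive correlation when more
#' shared genes change in the same direction — (up,up) + (down,down) —
#' than in opposite directions, negative when reversed, and mixed on a
#' tie.
#'
#' @param directional A `directional_overlap`, or a named numeric vector
#'   of the four counts (`up_up`, `down_down`, `up_down`, `down_up`).
#' @return List with `label` ("positive"/"negative"/"mixed"),
#'   `n_concordant`, `n_discordant`.
#' @export
classify_correlation <- function(directional) {
  counts <- if (inherits(directional, "directional_overlap"))
    directional$counts else directional
  stopifnot(all(c("up_up", "down_down", "up_down", "down_up") %in%
                  names(counts)))
  pos <- counts[["up_up"]] + counts[["down_down"]]
  neg <- counts[["up_down"]] + counts[["down_up"]]
  label <- if (pos > neg) "positive" else if (neg > pos) "negative"
  else "mixed"
  list(label = label, n_concordant = pos, n_discordant = neg)
}
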