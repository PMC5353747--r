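# Independent oracles and fixture builders used across the suite.

# Hypergeometric upper tail by direct summation of the counting formula
# (binomial coefficients only; independent of phyper).
oracle_hyper_tail <- function(k, n1, n2, N) {
  lo <- max(k, max(0, n1 + n2 - N))
  hi <- min(n1, n2)
  if (lo > hi) return(0)
  sum(choose(n1, lo:hi) * choose(N - n1, n2 - (lo:hi))) / choose(N, n2)
}

# Same tail by exhaustive enumeration of every possible draw of n2
# elements from a universe of N containing a fixed set of n1 (grounds
# the counting formula itself; only feasible for small N).
enum_hyper_tail <- function(k, n1, n2, N) {
  if (n2 == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n2)
  overlaps <- colSums(draws <= n1)
  mean(overlaps >= k)
}

# A ranked signature of n genes sampled from a universe, with random
# directions and p-values (uses the current RNG stream).
random_signature <- function(universe_genes, n, name = "sig") {
  genes <- sample(universe_genes, n)
  dirs <- sample(c("up", "down"), n, replace = TRUE)
  gene_signature(data.frame(
    gene_id = genes, direction = dirs,
    signed_fold_change = ifelse(dirs == "up", 1, -1) *
      stats::runif(n, 1.3, 4),
    p_value = stats::runif(n, 1e-10, 0.05),
    stringsAsFactors = FALSE), name = name)
}

# Brute-force directional overlap counts by plain set arithmetic.
brute_directional_counts <- function(query, reference) {
  qd <- stats::setNames(query$entries$direction, query$entries$gene_id)
  rd <- stats::setNames(reference$entries$direction,
                        reference$entries$gene_id)
  shared <- intersect(names(qd), names(rd))
  c(up_up = sum(qd[shared] == "up" & rd[shared] == "up"),
    down_down = sum(qd[shared] == "down" & rd[shared] == "down"),
    up_down = sum(qd[shared] == "up" & rd[shared] == "down"),
    down_up = sum(qd[shared] == "down" & rd[shared] == "up"))
}

# Brute-force 3-set Venn region tally from per-gene membership bits.
brute_venn_counts <- function(genes, s1, s2, s3, labels) {
  pattern <- vapply(genes, function(g) {
    b <- c(g %in% s1, g %in% s2, g %in% s3)
    if (!any(b)) "none" else paste(labels[b], collapse = "&")
  }, character(1))
  table(pattern)
}

# Small two-group dataset with optional per-feature numerator shifts.
make_dataset <- function(n_genes = 50, n_per_group = 4, shifts = 0,
                         sd = 0.5) {
  ids <- sprintf("T%03d", seq_len(n_genes))
  vals <- matrix(stats::rnorm(n_genes * 2 * n_per_group, 7, sd),
                 nrow = n_genes)
  vals[, seq_len(n_per_group)] <- vals[, seq_len(n_per_group)] + shifts
  colnames(vals) <- sprintf("s%02d", seq_len(2 * n_per_group))
  rownames(vals) <- ids
  grp <- stats::setNames(rep(c("patient", "control"), each = n_per_group),
                         colnames(vals))
  expression_dataset(vals, sample_groups = grp,
                     numerator = "patient", denominator = "control")
}

# Gene sets realising exact 3-set Venn region counts, for checking that
# marginals recompute from region counts. `regions` is a length-7 vector
# in the order: only1, only2, only3, 1&2, 1&3, 2&3, triple.
sets_from_region_counts <- function(regions, n_none = 0) {
  stopifnot(length(regions) == 7)
  total <- sum(regions) + n_none
  ids <- sprintf("V%04d", seq_len(total))
  grp <- rep(seq_len(8), c(regions, n_none))
  in1 <- grp %in% c(1, 4, 5, 7)
  in2 <- grp %in% c(2, 4, 6, 7)
  in3 <- grp %in% c(3, 5, 6, 7)
  list(bioset = ids, s1 = ids[in1], s2 = ids[in2], s3 = ids[in3])
}
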