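test_that("hypergeometric tail reproduces exact enumeration values", {
  expect_equal(hypergeometric_tail(1, 1, 1, 2), 0.5)
  expect_equal(hypergeometric_tail(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_tail(2, 3, 3, 6), 0.5)  # 10/20 draws
  expect_equal(hypergeometric_tail(0, 3, 3, 6), 1)
  expect_error(hypergeometric_tail(4, 3, 3, 6), "inconsistent")
  expect_error(hypergeometric_tail(1, 7, 3, 6), "inconsistent")
})

test_that("counting-formula oracle agrees with full draw enumeration", {
  # grounds the oracle used by the wider grid checks
  for (N in c(4, 6, 8)) for (n1 in 0:N) for (n2 in 0:N)
    for (k in 0:min(n1, n2))
      expect_equal(oracle_hyper_tail(k, n1, n2, N),
                   enum_hyper_tail(k, n1, n2, N), tolerance = 1e-12)
})

test_that("tail is non-increasing in k and 1 at the floor of the support", {
  set.seed(41)
  for (i in 1:50) {
    N <- sample(5:40, 1)
    n1 <- sample(0:N, 1); n2 <- sample(0:N, 1)
    ks <- max(0, n1 + n2 - N):min(n1, n2)
    tails <- vapply(ks, hypergeometric_tail, numeric(1), n1, n2, N)
    expect_true(all(diff(tails) <= 1e-14))
    expect_equal(tails[1], 1)
  }
})

test_that("cutoff schemes scan deciles or every rank of the shorter set", {
  d <- cutoff_pairs(100, 50, "deciles")
  expect_equal(nrow(d), 10)
  expect_equal(d[, "c_query"], as.integer(seq(10, 100, 10)))
  expect_equal(d[, "c_reference"], as.integer(seq(5, 50, 5)))
  # shorter signature under 10 entries: every rank
  s <- cutoff_pairs(20, 7, "deciles")
  expect_equal(nrow(s), 7)
  expect_equal(s[, "c_reference"], 1:7)
  pr <- cutoff_pairs(30, 12, "per-rank")
  expect_equal(nrow(pr), 12)
  expect_equal(nrow(cutoff_pairs(0, 5, "deciles")), 0)
})

test_that("running_fisher handles canonical cases", {
  genes <- sprintf("U%03d", 1:100)
  uni <- universe_from_members(genes)
  make_sig <- function(g) gene_signature(data.frame(
    gene_id = g, direction = rep("up", length(g)),
    signed_fold_change = rep(2, length(g)),
    p_value = seq_along(g) / 1000))

  # disjoint signatures: every cutoff tail is 1
  r0 <- running_fisher(make_sig(genes[1:10]), make_sig(genes[51:60]), uni)
  expect_equal(r0$p_final, 1)
  expect_equal(r0$n_overlap, 0)

  # identical 10-gene signatures over N = 100: best tail at full depth
  r1 <- running_fisher(make_sig(genes[1:10]), make_sig(genes[1:10]), uni)
  expect_equal(r1$n_cutoffs_scanned, 10)
  expect_equal(r1$p_raw_best, oracle_hyper_tail(10, 10, 10, 100),
               tolerance = 1e-12)
  expect_equal(r1$p_final, oracle_hyper_tail(10, 10, 10, 100) * 10,
               tolerance = 1e-12)
  expect_equal(r1$n_overlap, 10)

  # per-cutoff tails verified against the oracle over the whole scan
  set.seed(42)
  q <- random_signature(genes, 30); r <- random_signature(genes, 20)
  res <- running_fisher(q, r, uni)
  cuts <- cutoff_pairs(30, 20, "deciles")
  qg <- q$entries$gene_id; rg <- r$entries$gene_id
  tails <- vapply(seq_len(nrow(cuts)), function(i) {
    k <- length(intersect(qg[seq_len(cuts[i, 1])],
                          rg[seq_len(cuts[i, 2])]))
    oracle_hyper_tail(k, cuts[i, 1], cuts[i, 2], 100)
  }, numeric(1))
  expect_equal(res$p_raw_best, min(tails), tolerance = 1e-12)
  expect_equal(res$p_final, min(1, min(tails) * 10), tolerance = 1e-12)
  expect_equal(res$n_overlap, length(intersect(qg, rg)))

  # single shared gene, N = 2
  uni2 <- universe_from_members(c("A", "B"))
  r2 <- running_fisher(make_sig("A"), make_sig("A"), uni2)
  expect_equal(r2$p_raw_best, 0.5)
  expect_equal(r2$n_cutoffs_scanned, 1)
  expect_equal(r2$p_final, 0.5)

  # empty signature is degenerate, not an error
  r3 <- running_fisher(make_sig(character(0)), make_sig(genes[1:5]), uni)
  expect_equal(r3$p_final, 1)
  expect_equal(r3$n_overlap, 0)

  # genes outside the universe are a hard error
  expect_error(running_fisher(make_sig("ZZZ"), make_sig(genes[1:5]), uni),
               "outside the universe")
})

test_that("swapping query and reference preserves the overlap count", {
  genes <- sprintf("U%03d", 1:200)
  uni <- universe_from_members(genes)
  set.seed(43)
  for (i in 1:10) {
    q <- random_signature(genes, sample(10:60, 1))
    r <- random_signature(genes, sample(10:60, 1))
    a <- running_fisher(q, r, uni); b <- running_fisher(r, q, uni)
    expect_equal(a$n_overlap, b$n_overlap)
    expect_setequal(a$overlap_gene_ids, b$overlap_gene_ids)
  }
})

test_that("directional decomposition partitions the overlap", {
  uni <- universe_from_members(c("G1", "G2", "G3", "G4"))
  q <- gene_signature(data.frame(
    gene_id = c("G1", "G2"), direction = c("up", "down"),
    signed_fold_change = c(2, -2), p_value = c(0.01, 0.02)))
  r <- gene_signature(data.frame(
    gene_id = c("G1", "G2"), direction = c("up", "up"),
    signed_fold_change = c(2, 2), p_value = c(0.01, 0.02)))
  d <- directional_decomposition(q, r, uni)
  expect_equal(unname(d$counts[c("up_up", "down_up", "up_down",
                                 "down_down")]),
               c(1L, 1L, 0L, 0L))
  expect_equal(d$pairs$up_up$overlap_gene_ids, "G1")
  expect_equal(d$pairs$down_up$overlap_gene_ids, "G2")
  expect_equal(sum(d$counts), d$n_overlap_total)
  expect_equal(d$threshold, 0.0125)

  # identical all-up signatures: everything in (up,up), rest null
  r2 <- directional_decomposition(r, r, uni)
  expect_equal(unname(r2$counts["up_up"]), 2L)
  expect_equal(unname(r2$counts[c("down_down", "up_down", "down_up")]),
               c(0L, 0L, 0L))
  expect_equal(r2$pairs$down_down$p_final, 1)
})

test_that("directional counts match brute-force set arithmetic", {
  genes <- sprintf("U%04d", 1:500)
  uni <- universe_from_members(genes)
  set.seed(44)
  for (i in 1:20) {
    q <- random_signature(genes, 50)
    r <- random_signature(genes, 50)
    d <- directional_decomposition(q, r, uni)
    expect_equal(d$counts, brute_directional_counts(q, r))
    expect_equal(sum(d$counts), d$n_overlap_total)
    all_genes <- unlist(lapply(d$pairs, function(p) p$overlap_gene_ids))
    expect_false(anyDuplicated(all_genes) > 0)  # four cells disjoint
  }
})

test_that("Bonferroni threshold and correlation classification", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 12), 0.05 / 12)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.5, 4), "alpha")

  # the hippocampal directional counts classify as a positive correlation
  hip <- c(up_up = 64, down_down = 77, up_down = 14, down_up = 27)
  cls <- classify_correlation(hip)
  expect_equal(cls$label, "positive")
  expect_equal(cls$n_concordant, 141)
  expect_equal(cls$n_discordant, 41)
  expect_equal(classify_correlation(
    c(up_up = 0, down_down = 0, up_down = 0, down_up = 0))$label, "mixed")
  expect_equal(classify_correlation(
    c(up_up = 3, down_down = 1, up_down = 2, down_up = 1))$label,
    "positive")
  # equal concordant and discordant counts are a tie, hence mixed
  expect_equal(classify_correlation(
    c(up_up = 3, down_down = 0, up_down = 2, down_up = 1))$label,
    "mixed")
  expect_equal(classify_correlation(
    c(up_up = 1, down_down = 0, up_down = 2, down_up = 1))$label,
    "negative")
})
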