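small_cfg <- function(...) {
  args <- list(n_genes = 800, n_per_group = 5, shared_program_size = 40,
               specific_program_size = 20,
               celltype_sizes = c(FS = 30, AS = 25, OL = 28),
               celltype_overlap = c(FS = 0.5, AS = 0.2, OL = 0.3))
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 5)
  a <- generate_paired_datasets(cfg)
  b <- generate_paired_datasets(cfg)
  expect_identical(a, b)
  ca <- generate_celltype_sets(cfg, a$truth)
  cb <- generate_celltype_sets(cfg, b$truth)
  expect_identical(ca, cb)
  expect_identical(generate_ortholog_table(100, 0.1, seed = 3,
                                           missing_fraction = 0.2),
                   generate_ortholog_table(100, 0.1, seed = 3,
                                           missing_fraction = 0.2))
  # a different seed changes the data
  expect_false(identical(a$disease$values,
                         generate_paired_datasets(small_cfg(seed = 6))$
                           disease$values))
})

test_that("planted structure matches the truth record", {
  cfg <- small_cfg(seed = 15)
  sim <- generate_paired_datasets(cfg)
  tr <- sim$truth
  expect_length(tr$shared_genes, 40)
  expect_length(tr$disease_specific, 20)
  expect_length(tr$development_specific, 20)
  # with concordant_fraction = 1 every shared gene is concordant
  expect_setequal(tr$concordant_genes, tr$shared_genes)
  expect_equal(tr$disease_direction[tr$shared_genes],
               tr$development_direction[tr$shared_genes])
  # programs disjoint
  expect_length(intersect(tr$disease_specific, tr$development_specific), 0)
  expect_length(intersect(tr$shared_genes, tr$disease_specific), 0)

  # planted shifts are visible in the group means
  de <- differential_expression(sim$disease)
  planted <- de$feature_id %in% c(tr$shared_genes, tr$disease_specific)
  expect_gt(mean(abs(de$signed_fold_change[planted]) > 1.2), 0.95)

  # shared_program_size = 0 leaves the planted programs disjoint
  sim0 <- generate_paired_datasets(small_cfg(seed = 16,
                                             shared_program_size = 0))
  expect_length(sim0$truth$shared_genes, 0)
})

test_that("null configuration yields chance-level signatures", {
  cfg <- synthetic_config(n_genes = 2000, n_per_group = 5,
                          shared_program_size = 50,
                          specific_program_size = 0,
                          effect_size = 0, seed = 17)
  sim <- generate_paired_datasets(cfg)
  sig <- build_signature(sim$disease, 1.2, 0.05)
  # expected size about p-threshold x n_genes (FC filter barely binds at
  # n = 5); allow a generous binomial band around 0.05 x 2000 = 100
  expect_gt(length(sig), 40)
  expect_lt(length(sig), 170)
})

test_that("config validation rejects infeasible settings", {
  expect_error(synthetic_config(n_genes = 100, shared_program_size = 80,
                                specific_program_size = 20, seed = 1),
               "larger than")
  expect_error(synthetic_config(concordant_fraction = 1.2, seed = 1),
               "concordant_fraction")
  expect_error(synthetic_config(n_genes = 100, seed = 1,
                                shared_program_size = 10,
                                specific_program_size = 5,
                                celltype_sizes = c(FS = 200, AS = 1,
                                                   OL = 1)),
               "cell-type module")
  expect_error(synthetic_config(), "seed")
})

test_that("cell-type sets respect configured overlap with the program", {
  cfg <- small_cfg(seed = 18)
  sim <- generate_paired_datasets(cfg)
  cts <- generate_celltype_sets(cfg, sim$truth)
  for (ct in names(cfg$celltype_sizes)) {
    sig <- cts$signatures[[ct]]
    expect_equal(length(sig), unname(cfg$celltype_sizes[[ct]]))
    n_from_shared <- length(intersect(signature_genes <- sig$entries$gene_id,
                                      sim$truth$shared_genes))
    expect_equal(n_from_shared,
                 round(cfg$celltype_overlap[[ct]] *
                         cfg$celltype_sizes[[ct]]))
    # overlapping genes carry the development-side direction
    ov <- intersect(sig$entries$gene_id, sim$truth$shared_genes)
    expect_equal(
      sig$entries$direction[match(ov, sig$entries$gene_id)],
      unname(sim$truth$development_direction[ov]))
  }
  expect_setequal(cts$truth$triple,
                  Reduce(intersect, cts$truth$members))
})

test_that("ortholog table generator honours fan-out and missing fractions", {
  ident <- generate_ortholog_table(50, 0, seed = 2)
  expect_equal(ident$gene_a, ident$gene_b)
  expect_equal(nrow(ident), 50)

  miss <- generate_ortholog_table(100, 0, seed = 2,
                                  missing_fraction = 0.2)
  expect_equal(nrow(miss), 80)

  fan <- generate_ortholog_table(100, 0.1, seed = 2)
  expect_equal(nrow(fan), 110)
  expect_equal(sum(grepl("\\.1$", fan$gene_b)), 10)

  # round trip through an identity table is the identity
  sig <- gene_signature(data.frame(
    gene_id = ident$gene_a[1:10], direction = "up",
    signed_fold_change = 2, p_value = (1:10) / 100))
  round <- map_signature(map_signature(sig, ident, "a_to_b"),
                         ident, "b_to_a")
  expect_equal(round$entries, sig$entries)
})
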