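#' Configuration for the synthetic-data generator
#'
#' Describes a pair of two-group expression studies (a "disease" and a
#' "development" comparison) that share a planted directional program,
#' plus three cell-type developmental modules and a many-to-many
#' orthologue relation. Defaults emulate a desk-scale version of the
#' statistical structure a disease-vs-development signature comparison
#' assumes: arrays of ~10k genes, 10 samples per group, residual log2
#' intensity sd of 0.5 (typical of RMA-summarised arrays), a 100-gene
#' shared program of 1.5 log2-unit shifts, and 50 dataset-specific
#' differentially expressed genes per study.
#'
#' @param n_genes Number of genes on the (shared) platform.
#' @param n_per_group Samples per group per dataset.
#' @param baseline_mean,baseline_sd Mean and sd of baseline log2
#'   intensities per gene; `baseline_sd` is also the within-group
#'   residual sd.
#' @param shared_program_size Number of genes differentially expressed in
#'   both datasets.
#' @param effect_size Log2-scale group mean shift for planted genes.
#' @param concordant_fraction Probability that a shared-program gene
#'   shifts in the same direction in both datasets.
#' @param specific_program_size Dataset-specific DE genes added to each
#'   dataset (disjoint between datasets and from the shared program).
#' @param celltype_sizes Named integer vector: genes per cell-type module.
#' @param celltype_overlap Named numeric vector in [0, 1]: fraction of
#'   each cell-type module drawn from the shared program.
#' @param ortholog_fanout_fraction Fraction of genes with a second
#'   orthologue target.
#' @param ortholog_missing_fraction Fraction of genes with no orthologue.
#' @param seed Mandatory integer seed; all generation is reproducible
#'   from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 10000L, n_per_group = 10L,
                             baseline_mean = 7, baseline_sd = 0.5,
                             shared_program_size = 100L,
                             effect_size = 1.5,
                             concordant_fraction = 1,
                             specific_program_size = 50L,
                             celltype_sizes = c(FS = 120L, AS = 100L,
                                                OL = 110L),
                             celltype_overlap = c(FS = 0.4, AS = 0.15,
                                                  OL = 0.3),
                             ortholog_fanout_fraction = 0.05,
                             ortholog_missing_fraction = 0,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              shared_program_size = as.integer(shared_program_size),
              effect_size = effect_size,
              concordant_fraction = concordant_fraction,
              specific_program_size = as.integer(specific_program_size),
              celltype_sizes = celltype_sizes,
              celltype_overlap = celltype_overlap,
              ortholog_fanout_fraction = ortholog_fanout_fraction,
              ortholog_missing_fraction = ortholog_missing_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1 || n_per_group < 2) stop("invalid sizes")
    if (shared_program_size + 2 * specific_program_size > n_genes)
      stop("planted programs larger than the gene universe")
    if (concordant_fraction < 0 || concordant_fraction > 1)
      stop("concordant_fraction must be in [0, 1]")
    if (!is.finite(effect_size)) stop("effect size must be finite")
    if (any(celltype_sizes > n_genes))
      stop("cell-type module larger than the gene universe")
    if (ortholog_fanout_fraction < 0 || ortholog_fanout_fraction >= 1)
      stop("ortholog_fanout_fraction must be in [0, 1)")
  })
  structure(cfg, class = "synthetic_config")
}

synthetic_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# one two-group dataset with given per-gene log2 shifts (numerator group)
simulate_dataset <- function(gene_ids, shifts, n_per_group, baseline_mean,
                             baseline_sd, numerator, denominator,
                             sample_prefix) {
  n_genes <- length(gene_ids)
  base <- stats::rnorm(n_genes, baseline_mean, 1)
  n_samp <- 2L * n_per_group
  noise <- matrix(stats::rnorm(n_genes * n_samp, 0, baseline_sd),
                  nrow = n_genes)
  vals <- base + noise
  num_cols <- seq_len(n_per_group)
  vals[, num_cols] <- vals[, num_cols] + shifts
  samples <- sprintf("%s_%s%02d", sample_prefix,
                     rep(c("N", "D"), each = n_per_group),
                     c(seq_len(n_per_group), seq_len(n_per_group)))
  colnames(vals) <- samples
  rownames(vals) <- gene_ids
  groups <- stats::setNames(rep(c(numerator, denominator),
                                each = n_per_group), samples)
  expression_dataset(vals, sample_groups = groups,
                     numerator = numerator, denominator = denominator)
}

#' Generate a paired disease / development study with a planted shared
#' program
#'
#' Simulates two independent two-group expression datasets over the same
#' gene platform. A shared program of genes is shifted in both datasets —
#' in the same direction with probability `concordant_fraction` — and
#' each dataset additionally gets its own disjoint specific program. The
#' returned truth record lists every planted membership and direction so
#' downstream recovery can be scored without re-inference.
#'
#' @param config A [synthetic_config()].
#' @return List with `disease` and `development`
#'   ([expression_dataset()]s) and `truth`: a list with `gene_ids`,
#'   `shared_genes`, per-dataset planted direction vectors
#'   (`disease_direction`, `development_direction`, named by gene),
#'   `concordant_genes`, and the specific program gene ids.
#' @export
generate_paired_datasets <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- synthetic_gene_ids(n)

  planted_total <- config$shared_program_size +
    2L * config$specific_program_size
  planted <- sample(ids, planted_total)
  shared <- planted[seq_len(config$shared_program_size)]
  spec_dis <- planted[config$shared_program_size +
                        seq_len(config$specific_program_size)]
  spec_dev <- planted[config$shared_program_size +
                        config$specific_program_size +
                        seq_len(config$specific_program_size)]

  sign_dis <- stats::setNames(sample(c(-1, 1), length(shared),
                                     replace = TRUE), shared)
  flip <- stats::runif(length(shared)) > config$concordant_fraction
  sign_dev <- sign_dis * ifelse(flip, -1, 1)

  spec_dis_sign <- stats::setNames(sample(c(-1, 1), length(spec_dis),
                                          replace = TRUE), spec_dis)
  spec_dev_sign <- stats::setNames(sample(c(-1, 1), length(spec_dev),
                                          replace = TRUE), spec_dev)

  shift_dis <- stats::setNames(numeric(n), ids)
  shift_dis[shared] <- sign_dis * config$effect_size
  shift_dis[spec_dis] <- spec_dis_sign * config$effect_size
  shift_dev <- stats::setNames(numeric(n), ids)
  shift_dev[shared] <- sign_dev * config$effect_size
  shift_dev[spec_dev] <- spec_dev_sign * config$effect_size

  disease <- simulate_dataset(ids, unname(shift_dis), config$n_per_group,
                              config$baseline_mean, config$baseline_sd,
                              "patient", "control", "DIS")
  development <- simulate_dataset(ids, unname(shift_dev),
                                  config$n_per_group,
                                  config$baseline_mean, config$baseline_sd,
                                  "infant", "adult", "DEV")
  dirlab <- function(s) ifelse(s > 0, "up", "down")
  truth <- list(
    gene_ids = ids,
    shared_genes = shared,
    concordant_genes = shared[!flip],
    disease_direction = dirlab(c(sign_dis, spec_dis_sign)),
    development_direction = dirlab(c(sign_dev, spec_dev_sign)),
    disease_specific = spec_dis,
    development_specific = spec_dev)
  list(disease = disease, development = development, truth = truth)
}

#' Generate three cell-type developmental gene sets
#'
#' Draws, per cell type, a directed gene set of the configured size whose
#' overlap with the planted shared program is controlled by
#' `celltype_overlap`: that fraction of the module is sampled from the
#' shared program (inheriting the development-side direction, i.e. the
#' module agrees with the developmental signature on those genes), the
#' remainder from the rest of the platform with random directions.
#' Module fold changes are set to 2^effect_size and p-values drawn
#' uniformly below 0.05 so the sets behave like thresholded signatures.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth record from [generate_paired_datasets()].
#' @return List with `signatures` (named list of three `gene_signature`s)
#'   and `truth`: per-type member lists plus pairwise and triple overlap
#'   gene ids.
#' @export
generate_celltype_sets <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  types <- names(config$celltype_sizes)
  shared <- truth$shared_genes
  other <- setdiff(truth$gene_ids, shared)
  sigs <- list(); members <- list()
  for (ct in types) {
    size <- config$celltype_sizes[[ct]]
    n_from_shared <- min(length(shared),
                         round(config$celltype_overlap[[ct]] * size))
    from_shared <- if (n_from_shared > 0)
      sample(shared, n_from_shared) else character(0)
    from_other <- sample(other, size - n_from_shared)
    genes <- c(from_shared, from_other)
    dirs <- c(truth$development_direction[from_shared],
              sample(c("up", "down"), length(from_other), replace = TRUE))
    fc <- ifelse(dirs == "up", 2^config$effect_size,
                 -2^config$effect_size)
    entries <- data.frame(gene_id = genes, direction = unname(dirs),
                          signed_fold_change = fc,
                          p_value = stats::runif(size, 1e-8, 0.05),
                          stringsAsFactors = FALSE)
    sigs[[ct]] <- gene_signature(entries, name = paste0(ct, "_development"),
                                 species = "mouse")
    members[[ct]] <- genes
  }
  ct_truth <- list(members = members,
                   pairwise = list(), triple = Reduce(intersect, members))
  combos <- utils::combn(types, 2, simplify = FALSE)
  for (cb in combos)
    ct_truth$pairwise[[paste(cb, collapse = "_")]] <-
      intersect(members[[cb[1]]], members[[cb[2]]])
  list(signatures = sigs, truth = ct_truth)
}

#' Generate a synthetic orthologue table
#'
#' Identity-like mapping over the synthetic platform: every retained gene
#' maps to itself; a seeded fraction of genes additionally map to a
#' second target (`<id>.1`, one-to-many fan-out) and a seeded fraction
#' are dropped entirely (no orthologue). With both fractions zero the
#' table is the identity relation.
#'
#' @param n_genes Number of source genes (ids `G00001`...).
#' @param fanout_fraction Fraction in [0, 1) of genes with a second
#'   target.
#' @param seed Integer seed.
#' @param missing_fraction Fraction in [0, 1) of genes with no entry.
#' @return An [ortholog_table()].
#' @export
generate_ortholog_table <- function(n_genes, fanout_fraction = 0, seed,
                                    missing_fraction = 0) {
  if (fanout_fraction < 0 || fanout_fraction >= 1)
    stop("fanout_fraction must be in [0, 1)")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  set.seed(seed)
  ids <- synthetic_gene_ids(n_genes)
  keep <- if (missing_fraction > 0)
    sort(sample(ids, round((1 - missing_fraction) * n_genes))) else ids
  fan <- if (fanout_fraction > 0)
    sort(sample(keep, round(fanout_fraction * length(keep))))
  else character(0)
  fan_targets <- if (length(fan)) paste0(fan, ".1") else character(0)
  ortholog_table(c(keep, fan), c(keep, fan_targets))
}
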