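#' Load a run configuration
#'
#' Reads a YAML run configuration and validates it. Recognised fields:
#' file paths (`disease_expr`, `disease_groups`, `development_expr`,
#' `development_groups`, `orthologs`), per-dataset thresholds
#' (`disease_fc_threshold`, `development_fc_threshold`, `p_threshold`),
#' group roles (`disease_numerator`, `disease_denominator`,
#' `development_numerator`, `development_denominator`), `cutoff_scheme`,
#' `alpha`, `n_pairs` (dataset-pair Bonferroni m), `out_dir`, `seed`.
#' Values passed in `overrides` replace file values.
#'
#' @param path Path to a YAML file, or `NULL` to build a config from
#'   `overrides` alone.
#' @param overrides Named list of overriding values.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  defaults <- list(disease_fc_threshold = 1.2,
                   development_fc_threshold = 1.2,
                   p_threshold = 0.05, cutoff_scheme = "deciles",
                   alpha = 0.05, n_pairs = 1L,
                   disease_numerator = "patient",
                   disease_denominator = "control",
                   development_numerator = "infant",
                   development_denominator = "adult")
  miss <- setdiff(names(defaults), names(cfg))
  cfg[miss] <- defaults[miss]
  if (cfg$disease_fc_threshold < 1 || cfg$development_fc_threshold < 1)
    stop("fold-change thresholds must be >= 1")
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1)
    stop("p_threshold must be in (0, 1]")
  if (cfg$n_pairs < 1) stop("n_pairs must be >= 1")
  if (!cfg$cutoff_scheme %in% c("deciles", "per-rank"))
    stop("cutoff_scheme must be 'deciles' or 'per-rank'")
  for (f in intersect(c("disease_expr", "disease_groups",
                        "development_expr", "development_groups",
                        "orthologs"), names(cfg)))
    if (!file.exists(cfg[[f]]))
      stop("config path not found: ", f, " = ", cfg[[f]])
  structure(cfg, class = "run_config")
}

load_expression <- function(expr_path, groups_path, numerator,
                            denominator) {
  m <- if (grepl("\\.gct$", expr_path, ignore.case = TRUE))
    read_gct(expr_path)$values else read_tsv_matrix(expr_path)
  expression_dataset(m, sample_groups = read_groups_tsv(groups_path),
                     numerator = numerator, denominator = denominator)
}

#' Full overlap analysis between a disease and a development comparison
#'
#' Builds both differential-expression signatures, maps the development
#' signature into the disease id space through the orthologue table,
#' constructs the background universe, runs the undirected running
#' Fisher test and its four-way directional decomposition, and
#' classifies the correlation. All thresholds and the dataset-pair
#' Bonferroni m are echoed in the report for auditability.
#'
#' @param config A `run_config` from [load_run_config()], or a list of
#'   in-memory inputs: `disease` and `development`
#'   ([expression_dataset()]s), `orthologs` (an [ortholog_table()];
#'   identity assumed when absent), plus any threshold fields.
#' @return A report list (class `overlap_report`) with signature sizes,
#'   the `overlap_result`, the `directional_overlap`, the derived
#'   concordant bioset, thresholds, and the correlation classification.
#' @export
run_overlap_analysis <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(NULL, config)
  disease <- if (!is.null(cfg$disease)) cfg$disease else
    load_expression(cfg$disease_expr, cfg$disease_groups,
                    cfg$disease_numerator, cfg$disease_denominator)
  development <- if (!is.null(cfg$development)) cfg$development else
    load_expression(cfg$development_expr, cfg$development_groups,
                    cfg$development_numerator, cfg$development_denominator)

  sig_dis <- build_signature(disease, cfg$disease_fc_threshold,
                             cfg$p_threshold, name = "disease")
  sig_dev <- build_signature(development, cfg$development_fc_threshold,
                             cfg$p_threshold, name = "development")

  orth <- if (!is.null(cfg$orthologs) && !is.character(cfg$orthologs))
    cfg$orthologs
  else if (!is.null(cfg$orthologs)) read_ortholog_tsv(cfg$orthologs)
  else ortholog_table(development$feature_ids, development$feature_ids)

  # development signature expressed in the disease platform's id space
  sig_dev_mapped <- map_signature(sig_dev, orth, "b_to_a")
  universe <- build_universe(disease$feature_ids,
                             development$feature_ids, orth)
  keep_in_universe <- function(sig) {
    ent <- sig$entries[sig$entries$gene_id %in% universe$members, ,
                       drop = FALSE]
    ent$rank <- NULL
    gene_signature(ent, name = sig$name, species = sig$species,
                   fc_threshold = sig$fc_threshold,
                   p_threshold = sig$p_threshold)
  }
  sig_dis_u <- keep_in_universe(sig_dis)
  sig_dev_u <- keep_in_universe(sig_dev_mapped)

  overlap <- running_fisher(sig_dis_u, sig_dev_u, universe,
                            cfg$cutoff_scheme)
  directional <- directional_decomposition(sig_dis_u, sig_dev_u, universe,
                                           cfg$cutoff_scheme, cfg$alpha)
  bioset <- derive_concordant_bioset(directional, name = "concordant",
                                     sources = c("disease", "development"))
  structure(list(
    schema_version = "1.0",
    thresholds = list(disease_fc = cfg$disease_fc_threshold,
                      development_fc = cfg$development_fc_threshold,
                      p = cfg$p_threshold, alpha = cfg$alpha,
                      n_pairs = cfg$n_pairs,
                      pair_threshold = bonferroni_threshold(cfg$alpha,
                                                            cfg$n_pairs),
                      directional_threshold = directional$threshold),
    cutoff_scheme = cfg$cutoff_scheme,
    n_signature_disease = length(sig_dis),
    n_signature_development = length(sig_dev),
    universe_size = universe$size,
    overlap = overlap,
    directional = directional,
    significant_at_pair_threshold =
      overlap$p_final < bonferroni_threshold(cfg$alpha, cfg$n_pairs),
    classification = classify_correlation(directional),
    bioset = bioset,
    signatures = list(disease = sig_dis_u, development = sig_dev_u),
    universe = universe),
    class = "overlap_report")
}

#' Cell-type contribution analysis of a concordant bioset
#'
#' Tests the overlap of a concordant bioset with each of three cell-type
#' developmental signatures (running Fisher against the supplied
#' universe), partitions the bioset across the three sets into the 8
#' Venn regions with percentages, and counts direction concordance per
#' cell type.
#'
#' @param bioset A `concordant_bioset` (ids in the same space as the
#'   cell-type signatures, i.e. post-orthologue mapping).
#' @param celltype_signatures Named list of three `gene_signature`s.
#' @param universe A `universe` covering the bioset and the signatures.
#' @param cutoff_scheme Passed to [running_fisher()].
#' @param alpha Family-wise level echoed in the report.
#' @return A report list (class `contribution_report`) with per-cell-type
#'   overlap results, the `venn_partition`, marginal percentages and
#'   direction-concordance counts. An empty bioset yields an explicit
#'   `empty = TRUE` marker instead of statistics.
#' @export
run_contribution_analysis <- function(bioset, celltype_signatures,
                                      universe,
                                      cutoff_scheme = c("deciles",
                                                        "per-rank"),
                                      alpha = 0.05) {
  stopifnot(inherits(bioset, "concordant_bioset"),
            length(celltype_signatures) == 3L,
            !is.null(names(celltype_signatures)))
  cutoff_scheme <- match.arg(cutoff_scheme)
  if (nrow(bioset$members) == 0L)
    return(structure(list(schema_version = "1.0", empty = TRUE,
                          bioset_size = 0L),
                     class = "contribution_report"))
  # the bioset ranks genes alphabetically (it carries no p-values of its
  # own); overlap counts are unaffected, only the scan path depends on it
  bioset_sig <- gene_signature(data.frame(
    gene_id = bioset$members$gene_id,
    direction = bioset$members$direction,
    signed_fold_change = ifelse(bioset$members$direction == "up", 2, -2),
    p_value = 0.01, stringsAsFactors = FALSE), name = bioset$name)

  overlaps <- lapply(celltype_signatures, function(sig)
    running_fisher(bioset_sig, sig, universe, cutoff_scheme))
  concordance <- lapply(celltype_signatures, function(sig)
    direction_concordance(bioset, sig))
  venn <- venn_partition(bioset, celltype_signatures[[1]],
                         celltype_signatures[[2]],
                         celltype_signatures[[3]],
                         labels = names(celltype_signatures))
  structure(list(
    schema_version = "1.0", empty = FALSE,
    bioset_size = nrow(bioset$members),
    alpha = alpha, universe_size = universe$size,
    cutoff_scheme = cutoff_scheme,
    celltype_overlaps = overlaps,
    direction_concordance = concordance,
    venn = venn,
    marginal_percentages = venn$marginal_percentages),
    class = "contribution_report")
}
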