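#' Read a GCT 1.2 expression matrix
#'
#' Parses the two-header-line GCT dialect: line 1 is `#1.2`, line 2 gives
#' `<n_rows>\t<n_cols>`, line 3 holds `NAME`, `Description` and the
#' sample ids, then one row per feature. Malformed headers, dimension
#' mismatches, duplicate feature ids and non-numeric cells raise errors
#' naming the offending line.
#'
#' @param path Path to a GCT file.
#' @return List with `values` (numeric matrix, features x samples) and
#'   `descriptions` (character vector).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "#1.2")
    stop("line 1: expected GCT version header '#1.2'")
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop("line 2: expected '<n_rows>\\t<n_cols>'")
  n_rows <- as.integer(dims[1]); n_cols <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_cols + 2L)
    stop("line 3: expected ", n_cols + 2L, " columns, got ", length(header))
  if (length(lines) - 3L != n_rows)
    stop("expected ", n_rows, " data rows, found ", length(lines) - 3L)
  samples <- header[-(1:2)]
  ids <- character(n_rows); desc <- character(n_rows)
  vals <- matrix(NA_real_, n_rows, n_cols,
                 dimnames = list(NULL, samples))
  for (i in seq_len(n_rows)) {
    f <- strsplit(lines[3L + i], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_cols + 2L)
      stop("line ", 3L + i, ": expected ", n_cols + 2L,
           " fields, got ", length(f))
    ids[i] <- f[1]; desc[i] <- f[2]
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v))
      stop("line ", 3L + i, ": non-numeric expression value")
    vals[i, ] <- v
  }
  if (anyDuplicated(ids))
    stop("duplicated feature id: ", ids[duplicated(ids)][1])
  rownames(vals) <- ids
  list(values = vals, descriptions = stats::setNames(desc, ids))
}

#' Write a GCT 1.2 expression matrix
#'
#' @param values Numeric matrix with feature rownames and sample
#'   colnames.
#' @param path Output path.
#' @param descriptions Optional per-feature description column (defaults
#'   to "na").
#' @return `path`, invisibly.
#' @export
write_gct <- function(values, path, descriptions = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (is.null(descriptions)) descriptions <- rep("na", nrow(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t"),
               paste(c("NAME", "Description", colnames(values)),
                     collapse = "\t")), con)
  body <- cbind(rownames(values), descriptions,
                format(values, trim = TRUE, digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a plain TSV expression matrix
#'
#' First column feature id, header row of sample ids.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with feature rownames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated feature id: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  m
}

#' Read sample-group labels
#'
#' Two-column TSV with header `sample_id<TAB>group`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector, sample id -> group label.
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("groups file needs header 'sample_id\\tgroup'")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  stats::setNames(as.character(df$group), as.character(df$sample_id))
}

#' Read an orthologue table from TSV
#'
#' Two-column TSV with header `gene_a<TAB>gene_b` (HomoloGene-style
#' export).
#'
#' @param path Path to the TSV file.
#' @return An [ortholog_table()].
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("orthologue file needs header 'gene_a\\tgene_b'")
  ortholog_table(df$gene_a, df$gene_b)
}

#' Write an orthologue table to TSV
#' @param table An [ortholog_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a gene signature as extended GMT plus companion TSV
#'
#' GMT: two lines, `<name>_UP` and `<name>_DOWN`, each with a description
#' field followed by tab-separated gene ids in rank order. Companion TSV
#' (same path with extension `.tsv`): columns gene_id, direction,
#' signed_fold_change, p_value, rank.
#'
#' @param signature A `gene_signature`.
#' @param gmt_path Output GMT path.
#' @param tsv_path Companion TSV path; default replaces the extension.
#' @return `gmt_path`, invisibly.
#' @export
write_signature_gmt <- function(signature, gmt_path,
                                tsv_path = sub("\\.gmt$", ".tsv", gmt_path)) {
  ent <- signature$entries
  up <- ent$gene_id[ent$direction == "up"]
  down <- ent$gene_id[ent$direction == "down"]
  desc <- sprintf("fc>%s;p<%s", signature$fc_threshold,
                  signature$p_threshold)
  lines <- c(paste(c(paste0(signature$name, "_UP"), desc, up),
                   collapse = "\t"),
             paste(c(paste0(signature$name, "_DOWN"), desc, down),
                   collapse = "\t"))
  writeLines(lines, gmt_path)
  utils::write.table(ent, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(gmt_path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> gene ids); the
#'   description field is kept as attribute `"description"` on each set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("line ", i, ": GMT lines need name, description and >=1 gene")
    genes <- normalize_gene_ids(f[-(1:2)])
    attr(genes, "description") <- f[2]
    sets[[f[1]]] <- genes
  }
  sets
}

#' Read an extended-GMT signature pair back into a gene signature
#'
#' Reads the companion TSV written by [write_signature_gmt()] (the TSV
#' carries the fold changes, p-values and ranks the GMT lines drop).
#'
#' @param tsv_path Companion TSV path.
#' @param name Signature name.
#' @return A `gene_signature`.
#' @export
read_signature_tsv <- function(tsv_path, name = "signature") {
  ent <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  gene_signature(ent, name = name)
}

#' Serialize an analysis report
#'
#' Writes the report list as pretty JSON (machine-readable, with a schema
#' version field) and, where the report contains tabular components, flat
#' TSVs alongside.
#'
#' @param report A report list from [run_overlap_analysis()] or
#'   [run_contribution_analysis()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_plain(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# recursively convert S3 report objects into plain lists; named atomic
# vectors become named lists so JSON keeps the names
report_to_plain <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    out <- lapply(x, report_to_plain)
    attributes(out) <- list(names = names(x))
    return(out)
  }
  if (is.atomic(x) && !is.null(names(x)) && length(x) > 1)
    return(as.list(x))
  x
}
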