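#' Construct an omics sample-by-feature matrix with per-sample metadata
#'
#' The universal exchange container of the package: a dense numeric matrix
#' with samples in rows and molecular features (CpG probes or genes) in
#' columns, plus a per-sample metadata table. Methylation values are beta
#' fractions in \[0, 1\]; expression values are TPM or normalized
#' log-abundance depending on the pipeline stage.
#'
#' @param values Numeric matrix, samples x features.
#' @param metadata A data.frame with one row per sample. Recognised columns:
#'   `sample_id`, `age` (years, `NA` allowed only for unlabeled prediction
#'   input), `tissue`, `batch`, `modality` (`"methylation"` or
#'   `"expression"`), `label` (`"case"`, `"control"` or `"none"`), and any
#'   extra covariates (e.g. `time` for trajectory courses).
#' @param check_beta If `TRUE`, enforce values in \[0, 1\] for rows whose
#'   modality is `"methylation"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, metadata, check_beta = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (!is.data.frame(metadata))
    stop("`metadata` must be a data.frame")
  if (is.null(metadata$sample_id)) {
    if (is.null(rownames(values)))
      stop("sample ids required: metadata$sample_id or rownames(values)")
    metadata$sample_id <- rownames(values)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (is.null(rownames(values))) rownames(values) <- metadata$sample_id
  if (is.null(colnames(values)))
    stop("feature ids required as colnames(values)")
  if (nrow(values) != nrow(metadata))
    stop(sprintf("row mismatch: %d samples in values, %d metadata rows",
                 nrow(values), nrow(metadata)))
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  dupf <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dupf))
    stop("duplicated feature id(s): ", paste(dupf, collapse = ", "))
  if (!identical(rownames(values), metadata$sample_id))
    stop("rownames(values) do not match metadata$sample_id order")
  for (col in c("tissue", "batch", "modality", "label"))
    if (!is.null(metadata[[col]])) metadata[[col]] <- as.character(metadata[[col]])
  if (!is.null(metadata$modality)) {
    bad <- setdiff(unique(metadata$modality), c("methylation", "expression"))
    if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))
    if (check_beta) {
      meth <- metadata$modality == "methylation"
      if (any(meth)) {
        v <- values[meth, , drop = FALSE]
        if (any(v < 0 | v > 1, na.rm = TRUE))
          stop("methylation beta values must lie in [0, 1]")
      }
    }
  }
  if (!is.null(metadata$age) && any(metadata$age < 0, na.rm = TRUE))
    stop("ages must be non-negative")
  structure(list(values = values, metadata = metadata),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$metadata$modality))
    cat("  modality:", paste(sprintf("%s (%d)",
        names(table(x$metadata$modality)), table(x$metadata$modality)),
        collapse = ", "), "\n")
  if (!is.null(x$metadata$age) && any(!is.na(x$metadata$age)))
    cat(sprintf("  age: %.1f-%.1f years\n",
                min(x$metadata$age, na.rm = TRUE),
                max(x$metadata$age, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics_matrix by samples and/or features
#'
#' @param x An `omics_matrix`.
#' @param i Sample index (ids, logical, or positions).
#' @param j Feature index.
#' @param ... Ignored.
#' @return An `omics_matrix`.
#' @export
`[.omics_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$metadata$sample_id)
  out <- omics_matrix(x$values[i, j, drop = FALSE],
                      x$metadata[i, , drop = FALSE],
                      check_beta = FALSE)
  for (a in c("scaling", "prescaled"))
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  out
}

#' Read a delimited sample-by-feature matrix with its metadata table
#'
#' Expects samples in rows and features in columns (the first column holds
#' sample ids); transposed files are not auto-detected. Metadata is keyed by
#' a `sample_id` column and reordered to the matrix's sample order. Empty
#' cells and the string `"NA"` are read as missing; any other non-numeric
#' cell is an error locating the offending row and column.
#'
#' @param path Matrix file (TSV or CSV, inferred from extension).
#' @param metadata_path Metadata file with a `sample_id` column.
#' @return An `omics_matrix`.
#' @export
read_omics_matrix <- function(path, metadata_path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated sample id(s) in ", path, ": ", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(ifelse(cells == "" | cells == "NA",
                                                   NA, cells)),
                                 nrow = nrow(cells)))
  bad <- which(is.na(num) & !(cells == "" | cells == "NA" | is.na(cells)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at sample '%s', feature '%s' in %s",
                 ids[bad[1, 1]], colnames(cells)[bad[1, 2]], path))
  dimnames(num) <- list(ids, colnames(cells))
  msep <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(metadata_path, sep = msep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  if (is.null(meta$sample_id)) stop("metadata must have a sample_id column")
  missing_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_meta))
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$sample_id, ids)
  if (length(extra))
    stop("metadata samples missing from matrix: ", paste(extra, collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  omics_matrix(num, meta)
}

#' Write an omics_matrix to delimited files
#'
#' Inverse of [read_omics_matrix()]: round-tripping preserves the value
#' table and metadata.
#'
#' @param x An `omics_matrix`.
#' @param path Matrix output file (TSV or CSV by extension).
#' @param metadata_path Metadata output file.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, metadata_path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  msep <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x$metadata, metadata_path, sep = msep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CpG probe annotation manifest
#'
#' Three required columns: `probe_id`, `gene_id`, `region_class` (e.g.
#' `TSS200`, `TSS1500`, `Body`). Used to aggregate probe-level beta values
#' into proximal-promoter (TSS200) gene features.
#'
#' @param path TSV/CSV manifest file.
#' @return A data.frame of class `probe_manifest`.
#' @export
read_probe_manifest <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  man <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  probe_manifest(man)
}

#' Validate a probe manifest data.frame
#'
#' @param df data.frame with columns probe_id, gene_id, region_class.
#' @return The validated data.frame, classed `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  need <- c("probe_id", "gene_id", "region_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$probe_id, df$gene_id, df$region_class)
  if (anyDuplicated(key))
    stop("duplicated manifest row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  class(df) <- c("probe_manifest", "data.frame")
  df
}
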