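# Reading, validating and preprocessing FPKM matrices.

.SERIES_TABLE <- data.frame(
  series = c("AL", "AD", "LL", "LD"),
  medium = c("agar", "agar", "liquid", "liquid"),
  light  = c("light", "dark", "light", "dark"),
  stringsAsFactors = FALSE
)

#' Read a sample metadata table
#'
#' The table must contain columns `sample_id`, `medium` (`agar`/`liquid`),
#' `light` (`light`/`dark`) and `series` (`AL`/`AD`/`LL`/`LD`); `strain` and
#' `source_lab` are optional. The series label must be consistent with the
#' (medium, light) pair: AL = agar+light, AD = agar+dark, LL = liquid+light,
#' LD = liquid+dark.
#'
#' @param path path to a delimited text file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return a `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path, sep = ",") {
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata a candidate metadata `data.frame`.
#' @export
validate_sample_metadata <- function(metadata) {
  req <- c("sample_id", "medium", "light", "series")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  }
  if (!all(metadata$medium %in% c("agar", "liquid"))) {
    stop("medium must be 'agar' or 'liquid'")
  }
  if (!all(metadata$light %in% c("light", "dark"))) {
    stop("light must be 'light' or 'dark'")
  }
  if (!all(metadata$series %in% .SERIES_TABLE$series)) {
    stop("series must be one of AL, AD, LL, LD")
  }
  expected <- .SERIES_TABLE[match(metadata$series, .SERIES_TABLE$series), ]
  bad <- metadata$medium != expected$medium | metadata$light != expected$light
  if (any(bad)) {
    stop("series label inconsistent with (medium, light) for sample(s): ",
         paste(metadata$sample_id[bad], collapse = ", "))
  }
  if (is.null(metadata$strain)) metadata$strain <- "unknown"
  if (is.null(metadata$source_lab)) metadata$source_lab <- "unknown"
  rownames(metadata) <- metadata$sample_id
  metadata
}

#' Construct a validated expression dataset
#'
#' Bundles a non-negative FPKM matrix (genes x samples) with per-sample
#' metadata into a [SummarizedExperiment::SummarizedExperiment] with assay
#' `"fpkm"`. Every matrix column must have a metadata row; duplicate gene ids
#' and negative values are fatal.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param metadata `data.frame` as returned by [read_sample_metadata()].
#' @return a `SummarizedExperiment` with assay `fpkm`.
#' @export
expression_dataset <- function(values, metadata) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id(s): ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))]), 5),
               collapse = ", "))
  }
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (any(values < 0)) stop("expression matrix contains negative values")
  metadata <- validate_sample_metadata(metadata)
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent) > 0) {
    stop("no metadata for sample(s): ", paste(absent, collapse = ", "))
  }
  metadata <- metadata[colnames(values), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = values),
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id)
  )
}

#' Load an FPKM matrix with sample metadata
#'
#' Reads a delimited text matrix (gene ids in the first column, one column
#' per sample, header row of sample ids) and a metadata table, validates
#' them, and returns a `SummarizedExperiment`. Column order from the matrix
#' file is preserved.
#'
#' @param matrix_path path to the expression matrix file.
#' @param metadata_path path to the sample metadata file.
#' @param sep field separator for both files (default comma; use `"\t"`
#'   for tab-separated input).
#' @return a `SummarizedExperiment` with assay `fpkm`.
#' @export
load_expression <- function(matrix_path, metadata_path, sep = ",") {
  raw <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  gene_ids <- as.character(raw[[1]])
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  metadata <- read_sample_metadata(metadata_path, sep = sep)
  expression_dataset(values, metadata)
}

#' Remove genes with low reference-group expression
#'
#' Keeps exactly the genes whose arithmetic mean FPKM over the reference
#' samples is at least `threshold`. Filtering is computed on raw
#' (pre-floor) values; all samples are retained and gene order is preserved.
#'
#' @param x `SummarizedExperiment` with assay `fpkm`.
#' @param reference_samples sample ids over which the mean is taken
#'   (default: all samples).
#' @param threshold minimum mean FPKM (default 1).
#' @return the filtered `SummarizedExperiment`.
#' @export
filter_low_expression <- function(x, reference_samples = NULL, threshold = 1) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (is.null(reference_samples)) reference_samples <- colnames(x)
  if (length(reference_samples) == 0) stop("reference sample set is empty")
  absent <- setdiff(reference_samples, colnames(x))
  if (length(absent) > 0) {
    stop("reference sample(s) not in matrix: ", paste(absent, collapse = ", "))
  }
  fpkm <- SummarizedExperiment::assay(x, "fpkm")
  keep <- rowMeans(fpkm[, reference_samples, drop = FALSE]) >= threshold
  if (!any(keep)) stop("filtering removed every gene")
  message(sprintf("filter_low_expression: kept %d of %d genes (mean FPKM >= %g over %d reference samples)",
                  sum(keep), length(keep), threshold, length(reference_samples)))
  x[keep, ]
}

#' Floor low FPKM values
#'
#' Replaces every value below `floor` with `floor` so logarithms are finite.
#'
#' @param x `SummarizedExperiment` with assay `fpkm`.
#' @param floor positive replacement value (default 0.01 FPKM).
#' @return the floored `SummarizedExperiment`.
#' @export
apply_floor <- function(x, floor = 0.01) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    stop("floor must be a single positive number")
  }
  fpkm <- SummarizedExperiment::assay(x, "fpkm")
  n_floored <- sum(fpkm < floor)
  fpkm[fpkm < floor] <- floor
  message(sprintf("apply_floor: substituted %d cell(s) below %g FPKM", n_floored, floor))
  SummarizedExperiment::assay(x, "fpkm") <- fpkm
  x
}

#' Natural-log transform an expression dataset
#'
#' @param x `SummarizedExperiment` with strictly positive assay `fpkm`
#'   (apply [apply_floor()] first).
#' @return a `SummarizedExperiment` with assay `ln_fpkm`.
#' @export
to_log <- function(x) {
  fpkm <- SummarizedExperiment::assay(x, "fpkm")
  if (any(fpkm <= 0)) {
    stop("matrix contains non-positive values; run apply_floor() before to_log()")
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(ln_fpkm = log(fpkm)),
    colData = SummarizedExperiment::colData(x)
  )
}

#' Filter, floor and log-transform in one step
#'
#' Convenience wrapper running [filter_low_expression()], [apply_floor()]
#' and [to_log()] with the study defaults (filter on the agar series at
#' 1 FPKM when `reference_samples = "agar"`, floor at 0.01 FPKM).
#'
#' @param x `SummarizedExperiment` with assay `fpkm`.
#' @param reference_samples sample ids, or the shorthand `"agar"` /
#'   `"liquid"` to select by growth medium, or `NULL` for all samples.
#' @param threshold,floor see [filter_low_expression()] and [apply_floor()].
#' @return a `SummarizedExperiment` with assay `ln_fpkm`.
#' @export
prepare_expression <- function(x, reference_samples = "agar", threshold = 1,
                               floor = 0.01) {
  if (is.character(reference_samples) && length(reference_samples) == 1 &&
      reference_samples %in% c("agar", "liquid")) {
    md <- SummarizedExperiment::colData(x)
    reference_samples <- rownames(md)[md$medium == reference_samples]
  }
  x <- filter_low_expression(x, reference_samples, threshold)
  x <- apply_floor(x, floor)
  to_log(x)
}

# Extract the ln-expression matrix from a SummarizedExperiment or matrix.
.as_log_matrix <- function(y) {
  if (methods::is(y, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(y)
    if ("ln_fpkm" %in% nm) {
      return(SummarizedExperiment::assay(y, "ln_fpkm"))
    }
    stop("SummarizedExperiment has no 'ln_fpkm' assay; run to_log() first")
  }
  if (!is.matrix(y) || !is.numeric(y)) stop("expected a numeric matrix or SummarizedExperiment")
  y
}

# Sample metadata as a plain data.frame (NULL when unavailable).
.sample_metadata <- function(y) {
  if (methods::is(y, "SummarizedExperiment")) {
    as.data.frame(SummarizedExperiment::colData(y))
  } else {
    NULL
  }
}
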