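#' Construct an expression dataset
#'
#' Bundles a feature-by-sample abundance matrix with per-sample metadata and
#' an explicit scale flag. This is the container consumed by every analysis
#' in the package: transcript quantities (TPM/FPKM) or protein quantities
#' (iBAQ, LFQ, TMT), on linear or log2 scale.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row
#'   and column names are required and must be unique. Missing quantities are
#'   `NA`; on the linear scale all observed values must be non-negative.
#' @param meta Data frame with one row per sample and columns `sample`,
#'   `condition`, `replicate`, `layer` (one of `"rna"`, `"protein"`) and
#'   optionally `species`. Order is aligned to `colnames(values)`.
#' @param scale Either `"linear"` or `"log2"`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (matrix), `meta` (tibble) and `scale`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- tibble::tibble(sample = paste0("s", 1:4),
#'                        condition = rep(c("t0", "t1"), each = 2),
#'                        replicate = rep(c("r1", "r2"), 2),
#'                        layer = "rna")
#' ds <- expression_dataset(m, meta, scale = "log2")
expression_dataset <- function(values, meta, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have feature rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("Feature ids must be unique.")
  if (anyDuplicated(colnames(values))) abort("Sample ids must be unique.")
  meta <- as_tibble(meta)
  required <- c("sample", "condition", "replicate", "layer")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("`meta` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"species" %in% names(meta)) meta$species <- NA_character_
  for (nm in c("sample", "condition", "replicate", "layer", "species")) {
    meta[[nm]] <- as.character(meta[[nm]])
  }
  if (!setequal(meta$sample, colnames(values)) ||
      anyDuplicated(meta$sample)) {
    abort("`meta$sample` must match the sample columns of `values` exactly.")
  }
  meta <- meta[match(colnames(values), meta$sample), ]
  if (!all(meta$layer %in% c("rna", "protein"))) {
    abort("`meta$layer` values must be \"rna\" or \"protein\".")
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    abort("Linear-scale abundances must be non-negative.")
  }
  structure(list(values = values, meta = meta, scale = scale),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " features x ",
      ncol(x$values), " samples (", x$scale, " scale)\n", sep = "")
  cat("  layers: ", paste(unique(x$meta$layer), collapse = ", "),
      "; conditions: ", paste(unique(x$meta$condition), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Convert an expression dataset between linear and log2 scale
#'
#' @param dataset An [expression_dataset()].
#' @param to Target scale, `"linear"` or `"log2"`.
#' @param offset Added before taking log2 when converting linear to log2
#'   (guards zeros); default 0.
#' @return An `expression_dataset` on the requested scale.
#' @export
convert_scale <- function(dataset, to = c("linear", "log2"), offset = 0) {
  to <- match.arg(to)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale == to) return(dataset)
  v <- dataset$values
  v <- if (to == "log2") log2(v + offset) else 2^v
  expression_dataset(v, dataset$meta, scale = to)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix file is TSV with first column `feature` and one column per
#' sample; missing values are the literal string `NA`. The metadata file is
#' TSV with columns `sample`, `condition`, `replicate`, `layer` and
#' optionally `species`.
#'
#' @param values_path,meta_path Paths to the two TSV files.
#' @param scale Scale flag of the stored values.
#' @return [read_expression_tsv()] returns an `expression_dataset`;
#'   [write_expression_tsv()] returns its input invisibly.
#' @export
read_expression_tsv <- function(values_path, meta_path,
                                scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- readr::read_tsv(values_path, show_col_types = FALSE, na = "NA")
  if (names(tab)[1] != "feature") {
    abort("Expression TSV must have `feature` as its first column.")
  }
  m <- as.matrix(tab[-1])
  rownames(m) <- tab$feature
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, na = "NA")
  expression_dataset(m, meta, scale = scale)
}

#' @rdname read_expression_tsv
#' @param dataset An `expression_dataset` to write.
#' @export
write_expression_tsv <- function(dataset, values_path, meta_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- bind_cols_feature(dataset$values)
  readr::write_tsv(tab, values_path, na = "NA")
  readr::write_tsv(dataset$meta, meta_path, na = "NA")
  invisible(dataset)
}

bind_cols_feature <- function(m) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(feature = rownames(m)), out)
  out
}

#' Subset an expression dataset to one layer
#'
#' @param dataset An `expression_dataset`.
#' @param layer `"rna"` or `"protein"`.
#' @return An `expression_dataset` containing only the requested samples.
#' @export
dataset_layer <- function(dataset, layer) {
  stopifnot(inherits(dataset, "expression_dataset"))
  keep <- dataset$meta$layer == layer
  if (!any(keep)) abort(paste0("No samples with layer \"", layer, "\"."))
  expression_dataset(dataset$values[, keep, drop = FALSE],
                     dataset$meta[keep, ], scale = dataset$scale)
}
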