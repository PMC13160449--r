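#' Construct a single-modality cell-by-feature matrix
#'
#' The basic data container of the package: a numeric matrix with cells in
#' rows and features in columns, plus unique cell and feature identifiers,
#' optional per-cell type labels and a modality tag ("rna", "protein",
#' "atac", ...). Values are expected to be preprocessed (normalized,
#' log-transformed and/or scaled) measurements; see
#' [preprocess_modality()].
#'
#' @param values numeric matrix (dense) or sparse `Matrix`, cells x features.
#' @param feature_ids character vector of unique feature names; defaults to
#'   `colnames(values)`.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `rownames(values)`.
#' @param cell_type_labels optional character vector of per-cell labels.
#' @param modality_tag short string naming the modality.
#' @return An object of class `modality_matrix` with elements `values`,
#'   `feature_ids`, `cell_ids`, `cell_type_labels`, `modality_tag`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' mm <- modality_matrix(m, modality_tag = "rna")
#' mm
#' @export
modality_matrix <- function(values, feature_ids = colnames(values),
                            cell_ids = rownames(values),
                            cell_type_labels = NULL,
                            modality_tag = "modality") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop_mmihcl("`values` must be a matrix or sparse Matrix")
  n <- nrow(values); p <- ncol(values)
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(p))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != p)
    stop_mmihcl("length(feature_ids) != number of feature columns")
  if (length(cell_ids) != n)
    stop_mmihcl("length(cell_ids) != number of cell rows")
  if (anyDuplicated(feature_ids))
    stop_mmihcl("duplicate feature_ids: ",
                paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop_mmihcl("duplicate cell_ids")
  if (n < 2) stop_mmihcl("a modality needs at least 2 cells")
  if (p < 1) stop_mmihcl("a modality needs at least 1 feature")
  if (is.matrix(values) && !is.numeric(values))
    stop_mmihcl("`values` must be numeric")
  dense_chunk <- if (is.matrix(values)) values else values@x
  if (anyNA(dense_chunk) || any(!is.finite(dense_chunk)))
    stop_mmihcl("`values` contains missing or non-finite entries")
  if (!is.null(cell_type_labels)) {
    cell_type_labels <- as.character(cell_type_labels)
    if (length(cell_type_labels) != n)
      stop_mmihcl("cell_type_labels must have one entry per cell")
  }
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, feature_ids = feature_ids, cell_ids = cell_ids,
         cell_type_labels = cell_type_labels,
         modality_tag = as.character(modality_tag)[1]),
    class = "modality_matrix")
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix '%s'> %d cells x %d features (%s)\n",
              x$modality_tag, nrow(x$values), ncol(x$values),
              if (inherits(x$values, "Matrix")) "sparse" else "dense"))
  if (!is.null(x$cell_type_labels)) {
    tab <- table(x$cell_type_labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  steps <- attr(x, "preprocessing_log")
  if (!is.null(steps)) cat("  preprocessing:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.modality_matrix <- function(x) dim(x$values)

# coerce a modality_matrix or plain matrix to a base dense matrix
as_dense_values <- function(x) {
  v <- if (inherits(x, "modality_matrix")) x$values else x
  if (inherits(v, "Matrix")) v <- as.matrix(v)
  v
}

#' Load a modality matrix from disk
#'
#' Reads a cell-by-feature matrix in one of three dialects:
#' \describe{
#'   \item{`csv`}{delimited text, header row = feature ids, first column =
#'     cell ids. `sep` defaults to `","`; pass `sep = "\t"` for TSV.}
#'   \item{`mtx`}{MatrixMarket coordinate triplet in the common single-cell
#'     convention (features in rows, cells in columns), with sidecar
#'     `features.tsv` and `barcodes.tsv` files next to it (or given
#'     explicitly). The matrix is transposed to cells x features and kept
#'     sparse.}
#'   \item{`h5`}{an annotated single-cell HDF5 container (X plus obs/var
#'     names). Requires the optional `hdf5r` package.}
#' }
#'
#' @param path file path (for `mtx`, the `.mtx` file).
#' @param format one of `"csv"`, `"mtx"`, `"h5"`.
#' @param label_key optional: for `csv` the name of a label column to split
#'   off as `cell_type_labels`; for `h5` the obs column holding labels.
#' @param modality_tag modality tag for the result.
#' @param sep field separator for `csv`.
#' @param features_path,cells_path sidecar paths for `mtx`; default to
#'   `features.tsv` / `barcodes.tsv` in the directory of `path`.
#' @return A [modality_matrix()].
#' @export
load_modality <- function(path, format = c("csv", "mtx", "h5"),
                          label_key = NULL, modality_tag = "modality",
                          sep = ",", features_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mmihcl("file not found: ", path)
  switch(format,
    csv = load_modality_csv(path, label_key, modality_tag, sep),
    mtx = load_modality_mtx(path, features_path, cells_path, modality_tag),
    h5  = load_modality_h5(path, label_key, modality_tag))
}

load_modality_csv <- function(path, label_key, modality_tag, sep) {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", row.names = NULL)
  if (ncol(df) < 2)
    stop_mmihcl("CSV must have a cell-id column plus at least one feature")
  cell_ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  labels <- NULL
  if (!is.null(label_key)) {
    if (!label_key %in% colnames(df))
      stop_mmihcl("label column '", label_key, "' not found in ", path)
    labels <- df[[label_key]]
    df <- df[, setdiff(colnames(df), label_key), drop = FALSE]
  }
  vals <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    col <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(col) & !(df[[j]] %in% c("NA", "")))
    if (length(bad))
      stop_mmihcl(sprintf(
        "parse error in %s: non-numeric value '%s' at data row %d, column '%s'",
        path, df[[j]][bad[1]], bad[1], colnames(df)[j]))
    vals[, j] <- col
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_mmihcl(sprintf("parse error in %s: missing value at data row %d, column '%s'",
                        path, idx[1], colnames(df)[idx[2]]))
  }
  modality_matrix(vals, feature_ids = colnames(df), cell_ids = cell_ids,
                  cell_type_labels = labels, modality_tag = modality_tag)
}

load_modality_mtx <- function(path, features_path, cells_path, modality_tag) {
  dir <- dirname(path)
  features_path <- features_path %||% file.path(dir, "features.tsv")
  cells_path <- cells_path %||% file.path(dir, "barcodes.tsv")
  for (p in c(features_path, cells_path))
    if (!file.exists(p)) stop_mmihcl("MTX sidecar file not found: ", p)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop_mmihcl("malformed MTX file ", path, ": ",
                                                conditionMessage(e)))
  feats <- read.delim(features_path, header = FALSE, colClasses = "character")[[1]]
  cells <- read.delim(cells_path, header = FALSE, colClasses = "character")[[1]]
  if (length(feats) != nrow(m))
    stop_mmihcl(sprintf("features.tsv has %d entries but MTX declares %d rows",
                        length(feats), nrow(m)))
  if (length(cells) != ncol(m))
    stop_mmihcl(sprintf("barcodes.tsv has %d entries but MTX declares %d columns",
                        length(cells), ncol(m)))
  m <- Matrix::t(m)  # features x cells -> cells x features, stays sparse
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  modality_matrix(m, feature_ids = feats, cell_ids = cells,
                  modality_tag = modality_tag)
}

load_modality_h5 <- function(path, label_key, modality_tag) {
  if (!requireNamespace("hdf5r", quietly = TRUE))
    stop_mmihcl("reading annotated HDF5 containers requires the 'hdf5r' package; ",
                "use the CSV or MTX readers instead")
  h5 <- hdf5r::H5File$new(path, mode = "r")
  on.exit(h5$close_all(), add = TRUE)
  x <- h5[["X"]]$read()
  feats <- h5[["var/_index"]]$read()
  cells <- h5[["obs/_index"]]$read()
  labels <- if (!is.null(label_key)) h5[[paste0("obs/", label_key)]]$read() else NULL
  modality_matrix(t(x), feature_ids = feats, cell_ids = cells,
                  cell_type_labels = labels, modality_tag = modality_tag)
}

#' Write a modality matrix to disk
#'
#' Inverse of [load_modality()] for the `csv` and `mtx` dialects; round
#' trips names bit-exactly and values to printed precision (CSV) or exactly
#' (MTX).
#'
#' @param x a [modality_matrix()].
#' @param path output path (for `mtx`, the `.mtx` file; sidecars are written
#'   next to it).
#' @param format `"csv"` or `"mtx"`.
#' @param sep field separator for CSV output.
#' @export
write_modality <- function(x, path, format = c("csv", "mtx"), sep = ",") {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cell_id = x$cell_ids, as.matrix(x$values),
                     check.names = FALSE)
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    m <- Matrix::t(methods::as(x$values, "CsparseMatrix"))
    Matrix::writeMM(m, path)
    dir <- dirname(path)
    writeLines(x$feature_ids, file.path(dir, "features.tsv"))
    writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Standard preprocessing for a modality
#'
#' The conventional normalization chain for count-like single-cell data,
#' applied in order and logged on the returned object: per-cell total-count
#' normalization to the median library size, `log1p`, and per-feature
#' standardization (features with zero variance are centred only). Each step
#' is optional so intensity-style modalities (e.g. protein panels) can skip
#' the count-specific steps.
#'
#' @param x a [modality_matrix()].
#' @param normalize scale each cell so its total equals the median cell total.
#' @param log1p apply `log(1 + v)`.
#' @param scale centre each feature and divide by its standard deviation.
#' @return The preprocessed [modality_matrix()] (dense), with a
#'   `preprocessing_log` attribute recording the applied steps.
#' @export
preprocess_modality <- function(x, normalize = TRUE, log1p = TRUE, scale = TRUE) {
  v <- as_dense_values(x)
  log_steps <- character()
  if (normalize) {
    totals <- rowSums(v)
    if (any(totals <= 0))
      stop_mmihcl("cells with non-positive totals cannot be library-size normalized")
    v <- v * (stats::median(totals) / totals)
    log_steps <- c(log_steps, "median-total normalization")
  }
  if (log1p) {
    if (any(v < -1)) stop_mmihcl("log1p requires values > -1")
    v <- base::log1p(v)
    log_steps <- c(log_steps, "log1p")
  }
  if (scale) {
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    v <- sweep(v, 2, mu, "-")
    pos <- sdv > 0
    v[, pos] <- sweep(v[, pos, drop = FALSE], 2, sdv[pos], "/")
    log_steps <- c(log_steps, "per-feature standardization")
  }
  out <- modality_matrix(v, feature_ids = x$feature_ids, cell_ids = x$cell_ids,
                         cell_type_labels = x$cell_type_labels,
                         modality_tag = x$modality_tag)
  attr(out, "preprocessing_log") <- c(attr(x, "preprocessing_log"), log_steps)
  out
}
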