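#' Read a single-cell count matrix
#'
#' Reads a genes x cells matrix of non-negative integer counts, either from a
#' Matrix Market triplet file with 10x-style `features`/`genes` and `barcodes`
#' sidecar files, or from a delimited text file with genes in rows (by
#' default) and a header row of cell identifiers.
#'
#' @param path Path to the `.mtx` (optionally gzipped) file, or to the CSV.
#' @param format One of `"auto"`, `"mtx"`, `"csv"`. `"auto"` decides from the
#'   file extension.
#' @param genes_in_rows For CSV input, whether rows are genes (default). Set
#'   to `FALSE` to transpose a cells-in-rows export.
#' @return A genes x cells matrix (sparse [Matrix::dgCMatrix-class] for MTX,
#'   dense base matrix for CSV) with unique gene rownames and cell colnames.
#'   All entries are validated to be non-negative integers.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' write.csv(m, file.path(dir, "counts.csv"))
#' counts <- read_counts(file.path(dir, "counts.csv"))
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        genes_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "csv"
  }
  counts <- if (format == "mtx") .read_mtx(path) else {
    .read_csv_counts(path, genes_in_rows)
  }
  .validate_counts(counts)
  counts
}

.read_mtx <- function(path) {
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed MTX file '", path, "': ",
                                         conditionMessage(e)))
  dir <- dirname(path)
  find_sidecar <- function(stems) {
    for (stem in stems) {
      for (ext in c("", ".gz")) {
        p <- file.path(dir, paste0(stem, ext))
        if (file.exists(p)) return(p)
      }
    }
    stop("no sidecar file (", paste(stems, collapse = "/"),
         ") found next to ", path)
  }
  feat <- utils::read.table(
    find_sidecar(c("features.tsv", "genes.tsv", "features.txt", "genes.txt")),
    sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  barc <- utils::read.table(
    find_sidecar(c("barcodes.tsv", "barcodes.txt")),
    sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feat) != nrow(m)) stop("features sidecar has ", nrow(feat),
                                  " rows but matrix has ", nrow(m))
  if (nrow(barc) != ncol(m)) stop("barcodes sidecar has ", nrow(barc),
                                  " rows but matrix has ", ncol(m))
  rownames(m) <- feat[[1]]
  colnames(m) <- barc[[1]]
  methods::as(m, "CsparseMatrix")
}

.read_csv_counts <- function(path, genes_in_rows) {
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE),
    error = function(e) stop("malformed CSV file '", path, "': ",
                             conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in '", path, "'")
  if (!genes_in_rows) m <- t(m)
  m
}

#' Write and re-read the four result tables
#'
#' The output of a fitted cluster tree is a list of four tables: `meta`
#' (cluster label, size, robustness, parent), `samples` (one row per cell,
#' its cluster label at every resolution), `features` (marker genes with
#' log2 fold changes and p-values per cluster) and `methods` (which base
#' clustering methods contributed to each cluster). `write_result_tables()`
#' writes them as `meta.csv`, `samples.csv`, `features.csv` and `methods.csv`;
#' numeric columns are serialized with 17 significant digits so that
#' [read_result_tables()] reproduces them bit-exactly.
#'
#' @param tables A named list with elements `meta`, `samples`, `features`,
#'   `methods` (data frames), e.g. the `tables` element of an
#'   [ensemble_tree()] fit.
#' @param out_dir Directory to write into (created if absent).
#' @return `write_result_tables()` returns the four file paths invisibly;
#'   `read_result_tables()` returns the list of tables.
#' @export
write_result_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables),
            all(c("meta", "samples", "features", "methods") %in% names(tables)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in c("meta", "samples", "features", "methods")) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    .write_csv_exact(tables[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' @rdname write_result_tables
#' @param dir Directory containing the four CSV files.
#' @export
read_result_tables <- function(dir) {
  out <- list()
  for (nm in c("meta", "samples", "features", "methods")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing result table: ", p)
    out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE,
                                 check.names = FALSE)
  }
  out
}

# Write a data frame as comma-separated UTF-8 with "." decimal and no row
# index; doubles are printed with 17 significant digits so as.numeric()
# recovers them bit-exactly.
.write_csv_exact <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}
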