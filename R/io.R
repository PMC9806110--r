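#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' Writes `matrix.mtx` (genes x cells, the 10x orientation), `genes.tsv`
#' and `barcodes.tsv` into `dir`.
#'
#' @param counts cells x genes matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(Matrix::Matrix(Matrix::t(counts), sparse = TRUE),
                    "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(colnames(counts), colnames(counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(rownames(counts)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from a 10x triplet directory or a dense CSV
#'
#' Accepts either a directory holding `matrix.mtx` + `genes.tsv` (or
#' `features.tsv`) + `barcodes.tsv`, or the path of a dense CSV with cells
#' as rows (first column = cell id) and genes as columns.
#'
#' @param path directory or CSV file path.
#' @return Sparse cells x genes `dgCMatrix` with cell rownames and gene
#'   colnames.
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    if (!file.exists(genes_f)) genes_f <- file.path(path, "features.tsv")
    bc_f <- file.path(path, "barcodes.tsv")
    if (!file.exists(mtx) || !file.exists(genes_f) || !file.exists(bc_f)) {
      stop("directory must contain matrix.mtx, genes.tsv/features.tsv ",
           "and barcodes.tsv")
    }
    m <- Matrix::t(Matrix::readMM(mtx))  # stored genes x cells
    genes <- utils::read.table(genes_f, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.table(bc_f, sep = "\t",
                                  stringsAsFactors = FALSE)[[1]]
    dimnames(m) <- list(barcodes, genes)
    return(methods::as(m, "CsparseMatrix"))
  }
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE),
              "CsparseMatrix")
}

#' Write an expression or score matrix as dense CSV
#'
#' Cells/samples as rows (first column holds the row id).
#'
#' @param x matrix with rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(x, path) {
  utils::write.csv(as.matrix(x), path, quote = FALSE)
  invisible(path)
}

#' Read a samples x genes expression CSV
#'
#' @param path CSV with sample ids in the first column.
#' @return Numeric matrix with sample rownames.
#' @export
read_expression_csv <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
}

#' Write / read a marker panel as JSON
#'
#' @param panel a [marker_panel()].
#' @param path JSON file path.
#' @return `path` invisibly (write); a `marker_panel` (read).
#' @export
write_panel_json <- function(panel, path) {
  panel <- as_marker_panel(panel)
  jsonlite::write_json(list(panels = panel$panels,
                            selection_params = panel$selection_params),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_panel(as.list(obj$panels),
               selection_params = as.list(obj$selection_params))
}

#' Write / read a survival table as CSV
#'
#' Columns: `sample_id`, `time`, `event` and optionally `group`.
#'
#' @param table survival data.frame.
#' @param path CSV path.
#' @return `path` invisibly (write); a validated data.frame (read).
#' @export
write_survival_csv <- function(table, path) {
  check_survival_table(table)
  utils::write.csv(table, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_survival_table(tbl)
  tbl
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `truth` list from one of the simulators.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
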