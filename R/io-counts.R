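# Count-matrix and metadata I/O: MTX triplet (with feature/barcode TSVs)
# or dense TSV, plus per-cell metadata.

#' Read an isoform-by-cell count matrix with cell metadata
#'
#' Accepts either an MTX triplet (`matrix.mtx` plus `features.tsv` with
#' columns transcript_id, gene_id, and `barcodes.tsv`) or a dense TSV whose
#' first two columns are `transcript_id` and `gene_id` and remaining columns
#' are cells.
#'
#' @param matrix_path path to `matrix.mtx` or a dense counts TSV.
#' @param metadata_path TSV keyed by `cell_id` with columns `patient`,
#'   `batch`, `tissue`, `cell_type` (extra columns kept).
#' @return An [expr_matrix()].
#' @export
read_counts <- function(matrix_path, metadata_path) {
  if (grepl("\\.mtx$", matrix_path)) {
    dir <- dirname(matrix_path)
    m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
    feats <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
    cells <- read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
    if (nrow(feats) != nrow(m) || nrow(cells) != ncol(m))
      stop("matrix dimensions do not match feature/barcode files")
    dimnames(m) <- list(feats$transcript_id, cells$cell_id)
    gene_map <- setNames(feats$gene_id, feats$transcript_id)
  } else {
    d <- read.table(matrix_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
    gene_map <- setNames(d$gene_id, d$transcript_id)
    m <- as.matrix(d[, -(1:2), drop = FALSE])
    rownames(m) <- d$transcript_id
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  v <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stop("count matrix has negative or non-integer entries")
  meta <- read.table(metadata_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  missing <- setdiff(colnames(m), meta$cell_id)
  if (length(missing))
    stop("cells absent from metadata: ", paste(head(missing, 5), collapse = ", "))
  expr_matrix(m, gene_map, meta)
}

#' Write an expression matrix as MTX triplet, dense TSV and metadata TSV
#'
#' @param em an [expr_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(em, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(em$counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  write.table(data.frame(transcript_id = rownames(em$counts),
                         gene_id = unname(em$gene_map)),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = colnames(em$counts)),
              file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dense <- data.frame(transcript_id = rownames(em$counts),
                      gene_id = unname(em$gene_map),
                      as.matrix(em$counts), check.names = FALSE)
  write.table(dense, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(em$metadata, file.path(dir, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
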