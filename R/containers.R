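#' @importFrom Matrix Matrix rowSums colSums t readMM writeMM sparseMatrix
#' @importFrom stats wilcox.test p.adjust pbinom phyper fisher.test cor cor.test
#'   hclust cutree dist rnbinom rpois rbinom rlnorm rnorm runif rgamma var sd
#'   quantile setNames aggregate lm as.formula median complete.cases
#' @importFrom utils read.table write.table head modifyList
#' @importFrom methods as is
NULL

# ---------------------------------------------------------------------------
# transcript_models: exon/CDS structure per isoform, the source of UTR lengths
# and local splicing events.
# ---------------------------------------------------------------------------

#' Construct a transcript model set
#'
#' Container for isoform structures: one row per transcript with its gene,
#' location, strand and derived UTR/CDS lengths, plus exon and CDS interval
#' tables (1-based inclusive genomic coordinates, GTF convention).
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `ccds_id` (NA allowed), `utr3_len`, `utr5_len`,
#'   `cds_len`, `tx_len`, `coding`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#' @param cds data.frame with columns `transcript_id`, `start`, `end`
#'   (zero rows allowed).
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, exons, cds) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons), is.data.frame(cds))
  need <- c("transcript_id", "gene_id", "chrom", "strand", "ccds_id",
            "utr3_len", "utr5_len", "cds_len", "tx_len", "coding")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) stop("transcripts missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in transcript table")
  ord <- order(transcripts$gene_id, transcripts$transcript_id)
  transcripts <- transcripts[ord, , drop = FALSE]
  rownames(transcripts) <- NULL
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons, cds = cds),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d genes, %d exon records\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

# exon intervals of one transcript, sorted by start
tx_exons <- function(tm, tx) {
  e <- tm$exons[tm$exons$transcript_id == tx, c("start", "end"), drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

tx_cds <- function(tm, tx) {
  e <- tm$cds[tm$cds$transcript_id == tx, c("start", "end"), drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# expr_matrix: isoform x cell counts plus per-cell metadata.
# ---------------------------------------------------------------------------

#' Construct an expression matrix object
#'
#' @param counts isoform x cell matrix of non-negative integer counts
#'   (dense or `Matrix` sparse); rownames are transcript ids, colnames cell ids.
#' @param gene_map named character vector mapping transcript_id -> gene_id;
#'   must cover every row of `counts`.
#' @param metadata data.frame with one row per cell: columns `cell_id`,
#'   `patient`, `batch`, `tissue`, `cell_type`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, gene_map, metadata) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  cv <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(cv) && (any(cv < 0) || any(cv != floor(cv))))
    stop("counts must be non-negative integers")
  miss <- setdiff(rownames(counts), names(gene_map))
  if (length(miss))
    stop("gene_map missing transcripts: ", paste(head(miss, 5), collapse = ", "))
  need <- c("cell_id", "patient", "batch", "tissue", "cell_type")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  absent <- setdiff(colnames(counts), metadata$cell_id)
  if (length(absent))
    stop("cells missing from metadata: ", paste(head(absent, 5), collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$cell_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts,
                 gene_map = gene_map[rownames(counts)],
                 metadata = metadata),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d isoforms x %d cells (%d genes)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gene_map))))
  invisible(x)
}

#' Number of cells / features
#' @param x an `expr_matrix`
#' @return integer count
#' @export
n_cells <- function(x) ncol(x$counts)

# ---------------------------------------------------------------------------
# allelic_counts: per mutation site x cell (wt, mut, other) read counts.
# ---------------------------------------------------------------------------

#' Construct an allelic counts object
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene_id`.
#' @param wt,mut,other site x cell matrices of non-negative counts with
#'   identical dimnames; rownames are site ids.
#' @return An object of class `allelic_counts`.
#' @export
allelic_counts <- function(sites, wt, mut, other) {
  stopifnot(identical(dim(wt), dim(mut)), identical(dim(wt), dim(other)))
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  if (!identical(rownames(wt), sites$site_id))
    stop("count matrix rownames must equal sites$site_id")
  if (any(wt < 0) || any(mut < 0) || any(other < 0))
    stop("allele counts must be non-negative")
  structure(list(sites = sites, wt = wt, mut = mut, other = other),
            class = "allelic_counts")
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat(sprintf("allelic_counts: %d sites x %d cells\n",
              nrow(x$wt), ncol(x$wt)))
  invisible(x)
}
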