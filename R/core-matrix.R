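# Shared expression substrate: TPM normalization, cell/isoform QC, highly
# variable genes, Wilcoxon differential expression, isoform-complexity
# metrics and down-sampling.

#' Normalize counts to TPM and log expression
#'
#' TPM here is read counts per 1,000,000 mapped full-length reads for the
#' feature; the log view is the natural-log transform `log(TPM/10 + 1)`.
#'
#' @param m an [expr_matrix()].
#' @param level `"isoform"` (rows as-is) or `"gene"` (isoform counts summed
#'   per gene through the gene map).
#' @return list of class `norm_matrix` with elements `tpm`, `logexpr`
#'   (feature x cell dense matrices), `level`, `metadata` and, at isoform
#'   level, `gene_map`. All-zero cells give all-zero columns and are listed
#'   in attribute `"zero_cells"`.
#' @export
normalize_expression <- function(m, level = c("isoform", "gene")) {
  level <- match.arg(level)
  counts <- as.matrix(m$counts)
  if (level == "gene")
    counts <- rowsum(counts, group = m$gene_map[rownames(counts)])
  tot <- colSums(counts)
  zero <- colnames(counts)[tot == 0]
  tot[tot == 0] <- 1
  tpm <- sweep(counts, 2, tot, "/") * 1e6
  out <- list(tpm = tpm, logexpr = log(tpm / 10 + 1), level = level,
              metadata = m$metadata,
              gene_map = if (level == "isoform") m$gene_map else NULL)
  attr(out, "zero_cells") <- zero
  class(out) <- "norm_matrix"
  out
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix (%s level): %d features x %d cells\n",
              x$level, nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Quality-control filters for cells and isoforms
#'
#' Drops cells with fewer than `min_genes` detected genes (count >= 1) or a
#' mitochondrial count fraction strictly above `max_mito`; then keeps only
#' isoforms expressed (count >= 1) in at least `min_cells` cells in each of
#' at least `min_individuals` individuals (patients).
#'
#' @param m an [expr_matrix()].
#' @param mito_genes character vector of mitochondrial gene ids; if empty
#'   the mitochondrial rule is skipped with a warning.
#' @param min_genes,max_mito,min_cells,min_individuals thresholds.
#' @return The filtered [expr_matrix()]; attribute `"qc_report"` counts the
#'   cells/isoforms removed by each rule.
#' @export
qc_filters <- function(m, mito_genes = character(0), min_genes = 500,
                       max_mito = 0.60, min_cells = 3, min_individuals = 3) {
  counts <- m$counts
  gene_of <- m$gene_map[rownames(counts)]
  det <- rowsum((as.matrix(counts) >= 1) * 1L, group = gene_of)
  genes_per_cell <- colSums(det >= 1)
  drop_genes <- genes_per_cell < min_genes

  if (length(mito_genes)) {
    mito_tx <- rownames(counts)[gene_of %in% mito_genes]
    mito_frac <- Matrix::colSums(counts[mito_tx, , drop = FALSE]) /
      pmax(Matrix::colSums(counts), 1)
    drop_mito <- mito_frac > max_mito
  } else {
    warning("empty mitochondrial gene set; mitochondrial rule skipped")
    drop_mito <- rep(FALSE, ncol(counts))
  }
  keep_cells <- !(drop_genes | drop_mito)
  counts <- counts[, keep_cells, drop = FALSE]
  meta <- m$metadata[keep_cells, , drop = FALSE]

  # isoform rule: expressed in >= min_cells cells in >= min_individuals patients
  expressed <- as.matrix(counts) >= 1
  pat <- meta$patient
  per_pat <- t(rowsum(t(expressed) * 1L, group = pat))  # isoform x patient
  keep_iso <- rowSums(per_pat >= min_cells) >= min_individuals
  out <- expr_matrix(counts[keep_iso, , drop = FALSE],
                     m$gene_map[keep_iso], meta)
  attr(out, "qc_report") <- list(
    cells_low_genes = sum(drop_genes),
    cells_high_mito = sum(drop_mito & !drop_genes),
    isoforms_removed = sum(!keep_iso))
  out
}

#' Select highly variable genes per batch and return their union
#'
#' Within each batch, genes are ranked by standardized dispersion: variance
#' of log expression after removal of the binned mean-variance trend
#' (20 equal-frequency bins of mean log expression; dispersion is z-scored
#' within bin). Ties break by gene id.
#'
#' @param nm gene-level [normalize_expression()] result.
#' @param n number of genes per batch (default 1000).
#' @param batch per-cell batch labels; defaults to metadata `batch`.
#' @return character vector: union of per-batch top-`n` genes.
#' @export
select_hvg <- function(nm, n = 1000, batch = nm$metadata$batch) {
  if (n > nrow(nm$logexpr)) {
    warning("n exceeds gene count; returning all genes")
    return(sort(rownames(nm$logexpr)))
  }
  sel <- character(0)
  for (b in unique(batch)) {
    x <- nm$logexpr[, batch == b, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    bins <- cut(rank(mu, ties.method = "first"),
                breaks = 20, labels = FALSE)
    disp <- v
    for (k in unique(bins)) {
      i <- bins == k
      s <- sd(v[i])
      disp[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
    }
    ord <- order(-disp, rownames(x))
    sel <- union(sel, rownames(x)[ord[seq_len(n)]])
  }
  sort(sel)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per feature: two-sided rank-sum test on log expression between two cell
#' sets, BH-adjusted p, and fold change `(mean TPM A + 1)/(mean TPM B + 1)`.
#' Significant means adjusted p < `alpha` and fold change >= `fc_cut` or
#' <= 1/`fc_cut`.
#'
#' @param nm a [normalize_expression()] result (gene or isoform level).
#' @param group_a,group_b disjoint cell-id sets.
#' @param alpha,fc_cut significance thresholds (defaults 0.05 and 2).
#' @return data.frame: feature, mean_tpm_a, mean_tpm_b, fc, p, adj_p,
#'   significant.
#' @export
wilcoxon_de <- function(nm, group_a, group_b, alpha = 0.05, fc_cut = 2) {
  if (length(intersect(group_a, group_b)))
    stop("cell groups overlap")
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  a <- nm$logexpr[, group_a, drop = FALSE]
  b <- nm$logexpr[, group_b, drop = FALSE]
  ta <- nm$tpm[, group_a, drop = FALSE]
  tb <- nm$tpm[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(wilcox.test(x, y)$p.value)
  }, 0)
  ma <- rowMeans(ta); mb <- rowMeans(tb)
  fc <- (ma + 1) / (mb + 1)
  adj <- p.adjust(p, method = "BH")
  data.frame(feature = rownames(a), mean_tpm_a = ma, mean_tpm_b = mb,
             fc = fc, p = p, adj_p = adj,
             significant = (fc >= fc_cut | fc <= 1 / fc_cut) & adj < alpha,
             row.names = NULL)
}

#' Transcriptome complexity metrics
#'
#' Per cell: number of genes and isoforms detected. Per gene (pooled over
#' the given cells): expressed-isoform count, its bin (1, 2-3, 4-5, >=6)
#' and the expression share of the two most abundant isoforms.
#'
#' @param m an [expr_matrix()].
#' @param cells cell ids to pool (default all).
#' @return list with `per_cell` and `per_gene` data.frames and `bin_fractions`
#'   (fraction of expressed genes per isoform-count bin).
#' @export
complexity_metrics <- function(m, cells = colnames(m$counts)) {
  counts <- as.matrix(m$counts[, cells, drop = FALSE])
  gene_of <- m$gene_map[rownames(counts)]
  det <- counts >= 1
  per_cell <- data.frame(
    cell_id = cells,
    n_isoforms = colSums(det),
    n_genes = colSums(rowsum(det * 1L, group = gene_of) >= 1),
    row.names = NULL)
  pooled <- rowSums(counts)
  genes <- unique(gene_of)
  n_iso <- integer(length(genes)); top2 <- numeric(length(genes))
  for (i in seq_along(genes)) {
    v <- pooled[gene_of == genes[i]]
    v <- v[v > 0]
    n_iso[i] <- length(v)
    top2[i] <- if (length(v)) sum(sort(v, decreasing = TRUE)[seq_len(min(2, length(v)))]) / sum(v) else NA_real_
  }
  bin <- cut(n_iso, breaks = c(0.5, 1.5, 3.5, 5.5, Inf),
             labels = c("1", "2-3", "4-5", ">=6"))
  per_gene <- data.frame(gene_id = genes, n_isoforms = n_iso,
                         bin = bin, top2_share = top2, row.names = NULL)
  expressed <- per_gene[per_gene$n_isoforms > 0, , drop = FALSE]
  list(per_cell = per_cell, per_gene = per_gene,
       bin_fractions = table(expressed$bin) / nrow(expressed))
}

#' Down-sample cells and sequencing depth
#'
#' Subsamples `n_cells` cells without replacement, then binomially thins
#' each retained count at `depth_fraction`.
#'
#' @param m an [expr_matrix()].
#' @param n_cells cells to keep (default all).
#' @param depth_fraction in (0, 1].
#' @param seed integer seed.
#' @return A smaller [expr_matrix()].
#' @export
downsample_cells <- function(m, n_cells = ncol(m$counts), depth_fraction = 1,
                             seed = 1L) {
  if (depth_fraction <= 0 || depth_fraction > 1)
    stop("depth_fraction must lie in (0, 1]")
  if (n_cells > ncol(m$counts)) stop("n_cells exceeds available cells")
  set.seed(seed)
  keep <- sort(sample(colnames(m$counts), n_cells))
  counts <- as.matrix(m$counts[, keep, drop = FALSE])
  if (depth_fraction < 1) {
    thinned <- rbinom(length(counts), size = as.integer(counts),
                      prob = depth_fraction)
    counts <- matrix(thinned, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  }
  expr_matrix(Matrix::Matrix(counts, sparse = TRUE), m$gene_map,
              m$metadata[m$metadata$cell_id %in% keep, , drop = FALSE])
}
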