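# Gene-set module scoring with binned control genes, iCMS subtype
# assignment, and subtype-consistent differential expression / splicing.

#' Per-cell module score with binned control genes
#'
#' Genes are binned by average log expression into `n_bins`
#' equal-frequency bins; for each gene of the set, `n_ctrl` control genes
#' are sampled (with replacement when the bin is small) from the gene's
#' bin. The score of a cell is the mean expression of the set genes minus
#' the mean expression of the pooled control genes.
#'
#' @param nm gene-level [normalize_expression()] result.
#' @param gene_set character vector of gene ids; genes absent from the
#'   matrix are dropped (error if none remain).
#' @param n_bins,n_ctrl binning and control-sampling parameters (defaults
#'   25 and 100).
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(nm, gene_set, n_bins = 25, n_ctrl = 100, seed = 1L) {
  genes <- rownames(nm$logexpr)
  set <- intersect(gene_set, genes)
  if (!length(set))
    stop("no gene of the set is present in the matrix: ",
         paste(head(gene_set, 5), collapse = ", "))
  set.seed(seed)
  avg <- rowMeans(nm$logexpr)
  n_bins <- min(n_bins, length(genes))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- genes
  ctrl <- unlist(lapply(set, function(g) {
    pool <- genes[bins == bins[g]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  colMeans(nm$logexpr[set, , drop = FALSE]) -
    colMeans(nm$logexpr[ctrl, , drop = FALSE])
}

#' iCMS module scores and per-patient subtype assignment
#'
#' The score of a subtype is the module score of its upregulated marker
#' set minus that of its downregulated set. Each patient is assigned to
#' the subtype with the higher mean score over its cancer cells; a margin
#' below `tie_margin` leaves the patient unassigned.
#'
#' @param nm gene-level [normalize_expression()] result.
#' @param markers list with elements `icms2_up`, `icms2_down`, `icms3_up`,
#'   `icms3_down` (character vectors of gene ids).
#' @param cancer_cells cell ids of cancer cells.
#' @param patient named per-cell patient labels.
#' @param tie_margin minimum score margin for an assignment (default 0).
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return list: `scores` (per-cell data.frame with icms2_score and
#'   icms3_score), `assignment` (per-patient data.frame: patient,
#'   mean_icms2, mean_icms3, subtype).
#' @export
icms_assign <- function(nm, markers, cancer_cells, patient, tie_margin = 0,
                        n_bins = 25, n_ctrl = 100, seed = 1L) {
  need <- c("icms2_up", "icms2_down", "icms3_up", "icms3_down")
  if (!all(need %in% names(markers)))
    stop("markers must contain: ", paste(need, collapse = ", "))
  s2 <- module_score(nm, markers$icms2_up, n_bins, n_ctrl, seed) -
    module_score(nm, markers$icms2_down, n_bins, n_ctrl, seed + 1L)
  s3 <- module_score(nm, markers$icms3_up, n_bins, n_ctrl, seed + 2L) -
    module_score(nm, markers$icms3_down, n_bins, n_ctrl, seed + 3L)
  scores <- data.frame(cell_id = colnames(nm$logexpr),
                       icms2_score = unname(s2), icms3_score = unname(s3))
  cc <- intersect(cancer_cells, scores$cell_id)
  if (!length(cc)) stop("no cancer cells present in the matrix")
  pts <- unique(patient[cc])
  assign <- do.call(rbind, lapply(pts, function(pt) {
    cells <- cc[patient[cc] == pt]
    m2 <- mean(s2[cells]); m3 <- mean(s3[cells])
    sub <- if (abs(m2 - m3) <= tie_margin) "unassigned" else
      if (m2 > m3) "iCMS2" else "iCMS3"
    data.frame(patient = pt, mean_icms2 = m2, mean_icms3 = m3,
               subtype = sub, stringsAsFactors = FALSE)
  }))
  list(scores = scores, assignment = assign)
}

#' Subtype-consistent differential expression or splicing
#'
#' A feature is `Up in S` (expression mode) when it is upregulated in
#' subtype S versus both the other subtype and the normal comparator with
#' fold change >= `fc_cut` and p < `alpha` in both comparisons (and
#' `Down in S` symmetrically); a splicing event is subtype-specific when
#' its PSI is higher in S than in both comparators with dPSI >=
#' `min_dpsi` and p < `alpha`. Everything else is unclassified.
#'
#' @param x a gene/transcript-level [normalize_expression()] result
#'   (mode `"det"`) or a [compute_psi()] result (mode `"das"`).
#' @param groups named list of cell-id vectors: `icms2`, `icms3`, `normal`.
#' @param mode `"det"` or `"das"`.
#' @param alpha,fc_cut,min_dpsi thresholds (defaults 0.05, 2, 0.1).
#' @return data.frame: feature, class (`Up in iCMS2`, `Down in iCMS2`,
#'   `Up in iCMS3`, `Down in iCMS3`, `unclassified`), and the per-contrast
#'   statistics.
#' @export
subtype_consistent_changes <- function(x, groups, mode = c("det", "das"),
                                       alpha = 0.05, fc_cut = 2,
                                       min_dpsi = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(c("icms2", "icms3", "normal") %in% names(groups)))
  if (any(!lengths(groups[c("icms2", "icms3", "normal")])))
    stop("all three groups must be non-empty")
  if (mode == "det") {
    c2o <- wilcoxon_de(x, groups$icms2, groups$icms3, alpha = 1, fc_cut = 1)
    c2n <- wilcoxon_de(x, groups$icms2, groups$normal, alpha = 1, fc_cut = 1)
    c3o <- wilcoxon_de(x, groups$icms3, groups$icms2, alpha = 1, fc_cut = 1)
    c3n <- wilcoxon_de(x, groups$icms3, groups$normal, alpha = 1, fc_cut = 1)
    up <- function(d) d$fc >= fc_cut & d$p < alpha
    dn <- function(d) d$fc <= 1 / fc_cut & d$p < alpha
    cls <- rep("unclassified", nrow(c2o))
    cls[up(c2o) & up(c2n)] <- "Up in iCMS2"
    cls[dn(c2o) & dn(c2n)] <- "Down in iCMS2"
    cls[up(c3o) & up(c3n)] <- "Up in iCMS3"
    cls[dn(c3o) & dn(c3n)] <- "Down in iCMS3"
    return(data.frame(feature = c2o$feature, class = cls,
                      fc_vs_other_icms2 = c2o$fc, p_vs_other_icms2 = c2o$p,
                      fc_vs_normal_icms2 = c2n$fc, p_vs_normal_icms2 = c2n$p,
                      fc_vs_other_icms3 = c3o$fc, p_vs_other_icms3 = c3o$p,
                      fc_vs_normal_icms3 = c3n$fc, p_vs_normal_icms3 = c3n$p,
                      row.names = NULL))
  }
  d2o <- differential_splicing(x, groups$icms2, groups$icms3,
                               alpha = 1, min_dpsi = 0)
  d2n <- differential_splicing(x, groups$icms2, groups$normal,
                               alpha = 1, min_dpsi = 0)
  d3o <- differential_splicing(x, groups$icms3, groups$icms2,
                               alpha = 1, min_dpsi = 0)
  d3n <- differential_splicing(x, groups$icms3, groups$normal,
                               alpha = 1, min_dpsi = 0)
  hi <- function(d) !is.na(d$dpsi) & d$dpsi >= min_dpsi & d$p < alpha
  cls <- rep("unclassified", nrow(d2o))
  cls[hi(d2o) & hi(d2n)] <- "iCMS2 specific"
  cls[hi(d3o) & hi(d3n)] <- "iCMS3 specific"
  data.frame(feature = d2o$event_id, class = cls,
             dpsi_vs_other_icms2 = d2o$dpsi, p_vs_other_icms2 = d2o$p,
             dpsi_vs_normal_icms2 = d2n$dpsi, p_vs_normal_icms2 = d2n$p,
             dpsi_vs_other_icms3 = d3o$dpsi, p_vs_other_icms3 = d3o$p,
             dpsi_vs_normal_icms3 = d3n$dpsi, p_vs_normal_icms3 = d3n$p,
             row.names = NULL)
}
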