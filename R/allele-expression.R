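# Allele-specific expression from per-cell pileup counts at somatic
# mutation sites: wild-type / mutant / total allelic matrices, binomial
# mutation calling against the sequencing error rate, per-site mutant
# dominance, and allelic correlation-shift analysis against highly
# variable genes.

#' Assemble allelic expression matrices
#'
#' Builds the wild-type, mutant and total (wt + mut) site-by-cell count
#' matrices plus normalized views: counts per million mapped reads of the
#' cell (taken from the expression matrix), log-transformed as
#' `log(CPM/10 + 1)`.
#'
#' @param ac an [allelic_counts()].
#' @param m an [expr_matrix()] sharing cells with `ac` (used for per-cell
#'   total mapped reads).
#' @return list of class `allelic_matrices`: `e_wt`, `e_mut`, `e_tot`
#'   (counts), `log_wt`, `log_mut`, `log_tot` (normalized), `uncovered`
#'   (site ids with zero coverage everywhere).
#' @export
build_allelic_matrices <- function(ac, m) {
  cells <- intersect(colnames(ac$wt), colnames(m$counts))
  if (!length(cells)) stop("no shared cells between allelic and expression data")
  e_wt <- ac$wt[, cells, drop = FALSE]
  e_mut <- ac$mut[, cells, drop = FALSE]
  e_tot <- e_wt + e_mut
  lib <- Matrix::colSums(m$counts)[cells]
  lib[lib == 0] <- 1
  norm <- function(x) log(sweep(x, 2, lib, "/") * 1e6 / 10 + 1)
  structure(list(e_wt = e_wt, e_mut = e_mut, e_tot = e_tot,
                 log_wt = norm(e_wt), log_mut = norm(e_mut),
                 log_tot = norm(e_tot),
                 uncovered = rownames(e_tot)[rowSums(e_tot) == 0]),
            class = "allelic_matrices")
}

#' Call mutations per cell with a binomial sequencing-error model
#'
#' The sequencing error rate is estimated from reads matching neither
#' allele: `eps = C_other / (C_wt + C_mut + C_other)`, pooled per site
#' across cells by default (the per-cell estimate degenerates to zero
#' whenever no other-base read is seen, which would make any single mutant
#' read significant) and lower-bounded by `epsilon_floor`. Under the null
#' that mutant reads arise from sequencing error, the one-sided p-value is
#' `P(X >= C_mut)` for `X ~ Binomial(C_wt + C_mut + C_other, eps)`.
#' P-values are BH-adjusted across all tested (site, cell) pairs. A call
#' is confirmed when FDR < `fdr_cut` and allelic coverage `C_wt + C_mut`
#' is at least 3 in cancer cells or at least 10 in normal cells.
#'
#' @param ac an [allelic_counts()].
#' @param cell_class named per-cell labels, values `cancer` or `normal`.
#' @param epsilon_mode `"per_site_pooled"` (default) or `"per_cell"`.
#' @param epsilon_floor lower bound on the error rate (default 0.001).
#' @param fdr_cut FDR threshold (default 0.05).
#' @param min_cov_cancer,min_cov_normal coverage rules (defaults 3 and 10).
#' @return data.frame: site_id, cell_id, cell_class, c_wt, c_mut, c_other,
#'   epsilon, p, fdr, coverage, confirmed. Cells with zero reads at a site
#'   are untested (absent).
#' @export
call_mutations <- function(ac, cell_class,
                           epsilon_mode = c("per_site_pooled", "per_cell"),
                           epsilon_floor = 0.001, fdr_cut = 0.05,
                           min_cov_cancer = 3, min_cov_normal = 10) {
  epsilon_mode <- match.arg(epsilon_mode)
  cls <- cell_class[colnames(ac$wt)]
  if (anyNA(cls) || !all(cls %in% c("cancer", "normal")))
    stop("cell_class must label every cell as 'cancer' or 'normal'")
  n_tot <- ac$wt + ac$mut + ac$other
  idx <- which(n_tot > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame())
  site <- rownames(ac$wt)[idx[, 1]]
  cell <- colnames(ac$wt)[idx[, 2]]
  cw <- ac$wt[idx]; cm <- ac$mut[idx]; co <- ac$other[idx]
  n <- cw + cm + co
  if (epsilon_mode == "per_site_pooled") {
    pooled <- rowSums(ac$other) / pmax(rowSums(n_tot), 1)
    eps <- pooled[idx[, 1]]
  } else {
    eps <- co / n
  }
  eps <- pmax(eps, epsilon_floor)
  p <- pbinom(cm - 1, size = n, prob = eps, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  cov <- cw + cm
  cellcls <- unname(cls[idx[, 2]])
  confirmed <- fdr < fdr_cut &
    ((cellcls == "cancer" & cov >= min_cov_cancer) |
       (cellcls == "normal" & cov >= min_cov_normal))
  out <- data.frame(site_id = site, cell_id = cell, cell_class = cellcls,
                    c_wt = cw, c_mut = cm, c_other = co,
                    epsilon = unname(eps), p = p, fdr = fdr, coverage = cov,
                    confirmed = confirmed, stringsAsFactors = FALSE)
  out[order(out$site_id, out$cell_id), ]
}

#' Per-site mutant-allele dominance in confirmed cancer cells
#'
#' Pools wild-type and mutant reads over the confirmed cancer cells of
#' each site and reports the mutant fraction `mut/(mut+wt)` and the
#' mutant/wild-type coverage ratio (infinite ratio flagged when no
#' wild-type reads remain).
#'
#' @param ac an [allelic_counts()].
#' @param calls a [call_mutations()] result.
#' @return data.frame: site_id, n_cells, c_mut, c_wt, mut_fraction, ratio,
#'   ratio_infinite. Sites with no confirmed cancer cells get NA rows.
#' @export
mutant_dominance <- function(ac, calls) {
  res <- lapply(rownames(ac$wt), function(s) {
    cc <- calls[calls$site_id == s & calls$confirmed &
                  calls$cell_class == "cancer", ]
    if (!nrow(cc))
      return(data.frame(site_id = s, n_cells = 0L, c_mut = NA_integer_,
                        c_wt = NA_integer_, mut_fraction = NA_real_,
                        ratio = NA_real_, ratio_infinite = NA))
    sm <- sum(cc$c_mut); sw <- sum(cc$c_wt)
    data.frame(site_id = s, n_cells = nrow(cc), c_mut = sm, c_wt = sw,
               mut_fraction = sm / (sm + sw),
               ratio = if (sw > 0) sm / sw else NA_real_,
               ratio_infinite = sw == 0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Allelic correlation shift against highly variable genes
#'
#' For each mutation site, restricted to cells with allelic coverage
#' (`e_tot > 0`, at least `min_cells` of them), computes Pearson
#' correlations between the normalized total / wild-type / mutant allelic
#' vectors and each highly-variable-gene expression vector. The shift
#' `delta = r_mut - r_wt` per gene summarizes how the transcriptional
#' context of the mutant allele differs from the wild-type allele's; HVGs
#' are clustered (average linkage) on their delta profiles across sites.
#'
#' @param am a [build_allelic_matrices()] result.
#' @param hvg_nm gene-level [normalize_expression()] result restricted (or
#'   restrictable via `hvg_genes`) to highly variable genes.
#' @param hvg_genes gene ids to use (default all rows of `hvg_nm`).
#' @param k number of HVG clusters (default 2).
#' @param min_cells minimum covered cells per site (default 15).
#' @return list of class `correlation_shift`: `r_tot`, `r_wt`, `r_mut`,
#'   `delta` (site x gene matrices), `clusters` (named vector over genes),
#'   `skipped` (sites with too few covered cells or zero-variance allelic
#'   vectors).
#' @export
correlation_shift <- function(am, hvg_nm, hvg_genes = rownames(hvg_nm$logexpr),
                              k = 2, min_cells = 15) {
  hvg_genes <- intersect(hvg_genes, rownames(hvg_nm$logexpr))
  cells <- intersect(colnames(am$e_tot), colnames(hvg_nm$logexpr))
  sites <- rownames(am$e_tot)
  mk <- function() matrix(NA_real_, length(sites), length(hvg_genes),
                          dimnames = list(sites, hvg_genes))
  r_tot <- mk(); r_wt <- mk(); r_mut <- mk()
  skipped <- character(0)
  for (s in sites) {
    cov <- cells[am$e_tot[s, cells] > 0]
    if (length(cov) < min_cells) { skipped <- c(skipped, s); next }
    expr <- t(hvg_nm$logexpr[hvg_genes, cov, drop = FALSE])
    for (w in c("tot", "wt", "mut")) {
      v <- am[[paste0("log_", w)]][s, cov]
      if (sd(v) == 0) next    # zero-variance allelic vector: NA row
      r <- suppressWarnings(cor(v, expr))
      if (w == "tot") r_tot[s, ] <- r
      if (w == "wt") r_wt[s, ] <- r
      if (w == "mut") r_mut[s, ] <- r
    }
  }
  delta <- r_mut - r_wt
  ok_sites <- rowSums(is.na(delta)) < ncol(delta)
  clusters <- NULL
  dsub <- delta[ok_sites, , drop = FALSE]
  dsub <- dsub[, colSums(is.na(dsub)) == 0, drop = FALSE]
  if (ncol(dsub) >= k && nrow(dsub) >= 1) {
    hc <- hclust(dist(t(dsub)), method = "average")
    clusters <- cutree(hc, k = k)
  }
  structure(list(r_tot = r_tot, r_wt = r_wt, r_mut = r_mut, delta = delta,
                 clusters = clusters, skipped = unique(skipped)),
            class = "correlation_shift")
}
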