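# Percent-spliced-in quantification and rank-based differential splicing.

#' Compute per-cell PSI for extracted events
#'
#' PSI of an event in a cell is the summed isoform TPM of the inclusion
#' form divided by the summed TPM of all isoforms involved in the event;
#' it is missing when the total falls below `min_total_tpm`.
#'
#' @param nm isoform-level [normalize_expression()] result.
#' @param events data.frame from [extract_events()].
#' @param min_total_tpm minimum event TPM for a defined PSI (default 1).
#' @return list of class `psi_matrix`: `psi` (event x cell, NA = missing),
#'   `events`, `min_total_tpm`.
#' @export
compute_psi <- function(nm, events, min_total_tpm = 1) {
  if (nm$level != "isoform") stop("compute_psi needs an isoform-level matrix")
  psi <- matrix(NA_real_, nrow(events), ncol(nm$tpm),
                dimnames = list(events$event_id, colnames(nm$tpm)))
  for (i in seq_len(nrow(events))) {
    inc <- strsplit(events$inclusion[i], ",", fixed = TRUE)[[1]]
    tot <- strsplit(events$total[i], ",", fixed = TRUE)[[1]]
    inc <- intersect(inc, rownames(nm$tpm))
    tot <- intersect(tot, rownames(nm$tpm))
    if (!length(tot)) next
    s_inc <- colSums(nm$tpm[inc, , drop = FALSE])
    s_tot <- colSums(nm$tpm[tot, , drop = FALSE])
    v <- s_inc / s_tot
    v[s_tot < min_total_tpm] <- NA_real_
    psi[i, ] <- v
  }
  structure(list(psi = psi, events = events, min_total_tpm = min_total_tpm),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("psi_matrix: %d events x %d cells (min total %.3g TPM)\n",
              nrow(x$psi), ncol(x$psi), x$min_total_tpm))
  invisible(x)
}

#' Differential alternative splicing between two cell groups
#'
#' Per event: two-sided Wilcoxon rank-sum test on per-cell PSI and
#' `dpsi = mean(A) - mean(B)`. An event is significant when p < `alpha`
#' and `|dpsi| >= min_dpsi` (raw p, matching the event filter convention;
#' BH-adjusted p reported alongside). In per-patient mode each patient's
#' group-A cells are tested against the pooled group-B cells and the union
#' of significant events is returned with per-patient flags.
#'
#' @param psi a [compute_psi()] result.
#' @param group_a,group_b cell-id sets.
#' @param min_cells minimum cells with defined PSI per group (default 10).
#' @param alpha,min_dpsi significance gates (defaults 0.05, 0.1).
#' @param patient optional named per-cell patient labels for group-A cells;
#'   triggers per-patient mode.
#' @return data.frame: event_id, type, gene_id, psi_a, psi_b, dpsi, p,
#'   adj_p, n_a, n_b, significant, note (and `patient` in per-patient mode).
#' @export
differential_splicing <- function(psi, group_a, group_b, min_cells = 10,
                                  alpha = 0.05, min_dpsi = 0.1,
                                  patient = NULL) {
  if (!is.null(patient)) {
    pats <- unique(patient[intersect(group_a, names(patient))])
    res <- lapply(pats, function(pt) {
      cells_a <- intersect(group_a, names(patient)[patient == pt])
      d <- differential_splicing(psi, cells_a, group_b, min_cells,
                                 alpha, min_dpsi)
      d$patient <- pt
      d
    })
    return(do.call(rbind, res))
  }
  m <- psi$psi
  group_a <- intersect(group_a, colnames(m))
  group_b <- intersect(group_b, colnames(m))
  res <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, group_a]; x <- x[!is.na(x)]
    y <- m[i, group_b]; y <- y[!is.na(y)]
    ev <- psi$events[i, ]
    if (length(x) < min_cells || length(y) < min_cells)
      return(data.frame(event_id = ev$event_id, type = ev$type,
                        gene_id = ev$gene_id, psi_a = NA_real_,
                        psi_b = NA_real_, dpsi = NA_real_, p = NA_real_,
                        n_a = length(x), n_b = length(y),
                        significant = FALSE, note = "insufficient_cells"))
    p <- if (all(c(x, y) == c(x, y)[1])) 1 else
      suppressWarnings(wilcox.test(x, y)$p.value)
    dpsi <- mean(x) - mean(y)
    data.frame(event_id = ev$event_id, type = ev$type, gene_id = ev$gene_id,
               psi_a = mean(x), psi_b = mean(y), dpsi = dpsi, p = p,
               n_a = length(x), n_b = length(y),
               significant = p < alpha &&
                 abs(dpsi) >= min_dpsi - 1e-9,  # inclusive at the boundary
               note = "")
  })
  out <- do.call(rbind, res)
  out$adj_p <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("event_id", "type", "gene_id", "psi_a", "psi_b", "dpsi", "p",
          "adj_p", "n_a", "n_b", "significant", "note")]
}

#' Correlate splicing-factor expression with event PSI and cluster events
#'
#' Pairwise Pearson correlation between each event's per-cell PSI and each
#' splicing factor's log expression (cells with defined PSI only), then
#' hierarchical clustering of events (average linkage, Euclidean distance
#' on correlation profiles) cut into `k` clusters, and per cluster a 2x2
#' Fisher exact test of retained-intron membership versus the other
#' clusters.
#'
#' @param psi a [compute_psi()] result (typically restricted to
#'   differential events).
#' @param sf_nm gene-level [normalize_expression()] result for the
#'   splicing-factor genes.
#' @param sf_genes splicing-factor gene ids (rows of `sf_nm` to use).
#' @param k number of event clusters (default 2).
#' @param min_cells minimum defined-PSI cells for an event (default 10).
#' @return list: `correlation` (event x SF matrix), `clusters` (named
#'   integer vector), `ri_enrichment` (per-cluster Fisher test
#'   data.frame), `dropped` (events with too few cells).
#' @export
sf_psi_correlation <- function(psi, sf_nm, sf_genes = rownames(sf_nm$logexpr),
                               k = 2, min_cells = 10) {
  cells <- intersect(colnames(psi$psi), colnames(sf_nm$logexpr))
  sf_genes <- intersect(sf_genes, rownames(sf_nm$logexpr))
  if (!length(sf_genes)) stop("no splicing-factor genes found in matrix")
  expr <- sf_nm$logexpr[sf_genes, cells, drop = FALSE]
  pm <- psi$psi[, cells, drop = FALSE]
  ok <- rowSums(!is.na(pm)) >= min_cells
  dropped <- rownames(pm)[!ok]
  pm <- pm[ok, , drop = FALSE]
  if (nrow(pm) < max(2, k)) stop("too few events with defined PSI")
  cmat <- matrix(NA_real_, nrow(pm), length(sf_genes),
                 dimnames = list(rownames(pm), sf_genes))
  for (i in seq_len(nrow(pm))) {
    def <- !is.na(pm[i, ])
    x <- pm[i, def]
    if (sd(x) == 0) next
    for (j in seq_along(sf_genes)) {
      y <- expr[j, def]
      cmat[i, j] <- if (sd(y) == 0) NA_real_ else cor(x, y)
    }
  }
  keep <- rowSums(is.na(cmat)) == 0
  cmat <- cmat[keep, , drop = FALSE]
  hc <- hclust(dist(cmat), method = "average")
  cl <- cutree(hc, k = k)
  is_ri <- grepl("^RI:", names(cl))
  enr <- do.call(rbind, lapply(sort(unique(cl)), function(cc) {
    tab <- matrix(c(sum(is_ri & cl == cc), sum(!is_ri & cl == cc),
                    sum(is_ri & cl != cc), sum(!is_ri & cl != cc)), 2)
    ft <- fisher.test(tab)
    data.frame(cluster = cc, n_events = sum(cl == cc),
               n_ri = sum(is_ri & cl == cc), odds_ratio = unname(ft$estimate),
               p = ft$p.value)
  }))
  list(correlation = cmat, clusters = cl, ri_enrichment = enr,
       dropped = dropped)
}

#' Overlap of differential-splicing signatures between two comparisons
#'
#' An event is direction-consistent when `|dpsi| > min_dpsi` in both tables
#' with the same sign (opposite sign in rescue mode, for perturbations
#' expected to revert the in vivo change). Overlap significance is the
#' upper-tail hypergeometric probability of observing at least the shared
#' count given the universe and the two qualifying-set sizes.
#'
#' @param das_a,das_b [differential_splicing()] results sharing event keys.
#' @param universe event-id universe.
#' @param min_dpsi magnitude gate (default 0.05, no significance required).
#' @param rescue if TRUE, consistency requires opposite signs.
#' @return list: `consistent` (event ids), `set_a`, `set_b`, `p`
#'   (hypergeometric upper tail), `expected` (overlap expected by chance).
#' @export
event_overlap <- function(das_a, das_b, universe, min_dpsi = 0.05,
                          rescue = FALSE) {
  if (!length(universe)) stop("empty event universe")
  gate <- min_dpsi + 1e-9                 # strictly greater than the gate
  qa <- das_a[!is.na(das_a$dpsi) & abs(das_a$dpsi) > gate, ]
  qb <- das_b[!is.na(das_b$dpsi) & abs(das_b$dpsi) > gate, ]
  set_a <- intersect(qa$event_id, universe)
  set_b <- intersect(qb$event_id, universe)
  shared <- intersect(set_a, set_b)
  sa <- qa$dpsi[match(shared, qa$event_id)]
  sb <- qb$dpsi[match(shared, qb$event_id)]
  consistent <- if (rescue) shared[sign(sa) != sign(sb)] else
    shared[sign(sa) == sign(sb)]
  k <- length(shared)
  N <- length(universe); a <- length(set_a); b <- length(set_b)
  p <- phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  list(consistent = consistent, set_a = set_a, set_b = set_b,
       p = p, expected = a * b / N)
}
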