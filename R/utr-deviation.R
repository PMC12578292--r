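# Expressed UTR length (EUL), gene UTR deviation (GUD) and the mixed-model
# classifier of UTR-shortened / UTR-lengthened genes.
#
# EUL_{g,c} = sum_i M_{g,i} C_{i,c} l_i / sum_i M_{g,i} C_{i,c}, the
# expression-weighted mean of isoform UTR lengths, with TPM as the
# expression weight C so that sequencing depth cancels. GUD subtracts the
# gene's mean EUL over a normal-cell baseline.

#' Compute expressed UTR length per gene per cell
#'
#' @param nm isoform-level [normalize_expression()] result.
#' @param annotation a [transcript_models()] object supplying per-isoform
#'   UTR lengths; isoforms with undefined UTR (non-coding) are excluded
#'   from both sums. Genes with no UTR-defined isoform are dropped.
#' @param end `"3p"` or `"5p"`.
#' @return gene x cell matrix of EUL in bases; NA where the gene has no
#'   expressed UTR-defined isoform in that cell.
#' @export
compute_eul <- function(nm, annotation, end = c("3p", "5p")) {
  end <- match.arg(end)
  if (nm$level != "isoform") stop("compute_eul needs an isoform-level matrix")
  txs <- annotation$transcripts
  len <- setNames(if (end == "3p") txs$utr3_len else txs$utr5_len,
                  txs$transcript_id)
  shared <- intersect(rownames(nm$tpm), names(len))
  len <- len[shared]
  keep <- shared[!is.na(len)]
  dropped_tx <- setdiff(shared, keep)
  if (!length(keep)) stop("no isoforms with defined UTR length")
  tpm <- nm$tpm[keep, , drop = FALSE]
  gene <- nm$gene_map[keep]
  num <- rowsum(tpm * len[keep], group = gene)
  den <- rowsum(tpm, group = gene)
  eul <- num / den
  eul[den == 0] <- NA_real_
  attr(eul, "dropped_isoforms") <- dropped_tx
  eul
}

#' Compute gene UTR deviation against a normal-cell baseline
#'
#' @param eul gene x cell EUL matrix from [compute_eul()].
#' @param normal_cells cell ids forming the baseline; per gene the baseline
#'   is the mean EUL over those of these cells where EUL is defined. Genes
#'   never expressed in the baseline cells are dropped (recorded in
#'   attribute `"dropped_genes"`).
#' @return list of class `utr_deviation`: `gud` (gene x cell deviation,
#'   bases), `eul`, `baseline` (per-gene mean), `cell_mean` (per-cell mean
#'   GUD across genes).
#' @export
compute_gud <- function(eul, normal_cells) {
  normal_cells <- intersect(normal_cells, colnames(eul))
  if (!length(normal_cells)) stop("empty normal cell set")
  base <- rowMeans(eul[, normal_cells, drop = FALSE], na.rm = TRUE)
  drop <- is.nan(base)
  gud <- eul[!drop, , drop = FALSE] - base[!drop]
  out <- list(gud = gud, eul = eul[!drop, , drop = FALSE],
              baseline = base[!drop],
              cell_mean = colMeans(gud, na.rm = TRUE))
  attr(out, "dropped_genes") <- rownames(eul)[drop]
  class(out) <- "utr_deviation"
  out
}

#' Classify UTR-shortened and UTR-lengthened genes
#'
#' Per gene, fits UTR deviation ~ cell type with a technology-batch term:
#' a random batch intercept (lmerTest) when three or more batch levels are
#' present, a fixed batch covariate otherwise (a random intercept is
#' unstable at two levels). A gene is `shortened` when the target-cell-type
#' coefficient is negative with p < `alpha` and the mean GUD difference
#' (target - reference) is <= -`min_diff` bases; `lengthened` mirrors this;
#' anything else (including singular fits, flagged in `note`) is
#' `unchanged`.
#'
#' @param dev a [compute_gud()] result.
#' @param cell_type named per-cell labels (names = cell ids) with two
#'   levels.
#' @param target,reference the two `cell_type` levels to contrast
#'   (target = cancer-side).
#' @param batch named per-cell batch labels.
#' @param min_cells minimum cells with defined GUD per type (default 10).
#' @param alpha p-value threshold (default 0.05).
#' @param min_diff magnitude rule in bases (default 10).
#' @return data.frame: gene_id, estimate, p_value, mean_diff, class, note.
#' @export
classify_utr_genes <- function(dev, cell_type, target, reference, batch,
                               min_cells = 10, alpha = 0.05, min_diff = 10) {
  cells <- colnames(dev$gud)
  ct <- cell_type[cells]
  bt <- batch[cells]
  use <- ct %in% c(target, reference)
  res <- lapply(rownames(dev$gud), function(g) {
    y <- dev$gud[g, ]
    ok <- use & !is.na(y)
    if (sum(ok & ct == target) < min_cells ||
        sum(ok & ct == reference) < min_cells)
      return(data.frame(gene_id = g, estimate = NA_real_, p_value = NA_real_,
                        mean_diff = NA_real_, class = "unchanged",
                        note = "insufficient_cells"))
    d <- data.frame(y = y[ok],
                    type = factor(ct[ok], levels = c(reference, target)),
                    batch = factor(bt[ok]))
    fit <- fit_type_effect(d)
    md <- mean(d$y[d$type == target]) - mean(d$y[d$type == reference])
    cls <- "unchanged"
    if (is.na(fit$p)) {
      note <- fit$note
    } else {
      note <- fit$note
      if (fit$est < 0 && fit$p < alpha && md <= -min_diff) cls <- "shortened"
      if (fit$est > 0 && fit$p < alpha && md >= min_diff) cls <- "lengthened"
    }
    data.frame(gene_id = g, estimate = fit$est, p_value = fit$p,
               mean_diff = md, class = cls, note = note)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# linear (mixed) model for the cell-type coefficient; batch random when >= 3
# levels, fixed otherwise
fit_type_effect <- function(d) {
  nb <- length(unique(d$batch))
  est <- NA_real_; p <- NA_real_; note <- ""
  if (nb >= 3) {
    fit <- tryCatch(
      lmerTest::lmer(y ~ type + (1 | batch), data = d,
                     control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4))),
      error = function(e) NULL)
    if (is.null(fit)) return(list(est = NA_real_, p = NA_real_,
                                  note = "fit_failed"))
    co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    row <- grep("^type", rownames(co))
    if (!is.null(co) && length(row) == 1 && ncol(co) >= 5) {
      est <- co[row, "Estimate"]; p <- co[row, "Pr(>|t|)"]
    } else note <- "singular_fit"
  } else {
    form <- if (nb >= 2) y ~ type + batch else y ~ type
    fit <- tryCatch(lm(form, data = d), error = function(e) NULL)
    co <- if (!is.null(fit)) summary(fit)$coefficients else NULL
    row <- grep("^type", rownames(co))
    if (!is.null(co) && length(row) == 1) {
      est <- co[row, "Estimate"]; p <- co[row, "Pr(>|t|)"]
      if (is.nan(p)) { p <- NA_real_; note <- "singular_fit" }
    } else note <- "singular_fit"
  }
  list(est = est, p = p, note = note)
}

#' Correlate UTR deviation with gene expression
#'
#' Self mode pairs each gene's own deviation with its own (gene-level)
#' expression; cross mode pairs every gene's deviation with the expression
#' of each supplied regulator gene (e.g. cleavage/polyadenylation factors).
#'
#' @param dev a [compute_gud()] result.
#' @param nm gene-level [normalize_expression()] result.
#' @param genes deviation genes to use (default all in `dev`).
#' @param regulators regulator gene ids for cross mode; `NULL` = self mode.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_pairs minimum paired cells with defined deviation (default 20).
#' @return data.frame: gene_id, regulator (NA in self mode), rho, p, fdr,
#'   n, note. Pairs with too few cells or a constant vector get NA with a
#'   reason.
#' @export
correlate_deviation <- function(dev, nm, genes = rownames(dev$gud),
                                regulators = NULL,
                                method = c("spearman", "pearson"),
                                min_pairs = 20) {
  method <- match.arg(method)
  cells <- intersect(colnames(dev$gud), colnames(nm$logexpr))
  genes <- intersect(genes, rownames(dev$gud))
  pairs <- if (is.null(regulators))
    data.frame(gene_id = genes, regulator = NA_character_)
  else
    expand.grid(gene_id = genes, regulator = regulators,
                stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]
    rgene <- if (is.na(pairs$regulator[i])) g else pairs$regulator[i]
    x <- dev$gud[g, cells]
    y <- nm$logexpr[rgene, cells]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs)
      return(data.frame(gene_id = g, regulator = pairs$regulator[i],
                        rho = NA_real_, p = NA_real_, n = sum(ok),
                        note = "too_few_pairs"))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(gene_id = g, regulator = pairs$regulator[i],
                        rho = NA_real_, p = NA_real_, n = sum(ok),
                        note = "constant_vector"))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
    data.frame(gene_id = g, regulator = pairs$regulator[i],
               rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               note = "")
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("gene_id", "regulator", "rho", "p", "fdr", "n", "note")]
}
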