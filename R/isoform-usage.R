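# Differential transcript usage (DTU) and differential CDS usage (DCU):
# a two-stage screen/confirm procedure on within-gene unit proportions.
#
# Stage 1 screens genes for any change in unit-proportion composition:
# per-cell unit proportions are compared between groups by rank-sum test
# per unit and combined per gene by Sidak over the gene's free dimensions
# (1 - (1 - min p)^(k-1) for k units); BH across gene screen p-values
# yields the overall FDR (OFDR). Stage 2 confirms
# units within screened genes with Holm-adjusted per-unit tests. A unit is
# significant under the dual criterion: OFDR < 0.05 and pooled proportion
# difference exceeding 10%.

#' Group transcripts by shared coding sequence
#'
#' Transcripts sharing a `ccds_id` (or, when absent, an identical CDS
#' genomic interval set) form one CDS group; non-coding transcripts form
#' flagged singleton groups.
#'
#' @param annotation a [transcript_models()] object.
#' @return data.frame: transcript_id, gene_id, cds_group, coding.
#' @export
group_by_cds <- function(annotation) {
  txs <- annotation$transcripts
  key <- character(nrow(txs))
  for (i in seq_len(nrow(txs))) {
    if (!txs$coding[i]) {
      key[i] <- paste0("noncoding_", txs$transcript_id[i])
    } else if (!is.na(txs$ccds_id[i])) {
      key[i] <- txs$ccds_id[i]
    } else {
      cc <- tx_cds(annotation, txs$transcript_id[i])
      key[i] <- paste0(txs$gene_id[i], ":",
                       paste(cc$start, cc$end, sep = "-", collapse = ";"))
    }
  }
  data.frame(transcript_id = txs$transcript_id, gene_id = txs$gene_id,
             cds_group = key, coding = txs$coding, stringsAsFactors = FALSE)
}

#' Two-stage differential transcript / CDS usage test
#'
#' @param m an [expr_matrix()].
#' @param group_a,group_b disjoint cell-id sets (A = target/cancer side).
#' @param grouping `"transcript"` (units are isoforms) or `"cds"` (isoforms
#'   collapsed by [group_by_cds()]; requires `annotation`).
#' @param annotation [transcript_models()], needed for `grouping = "cds"`.
#' @param min_cells minimum cells expressing the gene per group (default 10).
#' @param ofdr_cut,prop_cut the dual significance criterion (defaults 0.05
#'   and 0.10).
#' @return list of class `usage_result`: `genes` (gene_id, screen_p,
#'   screen_ofdr, n_units), `units` (gene_id, unit, confirm_p, holm_p,
#'   prop_a, prop_b, delta_proportion, significant), `grouping`.
#' @export
usage_test <- function(m, group_a, group_b,
                       grouping = c("transcript", "cds"),
                       annotation = NULL, min_cells = 10,
                       ofdr_cut = 0.05, prop_cut = 0.10) {
  grouping <- match.arg(grouping)
  if (length(intersect(group_a, group_b))) stop("cell groups overlap")
  counts <- as.matrix(m$counts)
  unit_of <- rownames(counts)
  if (grouping == "cds") {
    if (is.null(annotation)) stop("grouping = 'cds' requires an annotation")
    map <- group_by_cds(annotation)
    unit_of <- map$cds_group[match(rownames(counts), map$transcript_id)]
    if (anyNA(unit_of)) stop("annotation does not cover all isoforms")
    counts <- rowsum(counts, group = unit_of)
    gene_of_unit <- map$gene_id[match(rownames(counts), map$cds_group)]
  } else {
    gene_of_unit <- unname(m$gene_map[rownames(counts)])
  }
  ca <- counts[, intersect(group_a, colnames(counts)), drop = FALSE]
  cb <- counts[, intersect(group_b, colnames(counts)), drop = FALSE]

  gene_rows <- list(); unit_rows <- list()
  for (g in unique(gene_of_unit)) {
    idx <- which(gene_of_unit == g)
    if (length(idx) < 2) next    # single-unit gene: usage undefined
    ga <- ca[idx, , drop = FALSE]; gb <- cb[idx, , drop = FALSE]
    tot_a <- colSums(ga); tot_b <- colSums(gb)
    use_a <- tot_a > 0; use_b <- tot_b > 0
    if (sum(use_a) < min_cells || sum(use_b) < min_cells) next
    pa <- sweep(ga[, use_a, drop = FALSE], 2, tot_a[use_a], "/")
    pb <- sweep(gb[, use_b, drop = FALSE], 2, tot_b[use_b], "/")
    p_units <- vapply(seq_along(idx), function(u) {
      x <- pa[u, ]; y <- pb[u, ]
      if (all(c(x, y) == c(x, y)[1])) return(1)
      suppressWarnings(wilcox.test(x, y)$p.value)
    }, 0)
    # unit proportions sum to 1 per cell, so a k-unit gene has k-1 free
    # dimensions (for k = 2 the two per-unit tests coincide); Sidak over
    # the free dimensions keeps the screen p uniform under the null
    mu <- length(idx)
    screen_p <- 1 - (1 - min(p_units))^(mu - 1L)
    pooled_a <- rowSums(ga) / max(sum(ga), 1)
    pooled_b <- rowSums(gb) / max(sum(gb), 1)
    gene_rows[[g]] <- data.frame(gene_id = g, screen_p = screen_p,
                                 n_units = mu)
    unit_rows[[g]] <- data.frame(
      gene_id = g, unit = rownames(counts)[idx], confirm_p = p_units,
      holm_p = p.adjust(p_units, method = "holm"),
      prop_a = pooled_a, prop_b = pooled_b,
      delta_proportion = pooled_a - pooled_b, stringsAsFactors = FALSE)
  }
  if (!length(gene_rows))
    return(structure(list(genes = data.frame(), units = data.frame(),
                          grouping = grouping), class = "usage_result"))
  genes <- do.call(rbind, gene_rows)
  genes$screen_ofdr <- p.adjust(genes$screen_p, method = "BH")
  units <- do.call(rbind, unit_rows)
  units$screen_ofdr <- genes$screen_ofdr[match(units$gene_id, genes$gene_id)]
  units$significant <- units$screen_ofdr < ofdr_cut &
    units$holm_p < 0.05 &
    abs(units$delta_proportion) > prop_cut + 1e-9   # strictly exceeding
  rownames(genes) <- rownames(units) <- NULL
  structure(list(genes = genes, units = units, grouping = grouping),
            class = "usage_result")
}

#' @export
print.usage_result <- function(x, ...) {
  cat(sprintf("usage_result (%s): %d genes tested, %d significant units\n",
              x$grouping, nrow(x$genes), sum(x$units$significant)))
  invisible(x)
}

#' Annotate coding-sequence changes for significant usage switches
#'
#' For each gene with a significant usage switch, picks the dominant
#' up-switching and down-switching units (largest positive and negative
#' proportion difference), and reports their CDS length difference, the
#' number of differing exons (symmetric difference of exon interval sets)
#' and, when a domain table is supplied, protein domains gained or lost
#' (a domain is lost in the isoform whose CDS lacks part of the domain's
#' CDS-relative interval). The switch is flagged CDS-changing when the CDS
#' length difference exceeds `min_bp` (default 20 bases).
#'
#' @param usage a [usage_test()] result with `grouping = "transcript"`.
#' @param annotation a [transcript_models()] object.
#' @param domains optional data.frame (transcript_id, domain_name,
#'   cds_start, cds_end; 1-based inclusive, CDS-relative).
#' @param min_bp CDS length-change threshold in bases (default 20).
#' @return data.frame: gene_id, up_unit, down_unit, cds_len_up,
#'   cds_len_down, cds_diff_bp, n_exon_diff, cds_changed,
#'   domains_lost_in_up, domains_lost_in_down, note.
#' @export
annotate_cds_change <- function(usage, annotation, domains = NULL,
                                min_bp = 20) {
  stopifnot(usage$grouping == "transcript")
  units <- usage$units
  sig_genes <- unique(units$gene_id[units$significant])
  txs <- annotation$transcripts
  res <- lapply(sig_genes, function(g) {
    u <- units[units$gene_id == g, ]
    up <- u$unit[which.max(u$delta_proportion)]
    dn <- u$unit[which.min(u$delta_proportion)]
    row_up <- txs[txs$transcript_id == up, ]
    row_dn <- txs[txs$transcript_id == dn, ]
    if (!row_up$coding || !row_dn$coding)
      return(data.frame(gene_id = g, up_unit = up, down_unit = dn,
                        cds_len_up = NA_integer_, cds_len_down = NA_integer_,
                        cds_diff_bp = NA_integer_, n_exon_diff = NA_integer_,
                        cds_changed = NA,
                        domains_lost_in_up = NA_character_,
                        domains_lost_in_down = NA_character_,
                        note = "missing_cds"))
    diff_bp <- abs(row_up$cds_len - row_dn$cds_len)
    e_up <- tx_exons(annotation, up); e_dn <- tx_exons(annotation, dn)
    k_up <- paste(e_up$start, e_up$end); k_dn <- paste(e_dn$start, e_dn$end)
    n_exon_diff <- length(setdiff(k_up, k_dn)) + length(setdiff(k_dn, k_up))
    lost_up <- lost_dn <- NA_character_
    if (!is.null(domains)) {
      lost_dn <- paste(domains_lost(annotation, from = up, to = dn, domains),
                       collapse = ",")
      lost_up <- paste(domains_lost(annotation, from = dn, to = up, domains),
                       collapse = ",")
    }
    data.frame(gene_id = g, up_unit = up, down_unit = dn,
               cds_len_up = row_up$cds_len, cds_len_down = row_dn$cds_len,
               cds_diff_bp = diff_bp, n_exon_diff = n_exon_diff,
               cds_changed = diff_bp > min_bp,
               domains_lost_in_up = lost_up, domains_lost_in_down = lost_dn,
               note = "")
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0))
  rownames(out) <- NULL
  out
}

# domains annotated on isoform `from` whose CDS-relative interval overlaps
# CDS regions absent from isoform `to`
domains_lost <- function(annotation, from, to, domains) {
  dd <- domains[domains$transcript_id == from, , drop = FALSE]
  if (!nrow(dd)) return(character(0))
  gen_from <- cds_genomic_map(annotation, from)   # CDS position -> genomic
  gen_to <- cds_genomic_bases(annotation, to)
  lost <- character(0)
  for (i in seq_len(nrow(dd))) {
    span <- gen_from[dd$cds_start[i]:dd$cds_end[i]]
    if (any(!(span %in% gen_to))) lost <- c(lost, dd$domain_name[i])
  }
  unique(lost)
}

cds_genomic_map <- function(annotation, tx) {
  cc <- tx_cds(annotation, tx)
  strand <- annotation$transcripts$strand[
    annotation$transcripts$transcript_id == tx]
  pos <- unlist(lapply(seq_len(nrow(cc)), function(i) cc$start[i]:cc$end[i]))
  if (strand == "-") rev(pos) else pos
}

cds_genomic_bases <- function(annotation, tx) {
  cc <- tx_cds(annotation, tx)
  unlist(lapply(seq_len(nrow(cc)), function(i) cc$start[i]:cc$end[i]))
}
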