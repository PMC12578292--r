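# Synthetic isoform x cell counts: negative-binomial noise around
# group-specific expected isoform proportions times log-normal library sizes.
# Proportions are encoded through expected isoform means (not a per-cell
# Dirichlet), so planted effect sizes are recoverable in closed form.

#' Simulate an isoform-by-cell count matrix with planted effects
#'
#' @param config a [sim_config()] (the same one passed to
#'   [simulate_annotation()]; planted-gene names are taken from the
#'   annotation's embedded copy).
#' @param annotation result of [simulate_annotation()].
#' @return list with elements `expr` (an [expr_matrix()]) and `truth`
#'   (a `truth_table` list: planted APA/DAS/DTU/SF/program effects with
#'   their expected group-level proportions, plus per-cell latents for
#'   coupled events).
#' @export
simulate_expression <- function(config, annotation) {
  cfg <- attr(annotation, "config")
  if (is.null(cfg)) cfg <- config
  planted <- attr(annotation, "planted")
  set.seed(config$seed + 1L)

  txs <- annotation$transcripts
  gene_ids <- unique(txs$gene_id)
  check_planted_genes(cfg, gene_ids)

  meta <- make_cell_metadata(config)
  nc <- nrow(meta)
  groups <- meta$group

  lib <- rlnorm(nc, config$library_size_meanlog, config$library_size_sdlog)

  # per-gene baseline relative abundance
  alpha <- setNames(rlnorm(length(gene_ids), 0, 1), gene_ids)
  amat <- matrix(alpha, nrow = length(gene_ids), ncol = nc,
                 dimnames = list(gene_ids, meta$cell_id))

  # group-specific expression programs
  progs <- cfg$planted_programs
  if (!is.null(progs)) {
    for (r in seq_len(nrow(progs))) {
      sel <- groups == progs$group[r]
      amat[progs$gene[r], sel] <- amat[progs$gene[r], sel] * 2^progs$log2fc[r]
    }
  }

  # splicing-factor coupling latents: one z per cell per coupled pair
  sfc <- cfg$planted_sf_coupling
  latents <- list()
  if (!is.null(sfc)) {
    for (r in seq_len(nrow(sfc))) {
      z <- rnorm(nc)
      latents[[sfc$event_gene[r]]] <- z
      amat[sfc$sf_gene[r], ] <- amat[sfc$sf_gene[r], ] * exp(0.6 * sfc$sign[r] * z)
    }
  }

  props <- expected_proportions(cfg, annotation, planted, unique(groups))

  # expected isoform means and NB counts
  tx_gene <- setNames(txs$gene_id, txs$transcript_id)
  n_iso <- nrow(txs)
  pi_mat <- matrix(0, n_iso, nc, dimnames = list(txs$transcript_id, meta$cell_id))
  for (g in gene_ids) {
    idx <- which(tx_gene == g)
    if (!is.null(latents[[g]])) {          # per-cell PSI for coupled SE genes
      p_inc <- pmin(0.95, pmax(0.05, 0.5 + 0.35 * tanh(latents[[g]])))
      pi_mat[idx[1], ] <- p_inc            # isoform 1 = inclusion (backbone)
      pi_mat[idx[2], ] <- 1 - p_inc
    } else {
      pg <- props[[g]]                     # n_iso x n_groups matrix
      pi_mat[idx, ] <- pg[, groups, drop = FALSE]
    }
  }
  rel <- sweep(amat, 2, colSums(amat), "/")
  mu <- pi_mat * rel[tx_gene, , drop = FALSE] *
    matrix(lib, n_iso, nc, byrow = TRUE)
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                           size = 1 / config$nb_dispersion),
                   n_iso, nc, dimnames = dimnames(mu))

  em <- expr_matrix(Matrix::Matrix(counts, sparse = TRUE), tx_gene, meta)
  truth <- structure(list(apa = cfg$planted_apa, das = cfg$planted_das,
                          dtu = cfg$planted_dtu, sf = sfc,
                          programs = progs, expected_props = props,
                          latents = latents, planted = planted,
                          cells = meta),
                     class = "truth_table")
  list(expr = em, truth = truth)
}

check_planted_genes <- function(cfg, gene_ids) {
  want <- c(cfg$planted_apa$gene, cfg$planted_das$gene, cfg$planted_dtu$gene,
            cfg$planted_sf_coupling$sf_gene, cfg$planted_sf_coupling$event_gene,
            cfg$planted_programs$gene)
  miss <- setdiff(want, gene_ids)
  if (length(miss))
    stop("planted gene(s) absent from annotation: ",
         paste(miss, collapse = ", "))
}

make_cell_metadata <- function(config) {
  rows <- list()
  idx <- 0L
  for (grp in names(config$n_cells_per_group)) {
    n <- config$n_cells_per_group[[grp]]
    cls <- if (grp == "normal") "normal" else "cancer"
    pat <- sprintf("P%02d", 1L + (seq_len(n) - 1L) %% config$n_patients)
    rows[[grp]] <- data.frame(
      cell_id = sprintf("c%05d", idx + seq_len(n)),
      patient = pat,
      batch = sprintf("b%d", 1L + (as.integer(sub("P", "", pat)) - 1L) %%
                        config$n_batches),
      tissue = if (cls == "normal") "normal" else "tumor",
      cell_type = if (cls == "normal") "stem_TA" else "stem_TA_like",
      group = grp, cell_class = cls,
      stringsAsFactors = FALSE)
    idx <- idx + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# expected isoform proportion matrix (isoform x group) per gene
expected_proportions <- function(cfg, annotation, planted, group_names) {
  txs <- annotation$transcripts
  gene_ids <- unique(txs$gene_id)
  cancer_groups <- setdiff(group_names, "normal")
  props <- list()
  for (g in gene_ids) {
    k <- sum(txs$gene_id == g)
    p0 <- rgamma(k, shape = 5)
    p0 <- p0 / sum(p0)                   # shared across groups: null gene
    pg <- matrix(p0, k, length(group_names),
                 dimnames = list(NULL, group_names))
    props[[g]] <- pg
  }
  apa <- cfg$planted_apa
  if (!is.null(apa)) for (r in seq_len(nrow(apa))) {
    g <- apa$gene[r]
    D <- planted$param[planted$effect == "apa" & planted$gene == g]
    p_long <- c(normal = 0.5)
    aff <- apa$group[r]
    for (cg in cancer_groups)
      p_long[cg] <- if (cg == aff || aff == "cancer") 0.5 + apa$delta_utr3[r] / D else 0.5
    props[[g]] <- rbind(1 - p_long, p_long)[, group_names, drop = FALSE]
    colnames(props[[g]]) <- group_names
  }
  das <- cfg$planted_das
  if (!is.null(das)) for (r in seq_len(nrow(das))) {
    g <- das$gene[r]
    inc <- planted$param[planted$effect == "das" & planted$gene == g]
    p_inc <- setNames(rep(0.5, length(group_names)), group_names)
    aff <- das$group[r]
    sel <- if (aff == "cancer") cancer_groups else aff
    p_inc[sel] <- 0.5 + das$dpsi[r]
    pg <- matrix(0, 2, length(group_names), dimnames = list(NULL, group_names))
    pg[inc, ] <- p_inc
    pg[3 - inc, ] <- 1 - p_inc
    props[[g]] <- pg
  }
  dtu <- cfg$planted_dtu
  if (!is.null(dtu)) for (r in seq_len(nrow(dtu))) {
    g <- dtu$gene[r]
    p1 <- setNames(rep(dtu$prop_b1[r], length(group_names)), group_names)
    p1["normal"] <- dtu$prop_a1[r]
    props[[g]] <- rbind(p1, 1 - p1)[, group_names, drop = FALSE]
    colnames(props[[g]]) <- group_names
  }
  props
}

#' Shift an expression program in a chosen cell set
#'
#' Multiplies the counts of `genes` in `cells` by `2^log2fc` (rounded back
#' to integers). Used to plant cell-set-specific programs, e.g. an
#' expression module confined to mutation-carrier cells.
#'
#' @param em an [expr_matrix()].
#' @param genes gene ids whose isoforms are shifted.
#' @param cells cell ids to shift.
#' @param log2fc log2 fold change.
#' @return The modified `expr_matrix`.
#' @export
plant_program <- function(em, genes, cells, log2fc) {
  sel_tx <- names(em$gene_map)[em$gene_map %in% genes]
  if (!length(sel_tx)) stop("no isoforms found for the requested genes")
  sub <- em$counts[sel_tx, cells, drop = FALSE]
  em$counts[sel_tx, cells] <- round(sub * 2^log2fc)
  em
}
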