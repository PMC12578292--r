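# Synthetic transcript annotation: multi-isoform genes built by applying
# structural variant operations (exon skip, intron retention, splice-site
# shifts, alternative first/last exons, mutually exclusive exons, UTR-end
# moves) to a shared exon backbone. Coordinates are 1-based inclusive.

EXON_W <- 200L     # backbone exon width
INTRON_W <- 600L   # backbone intron width
GENE_SPACING <- 50000L

#' Simulate a transcript annotation
#'
#' Generates a gene catalog in which every multi-isoform gene's isoforms
#' differ in at least one of 3'-UTR length, 5'-UTR length, exon set or CDS,
#' so that expressed-UTR-length statistics, local splicing events of every
#' type, and transcript/CDS usage switches are all instantiable. Genes
#' required by planted effects in the configuration are appended after the
#' background genes, on the + strand, with the exact isoform pair each
#' effect needs.
#'
#' @param config a [sim_config()].
#' @return A [transcript_models()] object; the attribute `"planted"` holds a
#'   data.frame describing the planted genes (effect, gene, role columns)
#'   consumed by [simulate_expression()].
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_ex <- config$n_exons
  ops_all <- variant_ops(n_ex)

  genes <- list()   # each: list(gene_id, chrom, strand, isoforms = list of exon dfs)
  gi <- 0L
  add_gene <- function(gene_id, strand, op_list) {
    gi <<- gi + 1L
    chrom <- paste0("chr", 1L + (gi - 1L) %% 4L)
    origin <- 10000L + GENE_SPACING * ((gi - 1L) %/% 4L)
    backbone <- backbone_exons(origin, n_ex)
    isoforms <- list(backbone)
    for (op in op_list) isoforms <- c(isoforms, list(apply_op(backbone, op, strand)))
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         origin = origin, isoforms = isoforms)
  }

  # background genes
  n_iso_bg <- sample(1:6, config$n_genes, replace = TRUE,
                     prob = config$isoform_probs)
  for (g in seq_len(config$n_genes)) {
    strand <- sample(c("+", "-"), 1L)
    k <- n_iso_bg[g]
    ops <- if (k > 1) sample(ops_all, k - 1L) else character(0)
    genes[[length(genes) + 1L]] <-
      add_gene(sprintf("g%03d", g), strand, ops)
  }

  planted <- list()
  plant <- function(effect, gene, role, param) {
    planted[[length(planted) + 1L]] <<-
      data.frame(effect = effect, gene = gene, role = role, param = param,
                 stringsAsFactors = FALSE)
  }

  # APA genes: short isoform = backbone, long isoform extends the 3' end by D
  apa <- config$planted_apa
  if (!is.null(apa)) {
    if (is.null(apa$gene)) apa$gene <- sprintf("apa%02d", seq_len(nrow(apa)))
    for (r in seq_len(nrow(apa))) {
      D <- max(200L, 2L * ceiling(abs(apa$delta_utr3[r])) + 20L)
      genes[[length(genes) + 1L]] <-
        add_gene(apa$gene[r], "+", sprintf("utr3ext:%d", D))
      plant("apa", apa$gene[r], "utr_span", D)
    }
    config$planted_apa <- apa
  }

  # DAS genes: backbone + one variant of the requested event type
  das <- config$planted_das
  if (!is.null(das)) {
    if (is.null(das$gene)) das$gene <- sprintf("das%02d", seq_len(nrow(das)))
    for (r in seq_len(nrow(das))) {
      op <- das_template_op(das$type[r], n_ex)
      genes[[length(genes) + 1L]] <- add_gene(das$gene[r], "+", op)
      plant("das", das$gene[r], "inclusion",
            if (das$type[r] %in% c("SE", "MX")) 1 else 2)
    }
    config$planted_das <- das
  }

  # DTU genes: backbone vs exon-skip variant (distinct CDS, |diff| = 200 bp)
  dtu <- config$planted_dtu
  if (!is.null(dtu)) {
    if (is.null(dtu$gene)) dtu$gene <- sprintf("dtu%02d", seq_len(nrow(dtu)))
    for (r in seq_len(nrow(dtu))) {
      genes[[length(genes) + 1L]] <- add_gene(dtu$gene[r], "+", "se:4")
      plant("dtu", dtu$gene[r], "switch", NA_real_)
    }
    config$planted_dtu <- dtu
  }

  # SF coupling: single-isoform SF gene + SE event gene
  sfc <- config$planted_sf_coupling
  if (!is.null(sfc)) {
    if (is.null(sfc$sf_gene)) sfc$sf_gene <- sprintf("sf%02d", seq_len(nrow(sfc)))
    if (is.null(sfc$event_gene))
      sfc$event_gene <- sprintf("sfev%02d", seq_len(nrow(sfc)))
    for (r in seq_len(nrow(sfc))) {
      if (!any(vapply(genes, function(g) g$gene_id == sfc$sf_gene[r], TRUE)))
        genes[[length(genes) + 1L]] <- add_gene(sfc$sf_gene[r], "+", character(0))
      genes[[length(genes) + 1L]] <- add_gene(sfc$event_gene[r], "+", "se:4")
      plant("sf", sfc$sf_gene[r], "factor", sfc$sign[r])
      plant("sf", sfc$event_gene[r], "event", sfc$sign[r])
    }
    config$planted_sf_coupling <- sfc
  }

  tm <- assemble_models(genes, n_ex)
  attr(tm, "planted") <- if (length(planted)) do.call(rbind, planted) else
    data.frame(effect = character(0), gene = character(0),
               role = character(0), param = numeric(0))
  attr(tm, "config") <- config
  tm
}

backbone_exons <- function(origin, n_ex) {
  starts <- origin + (0:(n_ex - 1L)) * (EXON_W + INTRON_W)
  data.frame(start = starts, end = starts + EXON_W - 1L)
}

# apply one structural variant op to the backbone; `op` is "name:slot"
apply_op <- function(exons, op, strand) {
  parts <- strsplit(op, ":", fixed = TRUE)[[1]]
  name <- parts[1]; j <- as.integer(parts[2])
  n <- nrow(exons)
  out <- exons
  if (name == "se") {
    out <- exons[-j, , drop = FALSE]
  } else if (name == "ri") {
    out$end[j] <- exons$end[j + 1L]
    out <- out[-(j + 1L), , drop = FALSE]
  } else if (name == "a5") {
    out$end[j] <- exons$end[j] + 60L      # donor shift on + strand
  } else if (name == "a3") {
    out$start[j] <- exons$start[j] - 60L  # acceptor shift on + strand
  } else if (name == "mx") {
    out$start[j] <- exons$end[j] + 200L   # swap in a non-overlapping exon
    out$end[j] <- exons$end[j] + 399L
  } else if (name == "af") {
    out$start[1] <- exons$start[1] - 800L
    out$end[1] <- exons$start[1] - 601L
  } else if (name == "al") {
    out$start[n] <- exons$end[n] + 601L
    out$end[n] <- exons$end[n] + 800L
  } else if (name == "utr3") {           # background 3'-end move
    if (strand == "+") out$end[n] <- exons$end[n] - 120L
    else out$start[1] <- exons$start[1] + 120L
  } else if (name == "utr5") {
    if (strand == "+") out$start[1] <- exons$start[1] + 120L
    else out$end[n] <- exons$end[n] - 120L
  } else if (name == "utr3ext") {        # planted APA long isoform, + strand
    out$end[n] <- exons$end[n] + j       # here j carries the extension D
  } else stop("unknown op: ", name)
  rownames(out) <- NULL
  out
}

das_template_op <- function(type, n_ex) {
  slot <- max(3L, min(4L, n_ex - 2L))
  switch(type,
         SE = paste0("se:", slot), RI = paste0("ri:", slot),
         A5 = paste0("a5:", slot), A3 = paste0("a3:", slot),
         AF = "af:1", AL = "al:1", MX = paste0("mx:", slot),
         stop("unknown event type: ", type))
}

# build the transcript_models object: per-isoform CDS is the genomic CDS
# span of the gene intersected with the isoform's exons
assemble_models <- function(genes, n_ex) {
  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  for (g in genes) {
    # CDS span: middle of backbone exon 2 to middle of backbone exon n-1
    cds_lo <- g$origin + (EXON_W + INTRON_W) + 100L
    cds_hi <- g$origin + (n_ex - 2L) * (EXON_W + INTRON_W) + 99L
    cds_sets <- list()
    for (k in seq_along(g$isoforms)) {
      tx_id <- sprintf("%s.t%d", g$gene_id, k)
      ex <- g$isoforms[[k]]
      cds <- intersect_intervals(ex, cds_lo, cds_hi)
      ann <- derive_tx_annotation(ex, cds, g$strand)
      cds_sets[[k]] <- cds
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = tx_id, gene_id = g$gene_id, chrom = g$chrom,
        strand = g$strand, ccds_id = NA_character_,
        utr3_len = ann$utr3_len, utr5_len = ann$utr5_len,
        cds_len = ann$cds_len, tx_len = ann$tx_len, coding = ann$coding,
        stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(transcript_id = tx_id, start = ex$start, end = ex$end)
      if (nrow(cds))
        cds_rows[[length(cds_rows) + 1L]] <-
          data.frame(transcript_id = tx_id, start = cds$start, end = cds$end)
    }
    # CCDS ids: isoforms sharing an identical CDS interval set share an id
    keys <- vapply(cds_sets, function(cc)
      paste(cc$start, cc$end, sep = "-", collapse = ";"), "")
    grp <- match(keys, unique(keys))
    for (k in seq_along(g$isoforms)) {
      i <- length(tx_rows) - length(g$isoforms) + k
      tx_rows[[i]]$ccds_id <- sprintf("CCDS_%s_%d", g$gene_id, grp[k])
    }
  }
  transcript_models(do.call(rbind, tx_rows), do.call(rbind, exon_rows),
                    if (length(cds_rows)) do.call(rbind, cds_rows) else
                      data.frame(transcript_id = character(0),
                                 start = integer(0), end = integer(0)))
}

intersect_intervals <- function(exons, lo, hi) {
  s <- pmax(exons$start, lo); e <- pmin(exons$end, hi)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

# transcript-orientation UTR/CDS lengths from exon + CDS intervals
derive_tx_annotation <- function(exons, cds, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  w <- exons$end - exons$start + 1L
  tx_len <- sum(w)
  if (nrow(cds) == 0)
    return(list(tx_len = tx_len, cds_len = 0L, utr3_len = NA_integer_,
                utr5_len = NA_integer_, coding = FALSE))
  cds_len <- sum(cds$end - cds$start + 1L)
  txpos_plus <- function(pos) {   # 1-based transcript coordinate, + sense
    idx <- which(exons$start <= pos & exons$end >= pos)
    if (length(idx) != 1) stop("CDS boundary outside exons")
    (pos - exons$start[idx] + 1L) + sum(w[seq_len(idx - 1L)])
  }
  if (strand == "+") {
    utr5 <- txpos_plus(min(cds$start)) - 1L
    utr3 <- tx_len - txpos_plus(max(cds$end))
  } else {
    utr5 <- tx_len - txpos_plus(max(cds$end))
    utr3 <- txpos_plus(min(cds$start)) - 1L
  }
  list(tx_len = tx_len, cds_len = cds_len, utr3_len = utr3,
       utr5_len = utr5, coding = TRUE)
}
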