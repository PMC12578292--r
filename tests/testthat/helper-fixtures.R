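# Shared fixture builders and independent oracles.

# tiny expression matrix from a dense count table
make_em <- function(counts, gene_map, patient = NULL, batch = NULL,
                    cell_type = NULL, tissue = NULL) {
  nc <- ncol(counts)
  meta <- data.frame(
    cell_id = colnames(counts),
    patient = if (is.null(patient)) rep("P01", nc) else patient,
    batch = if (is.null(batch)) rep("b1", nc) else batch,
    tissue = if (is.null(tissue)) rep("tumor", nc) else tissue,
    cell_type = if (is.null(cell_type)) rep("stem_TA", nc) else cell_type,
    stringsAsFactors = FALSE)
  expr_matrix(Matrix::Matrix(counts, sparse = TRUE), gene_map, meta)
}

# hand-built transcript model set from a list of exon tables
make_tm <- function(iso_list, gene_id = "g1", chrom = "chr1", strand = "+",
                    cds = NULL) {
  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  for (tx in names(iso_list)) {
    ex <- iso_list[[tx]]
    cc <- if (is.null(cds) || is.null(cds[[tx]]))
      data.frame(start = integer(0), end = integer(0)) else cds[[tx]]
    ann <- sciso:::derive_tx_annotation(ex, cc, strand)
    tx_rows[[tx]] <- data.frame(
      transcript_id = tx, gene_id = gene_id, chrom = chrom, strand = strand,
      ccds_id = NA_character_, utr3_len = ann$utr3_len,
      utr5_len = ann$utr5_len, cds_len = ann$cds_len, tx_len = ann$tx_len,
      coding = ann$coding, stringsAsFactors = FALSE)
    exon_rows[[tx]] <- data.frame(transcript_id = tx, start = ex$start,
                                  end = ex$end)
    if (nrow(cc))
      cds_rows[[tx]] <- data.frame(transcript_id = tx, start = cc$start,
                                   end = cc$end)
  }
  transcript_models(do.call(rbind, tx_rows), do.call(rbind, exon_rows),
                    if (length(cds_rows)) do.call(rbind, cds_rows) else
                      data.frame(transcript_id = character(0),
                                 start = integer(0), end = integer(0)))
}

# ---------------------------------------------------------------------------
# Independent brute-force splicing-event oracle.
#
# Enumerates candidate events per type by scanning intron/exon combinations
# across the whole gene (not by pairwise comparison), then derives inclusion
# and exclusion membership from first principles. Events require at least
# one isoform on each side.
# ---------------------------------------------------------------------------
oracle_gene_events <- function(iso_list, chrom, strand) {
  introns <- lapply(iso_list, function(ex) {
    n <- nrow(ex)
    if (n < 2) return(cbind(l = integer(0), r = integer(0)))
    cbind(l = ex$end[-n], r = ex$start[-1])
  })
  txids <- names(iso_list)
  all_introns <- unique(do.call(rbind, introns))
  has_i <- function(t, l, r) any(introns[[t]][, 1] == l & introns[[t]][, 2] == r)
  has_e <- function(t, s, e) any(iso_list[[t]]$start == s & iso_list[[t]]$end == e)
  members <- function(test) txids[vapply(txids, test, TRUE)]
  out <- list()
  emit <- function(id, inc, exc) {
    if (length(inc) && length(exc))
      out[[id]] <<- data.frame(event_id = id,
                               inclusion = paste(sort(inc), collapse = ","),
                               total = paste(sort(c(inc, exc)), collapse = ","))
  }

  # SE: any exon (B,C) with flanking introns (A,B),(C,D) somewhere, and
  # the skip intron (A,D) somewhere
  for (t in txids) {
    ex <- iso_list[[t]]; n <- nrow(ex)
    if (n < 3) next
    for (k in 2:(n - 1)) {
      A <- ex$end[k - 1]; B <- ex$start[k]; C <- ex$end[k]; D <- ex$start[k + 1]
      if (!any(vapply(txids, function(s) has_i(s, A, D), TRUE))) next
      emit(sprintf("SE:%s:%d-%d:%d-%d:%s", chrom, A, B, C, D, strand),
           members(function(s) has_i(s, A, B) && has_i(s, C, D)),
           members(function(s) has_i(s, A, D)))
    }
  }
  # RI: intron (l,r) with exact flanking exons (s,l),(r,e) in one isoform
  # and a spanning exon (s,e) in another
  for (t in txids) {
    ex <- iso_list[[t]]
    it <- introns[[t]]
    if (!nrow(it)) next
    for (k in seq_len(nrow(it))) {
      l <- it[k, 1]; r <- it[k, 2]
      s <- ex$start[ex$end == l]; e <- ex$end[ex$start == r]
      if (!any(vapply(txids, function(u) has_e(u, s, e), TRUE))) next
      emit(sprintf("RI:%s:%d:%d-%d:%d:%s", chrom, s, l, r, e, strand),
           members(function(u) has_e(u, s, e)),
           members(function(u) has_i(u, l, r) && has_e(u, s, l) &&
                     has_e(u, r, e)))
    }
  }
  # A5/A3: two introns sharing one boundary with overlapping flank exons
  if (nrow(all_introns) >= 2) {
    for (i in seq_len(nrow(all_introns) - 1)) for (j in (i + 1):nrow(all_introns)) {
      i1 <- all_introns[i, ]; i2 <- all_introns[j, ]
      if (i1["r"] == i2["r"] && i1["l"] != i2["l"]) {
        ok <- FALSE
        for (t in txids) for (u in txids) {
          a1 <- iso_list[[t]]$start[iso_list[[t]]$end == i1["l"]]
          a2 <- iso_list[[u]]$start[iso_list[[u]]$end == i2["l"]]
          if (length(a1) && length(a2) && has_i(t, i1["l"], i1["r"]) &&
              has_i(u, i2["l"], i2["r"]) &&
              a1 <= i2["l"] && a2 <= i1["l"]) ok <- TRUE
        }
        if (ok) {
          li <- max(i1["l"], i2["l"]); le <- min(i1["l"], i2["l"])
          type <- if (strand == "+") "A5" else "A3"
          emit(sprintf("%s:%s:%d-%d:%d-%d:%s", type, chrom, li, i1["r"],
                       le, i1["r"], strand),
               members(function(u) has_i(u, li, i1["r"])),
               members(function(u) has_i(u, le, i1["r"])))
        }
      }
      if (i1["l"] == i2["l"] && i1["r"] != i2["r"]) {
        ok <- FALSE
        for (t in txids) for (u in txids) {
          b1 <- iso_list[[t]]$end[iso_list[[t]]$start == i1["r"]]
          b2 <- iso_list[[u]]$end[iso_list[[u]]$start == i2["r"]]
          if (length(b1) && length(b2) && has_i(t, i1["l"], i1["r"]) &&
              has_i(u, i2["l"], i2["r"]) &&
              i1["r"] <= b2 && i2["r"] <= b1) ok <- TRUE
        }
        if (ok) {
          ri <- min(i1["r"], i2["r"]); re <- max(i1["r"], i2["r"])
          type <- if (strand == "+") "A3" else "A5"
          emit(sprintf("%s:%s:%d-%d:%d-%d:%s", type, chrom, i1["l"], ri,
                       i1["l"], re, strand),
               members(function(u) has_i(u, i1["l"], ri)),
               members(function(u) has_i(u, i1["l"], re)))
        }
      }
    }
  }
  # AF/AL: alternative non-overlapping terminal exons into a shared boundary
  first_exon <- function(t) iso_list[[t]][1, ]
  last_exon <- function(t) iso_list[[t]][nrow(iso_list[[t]]), ]
  multi <- txids[vapply(txids, function(t) nrow(iso_list[[t]]) >= 2, TRUE)]
  if (length(multi) >= 2) {
    for (t in multi) for (u in multi) {
      f1 <- first_exon(t); f2 <- first_exon(u)
      r1 <- introns[[t]][1, 2]; r2 <- introns[[u]][1, 2]
      if (r1 == r2 && (f1$end < f2$start || f2$end < f1$start)) {
        d <- if (f1$start < f2$start) f1 else f2
        p <- if (f1$start < f2$start) f2 else f1
        type <- if (strand == "+") "AF" else "AL"
        emit(sprintf("%s:%s:%d:%d-%d:%d:%d-%d:%s", type, chrom, d$start,
                     d$end, r1, p$start, p$end, r1, strand),
             members(function(v) nrow(introns[[v]]) > 0 &&
                       first_exon(v)$start == d$start &&
                       first_exon(v)$end == d$end && introns[[v]][1, 2] == r1),
             members(function(v) nrow(introns[[v]]) > 0 &&
                       first_exon(v)$start == p$start &&
                       first_exon(v)$end == p$end && introns[[v]][1, 2] == r1))
      }
      g1 <- last_exon(t); g2 <- last_exon(u)
      l1 <- introns[[t]][nrow(introns[[t]]), 1]
      l2 <- introns[[u]][nrow(introns[[u]]), 1]
      if (l1 == l2 && (g1$end < g2$start || g2$end < g1$start)) {
        d <- if (g1$end > g2$end) g1 else g2
        p <- if (g1$end > g2$end) g2 else g1
        type <- if (strand == "+") "AL" else "AF"
        emit(sprintf("%s:%s:%d-%d:%d:%d-%d:%d:%s", type, chrom, l1, d$start,
                     d$end, l1, p$start, p$end, strand),
             members(function(v) {
               nn <- nrow(introns[[v]])
               nn > 0 && last_exon(v)$start == d$start &&
                 last_exon(v)$end == d$end && introns[[v]][nn, 1] == l1
             }),
             members(function(v) {
               nn <- nrow(introns[[v]])
               nn > 0 && last_exon(v)$start == p$start &&
                 last_exon(v)$end == p$end && introns[[v]][nn, 1] == l1
             }))
      }
    }
  }
  # MX: two internal exons, shared outer flanks, non-overlapping, never
  # co-occurring
  internal <- list()
  for (t in txids) {
    ex <- iso_list[[t]]; n <- nrow(ex)
    if (n < 3) next
    for (k in 2:(n - 1))
      internal[[length(internal) + 1]] <-
        c(A = ex$end[k - 1], B = ex$start[k], C = ex$end[k], D = ex$start[k + 1])
  }
  if (length(internal) >= 2) {
    internal <- unique(do.call(rbind, internal))
    for (i in seq_len(nrow(internal) - 1)) for (j in (i + 1):nrow(internal)) {
      x <- internal[i, ]; y <- internal[j, ]
      if (x["A"] != y["A"] || x["D"] != y["D"]) next
      if (x["B"] == y["B"] && x["C"] == y["C"]) next
      if (!(x["C"] < y["B"] || y["C"] < x["B"])) next
      cooccur <- any(vapply(txids, function(t)
        has_e(t, x["B"], x["C"]) && has_e(t, y["B"], y["C"]), TRUE))
      if (cooccur) next
      lx <- if (x["B"] < y["B"]) x else y
      rx <- if (x["B"] < y["B"]) y else x
      emit(sprintf("MX:%s:%d-%d:%d-%d:%d-%d:%d-%d:%s", chrom, lx["A"],
                   lx["B"], lx["C"], lx["D"], rx["A"], rx["B"], rx["C"],
                   rx["D"], strand),
           members(function(t) has_i(t, lx["A"], lx["B"]) &&
                     has_i(t, lx["C"], lx["D"])),
           members(function(t) has_i(t, rx["A"], rx["B"]) &&
                     has_i(t, rx["C"], rx["D"])))
    }
  }
  if (!length(out))
    return(data.frame(event_id = character(0), inclusion = character(0),
                      total = character(0)))
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

oracle_events <- function(tm) {
  txs <- tm$transcripts
  out <- list()
  for (g in unique(txs$gene_id)) {
    ids <- txs$transcript_id[txs$gene_id == g]
    if (length(ids) < 2) next
    iso <- lapply(ids, function(tx) sciso:::tx_exons(tm, tx))
    names(iso) <- ids
    ev <- oracle_gene_events(iso, txs$chrom[txs$gene_id == g][1],
                             txs$strand[txs$gene_id == g][1])
    if (nrow(ev)) out[[g]] <- ev
  }
  if (!length(out))
    return(data.frame(event_id = character(0), inclusion = character(0),
                      total = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$event_id), ]
  rownames(res) <- NULL
  res
}
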