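# Local alternative-splicing event extraction from transcript models.
#
# Seven event types are enumerated per gene by pairwise isoform structure
# comparison: skipping exon (SE), retained intron (RI), alternative 5'/3'
# splice site (A5/A3), alternative first/last exon (AF/AL) and mutually
# exclusive exons (MX). Coordinates in event ids are the 1-based GTF exon
# boundaries flanking the variable region, written
# upstreamExonEnd-variableStart:variableEnd-downstreamStart for SE.
# For each event the inclusion set is the isoforms exhibiting the
# inclusion form (the exon-containing / intron-retaining / long-exon /
# distal-terminal / genomic-left-exon form), the total set those
# exhibiting either form; membership is recomputed over all isoforms of
# the gene, so output is independent of transcript order.

#' Extract local alternative-splicing events
#'
#' @param annotation a [transcript_models()] object.
#' @return data.frame with one row per event: `event_id`
#'   (`TYPE:chrom:blocks:strand`), `type`, `gene_id`, `inclusion`
#'   and `total` (comma-separated, sorted transcript ids).
#' @export
extract_events <- function(annotation) {
  txs <- annotation$transcripts
  out <- list()
  for (g in unique(txs$gene_id)) {
    ids <- txs$transcript_id[txs$gene_id == g]
    if (length(ids) < 2) next
    iso <- lapply(ids, function(tx) tx_exons(annotation, tx))
    names(iso) <- ids
    chrom <- txs$chrom[txs$gene_id == g][1]
    strand <- txs$strand[txs$gene_id == g][1]
    ev <- gene_events(iso, chrom, strand)
    if (nrow(ev)) { ev$gene_id <- g; out[[g]] <- ev }
  }
  if (!length(out))
    return(data.frame(event_id = character(0), type = character(0),
                      gene_id = character(0), inclusion = character(0),
                      total = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$event_id), c("event_id", "type", "gene_id",
                                    "inclusion", "total")]
  rownames(res) <- NULL
  res
}

intron_table <- function(ex) {
  n <- nrow(ex)
  if (n < 2) return(data.frame(l = integer(0), r = integer(0)))
  data.frame(l = ex$end[-n], r = ex$start[-1])
}

has_intron <- function(intr, l, r) any(intr$l == l & intr$r == r)
has_exon <- function(ex, s, e) any(ex$start == s & ex$end == e)

# all events within one gene, given the named isoform exon tables
gene_events <- function(iso, chrom, strand) {
  intr <- lapply(iso, intron_table)
  txids <- names(iso)
  found <- new.env(parent = emptyenv())

  add_event <- function(id, type, inc_test, exc_test) {
    if (!is.null(found[[id]])) return(invisible())
    inc <- txids[vapply(txids, inc_test, TRUE)]
    exc <- txids[vapply(txids, exc_test, TRUE)]
    if (!length(inc) || !length(exc)) return(invisible())
    found[[id]] <- data.frame(
      event_id = id, type = sub(":.*", "", id),
      inclusion = paste(sort(inc), collapse = ","),
      total = paste(sort(c(inc, exc)), collapse = ","),
      stringsAsFactors = FALSE)
    invisible()
  }

  for (t1 in txids) for (t2 in txids) {
    if (t1 == t2) next
    e1 <- iso[[t1]]; i1 <- intr[[t1]]
    e2 <- iso[[t2]]; i2 <- intr[[t2]]
    n1 <- nrow(e1)

    # SE: exon k of t1 skipped in t2 via an intron joining t1's flanks
    if (n1 >= 3) for (k in 2:(n1 - 1)) {
      A <- e1$end[k - 1]; B <- e1$start[k]; C <- e1$end[k]; D <- e1$start[k + 1]
      if (has_intron(i2, A, D))
        add_event(sprintf("SE:%s:%d-%d:%d-%d:%s", chrom, A, B, C, D, strand),
                  "SE",
                  function(t) has_intron(intr[[t]], A, B) &&
                    has_intron(intr[[t]], C, D),
                  function(t) has_intron(intr[[t]], A, D))
    }

    # RI: intron of t1 fully exonic in t2 (t2 exon spans both flanks)
    if (nrow(i1)) for (k in seq_len(nrow(i1))) {
      l <- i1$l[k]; r <- i1$r[k]
      s <- e1$start[which(e1$end == l)]; e <- e1$end[which(e1$start == r)]
      if (has_exon(e2, s, e))
        add_event(sprintf("RI:%s:%d:%d-%d:%d:%s", chrom, s, l, r, e, strand),
                  "RI",
                  function(t) has_exon(iso[[t]], s, e),
                  function(t) has_intron(intr[[t]], l, r) &&
                    has_exon(iso[[t]], s, l) && has_exon(iso[[t]], r, e))
    }

    # A5/A3: introns sharing one boundary, overlapping flanking exons
    if (nrow(i1) && nrow(i2)) for (k in seq_len(nrow(i1))) {
      l1 <- i1$l[k]; r1 <- i1$r[k]
      # shared right boundary, differing left
      m <- which(i2$r == r1 & i2$l != l1)
      for (j in m) {
        l2 <- i2$l[j]
        a1 <- e1$start[e1$end == l1]; a2 <- e2$start[e2$end == l2]
        if (length(a1) && length(a2) && a1 <= l2 && a2 <= l1) {
          li <- max(l1, l2); le <- min(l1, l2)   # long-exon form = shorter intron
          type <- if (strand == "+") "A5" else "A3"
          add_event(sprintf("%s:%s:%d-%d:%d-%d:%s", type, chrom,
                            li, r1, le, r1, strand), type,
                    function(t) has_intron(intr[[t]], li, r1),
                    function(t) has_intron(intr[[t]], le, r1))
        }
      }
      # shared left boundary, differing right
      m <- which(i2$l == l1 & i2$r != r1)
      for (j in m) {
        r2 <- i2$r[j]
        b1 <- e1$end[e1$start == r1]; b2 <- e2$end[e2$start == r2]
        if (length(b1) && length(b2) && r1 <= b2 && r2 <= b1) {
          ri <- min(r1, r2); re <- max(r1, r2)
          type <- if (strand == "+") "A3" else "A5"
          add_event(sprintf("%s:%s:%d-%d:%d-%d:%s", type, chrom,
                            l1, ri, l1, re, strand), type,
                    function(t) has_intron(intr[[t]], l1, ri),
                    function(t) has_intron(intr[[t]], l1, re))
        }
      }
    }

    # AF/AL: alternative non-overlapping terminal exons splicing to a
    # shared boundary
    if (nrow(i1) && nrow(i2)) {
      # left-terminal exons
      f1 <- e1[1, ]; f2 <- e2[1, ]
      if (i1$r[1] == i2$r[1] && !(f1$start == f2$start && f1$end == f2$end) &&
          (f1$end < f2$start || f2$end < f1$start)) {
        r <- i1$r[1]
        d <- if (f1$start < f2$start) f1 else f2   # distal (inclusion) exon
        p <- if (f1$start < f2$start) f2 else f1
        type <- if (strand == "+") "AF" else "AL"
        add_event(sprintf("%s:%s:%d:%d-%d:%d:%d-%d:%s", type, chrom,
                          d$start, d$end, r, p$start, p$end, r, strand), type,
                  function(t) {
                    ex <- iso[[t]]; it <- intr[[t]]
                    nrow(it) > 0 && ex$start[1] == d$start &&
                      ex$end[1] == d$end && it$r[1] == r
                  },
                  function(t) {
                    ex <- iso[[t]]; it <- intr[[t]]
                    nrow(it) > 0 && ex$start[1] == p$start &&
                      ex$end[1] == p$end && it$r[1] == r
                  })
      }
      # right-terminal exons
      g1 <- e1[nrow(e1), ]; g2 <- e2[nrow(e2), ]
      if (i1$l[nrow(i1)] == i2$l[nrow(i2)] &&
          !(g1$start == g2$start && g1$end == g2$end) &&
          (g1$end < g2$start || g2$end < g1$start)) {
        l <- i1$l[nrow(i1)]
        d <- if (g1$end > g2$end) g1 else g2
        p <- if (g1$end > g2$end) g2 else g1
        type <- if (strand == "+") "AL" else "AF"
        add_event(sprintf("%s:%s:%d-%d:%d:%d-%d:%d:%s", type, chrom,
                          l, d$start, d$end, l, p$start, p$end, strand), type,
                  function(t) {
                    ex <- iso[[t]]; it <- intr[[t]]
                    n <- nrow(ex)
                    nrow(it) > 0 && ex$start[n] == d$start &&
                      ex$end[n] == d$end && it$l[nrow(it)] == l
                  },
                  function(t) {
                    ex <- iso[[t]]; it <- intr[[t]]
                    n <- nrow(ex)
                    nrow(it) > 0 && ex$start[n] == p$start &&
                      ex$end[n] == p$end && it$l[nrow(it)] == l
                  })
      }
    }

    # MX: internal exons of t1/t2 with shared outer flanks, non-overlapping,
    # never co-occurring in any isoform
    if (n1 >= 3 && nrow(e2) >= 3) for (k in 2:(n1 - 1)) {
      A <- e1$end[k - 1]; B <- e1$start[k]; C <- e1$end[k]; D <- e1$start[k + 1]
      for (j in 2:(nrow(e2) - 1)) {
        Bp <- e2$start[j]; Cp <- e2$end[j]
        if (e2$end[j - 1] != A || e2$start[j + 1] != D) next
        if (B == Bp && C == Cp) next
        if (!(C < Bp || Cp < B)) next               # must not overlap
        cooccur <- any(vapply(txids, function(t)
          has_exon(iso[[t]], B, C) && has_exon(iso[[t]], Bp, Cp), TRUE))
        if (cooccur) next
        lx <- if (B < Bp) c(B, C) else c(Bp, Cp)    # genomic-left = inclusion
        rx <- if (B < Bp) c(Bp, Cp) else c(B, C)
        add_event(sprintf("MX:%s:%d-%d:%d-%d:%d-%d:%d-%d:%s", chrom,
                          A, lx[1], lx[2], D, A, rx[1], rx[2], D, strand),
                  "MX",
                  function(t) has_intron(intr[[t]], A, lx[1]) &&
                    has_intron(intr[[t]], lx[2], D),
                  function(t) has_intron(intr[[t]], A, rx[1]) &&
                    has_intron(intr[[t]], rx[2], D))
      }
    }
  }
  evs <- as.list(found)
  if (!length(evs))
    return(data.frame(event_id = character(0), type = character(0),
                      inclusion = character(0), total = character(0)))
  res <- do.call(rbind, evs[order(names(evs))])
  rownames(res) <- NULL
  res
}
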