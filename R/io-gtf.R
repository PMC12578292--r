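# GTF annotation I/O (Ensembl dialect) via rtracklayer, with UTR lengths
# derived from exon-minus-CDS structure in transcript orientation.

#' Read a transcript annotation from GTF
#'
#' Parses exon and CDS features (Ensembl-style `gene_id`/`transcript_id`
#' attributes, optional `ccds_id`) and derives per-transcript 5'/3'-UTR
#' lengths: the 3'-UTR is the transcript sequence downstream of the CDS
#' stop in transcript orientation (strand-aware). Transcripts without CDS
#' are flagged non-coding with undefined UTR lengths.
#'
#' @param path GTF file path.
#' @return A [transcript_models()] object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0) stop("no exon/CDS features in ", path)
  bad <- which(is.na(df$gene_id) | is.na(df$transcript_id))
  if (length(bad))
    stop("records missing gene_id/transcript_id at feature index: ",
         paste(head(bad, 5), collapse = ", "))
  if (!"ccds_id" %in% names(df)) df$ccds_id <- NA_character_

  ex <- df[df$type == "exon", , drop = FALSE]
  cd <- df[df$type == "CDS", , drop = FALSE]

  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tx)
    cc <- cd[cd$transcript_id == tx, c("start", "end"), drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    # every CDS base must fall inside an exon
    if (nrow(cc)) {
      inside <- vapply(seq_len(nrow(cc)), function(i)
        any(e$start <= cc$start[i] & e$end >= cc$end[i]), TRUE)
      if (!all(inside))
        stop("CDS outside exons in transcript ", tx)
    }
    strand <- as.character(e$strand[1])
    ann <- derive_tx_annotation(e[, c("start", "end")], cc, strand)
    ccds <- e$ccds_id[!is.na(e$ccds_id)]
    if (!length(ccds) && nrow(cc) && "ccds_id" %in% names(cd)) {
      ci <- cd$ccds_id[cd$transcript_id == tx]
      ccds <- ci[!is.na(ci)]
    }
    tx_rows[[tx]] <- data.frame(
      transcript_id = tx, gene_id = e$gene_id[1],
      chrom = as.character(e$seqnames[1]), strand = strand,
      ccds_id = if (length(ccds)) ccds[1] else NA_character_,
      utr3_len = ann$utr3_len, utr5_len = ann$utr5_len,
      cds_len = ann$cds_len, tx_len = ann$tx_len, coding = ann$coding,
      stringsAsFactors = FALSE)
    exon_rows[[tx]] <- data.frame(transcript_id = tx,
                                  start = e$start, end = e$end)
    if (nrow(cc))
      cds_rows[[tx]] <- data.frame(transcript_id = tx,
                                   start = cc$start, end = cc$end)
  }
  transcript_models(do.call(rbind, tx_rows), do.call(rbind, exon_rows),
                    if (length(cds_rows)) do.call(rbind, cds_rows) else
                      data.frame(transcript_id = character(0),
                                 start = integer(0), end = integer(0)))
}

#' Write a transcript annotation to GTF
#'
#' @param tm a [transcript_models()] object.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(tm, path) {
  txs <- tm$transcripts
  rows <- list()
  for (i in seq_len(nrow(txs))) {
    tx <- txs$transcript_id[i]
    e <- tx_exons(tm, tx)
    cc <- tx_cds(tm, tx)
    feat <- rbind(
      data.frame(type = "transcript", start = min(e$start), end = max(e$end)),
      data.frame(type = "exon", start = e$start, end = e$end),
      if (nrow(cc)) data.frame(type = "CDS", start = cc$start, end = cc$end))
    feat$seqnames <- txs$chrom[i]
    feat$strand <- txs$strand[i]
    feat$gene_id <- txs$gene_id[i]
    feat$transcript_id <- tx
    feat$ccds_id <- txs$ccds_id[i]
    rows[[i]] <- feat
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  S4Vectors::mcols(gr)$ccds_id <- df$ccds_id
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
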