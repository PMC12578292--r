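# Mutation-site (VCF) and per-cell allele-count I/O.

#' Read mutation sites and per-cell allele counts
#'
#' @param vcf_path minimal VCF v4 (CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO);
#'   the optional INFO key `GENE=` carries a gene id.
#' @param counts_path TSV with columns `site_id`, `cell_id`, `c_wt`,
#'   `c_mut`, `c_other`; `site_id` matches the VCF ID column (`chrom_pos`
#'   when ID is missing). Cells never observed at a
#'   site get all-zero counts (uncovered).
#' @param cell_ids cell universe (columns of the result); defaults to the
#'   cells present in the count table.
#' @param pass_only drop records whose FILTER is not PASS (or `.`), with a
#'   message reporting how many were removed.
#' @return An [allelic_counts()].
#' @export
read_mutation_inputs <- function(vcf_path, counts_path, cell_ids = NULL,
                                 pass_only = FALSE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (pass_only) {
    keep <- fix$FILTER %in% c("PASS", ".")
    if (any(!keep))
      message(sum(!keep), " non-PASS variant record(s) dropped")
    fix <- fix[keep, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no usable variant records in ", vcf_path)
  gene <- rep(NA_character_, nrow(fix))
  has_gene <- grepl("GENE=", fix$INFO)
  gene[has_gene] <- sub(".*GENE=([^;]+).*", "\\1", fix$INFO[has_gene])
  ids <- fix$ID
  if (is.null(ids)) ids <- rep(NA_character_, nrow(fix))
  ids <- ifelse(is.na(ids) | ids == ".",
                paste(fix$CHROM, fix$POS, sep = "_"), ids)
  sites <- data.frame(site_id = ids,
                      chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, gene_id = gene,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sites$site_id)) stop("duplicate sites in VCF")

  cnt <- read.table(counts_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("site_id", "cell_id", "c_wt", "c_mut", "c_other")
  if (!all(need %in% names(cnt)))
    stop("allele count table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(cnt$site_id, sites$site_id)
  if (length(unknown))
    stop("counts refer to sites absent from VCF: ",
         paste(head(unknown, 5), collapse = ", "))
  if (anyDuplicated(cnt[, c("site_id", "cell_id")]))
    stop("duplicate (site, cell) rows in allele count table")
  if (is.null(cell_ids)) cell_ids <- sort(unique(cnt$cell_id))
  dn <- list(sites$site_id, cell_ids)
  wt <- mut <- oth <- matrix(0L, nrow(sites), length(cell_ids), dimnames = dn)
  ri <- match(cnt$site_id, sites$site_id)
  ci <- match(cnt$cell_id, cell_ids)
  if (anyNA(ci)) stop("counts refer to cells outside the cell universe")
  wt[cbind(ri, ci)] <- cnt$c_wt
  mut[cbind(ri, ci)] <- cnt$c_mut
  oth[cbind(ri, ci)] <- cnt$c_other
  allelic_counts(sites, wt, mut, oth)
}

#' Write mutation sites (VCF) and per-cell allele counts (TSV)
#'
#' Only (site, cell) pairs with at least one read are written to the count
#' table; uncovered pairs are implicit zeros.
#'
#' @param ac an [allelic_counts()].
#' @param vcf_path,counts_path output paths.
#' @return invisibly, the two paths.
#' @export
write_mutation_inputs <- function(ac, vcf_path, counts_path) {
  s <- ac$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tGENE=%s",
                  s$chrom, s$pos, s$site_id, s$ref, s$alt, s$gene_id)
  writeLines(c(hdr, body), vcf_path)
  tot <- ac$wt + ac$mut + ac$other
  idx <- which(tot > 0, arr.ind = TRUE)
  cnt <- data.frame(site_id = rownames(tot)[idx[, 1]],
                    cell_id = colnames(tot)[idx[, 2]],
                    c_wt = ac$wt[idx], c_mut = ac$mut[idx],
                    c_other = ac$other[idx])
  cnt <- cnt[order(cnt$site_id, cnt$cell_id), , drop = FALSE]
  write.table(cnt, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf_path, counts_path))
}
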