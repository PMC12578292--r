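# Synthetic per-cell allelic pileup counts at somatic mutation sites.
#
# Reads at a site in a non-carrier cell are wild-type except for uniform
# sequencing error at rate `error_rate`: a misread lands on each of the
# three non-reference bases with equal probability, so the specific mutant
# base receives error_rate/3 of reads and the two remaining bases ("other")
# receive 2*error_rate/3. In carrier cells the mutant allele is expressed
# at `mutant_allele_fraction`, scaled so that E[mut/(wt+mut)] equals the
# configured fraction exactly.

#' Simulate per-site per-cell allelic read counts
#'
#' @param config a [sim_config()].
#' @param cells cell metadata data.frame with columns `cell_id` and
#'   `cell_class` (values `normal`/`cancer`), e.g. `truth$cells` from
#'   [simulate_expression()].
#' @return list with `counts` (an [allelic_counts()]) and `truth` (class
#'   `allelic_truth`: data.frame of carrier (site_id, cell_id) pairs plus
#'   the site table).
#' @export
simulate_allelic_counts <- function(config, cells) {
  stopifnot(all(c("cell_id", "cell_class") %in% names(cells)))
  cancer_cells <- cells$cell_id[cells$cell_class == "cancer"]
  if (config$mutant_cell_fraction > 0 && length(cancer_cells) == 0)
    stop("mutant_cell_fraction > 0 requires cancer cells")
  set.seed(config$seed + 2L)

  ns <- config$n_mutation_sites
  nc <- nrow(cells)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  sites <- data.frame(site_id = sprintf("s%03d", seq_len(ns)),
                      chrom = "chr1", pos = 1000000L + seq_len(ns) * 1000L,
                      ref = ref, alt = unname(alt),
                      gene_id = sprintf("mutg%03d", seq_len(ns)),
                      stringsAsFactors = FALSE)

  dn <- list(sites$site_id, cells$cell_id)
  wt <- mut <- oth <- matrix(0L, ns, nc, dimnames = dn)

  n_carrier <- round(config$mutant_cell_fraction * length(cancer_cells))
  carriers <- list()
  e <- config$error_rate
  maf <- config$mutant_allele_fraction
  for (s in seq_len(ns)) {
    car <- if (n_carrier > 0) sample(cancer_cells, n_carrier) else character(0)
    carriers[[s]] <- car
    covered <- runif(nc) >= config$coverage_zero_prob
    n_reads <- ifelse(covered, rpois(nc, config$coverage_mean), 0L)
    is_car <- cells$cell_id %in% car
    # carrier: mut/(wt+mut) has expectation maf; error reads split 1/3-2/3
    p_mut <- ifelse(is_car, maf * (1 - 2 * e / 3), e / 3)
    p_oth <- rep(2 * e / 3, nc)
    for (c in which(n_reads > 0)) {
      draw <- stats::rmultinom(1, n_reads[c],
                               c(1 - p_mut[c] - p_oth[c], p_mut[c], p_oth[c]))
      wt[s, c] <- draw[1]; mut[s, c] <- draw[2]; oth[s, c] <- draw[3]
    }
  }
  carrier_df <- do.call(rbind, lapply(seq_len(ns), function(s)
    if (length(carriers[[s]]))
      data.frame(site_id = sites$site_id[s], cell_id = carriers[[s]],
                 stringsAsFactors = FALSE)))
  if (is.null(carrier_df))
    carrier_df <- data.frame(site_id = character(0), cell_id = character(0))
  list(counts = allelic_counts(sites, wt, mut, oth),
       truth = structure(list(carriers = carrier_df, sites = sites),
                         class = "allelic_truth"))
}
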