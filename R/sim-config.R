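# Simulation configuration for the synthetic long-read scRNA-seq generator.

#' Build a simulation configuration
#'
#' Defines the study conditions emulated by the synthetic generator: a cohort
#' of tumor and matched-normal epithelial cells profiled with two full-length
#' scRNA-seq technology batches, multi-isoform genes whose isoforms differ in
#' UTR length, exon structure and CDS, negative-binomial counts with
#' log-normal library sizes, and per-cell allelic pileup counts at somatic
#' mutation sites with a uniform sequencing-error process.
#'
#' Planted effects give every downstream statistic a ground truth:
#' \describe{
#'   \item{planted_apa}{data.frame(gene, delta_utr3, group): the affected
#'     group's expected expressed 3'-UTR length differs from the other
#'     group's by `delta_utr3` bases (negative = shortening).}
#'   \item{planted_das}{data.frame(gene, type, dpsi, group): a local
#'     splicing event of `type` (SE, RI, A5, A3, AF, AL, MX) whose expected
#'     inclusion PSI is 0.5 in the reference group and `0.5 + dpsi` in the
#'     affected group.}
#'   \item{planted_dtu}{data.frame(gene, prop_a1, prop_b1): two-isoform
#'     switch genes; isoform 1 has expected proportion `prop_a1` in group
#'     "normal" and `prop_b1` in group "cancer"; the two isoforms carry
#'     different CDS so the switch is also a CDS switch.}
#'   \item{planted_sf_coupling}{data.frame(sf_gene, event_gene, sign): a
#'     single-isoform splicing-factor gene whose expression co-varies (sign
#'     +1/-1) with the per-cell inclusion PSI of an SE event gene.}
#'   \item{planted_programs}{data.frame(gene, group, log2fc): group-specific
#'     expression shifts (marker programs, DE truth).}
#' }
#'
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @param n_genes number of background genes (planted genes are added on top).
#' @param isoform_probs probability over isoform counts 1..6 for background
#'   genes.
#' @param n_cells_per_group named integer vector; must include `normal`, all
#'   other names are treated as cancer groups (e.g. `cancer`, or `iCMS2` and
#'   `iCMS3`).
#' @param n_patients patients per group (cells are split round-robin).
#' @param n_batches technology batches (patients are split across batches).
#' @param n_exons exons in the backbone gene template (>= 4).
#' @param library_size_meanlog,library_size_sdlog log-normal reads/cell.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param planted_apa,planted_das,planted_dtu,planted_sf_coupling,planted_programs
#'   see Details; `NULL` for none.
#' @param n_mutation_sites somatic mutation sites to simulate.
#' @param error_rate per-read probability of a misread base.
#' @param mutant_cell_fraction fraction of cancer cells carrying each mutation.
#' @param mutant_allele_fraction expected mut/(wt+mut) in carrier cells.
#' @param coverage_mean mean reads per covered site per cell (Poisson).
#' @param coverage_zero_prob probability a (site, cell) pair is uncovered.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       isoform_probs = c(0.40, 0.30, 0.15, 0.10, 0.035, 0.015),
                       n_cells_per_group = c(normal = 200L, cancer = 200L),
                       n_patients = 4L,
                       n_batches = 2L,
                       n_exons = 8L,
                       library_size_meanlog = log(20000),
                       library_size_sdlog = 0.3,
                       nb_dispersion = 0.3,
                       planted_apa = NULL,
                       planted_das = NULL,
                       planted_dtu = NULL,
                       planted_sf_coupling = NULL,
                       planted_programs = NULL,
                       n_mutation_sites = 20L,
                       error_rate = 0.03,
                       mutant_cell_fraction = 0.6,
                       mutant_allele_fraction = 0.5,
                       coverage_mean = 6,
                       coverage_zero_prob = 0.4) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              isoform_probs = isoform_probs,
              n_cells_per_group = n_cells_per_group,
              n_patients = as.integer(n_patients),
              n_batches = as.integer(n_batches),
              n_exons = as.integer(n_exons),
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              nb_dispersion = nb_dispersion,
              planted_apa = planted_apa, planted_das = planted_das,
              planted_dtu = planted_dtu,
              planted_sf_coupling = planted_sf_coupling,
              planted_programs = planted_programs,
              n_mutation_sites = as.integer(n_mutation_sites),
              error_rate = error_rate,
              mutant_cell_fraction = mutant_cell_fraction,
              mutant_allele_fraction = mutant_allele_fraction,
              coverage_mean = coverage_mean,
              coverage_zero_prob = coverage_zero_prob)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_patients >= 1, cfg$n_batches >= 1,
            cfg$n_exons >= 4)
  if (length(cfg$isoform_probs) != 6 || any(cfg$isoform_probs < 0) ||
      abs(sum(cfg$isoform_probs) - 1) > 1e-8)
    stop("isoform_probs must be 6 non-negative values summing to 1")
  if (!"normal" %in% names(cfg$n_cells_per_group))
    stop("n_cells_per_group must include a 'normal' group")
  if (any(cfg$n_cells_per_group < 1)) stop("cell counts must be >= 1")
  for (f in c("error_rate", "mutant_cell_fraction", "mutant_allele_fraction",
              "coverage_zero_prob")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  # isoform structures are built by applying distinct structural variants to
  # a shared backbone; a small exon template supports few distinct variants
  max_iso <- max(which(cfg$isoform_probs > 0))
  if (max_iso - 1 > length(variant_ops(cfg$n_exons)))
    stop(sprintf(paste0("config requests up to %d isoform structures but the ",
                        "%d-exon template supports at most %d"),
                 max_iso, cfg$n_exons, length(variant_ops(cfg$n_exons)) + 1))
  if (!is.null(cfg$planted_das)) {
    stopifnot(all(cfg$planted_das$dpsi >= -1), all(cfg$planted_das$dpsi <= 1))
    if (any(abs(cfg$planted_das$dpsi) > 0.45))
      stop("|dpsi| must be <= 0.45 (reference PSI is 0.5)")
    if (!all(cfg$planted_das$type %in% c("SE", "RI", "A5", "A3", "AF", "AL", "MX")))
      stop("unknown splicing event type in planted_das")
  }
  if (!is.null(cfg$planted_dtu)) {
    p <- cfg$planted_dtu
    stopifnot(all(p$prop_a1 >= 0 & p$prop_a1 <= 1),
              all(p$prop_b1 >= 0 & p$prop_b1 <= 1))
  }
  invisible(cfg)
}

# Structural variant operations available on an n-exon backbone. Internal
# slots (exons 3 .. n-2) host CDS-altering variants; termini host UTR and
# first/last-exon variants. Returned as "op:slot" identifiers.
variant_ops <- function(n_exons) {
  ops <- character(0)
  internal <- if (n_exons >= 6) seq(3L, n_exons - 2L) else integer(0)
  for (j in internal) ops <- c(ops, paste0("se:", j), paste0("a5:", j),
                               paste0("a3:", j), paste0("mx:", j))
  if (length(internal) >= 2)
    for (j in internal[-length(internal)]) ops <- c(ops, paste0("ri:", j))
  c(ops, "af:1", "al:1", "utr3:1", "utr5:1")
}
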