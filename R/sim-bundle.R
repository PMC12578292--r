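# One-call fixture bundle: annotation + counts + metadata + mutation inputs
# + truth JSON, all plain text, round-trippable through the readers.

#' Simulate and write a complete fixture bundle
#'
#' Runs [simulate_annotation()], [simulate_expression()] and
#' [simulate_allelic_counts()] for `config` and writes: `annotation.gtf`,
#' `matrix.mtx` (+ `features.tsv`, `barcodes.tsv`), `counts.tsv`,
#' `cell_metadata.tsv`, `sites.vcf`, `allele_counts.tsv` and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return invisibly, a list with the in-memory objects (`annotation`,
#'   `expr`, `truth`, `allelic`, `allelic_truth`) and `dir`.
#' @export
write_fixture_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anno <- simulate_annotation(config)
  sim <- simulate_expression(config, anno)
  al <- simulate_allelic_counts(config, sim$truth$cells)

  write_annotation(anno, file.path(dir, "annotation.gtf"))
  write_counts(sim$expr, dir)
  write_mutation_inputs(al$counts, file.path(dir, "sites.vcf"),
                        file.path(dir, "allele_counts.tsv"))

  truth_json <- list(
    apa = df_or_empty(sim$truth$apa),
    das = df_or_empty(sim$truth$das),
    dtu = df_or_empty(sim$truth$dtu),
    sf = df_or_empty(sim$truth$sf),
    programs = df_or_empty(sim$truth$programs),
    carriers = df_or_empty(al$truth$carriers))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(list(annotation = anno, expr = sim$expr, truth = sim$truth,
                 allelic = al$counts, allelic_truth = al$truth, dir = dir))
}

df_or_empty <- function(x) if (is.null(x)) list() else x
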