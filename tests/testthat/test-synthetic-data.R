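# Synthetic-data generator: determinism, planted-effect encoding, error
# process calibration.

test_that("annotation generation is deterministic and honors templates", {
  cfg <- sim_config(seed = 42, n_genes = 5,
                    planted_das = data.frame(type = "SE", dpsi = 0.2,
                                             group = "cancer"))
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$transcripts, a2$transcripts)
  expect_identical(a1$exons, a2$exons)

  # byte-identical GTF for the same seed
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_annotation(a1, f1); write_annotation(a2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # SE template: a gene whose two isoforms share flanking exons, one
  # skipping an exon the other keeps
  ev <- extract_events(a1)
  se <- ev[ev$gene_id == "das01" & ev$type == "SE", ]
  expect_equal(nrow(se), 1)

  # degenerate config: single gene, single isoform
  cfg1 <- sim_config(seed = 1, n_genes = 1,
                     isoform_probs = c(1, 0, 0, 0, 0, 0))
  a <- simulate_annotation(cfg1)
  expect_equal(nrow(a$transcripts), 1)
  expect_true(a$transcripts$utr3_len > 0)
})

test_that("configs requesting more structures than the template allows fail", {
  expect_error(
    sim_config(seed = 1, n_genes = 2, n_exons = 4,
               isoform_probs = c(0, 0, 0, 0, 0, 1)),
    "template")
})

test_that("multi-isoform genes differ in structure, UTR or CDS", {
  cfg <- sim_config(seed = 9, n_genes = 40)
  a <- simulate_annotation(cfg)
  for (g in unique(a$transcripts$gene_id)) {
    ids <- a$transcripts$transcript_id[a$transcripts$gene_id == g]
    if (length(ids) < 2) next
    keys <- vapply(ids, function(tx) {
      e <- sciso:::tx_exons(a, tx)
      paste(e$start, e$end, collapse = ";")
    }, "")
    expect_equal(anyDuplicated(keys), 0)
  }
})

test_that("planted DTU proportions are recovered from pooled counts", {
  cfg <- sim_config(seed = 5, n_genes = 4,
                    n_cells_per_group = c(normal = 500, cancer = 500),
                    planted_dtu = data.frame(prop_a1 = 0.8, prop_b1 = 0.2))
  anno <- simulate_annotation(cfg)
  sim <- simulate_expression(cfg, anno)
  counts <- as.matrix(sim$expr$counts)
  meta <- sim$expr$metadata
  iso <- grep("^dtu01", rownames(counts), value = TRUE)
  for (grp in c("normal", "cancer")) {
    pooled <- rowSums(counts[iso, meta$group == grp, drop = FALSE])
    want <- if (grp == "normal") 0.8 else 0.2
    expect_lt(abs(pooled["dtu01.t1"] / sum(pooled) - want), 0.05)
  }
})

test_that("library-size scaling changes depth, not proportions", {
  base <- sim_config(seed = 3, n_genes = 10,
                     n_cells_per_group = c(normal = 80, cancer = 80))
  up <- base; up$library_size_meanlog <- base$library_size_meanlog + log(10)
  a1 <- simulate_annotation(base)
  s1 <- simulate_expression(base, a1)
  s2 <- simulate_expression(up, a1)
  r <- sum(s2$expr$counts) / sum(s1$expr$counts)
  expect_lt(abs(r - 10) / 10, 0.05)
  # expected proportions identical by construction
  expect_identical(s1$truth$expected_props, s2$truth$expected_props)
})

test_that("planted genes missing from the annotation are reported", {
  cfg <- sim_config(seed = 2, n_genes = 3)
  anno <- simulate_annotation(cfg)
  cfg2 <- cfg
  cfg2$planted_programs <- data.frame(gene = "not_a_gene", group = "cancer",
                                      log2fc = 1)
  attr(anno, "config") <- cfg2
  expect_error(simulate_expression(cfg2, anno), "not_a_gene")
})

test_that("allelic error process follows the one-third / two-thirds split", {
  # no carriers, error rate 3%: pooled other ~ 2%, mutant ~ 1% of reads
  cfg <- sim_config(seed = 8, n_genes = 2,
                    n_cells_per_group = c(normal = 250, cancer = 250),
                    n_mutation_sites = 25, error_rate = 0.03,
                    mutant_cell_fraction = 0, coverage_zero_prob = 0.2,
                    coverage_mean = 8)
  cells <- sciso:::make_cell_metadata(cfg)
  al <- simulate_allelic_counts(cfg, cells)
  tot <- sum(al$counts$wt) + sum(al$counts$mut) + sum(al$counts$other)
  expect_lt(abs(sum(al$counts$other) / tot - 0.02), 0.003)
  expect_lt(abs(sum(al$counts$mut) / tot - 0.01), 0.003)

  # noiseless null: zero mutant reads anywhere
  cfg0 <- cfg; cfg0$error_rate <- 0
  al0 <- simulate_allelic_counts(cfg0, cells)
  expect_equal(sum(al0$counts$mut), 0)
  expect_equal(sum(al0$counts$other), 0)

  # full mutant allele fraction: no wild-type reads in carrier cells
  cfg1 <- cfg; cfg1$error_rate <- 0; cfg1$mutant_cell_fraction <- 1
  cfg1$mutant_allele_fraction <- 1
  al1 <- simulate_allelic_counts(cfg1, cells)
  carriers <- unique(al1$truth$carriers$cell_id)
  expect_equal(sum(al1$counts$wt[, carriers]), 0)
  expect_gt(sum(al1$counts$mut[, carriers]), 0)
})

test_that("carrier simulation requires cancer cells", {
  cfg <- sim_config(seed = 1, n_genes = 2, mutant_cell_fraction = 0.5)
  cells <- data.frame(cell_id = c("c1", "c2"),
                      cell_class = c("normal", "normal"))
  expect_error(simulate_allelic_counts(cfg, cells), "cancer")
})

test_that("fixture bundles round-trip through the readers", {
  cfg <- sim_config(seed = 21, n_genes = 8,
                    n_cells_per_group = c(normal = 30, cancer = 30),
                    n_mutation_sites = 5,
                    planted_apa = data.frame(delta_utr3 = -40,
                                             group = "cancer"))
  dir <- tempfile()
  b <- write_fixture_bundle(cfg, dir)
  expect_true(all(c("annotation.gtf", "matrix.mtx", "counts.tsv",
                    "cell_metadata.tsv", "sites.vcf", "allele_counts.tsv",
                    "truth.json") %in% list.files(dir)))
  a2 <- read_annotation(file.path(dir, "annotation.gtf"))
  expect_equal(a2$transcripts$utr3_len, b$annotation$transcripts$utr3_len)
  expect_equal(a2$exons, b$annotation$exons)

  em_mtx <- read_counts(file.path(dir, "matrix.mtx"),
                        file.path(dir, "cell_metadata.tsv"))
  em_tsv <- read_counts(file.path(dir, "counts.tsv"),
                        file.path(dir, "cell_metadata.tsv"))
  expect_equal(as.matrix(em_mtx$counts), as.matrix(b$expr$counts))
  expect_equal(as.matrix(em_tsv$counts), as.matrix(em_mtx$counts))

  ac <- read_mutation_inputs(file.path(dir, "sites.vcf"),
                             file.path(dir, "allele_counts.tsv"),
                             cell_ids = colnames(b$allelic$wt))
  expect_equal(ac$mut, b$allelic$mut)
  expect_equal(ac$wt, b$allelic$wt)

  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(tr$apa$gene), "apa01")
  expect_equal(nrow(b$allelic_truth$carriers),
               length(tr$carriers$site_id))
  unlink(dir, recursive = TRUE)
})

test_that("empty planted-effect config yields empty truth lists", {
  cfg <- sim_config(seed = 4, n_genes = 3,
                    n_cells_per_group = c(normal = 10, cancer = 10),
                    n_mutation_sites = 2, mutant_cell_fraction = 0)
  dir <- tempfile()
  write_fixture_bundle(cfg, dir)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_length(tr$apa, 0)
  expect_length(tr$dtu, 0)
  expect_length(tr$carriers$site_id, 0)
  unlink(dir, recursive = TRUE)
})
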