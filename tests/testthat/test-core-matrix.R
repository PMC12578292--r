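# Normalization, QC boundaries, HVG selection, Wilcoxon DE, complexity,
# down-sampling.

test_that("TPM normalization matches its definition", {
  counts <- matrix(c(5, 15, 80), 3, 1, dimnames = list(paste0("t", 1:3), "c1"))
  em <- make_em(counts, setNames(paste0("g", 1:3), paste0("t", 1:3)))
  nm <- normalize_expression(em, "isoform")
  expect_equal(unname(nm$tpm[, 1]), c(50000, 150000, 800000))
  expect_equal(sum(nm$tpm[, 1]), 1e6)
  # log view: TPM 10 -> ln(2)
  expect_equal(log(10 / 10 + 1), log(2))
  expect_equal(nm$logexpr[1, 1], log(nm$tpm[1, 1] / 10 + 1))

  # scale invariance: doubling a cell's counts leaves TPM unchanged
  em2 <- make_em(counts * 2, setNames(paste0("g", 1:3), paste0("t", 1:3)))
  expect_equal(normalize_expression(em2, "isoform")$tpm, nm$tpm)

  # per-cell sums are exactly 1e6 on a larger random matrix
  set.seed(1)
  big <- matrix(rpois(600, 4), 30, 20,
                dimnames = list(sprintf("t%02d", 1:30), sprintf("c%02d", 1:20)))
  emb <- make_em(big, setNames(rep(sprintf("g%02d", 1:10), each = 3),
                               sprintf("t%02d", 1:30)))
  tps <- colSums(normalize_expression(emb, "isoform")$tpm)
  expect_true(all(abs(tps - 1e6) < 1e-6 * 1e6))
})

test_that("gene-level normalization sums isoforms through the gene map", {
  counts <- matrix(c(1, 3, 6), 3, 1, dimnames = list(paste0("t", 1:3), "c1"))
  em <- make_em(counts, c(t1 = "g1", t2 = "g1", t3 = "g2"))
  nm <- normalize_expression(em, "gene")
  expect_equal(unname(nm$tpm["g1", 1]), 4e5)
  expect_equal(unname(nm$tpm["g2", 1]), 6e5)
})

test_that("cell QC boundaries follow the printed rules", {
  # 600 genes, one isoform each; cellA detects 499 genes, cellB 500
  n <- 600
  counts <- matrix(0, n, 2, dimnames = list(sprintf("t%03d", 1:n),
                                            c("cellA", "cellB")))
  counts[1:499, 1] <- 1
  counts[1:500, 2] <- 1
  gm <- setNames(sprintf("g%03d", 1:n), sprintf("t%03d", 1:n))
  em <- make_em(counts, gm)
  suppressWarnings(out <- qc_filters(em, mito_genes = character(0),
                                     min_cells = 1, min_individuals = 1))
  expect_equal(colnames(out$counts), "cellB")

  # mito fraction exactly 0.60 is kept; above is dropped
  counts <- matrix(0, 600, 2, dimnames = list(sprintf("t%03d", 1:600),
                                              c("at60", "above60")))
  counts[1:400, ] <- 1             # 400 nuclear reads
  counts[600, 1] <- 600            # 600/1000: exactly 60%
  counts[600, 2] <- 601            # 601/1001: above 60%
  em <- make_em(counts, gm[1:600])
  out <- qc_filters(em, mito_genes = "g600", min_genes = 1,
                    min_cells = 1, min_individuals = 1)
  expect_equal(colnames(out$counts), "at60")
})

test_that("isoform filter needs three cells in each of three individuals", {
  # one isoform expressed in 3 cells of only 2 patients -> removed;
  # another expressed in 3 cells of 3 patients -> kept
  cells <- sprintf("c%02d", 1:9)
  pat <- rep(c("P1", "P2", "P3"), each = 3)
  counts <- matrix(0, 3, 9, dimnames = list(c("keep", "drop", "filler"), cells))
  counts["keep", ] <- 1                      # 3 cells in all 3 patients
  counts["drop", 1:6] <- 1                   # 3 cells in P1 and P2 only
  counts["filler", ] <- 1
  em <- make_em(counts, c(keep = "g1", drop = "g2", filler = "g3"),
                patient = pat)
  out <- qc_filters(em, mito_genes = "none", min_genes = 1)
  expect_true("keep" %in% rownames(out$counts))
  expect_false("drop" %in% rownames(out$counts))
  expect_equal(attr(out, "qc_report")$isoforms_removed, 1)
})

test_that("HVG selection ranks dispersion and unions batches", {
  set.seed(7)
  n <- 60
  counts <- matrix(rpois(n * 40, 20), n, 40,
                   dimnames = list(sprintf("g%02d", 1:n), sprintf("c%02d", 1:40)))
  counts["g01", ] <- rpois(40, 20) * sample(c(1, 40), 40, replace = TRUE)
  counts["g02", ] <- 20                     # constant -> never selected
  gm <- setNames(rownames(counts), rownames(counts))
  em <- make_em(counts, gm)
  nm <- normalize_expression(em, "gene")
  top <- select_hvg(nm, n = 5, batch = rep("b1", 40))
  expect_true("g01" %in% top)
  expect_false("g02" %in% top)

  # two batches with disjoint top lists: union has both
  batch <- rep(c("b1", "b2"), each = 20)
  counts2 <- matrix(rpois(n * 40, 20), n, 40, dimnames = dimnames(counts))
  counts2["g03", batch == "b1"] <- rpois(20, 20) * sample(c(1, 50), 20, TRUE)
  counts2["g04", batch == "b2"] <- rpois(20, 20) * sample(c(1, 50), 20, TRUE)
  em2 <- make_em(counts2, gm)
  nm2 <- normalize_expression(em2, "gene")
  top2 <- select_hvg(nm2, n = 1, batch = batch)
  expect_setequal(top2, c("g03", "g04"))

  expect_warning(select_hvg(nm, n = 1000), "all genes")
})

test_that("Wilcoxon DE applies the fold-change and BH gates", {
  set.seed(3)
  nA <- 50; nB <- 50
  counts <- matrix(rnbinom(40 * 100, mu = 30, size = 1 / 0.3), 40, 100,
                   dimnames = list(sprintf("g%02d", 1:40), sprintf("c%03d", 1:100)))
  counts["g01", 1:nA] <- rnbinom(nA, mu = 120, size = 1 / 0.3)   # 4-fold up
  gm <- setNames(rownames(counts), rownames(counts))
  em <- make_em(counts, gm)
  nm <- normalize_expression(em, "gene")
  # a feature constant in the normalized matrix: p = 1, FC = 1
  nm$tpm["g02", ] <- 10
  nm$logexpr["g02", ] <- log(2)
  groupA <- sprintf("c%03d", 1:nA); groupB <- sprintf("c%03d", nA + 1:nB)
  de <- wilcoxon_de(nm, groupA, groupB)
  expect_true(de$significant[de$feature == "g01"])
  expect_equal(de$p[de$feature == "g02"], 1)
  expect_equal(de$fc[de$feature == "g02"], 1)
  expect_error(wilcoxon_de(nm, groupA, groupA[1:10]), "overlap")

  # BH adjustment equals the textbook step-up procedure on the raw p's
  p <- de$p
  n <- length(p)
  o <- order(p)
  stepup <- numeric(n)
  stepup[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(de$adj_p, pmin(stepup, 1))
})

test_that("complexity metrics bin genes and compute top-2 shares", {
  counts <- matrix(c(70, 25, 5,   # gene A: 3 isoforms, top2 = 0.95
                     40, 0, 0,    # gene B: 1 expressed isoform
                     10, 10, 0), 9, 1,
                   dimnames = list(sprintf("t%d", 1:9), "c1"))
  counts <- cbind(counts, counts)
  colnames(counts) <- c("c1", "c2")
  gm <- setNames(rep(c("gA", "gB", "gC"), each = 3), sprintf("t%d", 1:9))
  em <- make_em(counts, gm)
  cm <- complexity_metrics(em)
  pg <- cm$per_gene
  expect_equal(pg$top2_share[pg$gene_id == "gA"], 0.95)
  expect_equal(pg$top2_share[pg$gene_id == "gB"], 1.0)
  expect_equal(as.character(pg$bin[pg$gene_id == "gA"]), "2-3")
  expect_equal(sum(cm$bin_fractions), 1)
  expect_equal(cm$per_cell$n_genes, c(3, 3))
})

test_that("down-sampling thins depth and is seed-deterministic", {
  set.seed(2)
  counts <- matrix(rpois(2000, 50), 20, 100,
                   dimnames = list(sprintf("t%02d", 1:20), sprintf("c%03d", 1:100)))
  gm <- setNames(rownames(counts), rownames(counts))
  em <- make_em(counts, gm)
  expect_error(downsample_cells(em, depth_fraction = 0), "depth_fraction")

  full <- downsample_cells(em, depth_fraction = 1, seed = 5)
  expect_equal(as.matrix(full$counts), counts)

  half1 <- downsample_cells(em, n_cells = 50, depth_fraction = 0.5, seed = 5)
  half2 <- downsample_cells(em, n_cells = 50, depth_fraction = 0.5, seed = 5)
  expect_identical(as.matrix(half1$counts), as.matrix(half2$counts))
  expect_equal(ncol(half1$counts), 50)
  tot <- sum(counts[, colnames(half1$counts)])
  expect_lt(abs(sum(half1$counts) - tot / 2), 4 * sqrt(tot * 0.25))
})
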