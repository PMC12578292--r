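# Event extraction, PSI, differential splicing, SF correlation, overlap.

test_that("a skipped exon yields one SE event with the printed id shape", {
  tm <- make_tm(list(
    T1 = data.frame(start = c(101, 301, 501), end = c(200, 400, 600)),
    T2 = data.frame(start = c(101, 501), end = c(200, 600))),
    chrom = "chr", strand = "+")
  ev <- extract_events(tm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_id, "SE:chr:200-301:400-501:+")
  expect_equal(ev$type, "SE")
  expect_equal(ev$inclusion, "T1")
  expect_equal(ev$total, "T1,T2")
})

test_that("a retained intron yields one RI event, retaining isoform included", {
  tm <- make_tm(list(
    T1 = data.frame(start = c(101, 301), end = c(200, 400)),
    T2 = data.frame(start = 101, end = 400)))
  ev <- extract_events(tm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "RI")
  expect_equal(ev$event_id, "RI:chr1:101:200-301:400:+")
  expect_equal(ev$inclusion, "T2")
})

test_that("splice-site shifts are typed strand-aware", {
  iso <- list(
    T1 = data.frame(start = c(101, 301), end = c(200, 400)),
    T2 = data.frame(start = c(101, 301), end = c(260, 400)))
  # donor (left) boundary varies: A5 on +, A3 on -
  ev_p <- extract_events(make_tm(iso, strand = "+"))
  expect_equal(ev_p$type, "A5")
  expect_equal(ev_p$inclusion, "T2")     # longer exon = inclusion form
  ev_m <- extract_events(make_tm(iso, strand = "-"))
  expect_equal(ev_m$type, "A3")
})

test_that("alternative terminal exons are detected and oriented", {
  iso <- list(
    T1 = data.frame(start = c(101, 501), end = c(200, 600)),
    T2 = data.frame(start = c(301, 501), end = c(400, 600)))
  ev <- extract_events(make_tm(iso, strand = "+"))
  expect_equal(ev$type, "AF")
  expect_equal(ev$inclusion, "T1")       # distal first exon
  ev2 <- extract_events(make_tm(iso, strand = "-"))
  expect_equal(ev2$type, "AL")
})

test_that("mutually exclusive exons require non-co-occurrence", {
  iso <- list(
    T1 = data.frame(start = c(101, 301, 701), end = c(200, 400, 800)),
    T2 = data.frame(start = c(101, 501, 701), end = c(200, 600, 800)))
  ev <- extract_events(make_tm(iso))
  expect_equal(ev$type, "MX")
  expect_equal(ev$inclusion, "T1")       # genomic-left exon
  # a third isoform carrying both exons suppresses the MX call
  iso$T3 <- data.frame(start = c(101, 301, 501, 701),
                       end = c(200, 400, 600, 800))
  ev2 <- extract_events(make_tm(iso))
  expect_false(any(ev2$type == "MX"))
})

test_that("event extraction is independent of transcript order", {
  cfg <- sim_config(seed = 33, n_genes = 12)
  tm <- simulate_annotation(cfg)
  ev1 <- extract_events(tm)
  perm <- tm
  ord <- rev(seq_len(nrow(perm$transcripts)))
  perm$transcripts <- perm$transcripts[ord, ]
  perm <- transcript_models(perm$transcripts, perm$exons, perm$cds)
  ev2 <- extract_events(perm)
  expect_equal(ev1, ev2)
})

test_that("extraction matches the brute-force enumeration oracle", {
  # exhaustive comparison on simulated genes with up to 4 isoforms
  cfg <- sim_config(seed = 101, n_genes = 40,
                    isoform_probs = c(0.1, 0.3, 0.3, 0.3, 0, 0))
  tm <- simulate_annotation(cfg)
  got <- extract_events(tm)[, c("event_id", "inclusion", "total")]
  want <- oracle_events(tm)
  expect_equal(got, want)
})

test_that("PSI is the inclusion share of event TPM", {
  tm <- make_tm(list(
    T1 = data.frame(start = c(101, 301, 501), end = c(200, 400, 600)),
    T2 = data.frame(start = c(101, 501), end = c(200, 600))),
    chrom = "chr", strand = "+")
  ev <- extract_events(tm)
  counts <- matrix(c(30, 10, 40, 0, 0.4, 0.3), 2, 3,
                   dimnames = list(c("T1", "T2"), c("c1", "c2", "c3")))
  nm <- list(tpm = counts, logexpr = log(counts / 10 + 1), level = "isoform",
             metadata = data.frame(cell_id = colnames(counts)),
             gene_map = c(T1 = "g1", T2 = "g1"))
  class(nm) <- "norm_matrix"
  pm <- compute_psi(nm, ev)
  expect_equal(unname(pm$psi[1, "c1"]), 0.75)
  expect_equal(unname(pm$psi[1, "c2"]), 1.0)       # only inclusion expressed
  expect_true(is.na(pm$psi[1, "c3"]))              # below min_total_tpm

  # complement symmetry: swapping inclusion and exclusion gives 1 - PSI
  swapped <- ev
  swapped$inclusion <- "T2"
  pm2 <- compute_psi(nm, swapped)
  def <- !is.na(pm$psi)
  expect_equal(pm2$psi[def], 1 - pm$psi[def])
})

test_that("differential splicing applies the p and delta-PSI gates", {
  set.seed(21)
  n <- 300
  cells <- sprintf("c%03d", 1:(2 * n))
  ga <- cells[1:n]; gb <- cells[n + 1:n]
  psi <- matrix(NA_real_, 2, 2 * n, dimnames = list(c("e1", "e2"), cells))
  psi["e1", ] <- pmin(1, pmax(0, c(rnorm(n, 0.5, 0.1), rnorm(n, 0.5, 0.1))))
  # large-n shift of 0.08: significant p but below the 0.1 magnitude gate
  psi["e2", ] <- pmin(1, pmax(0, c(rnorm(n, 0.58, 0.1), rnorm(n, 0.5, 0.1))))
  pmx <- structure(list(psi = psi,
                        events = data.frame(event_id = c("e1", "e2"),
                                            type = c("SE", "SE"),
                                            gene_id = c("g1", "g2")),
                        min_total_tpm = 1), class = "psi_matrix")
  das <- differential_splicing(pmx, ga, gb)
  expect_false(das$significant[1])
  expect_lt(das$p[2], 0.05)
  expect_false(das$significant[2])

  # identical groups: delta 0, not significant
  das0 <- differential_splicing(pmx, ga, ga)
  expect_equal(das0$dpsi[1], 0)
  expect_false(any(das0$significant))

  # insufficient defined cells: skipped with reason
  psi["e1", ] <- NA
  pmx$psi <- psi
  das2 <- differential_splicing(pmx, ga, gb)
  expect_equal(das2$note[1], "insufficient_cells")
})

test_that("per-patient mode unions patient-level comparisons", {
  set.seed(9)
  n <- 60
  cells <- sprintf("c%03d", 1:(2 * n))
  ga <- cells[1:n]; gb <- cells[n + 1:n]
  psi <- matrix(runif(2 * n * 1, 0.3, 0.7), 1, 2 * n,
                dimnames = list("e1", cells))
  pmx <- structure(list(psi = psi,
                        events = data.frame(event_id = "e1", type = "SE",
                                            gene_id = "g1"),
                        min_total_tpm = 1), class = "psi_matrix")
  patient <- setNames(rep(c("P1", "P2"), length.out = n), ga)
  das <- differential_splicing(pmx, ga, gb, patient = patient)
  expect_setequal(das$patient, c("P1", "P2"))
  expect_equal(nrow(das), 2)
})

test_that("SF-PSI correlation clusters events by sign and tests RI", {
  set.seed(31)
  n <- 120
  cells <- sprintf("c%03d", 1:n)
  sf <- rnorm(n)
  # 5 events follow the factor, 5 oppose it
  psi <- rbind(
    matrix(rep(sf, 5), 5, n, byrow = TRUE) + rnorm(5 * n, 0, 0.3),
    matrix(rep(-sf, 5), 5, n, byrow = TRUE) + rnorm(5 * n, 0, 0.3))
  psi <- (psi - min(psi)) / diff(range(psi))
  rownames(psi) <- c(sprintf("RI:chr1:%d:+", 1:5), sprintf("SE:chr1:%d:+", 1:5))
  colnames(psi) <- cells
  pmx <- structure(list(psi = psi,
                        events = data.frame(event_id = rownames(psi),
                                            type = rep(c("RI", "SE"), each = 5),
                                            gene_id = sprintf("g%d", 1:10)),
                        min_total_tpm = 1), class = "psi_matrix")
  sf_nm <- list(tpm = matrix(exp(sf), 1, n, dimnames = list("SF1", cells)),
                logexpr = matrix(sf, 1, n, dimnames = list("SF1", cells)),
                level = "gene", metadata = data.frame(cell_id = cells))
  class(sf_nm) <- "norm_matrix"
  res <- sf_psi_correlation(pmx, sf_nm, "SF1", k = 2)
  cl <- res$clusters
  expect_equal(length(unique(cl[grepl("^RI", names(cl))])), 1)
  expect_equal(length(unique(cl[grepl("^SE", names(cl))])), 1)
  expect_true(all(res$correlation[grepl("^RI", rownames(res$correlation)), ] > 0))
  expect_true(all(res$correlation[grepl("^SE", rownames(res$correlation)), ] < 0))
  # perfectly coupled vector correlates at 1
  pmx$psi["RI:chr1:1:+", ] <- sf
  res2 <- sf_psi_correlation(pmx, sf_nm, "SF1", k = 2)
  expect_equal(unname(res2$correlation["RI:chr1:1:+", "SF1"]), 1)
})

test_that("Fisher RI-enrichment matches exact hypergeometric enumeration", {
  # cluster of 30 with 10 RI vs rest of 31 with 1 RI
  clusters <- c(rep(1, 30), rep(2, 31))
  is_ri <- c(rep(TRUE, 10), rep(FALSE, 20), TRUE, rep(FALSE, 30))
  tab <- matrix(c(10, 20, 1, 30), 2)
  p_fisher <- fisher.test(tab)$p.value
  # independent oracle: sum of hypergeometric point probabilities no more
  # likely than the observed table
  m <- 11; nn <- 50; kk <- 30
  probs <- dhyper(0:m, m, nn, kk)
  p_exact <- sum(probs[probs <= dhyper(10, m, nn, kk) * (1 + 1e-7)])
  expect_equal(p_fisher, p_exact, tolerance = 1e-10)
})

test_that("signature overlap uses the 5% gate and hypergeometric tail", {
  mk <- function(ids, dpsi) data.frame(event_id = ids, dpsi = dpsi)
  universe <- sprintf("e%03d", 1:100)
  a <- mk(universe[1:10], rep(0.2, 10))
  b <- mk(universe[6:15], c(rep(0.2, 5), rep(-0.2, 5)))
  ov <- event_overlap(a, b, universe)
  # overlap of qualifying sets is 5; consistency needs matching sign
  expect_equal(length(ov$consistent), 5)
  p_exact <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k), 0)) / choose(100, 10)
  expect_equal(ov$p, p_exact, tolerance = 1e-10)

  # rescue mode flips the sign requirement
  ov_r <- event_overlap(a, b, universe, rescue = TRUE)
  expect_equal(length(ov_r$consistent), 0)

  # |dpsi| at 0.04 is excluded by the 5% rule
  a2 <- mk(universe[1:10], c(0.04, rep(0.2, 9)))
  ov2 <- event_overlap(a2, b, universe)
  expect_false(universe[1] %in% ov2$set_a)

  # empty overlap with expectation > 0: p = 1
  c_tab <- mk(universe[90:99], rep(0.3, 10))
  ov3 <- event_overlap(a, c_tab, universe)
  expect_equal(ov3$p, 1)
  expect_error(event_overlap(a, b, character(0)), "universe")
})
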