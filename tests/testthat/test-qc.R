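test_that("saturation bins are hand-computable and omit empty bins", {
  metrics <- tibble::tibble(reads = c(10000, 12000), genes = c(100, 120))
  sc <- saturation_curve(metrics, window = 20000, step = 5000)
  expect_equal(sc$mean_genes[1], 110)    # both cells in [0, 20k)
  expect_true(all(sc$n_cells >= 1))      # empty bins omitted
  expect_true(all(diff(sc$center) > 0))
  expect_error(saturation_curve(metrics, window = 0, step = 5), "positive")
})

test_that("disjoint bins (step = window) partition cells like a brute-force cut", {
  set.seed(71)
  metrics <- tibble::tibble(reads = sample(1:99999, 500), genes = rpois(500, 50))
  sc <- saturation_curve(metrics, window = 10000, step = 10000)
  expect_equal(sum(sc$n_cells), nrow(metrics))
  brute <- table(cut(metrics$reads, seq(0, 100000, by = 10000), right = FALSE))
  expect_equal(sc$n_cells, as.integer(brute[brute > 0]), ignore_attr = TRUE)
})

test_that("replicate-level sd is computed across experiments", {
  metrics <- tibble::tibble(
    reads = rep(c(5000, 6000), 3),
    genes = c(100, 110, 120, 130, 80, 90),
    experiment = rep(c("e1", "e2", "e3"), each = 2)
  )
  sc <- saturation_curve(metrics, window = 10000, step = 10000)
  expect_equal(nrow(sc), 1)
  per_exp <- c(105, 125, 85)
  expect_equal(sc$mean_genes, mean(per_exp))
  expect_equal(sc$sd_genes, sd(per_exp))
})

test_that("saturation means rise with depth on saturating simulations", {
  # deeper cells detect at least as many genes on average: sample cells on a
  # depth grid so every bin is well populated, over 10 seeds
  for (s in 1:10) {
    set.seed(700 + s)
    panel <- make_panel(300, 250, prefix = "sat")
    rates <- simulate_probe_rates(panel, sdlog = 1.5)
    gene_of <- panel$gene
    depth <- rep(seq(50, 950, by = 50), each = 40)
    genes <- vapply(depth, function(d) {
      cnt <- stats::rmultinom(1, d, rates)[, 1]
      length(unique(gene_of[cnt > 0]))
    }, numeric(1))
    sc <- saturation_curve(tibble::tibble(reads = depth, genes = genes),
                           window = 200, step = 200)
    expect_true(all(diff(sc$mean_genes) >= 0))
  }
})

test_that("barnyard classification follows the minor-fraction rule", {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 2, 3, 3), j = c(1, 1, 2, 1, 2),
    x = c(100, 2750, 2250, 95, 5), dims = c(3, 2),
    dimnames = list(c("pureA", "mix", "mostlyA"), c("geneA", "geneB"))
  )
  cm <- count_matrix(m)
  map <- tibble::tibble(gene = c("geneA", "geneB"), species = c("spA", "spB"))
  rep <- classify_barnyard(cm, map)
  labs <- setNames(rep$cells$label, rep$cells$cell_barcode)
  expect_equal(labs[["pureA"]], "spA")       # 100% species A
  expect_equal(labs[["mix"]], "multiplet")   # 55/45 split, 5000 transcripts
  expect_equal(labs[["mostlyA"]], "spA")     # minor below both gates
  expect_error(classify_barnyard(cm, map[1, ]), "species label")
})

test_that("multiplet-rate correction implements observed / 2p(1-p)", {
  expect_equal(correct_multiplet_rate(0.01, 0.5), 0.02)
  expect_equal(correct_multiplet_rate(0, 0.3), 0)
  p <- 9397 / (9397 + 10291)
  expect_equal(round(100 * correct_multiplet_rate(0.0054, p), 2), 1.08)
  expect_error(correct_multiplet_rate(0.01, 1), "strictly between")
  # corrected >= 2 * observed for all p, equality iff p = 1/2
  for (p in seq(0.05, 0.95, by = 0.05)) {
    expect_gte(correct_multiplet_rate(0.01, p), 0.02 - 1e-12)
  }
  expect_gt(correct_multiplet_rate(0.01, 0.25), 0.02)
})

test_that("corrected rate recovers the configured doublet rate over 20 seeds", {
  set.seed(72)
  pa <- make_panel(60, 50, prefix = "hs")
  pb <- make_panel(60, 50, prefix = "mm")
  est <- vapply(1:20, function(s) {
    bs <- simulate_barnyard_counts(list(hs = pa, mm = pb), n_barcodes = 5000,
                                   doublet_rate = 0.03, umi_per_cell = 200,
                                   seed = 5000 + s)
    rep <- classify_barnyard(bs$matrix, bs$species_map)
    rep$corrected_multiplet_rate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.03) / 0.03, 0.15)
})

test_that("capture rate is the exact ratio with sanity checks", {
  cr <- capture_rate(10000, 4820)
  expect_equal(cr$percent, 48.2)
  expect_equal(capture_rate(5000, 5000)$percent, 100)
  expect_warning(capture_rate(100, 120), "exceeds")
  expect_error(capture_rate(0, 10), "positive")
})

test_that("simulated pipeline recovers nearly all planted cells", {
  cfg <- make_barnyard_config(n_cells = 200, seed = 73, doublet_rate = 0,
                              ambient_read_fraction = 0.05,
                              umi_dispersion = 10)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  dm <- demultiplex(sim$fastq, sim$layout, sim$scheme)
  knee <- find_knee(rank_barcodes(dm), min_barcodes = 50)
  cr <- capture_rate(cfg$n_cells, knee$n_called)
  expect_gte(cr$percent, 95)
  # called set vs truth cells: near-perfect overlap
  truth_bc <- unique(sim$truth$cells$cell_barcode)
  jacc <- length(intersect(knee$called_barcodes, truth_bc)) /
    length(union(knee$called_barcodes, truth_bc))
  expect_gte(jacc, 0.95)
})

test_that("pseudobulk correlation behaves at the identity and the null", {
  set.seed(74)
  genes <- sprintf("g%03d", 1:200)
  v <- setNames(rpois(200, 20), genes)
  expect_equal(pseudobulk_correlation(v, v), 1.0)
  # permuted labels destroy correlation
  vperm <- setNames(sample(v), genes)
  expect_lt(abs(pseudobulk_correlation(v, vperm)), 0.2)
  expect_error(pseudobulk_correlation(setNames(rep(1, 200), genes), v,
                                      log_transform = FALSE), "zero-variance")
})

test_that("contamination fractions recover the configured mito share", {
  set.seed(75)
  mito_genes <- sprintf("mt_gene%04d", 1:3)
  panel <- probe_panel(tibble::tibble(
    probe_id = sprintf("p%04d", 1:300),
    gene = c(mito_genes, sprintf("g%04d", 1:297)),
    sequence = unique_dna(300, 30),
    is_mito = c(rep(TRUE, 3), rep(FALSE, 297))
  ))
  rates <- simulate_probe_rates(panel, sdlog = 1, mito_fraction = 0.001)
  cells <- 400
  counts <- stats::rmultinom(cells, 1000, rates)   # probes x cells
  gene_counts <- rowsum(counts, panel$gene)
  cm <- count_matrix(Matrix::Matrix(t(gene_counts), sparse = TRUE,
                                    dimnames = list(sprintf("c%03d", 1:cells),
                                                    rownames(gene_counts))))
  cf <- contamination_fractions(cm, panel)
  # population mean within 3 SE of 0.1%
  se <- sqrt(0.001 * 0.999 / (cells * 1000)) * 100
  expect_lt(abs(mean(cf$mito_pct) - 0.1), 3 * se)
  # zero-flag cell case
  cm0 <- count_matrix(Matrix::sparseMatrix(
    i = 1, j = 1, x = 5, dims = c(1, 2),
    dimnames = list("c1", c("g0001", "g0002"))
  ))
  cf0 <- contamination_fractions(cm0, panel[4:5, ] |> probe_panel())
  expect_equal(cf0$mito_pct, 0)
})
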