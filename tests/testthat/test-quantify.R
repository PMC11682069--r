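# planted two-population ranked distribution: n_cells barcodes around
# cell_reads, n_noise barcodes around cell_reads/ratio
planted_ranked <- function(n_cells, n_noise, cell_reads = 10000, ratio = 100,
                           sdlog = 0.25) {
  tibble::tibble(
    cell_barcode = sprintf("bc%06d", seq_len(n_cells + n_noise)),
    reads = c(round(stats::rlnorm(n_cells, log(cell_reads), sdlog)),
              pmax(1, round(stats::rlnorm(n_noise, log(cell_reads / ratio), sdlog))))
  )
}

test_that("knee calling recovers a planted two-population split", {
  set.seed(61)
  ranked <- planted_ranked(1000, 50000, cell_reads = 10000, ratio = 100)
  knee <- find_knee(ranked)
  expect_lt(abs(knee$n_called - 1000) / 1000, 0.10)
  # every called barcode is above the threshold
  called_reads <- ranked$reads[ranked$cell_barcode %in% knee$called_barcodes]
  expect_true(all(called_reads >= knee$threshold_count))
})

test_that("degenerate distributions are rejected", {
  flat <- tibble::tibble(cell_barcode = sprintf("b%04d", 1:200),
                         reads = rep(7, 200))
  expect_error(find_knee(flat), "no inflection")
  few <- tibble::tibble(cell_barcode = sprintf("b%02d", 1:20),
                        reads = 20:1)
  expect_error(find_knee(few), "barcodes")
})

test_that("knee recovers planted cell counts within 10% across 20 seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n_cells <- sample(300:1500, 1)
    ranked <- planted_ranked(n_cells, 20 * n_cells, cell_reads = 5000,
                             ratio = 50)
    knee <- find_knee(ranked)
    abs(knee$n_called - n_cells) / n_cells
  }, numeric(1))
  expect_true(all(errs <= 0.10))
})

test_that("UMI collapse counts distinct UMIs once and is idempotent", {
  reads <- tibble::tibble(
    cell_barcode = rep("bc1", 5),
    probe_id = c("p1", "p1", "p1", NA, NA),
    umi = c("AAAA", "AAAA", "CCCC", "GGGG", "TTTT")
  )
  cc <- collapse_umis(reads)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$umi_count, 2L)
  # idempotence: re-collapsing the distinct set changes nothing
  distinct_reads <- dplyr::distinct(reads[!is.na(reads$probe_id), ])
  expect_equal(collapse_umis(distinct_reads), cc)
  # empty input
  expect_equal(nrow(collapse_umis(reads[0, ])), 0)
})

test_that("zero-error pipeline reproduces planted per-(cell, probe) counts", {
  cfg <- make_barnyard_config(n_cells = 60, seed = 62, doublet_rate = 0,
                              ambient_read_fraction = 0)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  dm <- demultiplex(sim$fastq, sim$layout, sim$scheme)
  reads <- assign_probes(dm, combine_panels(cfg$panels))
  got <- collapse_umis(reads)
  truth <- sim$truth$counts |>
    dplyr::left_join(sim$truth$cells[, c("cell_id", "cell_barcode")],
                     by = "cell_id") |>
    dplyr::group_by(cell_barcode, probe_id) |>
    dplyr::summarise(umi_count = sum(umi_count), .groups = "drop") |>
    dplyr::arrange(cell_barcode, probe_id)
  got <- dplyr::arrange(got, cell_barcode, probe_id)
  expect_equal(got, truth, ignore_attr = TRUE)
})

test_that("matrix construction sums probes per gene and conserves UMIs", {
  panel <- probe_panel(tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    gene = c("G1", "G1", "G2"),
    sequence = c(strrep("A", 10), strrep("C", 10), strrep("G", 10))
  ))
  pc <- tibble::tibble(
    cell_barcode = c("c1", "c1", "c1", "c2"),
    probe_id = c("p1", "p2", "p3", "p2"),
    umi_count = c(3L, 4L, 2L, 5L)
  )
  cm <- build_matrix(pc, panel)
  expect_equal(as.numeric(cm$counts["c1", "G1"]), 7)
  expect_equal(as.numeric(cm$counts["c1", "G2"]), 2)
  expect_equal(sum(cm$counts), sum(pc$umi_count))
  expect_error(
    build_matrix(tibble::tibble(cell_barcode = "c1", probe_id = "zz",
                                umi_count = 1L), panel),
    "absent from panel"
  )
})

test_that("per-cell metrics implement the detected-gene definition", {
  set.seed(63)
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 1), x = c(5, 1, 2),
                            dims = c(2, 3),
                            dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  cm <- count_matrix(m)
  met <- per_cell_metrics(cm)
  expect_equal(met$genes, c(2, 1))        # genes with UMI count > 0
  expect_equal(met$transcripts, c(6, 2))  # row sums
  expect_true(all(met$transcripts >= met$genes))

  # a constructed cell with counts on exactly 1,982 genes reports 1,982
  n_genes_cell <- 1982
  big <- Matrix::sparseMatrix(i = rep(1, n_genes_cell), j = seq_len(n_genes_cell),
                              x = rep(1, n_genes_cell),
                              dims = c(1, 2500),
                              dimnames = list("cell", sprintf("g%04d", 1:2500)))
  expect_equal(per_cell_metrics(count_matrix(big))$genes, n_genes_cell)
})

test_that("matrix sum equals the number of distinct (cell, probe, UMI) triples", {
  cfg <- make_barnyard_config(n_cells = 40, seed = 64, doublet_rate = 0,
                              ambient_read_fraction = 0)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  dm <- demultiplex(sim$fastq, sim$layout, sim$scheme)
  combined <- combine_panels(cfg$panels)
  reads <- assign_probes(dm, combined)
  cm <- build_matrix(collapse_umis(reads), combined)
  triples <- nrow(dplyr::distinct(reads[!is.na(reads$probe_id),
                                        c("cell_barcode", "probe_id", "umi")]))
  expect_equal(sum(cm$counts), triples)
})

test_that("MatrixMarket round trip preserves the matrix", {
  set.seed(65)
  m <- Matrix::rsparsematrix(30, 20, density = 0.2,
                             rand.x = function(n) rpois(n, 3) + 1)
  dimnames(m) <- list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:20))
  cm <- count_matrix(m)
  dir <- withr::local_tempdir()
  write_matrix(cm, dir)
  back <- read_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
})
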