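test_that("exact barcode at expected position matches with offset 0", {
  set.seed(21)
  wl <- generate_whitelist(8, 10, min_distance = 3)
  plate <- barcode_plate(wl, 1)
  win <- paste0("AAA", wl[5], "CCC")   # symmetric 3-nt context
  hit <- match_barcode(win, plate)
  expect_equal(hit$well, plate$well[5])
  expect_equal(hit$offset, 0L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$reason, "ok")
})

test_that("shifted and substituted barcodes are recovered with correct offset/mismatch", {
  set.seed(22)
  wl <- generate_whitelist(8, 10, min_distance = 3)
  plate <- barcode_plate(wl, 1)
  bc <- wl[3]
  sub <- bc
  substr(sub, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(bc, 4, 4))[1]
  # barcode shifted +2 from expected position, with 1 substitution
  win <- paste0("AAAAA", sub, "C")     # expected start 3, actual start 5
  hit <- match_barcode(win, plate)
  expect_equal(hit$well, plate$well[3])
  expect_equal(hit$offset, 2L)
  expect_equal(hit$mismatches, 1L)
})

test_that("windows beyond tolerance or too short are rejected with reasons", {
  set.seed(23)
  wl <- generate_whitelist(6, 10, min_distance = 5)
  plate <- barcode_plate(wl, 1)
  # corrupt 2 positions: distance 2 from truth, >= 3 from all others
  bad <- wl[1]
  substr(bad, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(bad, 1, 1))[1]
  substr(bad, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(bad, 2, 2))[1]
  win <- paste0("AAA", bad, "AAA")
  hit <- match_barcode(win, plate)
  expect_true(is.na(hit$well))
  expect_equal(hit$reason, "no_match")
  # brute-force scan over all wells x offsets agrees there is no hit
  expect_true(is.na(bf_match(win, wl)))

  short <- match_barcode("ACGT", plate)
  expect_equal(short$reason, "window_too_short")
})

test_that("matcher agrees with brute-force rank scan on random windows", {
  set.seed(24)
  wl <- generate_whitelist(10, 8, min_distance = 3)
  plate <- barcode_plate(wl, 1)
  wins <- character(0)
  for (i in 1:60) {
    bc <- sample(wl, 1)
    if (runif(1) < 0.3) bc <- random_dna_local(1, 8)      # mostly junk
    k <- sample(0:3, 1)
    win <- paste0(substr(random_dna_local(1, 6), 1, 3 + k), bc,
                  substr(random_dna_local(1, 6), 1, 3 - k))
    wins <- c(wins, win)
  }
  got <- match_barcode(wins, plate)
  oracle <- vapply(wins, bf_match, integer(1), whitelist = wl)
  expect_equal(got$well, ifelse(is.na(oracle), NA_character_, plate$well[oracle]),
               ignore_attr = TRUE)
})

test_that("every single substitution is corrected on a distance->=3 whitelist", {
  set.seed(25)
  wl <- generate_whitelist(6, 8, min_distance = 3)
  plate <- barcode_plate(wl, 1)
  for (w in seq_along(wl)) {
    variants <- splitpool:::one_sub_variants(wl[w])
    wins <- paste0("TTT", variants, "TTT")
    hits <- match_barcode(wins, plate)
    expect_true(all(hits$well == plate$well[w]))
    expect_true(all(hits$mismatches == 1L))
    expect_true(all(hits$offset == 0L))
  }
})

test_that("every double substitution is rejected on a distance->=5 whitelist", {
  set.seed(26)
  wl <- generate_whitelist(5, 8, min_distance = 5)
  plate <- barcode_plate(wl, 1)
  alphabet <- c("A", "C", "G", "T")
  # windows contain only the corrupted barcode (no flanking context), so the
  # check isolates mismatch tolerance from offset scanning
  for (w in seq_along(wl)) {
    chars <- strsplit(wl[w], "")[[1]]
    pairs <- utils::combn(8, 2)
    wins <- character(0)
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      for (b1 in setdiff(alphabet, chars[i1])) {
        for (b2 in setdiff(alphabet, chars[i2])) {
          v <- chars; v[i1] <- b1; v[i2] <- b2
          wins <- c(wins, paste0(v, collapse = ""))
        }
      }
    }
    hits <- match_barcode(wins, plate, expected_start = 0)
    expect_true(all(is.na(hits$well)))
    expect_true(all(hits$reason == "no_match"))
  }
})

test_that("zero-error simulation demultiplexes to exactly the truth", {
  cfg <- make_barnyard_config(n_cells = 80, seed = 31, doublet_rate = 0,
                              ambient_read_fraction = 0)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  dm <- demultiplex(sim$fastq, sim$layout, sim$scheme)
  expect_equal(dm$stats$fraction_valid, 1)
  truth <- sim$truth$reads
  got <- dm$reads[match(truth$read_id, dm$reads$read_id), ]
  expect_equal(got$cell_barcode, truth$cell_barcode)
  expect_equal(got$umi, truth$umi)
  # per-read barcode calls are clean: no offsets, no mismatches
  expect_true(all(got$bc1_offset == 0 & got$bc2_offset == 0 & got$bc3_offset == 0))
  expect_true(all(got$bc1_mismatches == 0))
})

test_that("systematic 1-substitution corruption of BC2 is fully corrected", {
  cfg <- make_barnyard_config(n_cells = 60, seed = 32, doublet_rate = 0,
                              ambient_read_fraction = 0)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  # inject exactly one substitution into every read's BC2 segment
  lay <- sim$layout
  bc2 <- lay[lay$segment == "bc2", ]
  r2_path <- sim$fastq[["r2"]]
  lines <- readLines(r2_path)
  seq_rows <- seq(2, length(lines), by = 4)
  set.seed(321)
  for (i in seq_rows) {
    pos <- bc2$start + sample.int(bc2$length, 1)
    ch <- substr(lines[i], pos, pos)
    substr(lines[i], pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  }
  r2_mut <- file.path(withr::local_tempdir(), "R2.fastq")
  writeLines(lines, r2_mut)
  fq <- sim$fastq; fq[["r2"]] <- r2_mut
  dm <- demultiplex(fq, sim$layout, sim$scheme)
  expect_equal(dm$stats$fraction_valid, 1)
  expect_true(all(dm$reads$bc2_mismatches == 1L))
  truth <- sim$truth$reads
  got <- dm$reads[match(truth$read_id, dm$reads$read_id), ]
  expect_equal(got$cell_barcode, truth$cell_barcode)
})

test_that("raising max_mismatch from 0 to 1 never loses valid reads", {
  cfg <- make_barnyard_config(n_cells = 60, seed = 33, barcode_error_rate = 0.05,
                              barcode_offset_rate = 0.3)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  dm0 <- demultiplex(sim$fastq, sim$layout, sim$scheme, max_mismatch = 0)
  dm1 <- demultiplex(sim$fastq, sim$layout, sim$scheme, max_mismatch = 1)
  expect_gte(dm1$stats$n_valid, dm0$stats$n_valid)
  expect_equal(dm0$stats$n_reads, dm1$stats$n_reads)
})

test_that("pooling conserves reads and groups by barcode", {
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    cell_barcode = c("A_B_C_D", "A_B_C_D", "E_F_G_H")
  )
  pooled <- pool_by_barcode(reads)
  expect_equal(sort(pooled$n_reads), c(1L, 2L))
  expect_equal(sum(pooled$n_reads), nrow(reads))
  empty <- pool_by_barcode(tibble::tibble(read_id = character(0),
                                          cell_barcode = character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("pooled group sizes match per-cell read counts at zero error", {
  cfg <- make_barnyard_config(n_cells = 50, seed = 34, doublet_rate = 0,
                              ambient_read_fraction = 0)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  dm <- demultiplex(sim$fastq, sim$layout, sim$scheme)
  pooled <- pool_by_barcode(dm)
  truth_sizes <- table(sim$truth$reads$cell_barcode)
  expect_equal(sort(pooled$n_reads),
               sort(as.integer(truth_sizes)))
  expect_setequal(pooled$cell_barcode, names(truth_sizes))
})
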