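#' Match an observed window against a barcode whitelist
#'
#' Scans a window of read sequence for a whitelist barcode, tolerating a
#' positional offset of up to `max_offset` nt from the expected position and
#' up to `max_mismatch` substitutions. Candidate hits are ranked by
#' (|offset| ascending, mismatches ascending); the unique best hit wins and
#' any tie between distinct wells at the best rank is discarded as
#' ambiguous — no silent misassignment.
#'
#' @param windows Character vector of observed windows (equal lengths). The
#'   barcode's expected start sits `expected_start` 0-based nt into the
#'   window (default `max_offset`, i.e. a symmetric window).
#' @param plate A [barcode_plate()] (or a character whitelist).
#' @param max_offset Maximum |offset| in nt (default 3).
#' @param max_mismatch Maximum substitutions (0 or 1; default 1).
#' @param expected_start 0-based offset of the expected barcode start within
#'   the window.
#' @return A tibble with one row per window: `well` (`NA` for no-match),
#'   `offset`, `mismatches`, `reason` (`"ok"`, `"no_match"`, `"ambiguous"`,
#'   `"window_too_short"`).
#' @export
match_barcode <- function(windows, plate, max_offset = 3, max_mismatch = 1,
                          expected_start = max_offset) {
  if (is.character(plate)) plate <- barcode_plate(plate, round_index = 1,
                                                  check_distance = FALSE)
  stopifnot(inherits(plate, "barcode_plate"))
  if (!max_mismatch %in% 0:1) abort("max_mismatch must be 0 or 1")
  lookup <- plate_lookup(plate)
  match_barcode_vec(windows, lookup, max_offset, max_mismatch, expected_start)
}

# internal: hash tables for exact and 1-mismatch matching. Variants shared
# by two wells (whitelist pairs at Hamming distance < 3) are marked
# ambiguous (well index 0).
plate_lookup <- function(plate) {
  n <- nrow(plate)
  variants <- lapply(plate$sequence, one_sub_variants)
  var_seq <- unlist(variants)
  var_well <- rep(seq_len(n), vapply(variants, length, integer(1)))
  # a variant equal to another whitelist barcode, or shared between wells,
  # cannot be corrected unambiguously
  var_well[var_seq %in% plate$sequence] <- 0L
  dup <- var_seq %in% var_seq[duplicated(var_seq)]
  conflicted <- dup & ave(var_well, var_seq, FUN = function(w) length(unique(w))) > 1
  var_well[conflicted] <- 0L
  keep <- !duplicated(var_seq)
  list(
    wells = plate$well,
    bc_len = attr(plate, "barcode_length"),
    exact_seq = plate$sequence,
    var_seq = var_seq[keep],
    var_well = var_well[keep]
  )
}

# internal: vectorized matcher over constant-length windows
match_barcode_vec <- function(windows, lookup, max_offset, max_mismatch,
                              expected_start) {
  n <- length(windows)
  bc_len <- lookup$bc_len
  wlen <- nchar(windows)
  out_well <- rep(NA_integer_, n)
  out_off <- rep(NA_integer_, n)
  out_mm <- rep(NA_integer_, n)
  reason <- rep("no_match", n)

  too_short <- wlen < bc_len
  reason[too_short] <- "window_too_short"
  live <- !too_short
  if (!any(live)) {
    return(tibble(well = NA_character_[rep(1, n)], offset = out_off,
                  mismatches = out_mm, reason = reason))
  }
  W <- max(wlen)

  # candidate well index at (offset k, mismatch level mm) for all windows
  cand_at <- function(k, mm) {
    pos <- expected_start + k           # 0-based start within window
    res <- rep(NA_integer_, n)
    valid <- live & pos >= 0 & (pos + bc_len) <= wlen
    if (!any(valid)) return(res)
    sub <- substr(windows[valid], pos + 1, pos + bc_len)
    if (mm == 0) {
      res[valid] <- match(sub, lookup$exact_seq)
    } else {
      hit <- match(sub, lookup$var_seq)
      res[valid] <- ifelse(is.na(hit), NA_integer_, lookup$var_well[hit])
    }
    res
  }

  unresolved <- live
  failed <- rep(FALSE, n)
  for (a in 0:max_offset) {
    for (mm in 0:max_mismatch) {
      if (!any(unresolved)) break
      offs <- if (a == 0) 0L else c(a, -a)
      cands <- lapply(offs, cand_at, mm = mm)
      for (j in seq_along(offs)) {
        c_j <- cands[[j]]
        amb_var <- unresolved & !is.na(c_j) & c_j == 0L   # ambiguous 1-mm variant
        failed[amb_var] <- TRUE
        reason[amb_var] <- "ambiguous"
        unresolved[amb_var] <- FALSE
        cands[[j]][!unresolved] <- NA_integer_
      }
      if (length(offs) == 1) {
        hit <- unresolved & !is.na(cands[[1]])
        out_well[hit] <- cands[[1]][hit]
        out_off[hit] <- 0L
        out_mm[hit] <- mm
        reason[hit] <- "ok"
        unresolved[hit] <- FALSE
      } else {
        c1 <- cands[[1]]; c2 <- cands[[2]]
        both <- unresolved & !is.na(c1) & !is.na(c2)
        conflict <- both & c1 != c2
        failed[conflict] <- TRUE
        reason[conflict] <- "ambiguous"
        unresolved[conflict] <- FALSE
        agree <- both & !conflict      # same well at +a and -a: keep +a
        one1 <- unresolved & !is.na(c1) & is.na(c2)
        one2 <- unresolved & is.na(c1) & !is.na(c2)
        take1 <- agree | one1
        out_well[take1] <- c1[take1]; out_off[take1] <- a
        out_well[one2] <- c2[one2]; out_off[one2] <- -a
        hit <- take1 | one2
        out_mm[hit] <- mm
        reason[hit] <- "ok"
        unresolved[hit] <- FALSE
      }
    }
  }
  tibble(
    well = ifelse(is.na(out_well), NA_character_, lookup$wells[out_well]),
    offset = out_off,
    mismatches = out_mm,
    reason = reason
  )
}

#' Demultiplex a barcoded run
#'
#' Resolves the 4-part cell barcode (three ligated rounds + UDI) and the UMI
#' from each read, tolerating up to `max_offset` nt positional offset and
#' `max_mismatch` substitutions per barcode round. A read is kept only when
#' all four rounds resolve uniquely; reads failing any round are dropped
#' (a cell identity requires the full combination).
#'
#' @param fastq Named paths `r1`, `r2`, `i1`, `i2` (as returned by
#'   [simulate_experiment()]), or the list returned by it.
#' @param layout A [read_layout()] consistent with the read lengths.
#' @param scheme A `barcode_scheme`.
#' @param max_offset,max_mismatch Matching tolerances (defaults 3 nt, 1
#'   substitution per round). Offsets apply to the ligated rounds on the
#'   barcode read; index reads are matched in place.
#' @return A `demux_result`: `$reads` is a tibble of valid reads (`read_id`,
#'   wells per round, `cell_barcode`, `sample`, `umi`, `insert`, per-round
#'   offsets/mismatches), `$stats` holds totals, the correctly-barcoded
#'   fraction, per-round failure counts, and per-sample read counts.
#'   [tidy()] returns the read table, [glance()] the summary row.
#' @export
demultiplex <- function(fastq, layout, scheme, max_offset = 3, max_mismatch = 1) {
  if (is.list(fastq) && !is.null(fastq$fastq)) fastq <- fastq$fastq
  req <- c("r1", "r2", "i1", "i2")
  if (!all(req %in% names(fastq))) {
    abort("fastq must be a named vector with entries r1, r2, i1, i2")
  }
  reads <- lapply(fastq[req], read_fastq_seqs)
  n <- length(reads$r1$seq)
  lens <- vapply(reads, function(r) length(r$seq), numeric(1))
  if (length(unique(lens)) != 1) {
    abort(sprintf("FASTQ files are unaligned: record counts %s",
                  paste(lens, collapse = "/")))
  }
  if (!all(reads$r2$id == reads$r1$id) || !all(reads$i1$id == reads$r1$id)) {
    abort("FASTQ read ids are not in the same order across files")
  }

  lk <- lapply(scheme, plate_lookup)
  seg <- function(nm) layout_segment(layout, nm)

  # ligated rounds live on r2; window = expected position +/- max_offset
  call_round <- function(name, lookup) {
    s <- seg(name)
    win_start <- pmax(0L, s$start - max_offset)
    win_end <- s$start + s$length + max_offset       # half-open, clipped below
    win <- substr(reads$r2$seq, win_start + 1, win_end)
    match_barcode_vec(win, lookup, max_offset, max_mismatch,
                      expected_start = s$start - win_start)
  }
  bc3 <- call_round("bc3", lk$bc3)
  bc2 <- call_round("bc2", lk$bc2)
  bc1 <- call_round("bc1", lk$bc1)

  # UDI: concatenated index reads, matched in place (no positional offset)
  h7 <- seg("udi_i7"); h5 <- seg("udi_i5")
  udi_win <- paste0(substr(reads$i1$seq, h7$start + 1, h7$start + h7$length),
                    substr(reads$i2$seq, h5$start + 1, h5$start + h5$length))
  udi <- match_barcode_vec(udi_win, lk$udi, max_offset = 0,
                           max_mismatch = max_mismatch, expected_start = 0)

  valid <- !is.na(bc1$well) & !is.na(bc2$well) & !is.na(bc3$well) & !is.na(udi$well)

  # UMI follows BC1; it shares BC1's positional offset
  u <- seg("umi")
  umi_start <- u$start + ifelse(is.na(bc1$offset), 0L, bc1$offset)
  umi <- substr(reads$r2$seq, umi_start + 1, umi_start + u$length)
  ins <- seg("insert")
  insert <- substr(reads$r1$seq, ins$start + 1, ins$start + ins$length)

  out <- tibble(
    read_id = reads$r1$id[valid],
    bc1_well = bc1$well[valid], bc2_well = bc2$well[valid],
    bc3_well = bc3$well[valid], udi_well = udi$well[valid],
    umi = umi[valid], insert = insert[valid],
    bc1_offset = bc1$offset[valid], bc2_offset = bc2$offset[valid],
    bc3_offset = bc3$offset[valid],
    bc1_mismatches = bc1$mismatches[valid],
    bc2_mismatches = bc2$mismatches[valid],
    bc3_mismatches = bc3$mismatches[valid],
    udi_mismatches = udi$mismatches[valid]
  )
  out$cell_barcode <- cell_barcode_id(out$bc1_well, out$bc2_well,
                                      out$bc3_well, out$udi_well)
  out$sample <- out$bc1_well

  per_sample <- out |> count(.data$sample, name = "n_reads")
  stats <- list(
    n_reads = n,
    n_valid = sum(valid),
    fraction_valid = sum(valid) / n,
    per_round_failures = c(
      bc1 = sum(is.na(bc1$well)), bc2 = sum(is.na(bc2$well)),
      bc3 = sum(is.na(bc3$well)), udi = sum(is.na(udi$well))
    ),
    per_sample_reads = per_sample
  )
  structure(list(reads = out, stats = stats), class = "demux_result")
}

# internal: read a FASTQ into list(id, seq) character vectors
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = unname(sub("\\s.*$", "", names(x))), seq = unname(as.character(x)))
}

#' Pool demultiplexed reads by cell barcode
#'
#' Reads featuring the same 4-part barcode combination are pooled into
#' barcode-associated groups. Group sizes sum to the number of valid reads.
#'
#' @param reads A `demux_result` or its `$reads` tibble.
#' @return A tibble with one row per barcode: `cell_barcode`, `n_reads`, and
#'   `reads` (list-column of per-group read tibbles), ordered by descending
#'   `n_reads`.
#' @export
pool_by_barcode <- function(reads) {
  if (inherits(reads, "demux_result")) reads <- reads$reads
  if (nrow(reads) == 0) {
    return(tibble(cell_barcode = character(0), n_reads = integer(0),
                  reads = list()))
  }
  reads |>
    tidyr::nest(reads = -"cell_barcode") |>
    mutate(n_reads = vapply(.data$reads, nrow, integer(1))) |>
    select("cell_barcode", "n_reads", "reads") |>
    arrange(dplyr::desc(.data$n_reads))
}

#' @exportS3Method base::print
print.demux_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<demux_result> %d reads, %d valid (%.1f%% correctly barcoded)\n",
              s$n_reads, s$n_valid, 100 * s$fraction_valid))
  invisible(x)
}

#' @export
tidy.demux_result <- function(x, ...) x$reads

#' @export
glance.demux_result <- function(x, ...) {
  s <- x$stats
  tibble(
    n_reads = s$n_reads, n_valid = s$n_valid,
    fraction_valid = s$fraction_valid,
    fail_bc1 = s$per_round_failures[["bc1"]],
    fail_bc2 = s$per_round_failures[["bc2"]],
    fail_bc3 = s$per_round_failures[["bc3"]],
    fail_udi = s$per_round_failures[["udi"]]
  )
}
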