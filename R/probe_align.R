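#' Build a probe lookup index
#'
#' Inserts in a probe-ligation assay are complete, fixed-length copies of the
#' ligated probe sequences, so assignment is global Hamming matching rather
#' than local alignment. The index couples an exact-lookup hash on the full
#' sequence (the fast path) with k-mer seeding: probe sequences are split
#' into `n_chunks` contiguous chunks, and by pigeonhole any insert within
#' `n_chunks - 1` substitutions of a probe matches at least one chunk
#' exactly.
#'
#' @param panel A [probe_panel()].
#' @param n_chunks Number of seed chunks (supports `max_mismatch` up to
#'   `n_chunks - 1` without falling back to a full scan). Default 3.
#' @return A `probe_index`.
#' @export
build_probe_index <- function(panel, n_chunks = 3) {
  stopifnot(inherits(panel, "probe_panel"))
  dup <- panel$sequence[duplicated(panel$sequence)]
  if (length(dup) > 0) {
    offenders <- panel$probe_id[panel$sequence %in% dup]
    abort(paste0("duplicate probe sequences across probes: ",
                 paste(offenders, collapse = ", ")))
  }
  plen <- attr(panel, "probe_length")
  n_chunks <- min(n_chunks, plen)
  bounds <- floor(seq(0, plen, length.out = n_chunks + 1))
  chunks <- lapply(seq_len(n_chunks), function(i) {
    key <- substr(panel$sequence, bounds[i] + 1, bounds[i + 1])
    split(seq_len(nrow(panel)), key)
  })
  seq_mat <- do.call(rbind, strsplit(panel$sequence, "", fixed = TRUE))
  structure(
    list(panel_ids = panel$probe_id, sequences = panel$sequence,
         seq_mat = seq_mat, probe_length = plen,
         bounds = bounds, chunks = chunks, n_chunks = n_chunks),
    class = "probe_index"
  )
}

#' Assign inserts to probes by unique best Hamming match
#'
#' Each insert is assigned to the unique probe with the fewest substitutions,
#' capped at `max_mismatch`; ties between probes leave the insert unassigned
#' (`unique = FALSE`). `N` bases count as mismatches. Inserts whose length
#' differs from the panel probe length, or containing characters outside
#' ACGTN, are unassigned with a reason.
#'
#' @param inserts Character vector of insert sequences.
#' @param index A [build_probe_index()] result.
#' @param max_mismatch Substitution cap (default 2).
#' @return A tibble: `insert`, `probe_id` (`NA` when unassigned),
#'   `mismatches`, `unique`, `reason` (`"ok"`, `"no_match"`, `"tie"`,
#'   `"length_mismatch"`, `"bad_alphabet"`).
#' @export
assign_probe <- function(inserts, index, max_mismatch = 2) {
  stopifnot(inherits(index, "probe_index"))
  n <- length(inserts)
  probe_id <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  uniq <- rep(NA, n)
  reason <- rep("no_match", n)

  bad_len <- nchar(inserts) != index$probe_length
  reason[bad_len] <- "length_mismatch"
  bad_chr <- !bad_len & grepl("[^ACGTN]", inserts)
  reason[bad_chr] <- "bad_alphabet"
  live <- !bad_len & !bad_chr

  # fast path: exact full-sequence hit (unique by index construction)
  hit <- match(inserts, index$sequences)
  exact <- live & !is.na(hit)
  probe_id[exact] <- index$panel_ids[hit[exact]]
  mismatches[exact] <- 0L
  uniq[exact] <- TRUE
  reason[exact] <- "ok"

  todo <- which(live & is.na(hit))
  if (length(todo) > 0 && max_mismatch > 0) {
    full_scan <- max_mismatch > index$n_chunks - 1
    for (i in todo) {
      ins <- inserts[i]
      cand <- if (full_scan) seq_along(index$panel_ids) else {
        idx <- unlist(lapply(seq_len(index$n_chunks), function(ci) {
          key <- substr(ins, index$bounds[ci] + 1, index$bounds[ci + 1])
          index$chunks[[ci]][[key]]
        }), use.names = FALSE)
        unique(idx)
      }
      if (length(cand) == 0) next
      ichr <- strsplit(ins, "", fixed = TRUE)[[1]]
      d <- rowSums(index$seq_mat[cand, , drop = FALSE] !=
                     matrix(ichr, nrow = length(cand),
                            ncol = index$probe_length, byrow = TRUE))
      dmin <- min(d)
      if (dmin > max_mismatch) next
      best <- cand[d == dmin]
      if (length(best) == 1) {
        probe_id[i] <- index$panel_ids[best]
        mismatches[i] <- as.integer(dmin)
        uniq[i] <- TRUE
        reason[i] <- "ok"
      } else {
        mismatches[i] <- as.integer(dmin)
        uniq[i] <- FALSE
        reason[i] <- "tie"
      }
    }
  }
  tibble(insert = inserts, probe_id = probe_id, mismatches = mismatches,
         unique = uniq, reason = reason)
}

#' Assign probes to a demultiplexed read table
#'
#' Convenience wrapper: runs [assign_probe()] on the `insert` column and
#' appends `probe_id`, `probe_mismatches` and the gene symbol.
#'
#' @param reads A `demux_result` or its `$reads` tibble.
#' @param panel A [probe_panel()].
#' @param max_mismatch Substitution cap passed to [assign_probe()].
#' @return The read tibble with probe assignment columns; unassigned reads
#'   keep `NA` probe ids.
#' @export
assign_probes <- function(reads, panel, max_mismatch = 2) {
  if (inherits(reads, "demux_result")) reads <- reads$reads
  index <- build_probe_index(panel)
  hits <- assign_probe(reads$insert, index, max_mismatch = max_mismatch)
  reads$probe_id <- hits$probe_id
  reads$probe_mismatches <- hits$mismatches
  reads$gene <- panel$gene[match(hits$probe_id, panel$probe_id)]
  reads
}
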