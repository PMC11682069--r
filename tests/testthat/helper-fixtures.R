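# Shared fixture builders and independent brute-force oracles.
# Fixtures are generated in code (no files); tests set their own seeds.

random_dna_local <- function(n, width) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

# unique fixed-length sequences: deterministic prefix encodes the index,
# random suffix fills to width
unique_dna <- function(n, width, prefix_width = ceiling(log(max(n, 2), 4))) {
  alphabet <- c("A", "C", "G", "T")
  idx <- seq_len(n) - 1L
  pre <- matrix("A", nrow = n, ncol = prefix_width)
  for (pos in prefix_width:1) {
    pre[, pos] <- alphabet[(idx %% 4L) + 1L]
    idx <- idx %/% 4L
  }
  paste0(apply(pre, 1, paste0, collapse = ""),
         random_dna_local(n, width - prefix_width))
}

make_panel <- function(n_probes, n_genes, prefix = "g", probe_length = 50,
                       n_attenuated = 0, attenuation_fold = 10,
                       mito_genes = character(0)) {
  genes <- sprintf("%s_gene%04d", prefix, rep(seq_len(n_genes), length.out = n_probes))
  fold <- rep(1L, n_probes)
  if (n_attenuated > 0) fold[seq_len(n_attenuated)] <- as.integer(attenuation_fold)
  probe_panel(tibble::tibble(
    probe_id = sprintf("%s_probe%05d", prefix, seq_len(n_probes)),
    gene = genes,
    sequence = unique_dna(n_probes, probe_length),
    attenuation_fold = fold,
    is_mito = genes %in% mito_genes
  ), name = prefix)
}

make_scheme <- function(plate_size = 12, bc_length = 10, udi_length = 16,
                        min_distance = 3) {
  plates <- lapply(1:4, function(r) {
    len <- if (r == 4) udi_length else bc_length
    barcode_plate(generate_whitelist(plate_size, len, min_distance = min_distance),
                  round_index = r)
  })
  barcode_scheme(plates)
}

# small two-species config used by several round-trip tests
make_barnyard_config <- function(n_cells = 150, seed = 7, ...) {
  set.seed(seed * 13 + 1)
  pa <- make_panel(120, 90, prefix = "hs")
  pb <- make_panel(100, 80, prefix = "mm")
  sim_config(
    panels = list(hs = pa, mm = pb), n_cells = n_cells,
    umi_per_cell = 120, plate_size = 12,
    layout = read_layout(insert_length = 50),
    seed = seed, ...
  )
}

## ---- independent oracles ----------------------------------------------------

# brute-force Hamming scan over a whole panel (oracle for assign_probe)
bf_assign <- function(insert, panel, max_mismatch = 2) {
  if (nchar(insert) != attr(panel, "probe_length")) {
    return(list(probe_id = NA_character_, mismatches = NA_integer_))
  }
  ichr <- strsplit(insert, "", fixed = TRUE)[[1]]
  d <- vapply(strsplit(panel$sequence, "", fixed = TRUE),
              function(p) sum(p != ichr), numeric(1))
  dmin <- min(d)
  if (dmin > max_mismatch || sum(d == dmin) != 1) {
    return(list(probe_id = NA_character_, mismatches = as.integer(dmin)))
  }
  list(probe_id = panel$probe_id[which.min(d)], mismatches = as.integer(dmin))
}

# brute-force barcode match: scan every well x offset, rank by
# (|offset|, mismatches), unique best or NA (oracle for match_barcode)
bf_match <- function(window, whitelist, max_offset = 3, max_mismatch = 1,
                     expected_start = max_offset) {
  bc_len <- nchar(whitelist[1])
  hits <- NULL
  for (k in -max_offset:max_offset) {
    pos <- expected_start + k
    if (pos < 0 || pos + bc_len > nchar(window)) next
    obs <- substr(window, pos + 1, pos + bc_len)
    for (w in seq_along(whitelist)) {
      mm <- sum(charToRaw(obs) != charToRaw(whitelist[w]))
      if (mm <= max_mismatch) {
        hits <- rbind(hits, data.frame(well = w, offset = k, mm = mm))
      }
    }
  }
  if (is.null(hits)) return(NA_integer_)
  hits$rank <- abs(hits$offset) * 10 + hits$mm
  best <- hits[hits$rank == min(hits$rank), ]
  if (length(unique(best$well)) != 1) return(NA_integer_)
  best$well[1]
}

# exhaustive hypergeometric upper tail by enumerating all size-n draws from
# a universe of N genes with K markers (oracle for the ORA p-value)
bf_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marker <- seq_len(K)  # the first K universe elements are markers
  hits <- apply(draws, 2, function(d) sum(d %in% marker))
  mean(hits >= k)
}
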