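#' Simulation configuration
#'
#' Bundles every parameter of the synthetic experiment generator. The
#' generator emulates a split-pool barcoded probe-ligation run: a known
#' number of cell-containing barcodes (1-2 species, with doublets sharing one
#' barcode), ambient background reads, per-barcode substitution and
#' positional-offset errors, and negative-binomial per-cell molecule counts
#' amplified into PCR-duplicated reads.
#'
#' @param panels Named list of [probe_panel()]s, one per species (names are
#'   the species labels). All panels must share a probe length.
#' @param n_cells Number of cell-containing barcodes. Doublet barcodes host
#'   two cells, so the number of cells is slightly larger than `n_cells`
#'   when `doublet_rate > 0`.
#' @param species_mix Named numeric vector of species proportions (must sum
#'   to 1 and name every panel).
#' @param doublet_rate Probability that a barcode hosts two cells.
#' @param umi_per_cell Mean molecules (UMIs) per cell.
#' @param umi_dispersion Negative-binomial size parameter for per-cell
#'   molecule counts (larger = less dispersed).
#' @param mean_reads_per_umi Mean sequenced reads per molecule (>= 1); each
#'   molecule is read `1 + Poisson(mean_reads_per_umi - 1)` times.
#' @param barcode_error_rate Per-barcode-segment probability of one random
#'   substitution (applied to BC1-3 and the UDI, after truth is recorded).
#' @param barcode_offset_rate Probability that a read's barcode block is
#'   shifted downstream by 1-3 nt (emulating imprecise barcode position).
#' @param ambient_read_fraction Fraction of all reads that are ambient:
#'   valid probes, but on barcodes not used by any cell, at roughly 100-fold
#'   lower per-barcode depth than real cells.
#' @param gene_rate_sdlog Log-normal sd of per-probe expression rates.
#' @param mito_fraction If non-`NULL`, rescale mito-flagged probes so they
#'   take exactly this share of each species' expression rate mass.
#' @param scheme A `barcode_scheme`, or `NULL` to generate whitelists
#'   (`plate_size` barcodes per round, pairwise Hamming distance >= 3).
#' @param plate_size Barcodes per generated plate.
#' @param layout A [read_layout()]; its insert length must equal the panel
#'   probe length.
#' @param seed Mandatory integer seed; every downstream draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(panels,
                       n_cells = 500,
                       species_mix = setNames(rep(1 / length(panels), length(panels)),
                                              names(panels)),
                       doublet_rate = 0.0109,
                       umi_per_cell = 400,
                       umi_dispersion = 4,
                       mean_reads_per_umi = 1.5,
                       barcode_error_rate = 0,
                       barcode_offset_rate = 0,
                       ambient_read_fraction = 0.05,
                       gene_rate_sdlog = 1.5,
                       mito_fraction = NULL,
                       scheme = NULL,
                       plate_size = 48,
                       layout = NULL,
                       seed) {
  if (missing(seed)) abort("a seed is mandatory for reproducible simulation")
  if (!is.list(panels) || is.null(names(panels)) || any(names(panels) == "")) {
    abort("panels must be a named list of probe_panel objects (names = species)")
  }
  for (p in panels) stopifnot(inherits(p, "probe_panel"))
  plens <- unique(vapply(panels, function(p) attr(p, "probe_length"), numeric(1)))
  if (length(plens) != 1) abort("all species panels must share one probe length")
  if (!setequal(names(species_mix), names(panels))) {
    abort("species_mix must name exactly the species in panels")
  }
  if (any(species_mix < 0) || abs(sum(species_mix) - 1) > 1e-8) {
    abort("species_mix proportions must be >= 0 and sum to 1")
  }
  if (doublet_rate < 0 || doublet_rate >= 1) abort("doublet_rate must be in [0, 1)")
  if (ambient_read_fraction < 0 || ambient_read_fraction >= 1) {
    abort("ambient_read_fraction must be in [0, 1)")
  }
  if (mean_reads_per_umi < 1) abort("mean_reads_per_umi must be >= 1")
  if (is.null(layout)) layout <- read_layout(insert_length = plens)
  ins <- layout_segment(layout, "insert")
  if (ins$length != plens) {
    abort("layout insert length must equal the panel probe length")
  }
  structure(
    list(panels = panels, n_cells = n_cells,
         species_mix = species_mix[names(panels)],
         doublet_rate = doublet_rate, umi_per_cell = umi_per_cell,
         umi_dispersion = umi_dispersion,
         mean_reads_per_umi = mean_reads_per_umi,
         barcode_error_rate = barcode_error_rate,
         barcode_offset_rate = barcode_offset_rate,
         ambient_read_fraction = ambient_read_fraction,
         gene_rate_sdlog = gene_rate_sdlog, mito_fraction = mito_fraction,
         scheme = scheme, plate_size = plate_size, layout = layout,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Per-probe expression rates for one species
#'
#' Probe-level sampling rates are log-normal (one shared law per species),
#' divided by each probe's attenuation fold — attenuation reduces but does
#' not eliminate counts — and normalized to probabilities. Optionally the
#' mito-flagged probes are rescaled to a fixed share of the rate mass.
#'
#' @param panel A [probe_panel()].
#' @param sdlog Log-normal sd of the gene-level law.
#' @param mito_fraction Optional fixed share of rate mass on mito probes.
#' @return Numeric vector of sampling probabilities, one per probe, in panel
#'   order, summing to 1.
#' @export
simulate_probe_rates <- function(panel, sdlog = 1.5, mito_fraction = NULL) {
  rates <- rlnorm(nrow(panel), meanlog = 0, sdlog = sdlog) / panel$attenuation_fold
  if (!is.null(mito_fraction)) {
    if (mito_fraction < 0 || mito_fraction >= 1) abort("mito_fraction must be in [0, 1)")
    m <- panel$is_mito
    if (any(m) && any(!m)) {
      rates[m] <- rates[m] / sum(rates[m]) * mito_fraction
      rates[!m] <- rates[!m] / sum(rates[!m]) * (1 - mito_fraction)
    }
  }
  rates / sum(rates)
}

# internal: decode linear combination indices (1-based) into per-round well
# indices for a scheme (mixed-radix little-endian: round 1 varies fastest)
decode_combo <- function(idx, sizes) {
  idx0 <- idx - 1
  out <- matrix(0L, nrow = length(idx), ncol = length(sizes))
  for (r in seq_along(sizes)) {
    out[, r] <- as.integer(idx0 %% sizes[r]) + 1L
    idx0 <- idx0 %/% sizes[r]
  }
  out
}

# internal: generate a distance->=3 scheme of 4 plates for simulation
default_scheme <- function(plate_size, layout) {
  bc_len <- layout_segment(layout, "bc1")$length
  udi_len <- layout_segment(layout, "udi_i7")$length + layout_segment(layout, "udi_i5")$length
  plates <- lapply(1:4, function(r) {
    len <- if (r == 4) udi_len else bc_len
    barcode_plate(generate_whitelist(plate_size, len, min_distance = 3),
                  round_index = r)
  })
  barcode_scheme(plates)
}

#' Simulate a split-pool barcoded experiment to paired FASTQ
#'
#' Generates the four FASTQ files of a dual-indexed paired-end run (R1 =
#' probe insert, R2 = BC3-linker-BC2-linker-BC1-UMI, I1/I2 = UDI halves)
#' plus complete ground truth. Errors (substitutions within barcode
#' segments; 1-3 nt offsets of the whole barcode block) are applied after
#' ground truth is recorded. Output is deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory for the FASTQ files (created if needed).
#' @param compress Write gzipped FASTQ (default `TRUE`).
#' @return A list with `fastq` (named paths r1, r2, i1, i2), `scheme`,
#'   `layout`, and `truth`: `cells` (one row per simulated cell: `cell_id`,
#'   `cell_barcode`, per-round wells, `species`, `is_doublet`, `n_umis`,
#'   `n_reads`), `counts` (planted per `cell_id` x `probe_id` UMI counts),
#'   and `reads` (per read: origin `cell_id` or `"ambient"`, `cell_barcode`,
#'   true `probe_id` and `umi`).
#' @export
simulate_experiment <- function(config, out_dir, compress = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  layout <- config$layout
  scheme <- config$scheme %||% default_scheme(config$plate_size, layout)
  sizes <- vapply(scheme, nrow, numeric(1))
  diversity <- prod(sizes)
  species <- names(config$panels)

  ## ---- barcodes and cells ------------------------------------------------
  n_bc <- config$n_cells
  if (n_bc > diversity) {
    abort(sprintf("requested %d cells exceeds barcode diversity %d", n_bc, diversity))
  }
  # reserve extra combinations for ambient barcodes
  n_ambient_bc_max <- min(diversity - n_bc, max(20L, 5L * n_bc))
  combo_idx <- sample.int(diversity, n_bc + n_ambient_bc_max)
  wells <- decode_combo(combo_idx, sizes)
  well_labels <- function(rows) {
    data.frame(
      bc1_well = scheme$bc1$well[rows[, 1]],
      bc2_well = scheme$bc2$well[rows[, 2]],
      bc3_well = scheme$bc3$well[rows[, 3]],
      udi_well = scheme$udi$well[rows[, 4]]
    )
  }
  cell_bc_wells <- well_labels(wells[seq_len(n_bc), , drop = FALSE])
  cell_bc_ids <- cell_barcode_id(cell_bc_wells$bc1_well, cell_bc_wells$bc2_well,
                                 cell_bc_wells$bc3_well, cell_bc_wells$udi_well)

  is_doublet_bc <- runif(n_bc) < config$doublet_rate
  cells_per_bc <- ifelse(is_doublet_bc, 2L, 1L)
  bc_of_cell <- rep(seq_len(n_bc), cells_per_bc)
  n_cells_total <- length(bc_of_cell)
  cell_species <- sample(species, n_cells_total, replace = TRUE,
                         prob = config$species_mix)
  cells <- tibble(
    cell_id = sprintf("cell%05d", seq_len(n_cells_total)),
    cell_barcode = cell_bc_ids[bc_of_cell],
    bc1_well = cell_bc_wells$bc1_well[bc_of_cell],
    bc2_well = cell_bc_wells$bc2_well[bc_of_cell],
    bc3_well = cell_bc_wells$bc3_well[bc_of_cell],
    udi_well = cell_bc_wells$udi_well[bc_of_cell],
    species = cell_species,
    is_doublet = is_doublet_bc[bc_of_cell]
  )

  ## ---- molecules (UMIs) per cell -----------------------------------------
  rates <- lapply(species, function(s) {
    simulate_probe_rates(config$panels[[s]], sdlog = config$gene_rate_sdlog,
                         mito_fraction = config$mito_fraction)
  })
  names(rates) <- species
  n_umis <- rnbinom(n_cells_total, mu = config$umi_per_cell,
                    size = config$umi_dispersion)
  n_umis <- pmax(n_umis, 1L)

  umi_space <- 4^layout_segment(layout, "umi")$length
  counts_list <- vector("list", n_cells_total)
  reads_list <- vector("list", n_cells_total)
  for (i in seq_len(n_cells_total)) {
    sp <- cell_species[i]
    panel <- config$panels[[sp]]
    cnt <- rmultinom(1, n_umis[i], rates[[sp]])[, 1]
    nz <- which(cnt > 0)
    probe_of_umi <- rep(panel$probe_id[nz], cnt[nz])
    # distinct UMIs within a cell so planted per-(cell, probe) distinct-UMI
    # counts are exact
    umi_idx <- sample.int(umi_space, length(probe_of_umi))
    umis <- index_dna_at(umi_idx, layout_segment(layout, "umi")$length)
    dup <- 1L + rpois(length(probe_of_umi), config$mean_reads_per_umi - 1)
    counts_list[[i]] <- tibble(cell_id = cells$cell_id[i],
                               probe_id = panel$probe_id[nz],
                               umi_count = cnt[nz])
    reads_list[[i]] <- tibble(
      cell_id = cells$cell_id[i],
      species = sp,
      probe_id = rep(probe_of_umi, dup),
      umi = rep(umis, dup)
    )
  }
  truth_counts <- bind_rows(counts_list)
  cell_reads <- bind_rows(reads_list)
  cells$n_umis <- n_umis
  cells$n_reads <- vapply(reads_list, nrow, numeric(1))

  ## ---- ambient reads ------------------------------------------------------
  n_true_reads <- nrow(cell_reads)
  f <- config$ambient_read_fraction
  n_ambient_reads <- round(f / (1 - f) * n_true_reads)
  ambient <- NULL
  if (n_ambient_reads > 0) {
    mean_cell_reads <- n_true_reads / n_bc
    n_amb_bc <- max(1L, min(n_ambient_bc_max,
                            ceiling(n_ambient_reads / (mean_cell_reads / 100))))
    amb_wells <- well_labels(wells[n_bc + seq_len(n_amb_bc), , drop = FALSE])
    amb_ids <- cell_barcode_id(amb_wells$bc1_well, amb_wells$bc2_well,
                               amb_wells$bc3_well, amb_wells$udi_well)
    pick_bc <- sample.int(n_amb_bc, n_ambient_reads, replace = TRUE)
    amb_sp <- sample(species, n_ambient_reads, replace = TRUE,
                     prob = config$species_mix)
    amb_probe <- vapply(amb_sp, function(s) {
      sample(config$panels[[s]]$probe_id, 1, prob = rates[[s]])
    }, character(1))
    ambient <- tibble(
      cell_id = "ambient",
      species = amb_sp,
      probe_id = amb_probe,
      umi = index_dna_at(sample.int(umi_space, n_ambient_reads, replace = TRUE),
                         layout_segment(layout, "umi")$length),
      bc1_well = amb_wells$bc1_well[pick_bc],
      bc2_well = amb_wells$bc2_well[pick_bc],
      bc3_well = amb_wells$bc3_well[pick_bc],
      udi_well = amb_wells$udi_well[pick_bc],
      cell_barcode = amb_ids[pick_bc]
    )
  }

  cell_reads <- cell_reads |>
    left_join(cells[, c("cell_id", "bc1_well", "bc2_well", "bc3_well",
                        "udi_well", "cell_barcode")], by = "cell_id")
  reads <- bind_rows(cell_reads, ambient)
  reads <- reads[sample.int(nrow(reads)), ]
  reads$read_id <- sprintf("read%07d", seq_len(nrow(reads)))

  ## ---- sequence assembly ---------------------------------------------------
  seqs <- assemble_reads(reads, scheme, layout, config)

  paths <- write_fastqs(seqs, reads$read_id, out_dir, compress)
  list(
    fastq = paths,
    scheme = scheme,
    layout = layout,
    truth = list(
      cells = cells,
      counts = truth_counts,
      reads = reads[, c("read_id", "cell_id", "cell_barcode", "species",
                        "probe_id", "umi")]
    )
  )
}

# internal: index -> DNA at given width for arbitrary (possibly repeated) draws
index_dna_at <- function(idx, width) {
  alphabet <- c("A", "C", "G", "T")
  idx0 <- idx - 1
  out <- matrix("A", nrow = length(idx), ncol = width)
  for (pos in width:1) {
    out[, pos] <- alphabet[(idx0 %% 4) + 1]
    idx0 <- idx0 %/% 4
  }
  apply(out, 1, paste0, collapse = "")
}

# internal: one random substitution inside selected strings (guaranteed to
# change the base at the chosen position)
substitute_one <- function(x, hit) {
  if (!any(hit)) return(x)
  idx <- which(hit)
  len <- nchar(x[idx])
  pos <- 1L + floor(runif(length(idx)) * len)
  orig <- substr(x[idx], pos, pos)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  newb <- vapply(seq_along(idx), function(i) sample(alts[[orig[i]]], 1), character(1))
  xi <- x[idx]
  substr(xi, pos, pos) <- newb
  x[idx] <- xi
  x
}

# internal: build the four read sequences for every read row
assemble_reads <- function(reads, scheme, layout, config) {
  n <- nrow(reads)
  plate_seq <- function(plate, wells) plate$sequence[match(wells, plate$well)]
  bc1 <- plate_seq(scheme$bc1, reads$bc1_well)
  bc2 <- plate_seq(scheme$bc2, reads$bc2_well)
  bc3 <- plate_seq(scheme$bc3, reads$bc3_well)
  udi <- plate_seq(scheme$udi, reads$udi_well)

  er <- config$barcode_error_rate
  if (er > 0) {
    bc1 <- substitute_one(bc1, runif(n) < er)
    bc2 <- substitute_one(bc2, runif(n) < er)
    bc3 <- substitute_one(bc3, runif(n) < er)
    udi <- substitute_one(udi, runif(n) < er)
  }

  linker_len <- layout_segment(layout, "linker1")$length
  linker1 <- strrep("T", linker_len)
  linker2 <- strrep("G", layout_segment(layout, "linker2")$length)
  core <- paste0(bc3, linker1, bc2, linker2, bc1, reads$umi)

  # positional offset: shift the whole barcode block 1-3 nt downstream by a
  # random prefix pad; read length stays constant (3 - k random suffix bases)
  max_off <- 3L
  k <- integer(n)
  if (config$barcode_offset_rate > 0) {
    shifted <- runif(n) < config$barcode_offset_rate
    k[shifted] <- sample.int(max_off, sum(shifted), replace = TRUE)
  }
  pad <- random_dna_padding(n, max_off)
  r2 <- paste0(substr(pad, 1, k), core, substr(pad, k + 1, max_off))

  ins <- reads |> left_join(all_probe_sequences(config$panels),
                            by = c("species", "probe_id"))
  udi_half <- layout_segment(layout, "udi_i7")$length
  list(
    r1 = ins$sequence,
    r2 = r2,
    i1 = substr(udi, 1, udi_half),
    i2 = substr(udi, udi_half + 1, nchar(udi))
  )
}

# internal: n random pads of fixed width (vectorized)
random_dna_padding <- function(n, width) {
  if (width == 0) return(rep("", n))
  random_dna(n, width)
}

# internal: long table species x probe_id -> sequence
all_probe_sequences <- function(panels) {
  bind_rows(lapply(names(panels), function(s) {
    tibble(species = s, probe_id = panels[[s]]$probe_id,
           sequence = panels[[s]]$sequence)
  }))
}

# internal: write the 4 FASTQ files with constant Phred-30 qualities
write_fastqs <- function(seqs, ids, out_dir, compress = TRUE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- c(r1 = file.path(out_dir, paste0("R1", ext)),
             r2 = file.path(out_dir, paste0("R2", ext)),
             i1 = file.path(out_dir, paste0("I1", ext)),
             i2 = file.path(out_dir, paste0("I2", ext)))
  for (nm in names(paths)) {
    x <- Biostrings::DNAStringSet(setNames(seqs[[nm]], ids))
    q <- Biostrings::BStringSet(strrep("?", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, paths[[nm]], format = "fastq",
                                compress = compress, qualities = q)
  }
  paths
}

#' Simulate a matched bulk expression profile
#'
#' Draws a bulk (non-barcoded) probe-counting profile from the same
#' generative law as the single-cell simulator: reads are multinomial over
#' the per-probe rates, then aggregated to genes. Used to emulate
#' bulk-versus-pseudo-bulk concordance checks.
#'
#' @param panel A [probe_panel()].
#' @param rates Per-probe sampling probabilities (from
#'   [simulate_probe_rates()]); share these with the single-cell run for a
#'   matched comparison.
#' @param total_reads Bulk sequencing depth (0 gives an all-zero profile).
#' @param seed Optional seed.
#' @return A tibble `gene`, `count` covering every gene in the panel.
#' @export
simulate_bulk_profile <- function(panel, rates, total_reads, seed = NULL) {
  stopifnot(inherits(panel, "probe_panel"), length(rates) == nrow(panel))
  if (!is.null(seed)) set.seed(seed)
  if (total_reads < 0) abort("total_reads must be >= 0")
  cnt <- if (total_reads == 0) rep(0L, nrow(panel)) else {
    rmultinom(1, total_reads, rates)[, 1]
  }
  tibble(gene = panel$gene, count = cnt) |>
    group_by(.data$gene) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Simulate a barnyard count matrix directly (no FASTQ)
#'
#' Fast path for multiplet-rate studies: generates per-barcode noise-free
#' UMI counts for a two-species mixture in which each barcode independently
#' hosts a second cell with probability `doublet_rate`, and each constituent
#' cell's species is drawn from `species_mix`.
#'
#' @param panels Named list of two [probe_panel()]s (names = species); gene
#'   symbols should be disjoint between species.
#' @param n_barcodes Number of barcodes.
#' @param doublet_rate Probability a barcode hosts two cells.
#' @param species_mix Named species proportions (default 50:50).
#' @param umi_per_cell,umi_dispersion Per-cell molecule count model as in
#'   [sim_config()].
#' @param gene_rate_sdlog Log-normal sd of probe rates.
#' @param seed Mandatory seed.
#' @return A list: `matrix` (a [count_matrix()] of barcodes x genes),
#'   `species_map` (tibble `gene`, `species`), `truth` (per barcode:
#'   `cell_barcode`, `species` of each constituent, `is_doublet`,
#'   `is_cross_species`).
#' @export
simulate_barnyard_counts <- function(panels, n_barcodes,
                                     doublet_rate = 0.0109,
                                     species_mix = setNames(c(0.5, 0.5), names(panels)),
                                     umi_per_cell = 400, umi_dispersion = 4,
                                     gene_rate_sdlog = 1.5, seed) {
  if (missing(seed)) abort("a seed is mandatory")
  if (length(panels) != 2) abort("barnyard simulation needs exactly two species panels")
  set.seed(seed)
  species <- names(panels)
  rates <- lapply(panels, simulate_probe_rates, sdlog = gene_rate_sdlog)

  barcodes <- sprintf("bc%06d", seq_len(n_barcodes))
  is_doublet <- runif(n_barcodes) < doublet_rate
  sp1 <- sample(species, n_barcodes, replace = TRUE, prob = species_mix[species])
  sp2 <- ifelse(is_doublet,
                sample(species, n_barcodes, replace = TRUE, prob = species_mix[species]),
                NA_character_)

  # per-constituent-cell molecule totals
  n1 <- pmax(rnbinom(n_barcodes, mu = umi_per_cell, size = umi_dispersion), 1L)
  n2 <- ifelse(is_doublet,
               pmax(rnbinom(n_barcodes, mu = umi_per_cell, size = umi_dispersion), 1L),
               0L)

  # species-level totals per barcode, then one multinomial per species over
  # probes, allocated back to barcodes by multinomial-splitting (draws per
  # barcode remain multinomial because species totals are fixed)
  per_species_counts <- function(sp) {
    tot <- n1 * (sp1 == sp) + n2 * (!is.na(sp2) & sp2 == sp)
    nz <- which(tot > 0)
    if (length(nz) == 0) return(NULL)
    panel <- panels[[sp]]
    cnt <- vapply(seq_along(nz), function(i) {
      rmultinom(1, tot[nz[i]], rates[[sp]])[, 1]
    }, numeric(nrow(panel)))
    idx <- which(cnt > 0, arr.ind = TRUE)
    tibble(cell_barcode = barcodes[nz[idx[, 2]]],
           gene = panel$gene[idx[, 1]],
           count = cnt[idx])
  }
  long <- bind_rows(lapply(species, per_species_counts)) |>
    group_by(.data$cell_barcode, .data$gene) |>
    summarise(count = sum(.data$count), .groups = "drop")

  species_map <- bind_rows(lapply(species, function(s) {
    tibble(gene = unique(panels[[s]]$gene), species = s)
  }))
  cm <- count_matrix_from_long(long, cells = barcodes,
                               genes = species_map$gene)
  truth <- tibble(
    cell_barcode = barcodes, species_1 = sp1, species_2 = sp2,
    is_doublet = is_doublet,
    is_cross_species = is_doublet & sp1 != sp2
  )
  list(matrix = cm, species_map = species_map, truth = truth)
}
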