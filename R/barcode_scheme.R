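#' Construct a barcode plate
#'
#' One split-pool round of barcoding corresponds to a plate of wells, each
#' well carrying a distinct barcode sequence. Rounds 1-3 are ligated in
#' split-pool fashion; round 4 is the unique dual index (UDI) added during
#' PCR, treated here as a single logical barcode (i7 and i5 halves
#' concatenated).
#'
#' @param sequences Character vector of equal-length DNA barcodes.
#' @param round_index Which round (1-4) the plate serves.
#' @param well_labels Labels parallel to `sequences`; default `W01`, `W02`, ...
#' @param check_distance If `TRUE` (default), warn when any pair of barcodes
#'   is at Hamming distance < 3, in which case single-mismatch correction can
#'   be ambiguous.
#' @return A `barcode_plate` tibble with columns `well`, `sequence` and
#'   attributes `round_index`, `barcode_length`, `min_distance`.
#' @export
barcode_plate <- function(sequences, round_index,
                          well_labels = sprintf("W%02d", seq_along(sequences)),
                          check_distance = TRUE) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0) abort("a barcode plate must contain at least one barcode")
  if (!round_index %in% 1:4) abort("round_index must be 1, 2, 3 or 4")
  if (length(well_labels) != length(sequences)) {
    abort("well_labels must be parallel to sequences")
  }
  if (any(grepl("[^ACGT]", sequences))) abort("barcodes must be over {A,C,G,T}")
  if (length(unique(nchar(sequences))) != 1) {
    abort("all barcodes on a plate must have the same length")
  }
  if (anyDuplicated(sequences)) abort("barcodes on a plate must be pairwise distinct")

  mind <- min_pairwise_distance(sequences)
  if (check_distance && length(sequences) > 1 && mind < 3) {
    warn(sprintf(paste0("minimum pairwise Hamming distance on round-%d plate is %d (< 3); ",
                        "1-mismatch correction may be ambiguous"),
                 round_index, mind))
  }
  structure(
    tibble(well = as.character(well_labels), sequence = sequences),
    round_index = as.integer(round_index),
    barcode_length = nchar(sequences[1]),
    min_distance = mind,
    class = c("barcode_plate", class(tibble()))
  )
}

#' Minimum pairwise Hamming distance among equal-length sequences
#' @param sequences Character vector of equal-length strings.
#' @return Integer; `Inf` for fewer than two sequences.
#' @export
min_pairwise_distance <- function(sequences) {
  if (length(sequences) < 2) return(Inf)
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  mind <- ncol(mat)
  for (i in seq_len(nrow(mat) - 1)) {
    d <- rowSums(mat[(i + 1):nrow(mat), , drop = FALSE] !=
                   matrix(mat[i, ], nrow = nrow(mat) - i, ncol = ncol(mat), byrow = TRUE))
    mind <- min(mind, d)
  }
  as.integer(mind)
}

#' Generate a whitelist with guaranteed minimum pairwise Hamming distance
#'
#' Random search with rejection: candidate barcodes are drawn uniformly and
#' kept only if at distance >= `min_distance` from all kept barcodes. With
#' distance >= 3 a single substitution is always unambiguously correctable;
#' distance >= 5 additionally guarantees that a double substitution can never
#' be miscorrected to a different barcode.
#'
#' @param n Number of barcodes.
#' @param width Barcode length in nt.
#' @param min_distance Minimum pairwise Hamming distance (default 3).
#' @param max_tries Attempt budget before giving up.
#' @return Character vector of `n` barcodes.
#' @export
generate_whitelist <- function(n, width, min_distance = 3, max_tries = 10000 * n) {
  kept <- character(0)
  kept_mat <- NULL
  tries <- 0
  while (length(kept) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- random_dna(1, width)
    cand_chars <- strsplit(cand, "", fixed = TRUE)[[1]]
    ok <- TRUE
    if (!is.null(kept_mat)) {
      d <- rowSums(kept_mat != matrix(cand_chars, nrow = nrow(kept_mat),
                                      ncol = width, byrow = TRUE))
      ok <- all(d >= min_distance)
    }
    if (ok) {
      kept <- c(kept, cand)
      kept_mat <- rbind(kept_mat, cand_chars)
    }
  }
  if (length(kept) < n) {
    abort(sprintf("could not place %d barcodes of width %d at distance >= %d",
                  n, width, min_distance))
  }
  kept
}

#' Construct a 4-round barcode scheme
#'
#' @param plates List of four [barcode_plate()]s with `round_index` 1-4
#'   (rounds 1-3 ligation, round 4 UDI).
#' @return A `barcode_scheme` (named list `bc1`, `bc2`, `bc3`, `udi`).
#' @export
barcode_scheme <- function(plates) {
  if (length(plates) == 0) abort("a scheme needs at least one plate")
  rounds <- vapply(plates, function(p) attr(p, "round_index"), integer(1))
  if (!identical(sort(rounds), seq_along(plates)) && !identical(sort(rounds), 1:4)) {
    abort("plates must carry distinct round_index values starting at 1")
  }
  plates <- plates[order(rounds)]
  names(plates) <- c("bc1", "bc2", "bc3", "udi")[seq_along(plates)]
  structure(plates, class = "barcode_scheme")
}

#' Total barcode diversity of a scheme
#'
#' The number of distinct cell barcodes is the product of the plate sizes
#' across rounds (e.g. four rounds of 48 give 48^4 = 5,308,416 combinations).
#' Diversity is multiplicative and invariant to round order.
#'
#' @param scheme A `barcode_scheme`, a list of [barcode_plate()]s, or a
#'   numeric vector of plate sizes.
#' @return Number of barcode combinations.
#' @export
#' @examples
#' barcode_diversity(c(48, 48, 48, 48))
barcode_diversity <- function(scheme) {
  sizes <- if (is.numeric(scheme)) {
    scheme
  } else {
    vapply(scheme, function(p) nrow(p), numeric(1))
  }
  if (length(sizes) == 0) abort("scheme must contain at least one plate")
  if (any(sizes < 1)) abort("empty plate: every round must have at least one barcode")
  prod(sizes)
}

#' Plan the distribution of cells across plate wells
#'
#' Cells are distributed evenly across the wells of a barcoding plate; the
#' per-well load is the integer floor (e.g. 100,000 cells over 48 wells is
#' 2,083 cells/well).
#'
#' @param n_cells Total cells entering the round.
#' @param n_wells Wells on the plate.
#' @return Integer cells per well; 0 with a warning when `n_cells < n_wells`.
#' @export
plan_plate_distribution <- function(n_cells, n_wells) {
  if (n_wells < 1) abort("n_wells must be >= 1")
  if (n_cells < 0) abort("n_cells must be >= 0")
  if (n_cells < n_wells) {
    warn("fewer cells than wells: some wells will be empty")
  }
  as.integer(n_cells %/% n_wells)
}

#' Read barcode plates from a TSV
#'
#' Expects columns `well_label`, `sequence`, `round`.
#'
#' @param path TSV path.
#' @return A `barcode_scheme`.
#' @export
read_plates <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("well_label", "sequence", "round")
  if (!all(req %in% names(tab))) {
    abort(paste0("plate TSV needs columns: ", paste(req, collapse = ", ")))
  }
  plates <- lapply(sort(unique(tab$round)), function(r) {
    sub <- tab[tab$round == r, ]
    barcode_plate(sub$sequence, round_index = r, well_labels = sub$well_label)
  })
  barcode_scheme(plates)
}

#' Write a barcode scheme to TSV
#' @param scheme A `barcode_scheme`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_plates <- function(scheme, path) {
  tab <- bind_rows(lapply(scheme, function(p) {
    tibble(well_label = p$well, sequence = p$sequence,
           round = attr(p, "round_index"))
  }))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Compose a cell barcode id from the four matched wells
#'
#' The composite id is `bc1well_bc2well_bc3well_udiwell`. Because the
#' round-1 plate is loaded before pooling, the round-1 well doubles as the
#' sample identifier in multiplexed designs.
#'
#' @param bc1,bc2,bc3,udi Well labels per round (vectorized).
#' @return Character vector of composite cell-barcode ids.
#' @export
cell_barcode_id <- function(bc1, bc2, bc3, udi) {
  paste(bc1, bc2, bc3, udi, sep = "_")
}

#' Sample identifier of a cell barcode (its round-1 well)
#' @param cell_barcode Composite id from [cell_barcode_id()].
#' @return Character vector of round-1 well labels.
#' @export
sample_id <- function(cell_barcode) {
  sub("_.*$", "", cell_barcode)
}

#' Default read layout
#'
#' The layout maps named segments to 0-based half-open coordinates on the
#' four reads of a paired-end, dual-indexed run. By default read 1 carries
#' the fixed-length probe insert; read 2 carries, in order,
#' BC3(10) - linker(4) - BC2(10) - linker(4) - BC1(10) - UMI(10); the index
#' reads carry the two UDI halves (i7 then i5), concatenated by the
#' demultiplexer into the round-4 barcode. All lengths are configurable; the
#' simulator and the demultiplexer share one layout object.
#'
#' @param bc_length Ligated barcode length (nt) for rounds 1-3.
#' @param linker_length Linker length between ligated barcodes.
#' @param umi_length UMI length.
#' @param insert_length Probe insert length (must equal the panel probe length).
#' @param udi_half_length Length of each UDI half (i7 and i5).
#' @return A `read_layout` tibble with columns `segment`, `source_read`,
#'   `start`, `length`.
#' @export
read_layout <- function(bc_length = 10, linker_length = 4, umi_length = 10,
                        insert_length = 50, udi_half_length = 8) {
  segs <- tibble(
    segment = c("insert", "bc3", "linker1", "bc2", "linker2", "bc1", "umi",
                "udi_i7", "udi_i5"),
    source_read = c("r1", "r2", "r2", "r2", "r2", "r2", "r2", "i1", "i2"),
    length = c(insert_length, bc_length, linker_length, bc_length,
               linker_length, bc_length, umi_length,
               udi_half_length, udi_half_length)
  )
  start <- c(
    0,                                             # insert on r1
    cumsum(c(0, segs$length[segs$source_read == "r2"]))[1:6],
    0, 0                                           # index reads
  )
  segs$start <- as.integer(start)
  structure(segs[, c("segment", "source_read", "start", "length")],
            class = c("read_layout", class(tibble())))
}

# internal: coordinates of one named segment
layout_segment <- function(layout, name) {
  row <- layout[layout$segment == name, ]
  if (nrow(row) != 1) abort(paste0("layout segment not found: ", name))
  as.list(row)
}
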