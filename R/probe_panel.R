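#' Construct a probe panel
#'
#' A probe panel is the detector-oligo reference for a probe-ligation assay:
#' one row per probe (the ligated upstream + downstream oligo product), with
#' the gene it reports on, its full ligated sequence, and panel bookkeeping
#' flags. Several probes may target one gene; attenuated probes are those for
#' which non-functional competitor oligos were spiked in to down-scale reads
#' from highly expressed genes.
#'
#' @param probes A data frame with columns `probe_id`, `gene`, `sequence`,
#'   and optionally `attenuation_fold` (integer >= 1, default 1), `is_mito`
#'   and `is_ribo` (logical, default `FALSE`).
#' @param name Panel name.
#'
#' @return A `probe_panel`: a tibble with columns `probe_id`, `gene`,
#'   `sequence`, `attenuated`, `attenuation_fold`, `is_mito`, `is_ribo` and
#'   attributes `name`, `probe_length`, `n_genes`.
#' @export
#' @examples
#' probe_panel(tibble::tibble(
#'   probe_id = c("p1", "p2"), gene = c("ACTB", "ACTB"),
#'   sequence = c(strrep("ACGT", 5), strrep("TGCA", 5))
#' ))
probe_panel <- function(probes, name = "panel") {
  probes <- as_tibble(probes)
  required <- c("probe_id", "gene", "sequence")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0) {
    abort(paste0("probe table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(probes) == 0) abort("probe panel must contain at least one probe")
  if (!("attenuation_fold" %in% names(probes))) probes$attenuation_fold <- 1L
  if (!("is_mito" %in% names(probes))) probes$is_mito <- FALSE
  if (!("is_ribo" %in% names(probes))) probes$is_ribo <- FALSE

  probes$probe_id <- as.character(probes$probe_id)
  probes$gene <- as.character(probes$gene)
  probes$sequence <- toupper(as.character(probes$sequence))
  probes$attenuation_fold <- as.integer(probes$attenuation_fold)
  probes$attenuated <- probes$attenuation_fold > 1L

  dup <- probes$probe_id[duplicated(probes$probe_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate probe_id in panel: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(probes$attenuation_fold)) || any(probes$attenuation_fold < 1L)) {
    abort("attenuation_fold must be an integer >= 1")
  }
  bad <- grepl("[^ACGT]", probes$sequence) | nchar(probes$sequence) == 0
  if (any(bad)) {
    abort(paste0("probe sequence must be non-empty over {A,C,G,T}; offending probe_id: ",
                 paste(head(probes$probe_id[bad], 5), collapse = ", ")))
  }
  len <- unique(nchar(probes$sequence))
  if (length(len) != 1) {
    abort(paste0("all probe sequences in a panel must have the same length; saw lengths ",
                 paste(sort(len), collapse = ", ")))
  }

  probes <- probes[, c("probe_id", "gene", "sequence", "attenuated",
                       "attenuation_fold", "is_mito", "is_ribo")]
  structure(
    probes,
    name = name,
    probe_length = len,
    n_genes = length(unique(probes$gene)),
    class = c("probe_panel", class(probes))
  )
}

#' Number of distinct genes in a panel
#' @param panel A [probe_panel()].
#' @return Integer count of distinct gene symbols.
#' @export
n_genes <- function(panel) {
  stopifnot(inherits(panel, "probe_panel"))
  length(unique(panel$gene))
}

#' Load a probe panel from FASTA + metadata TSV
#'
#' The panel is stored as two files in the dialect of vendor probe manifests:
#' a FASTA of ligated probe sequences (ids = probe ids) and a tab-separated
#' metadata table keyed by `probe_id` with columns `gene`,
#' `attenuation_fold`, `is_mito`, `is_ribo`.
#'
#' @param fasta_path Path to the probe FASTA.
#' @param meta_path Path to the metadata TSV.
#' @param name Panel name; defaults to the FASTA file stem.
#' @return A [probe_panel()].
#' @export
load_panel <- function(fasta_path, meta_path,
                       name = tools::file_path_sans_ext(basename(fasta_path))) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  if (!("probe_id" %in% names(meta))) abort("metadata TSV must have a probe_id column")
  missing_meta <- setdiff(ids, meta$probe_id)
  if (length(missing_meta) > 0) {
    abort(paste0("metadata row missing for probe_id: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  extra_meta <- setdiff(meta$probe_id, ids)
  if (length(extra_meta) > 0) {
    abort(paste0("metadata probe_id absent from FASTA: ",
                 paste(head(extra_meta, 5), collapse = ", ")))
  }
  probes <- tibble(probe_id = ids, sequence = as.character(seqs)) |>
    left_join(meta, by = "probe_id")
  probe_panel(probes, name = name)
}

#' Write a probe panel to FASTA + metadata TSV
#'
#' @param panel A [probe_panel()].
#' @param fasta_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, fasta_path, meta_path) {
  stopifnot(inherits(panel, "probe_panel"))
  seqs <- Biostrings::DNAStringSet(setNames(panel$sequence, panel$probe_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    panel[, c("probe_id", "gene", "attenuation_fold", "is_mito", "is_ribo")],
    meta_path
  )
  invisible(c(fasta = fasta_path, meta = meta_path))
}

#' Summarize probe attenuation in a panel
#'
#' Attenuated probes are spiked with non-functional competitors that divide
#' their effective sampling rate by `attenuation_fold`, reducing (not
#' eliminating) reads from highly expressed genes.
#'
#' @param panel A [probe_panel()].
#' @return A one-row tibble with `n_probes`, `n_attenuated`,
#'   `fraction_attenuated` (proportion) and `percent_attenuated` (percentage
#'   rounded to 2 decimals).
#' @export
attenuation_summary <- function(panel) {
  stopifnot(inherits(panel, "probe_panel"))
  if (nrow(panel) == 0) abort("cannot summarize an empty panel")
  n_att <- sum(panel$attenuated)
  frac <- n_att / nrow(panel)
  tibble(
    n_probes = nrow(panel),
    n_attenuated = n_att,
    fraction_attenuated = frac,
    percent_attenuated = round(100 * frac, 2)
  )
}

#' @exportS3Method base::print
print.probe_panel <- function(x, ...) {
  cat(sprintf("<probe_panel '%s'> %d probes, %d genes, %d nt, %d attenuated\n",
              attr(x, "name"), nrow(x), n_genes(x), attr(x, "probe_length"),
              sum(x$attenuated)))
  NextMethod()
}
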