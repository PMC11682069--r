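#' CPM (relative counts) normalization
#'
#' Scales each cell's counts so they sum to `scaling_factor` (default 1e6,
#' i.e. counts per million). Zero-total cells cannot be normalized and are
#' excluded with a warning. Normalization is idempotent.
#'
#' @param cm A [count_matrix()].
#' @param scaling_factor Per-cell target sum (default 1e6).
#' @return A normalized [count_matrix()].
#' @export
cpm_normalize <- function(cm, scaling_factor = 1e6) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- Matrix::rowSums(cm$counts)
  zero <- totals == 0
  if (any(zero)) {
    warn(sprintf("excluding %d cell(s) with zero total counts", sum(zero)))
  }
  m <- cm$counts[!zero, , drop = FALSE]
  m <- Matrix::Diagonal(x = scaling_factor / totals[!zero]) %*% m
  rownames(m) <- rownames(cm$counts)[!zero]
  count_matrix(m, normalized = TRUE)
}

#' Per-cell marker-set overrepresentation scan
#'
#' Scans every cell for enrichment of a marker gene set among its expressed
#' genes — the rare-cell identification procedure. A gene is "expressed" in
#' a cell when its normalized count exceeds `expression_threshold`. For each
#' cell, the upper-tail hypergeometric probability of drawing at least `k`
#' marker genes when sampling the cell's `n` expressed genes from the `N`
#' genes of the universe (of which `K` are markers) is computed
#' (`P(X >= k)`), then adjusted across cells with Benjamini-Hochberg FDR.
#'
#' @param cm A CPM-normalized [count_matrix()] (see [cpm_normalize()]); raw
#'   counts are accepted but a message notes the threshold then applies to
#'   raw values.
#' @param markers Character vector of marker gene symbols (e.g. the 7
#'   podocyte markers Nphs1, Nphs2, Podxl, Wt1, Magi2, Synpo, Thsd7a).
#' @param expression_threshold Normalized-count cut; a gene with value
#'   strictly greater is called expressed (default 150).
#' @param fdr_alpha FDR cut for calling a hit (default 0.0005).
#' @param universe `"detected"` (default): N = genes with nonzero count in at
#'   least one cell; `"panel"`: N = all genes in the matrix.
#' @return An `ora_result` tibble: per cell `k`, `n`, `K`, `N`, `p_value`,
#'   `fdr`, `hit`; attributes record the configuration.
#' @export
ora_scan <- function(cm, markers, expression_threshold = 150,
                     fdr_alpha = 0.0005, universe = c("detected", "panel")) {
  stopifnot(inherits(cm, "count_matrix"))
  universe <- match.arg(universe)
  if (length(markers) == 0) abort("marker set is empty")
  if (!cm$normalized) {
    inform("matrix is not normalized; expression_threshold applies to raw counts")
  }
  genes <- colnames(cm$counts)
  uni <- if (universe == "detected") {
    genes[Matrix::colSums(cm$counts > 0) > 0]
  } else genes
  missing_markers <- setdiff(markers, uni)
  if (length(missing_markers) > 0) {
    abort(paste0("marker gene(s) absent from the gene universe: ",
                 paste(missing_markers, collapse = ", ")))
  }
  N <- length(uni)
  K <- length(unique(markers))

  m <- cm$counts[, genes %in% uni, drop = FALSE]
  expressed <- m > expression_threshold
  n <- unname(Matrix::rowSums(expressed))
  k <- unname(Matrix::rowSums(expressed[, colnames(m) %in% markers, drop = FALSE]))

  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  out <- tibble(
    cell_barcode = rownames(cm$counts),
    k = as.integer(k), n = as.integer(n), K = K, N = N,
    p_value = p, fdr = fdr, hit = fdr < fdr_alpha
  )
  structure(out,
            markers = markers, expression_threshold = expression_threshold,
            fdr_alpha = fdr_alpha, universe = universe,
            class = c("ora_result", class(tibble())))
}

#' Prevalence of flagged cells
#'
#' @param hits Number of cells flagged.
#' @param total_cells Total cells scanned.
#' @return Percentage rounded to 2 decimals.
#' @export
prevalence <- function(hits, total_cells) {
  if (total_cells <= 0) abort("total_cells must be positive")
  round(100 * hits / total_cells, 2)
}

#' Read a marker set from a one-gene-per-line file or GMT
#'
#' @param path Text file with one gene per line, or a `.gmt` file (first set
#'   is used unless `set_name` given).
#' @param set_name For GMT input, the named set to extract.
#' @return Character vector of gene symbols.
#' @export
read_marker_set <- function(path, set_name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    names(fields) <- vapply(fields, `[[`, character(1), 1)
    pick <- if (is.null(set_name)) fields[[1]] else fields[[set_name]]
    if (is.null(pick)) abort(paste0("set not found in GMT: ", set_name))
    return(pick[-(1:2)])
  }
  trimws(lines)
}
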