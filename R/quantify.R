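#' Sparse cell-by-gene count matrix
#'
#' Thin S3 wrapper around a `Matrix::dgCMatrix` with cells (barcodes) on
#' rows and genes on columns. Values are UMI counts unless the matrix has
#' been normalized (see [cpm_normalize()]).
#'
#' @param counts A matrix or sparse Matrix, rows = cell barcodes, cols =
#'   genes, with dimnames set.
#' @param normalized Whether values are normalized rather than raw counts.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, normalized = FALSE) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count matrix needs cell barcodes as rownames and genes as colnames")
  }
  if (any(counts@x < 0)) abort("counts must be non-negative")
  structure(list(counts = counts, normalized = normalized),
            class = "count_matrix")
}

# internal: build a count_matrix from a long (cell, gene, count) table
count_matrix_from_long <- function(long, cells = unique(long$cell_barcode),
                                   genes = unique(long$gene)) {
  m <- Matrix::sparseMatrix(
    i = match(long$cell_barcode, cells),
    j = match(long$gene, genes),
    x = long$count,
    dims = c(length(cells), length(genes)),
    dimnames = list(cells, genes)
  )
  count_matrix(m)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix%s> %d cells x %d genes, %d nonzero entries\n",
              if (x$normalized) " (normalized)" else "",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
tidy.count_matrix <- function(x, ...) {
  tm <- Matrix::summary(x$counts)
  tibble(
    cell_barcode = rownames(x$counts)[tm$i],
    gene = colnames(x$counts)[tm$j],
    count = tm$x
  )
}

#' Per-cell summary metrics
#'
#' Transcripts per cell are row sums of the UMI matrix; genes per cell are
#' the number of genes with UMI count > 0 (a probe with any UMI counts as a
#' detected gene).
#'
#' @param cm A [count_matrix()].
#' @param reads Optional tibble `cell_barcode`, `reads` (e.g. from
#'   [pool_by_barcode()]'s `cell_barcode`/`n_reads`) to append read depth.
#' @return A tibble: `cell_barcode`, `transcripts`, `genes` (+ `reads`).
#' @export
per_cell_metrics <- function(cm, reads = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- tibble(
    cell_barcode = rownames(cm$counts),
    transcripts = unname(Matrix::rowSums(cm$counts)),
    genes = unname(Matrix::rowSums(cm$counts > 0))
  )
  if (!is.null(reads)) {
    if ("n_reads" %in% names(reads)) {
      reads <- tibble(cell_barcode = reads$cell_barcode, reads = reads$n_reads)
    }
    out <- left_join(out, reads[, c("cell_barcode", "reads")], by = "cell_barcode")
  }
  out
}

#' Rank barcodes by read count
#'
#' @param reads A `demux_result`, its `$reads` tibble, or a tibble with
#'   `cell_barcode` and `n_reads`.
#' @return A `ranked_barcodes` tibble: `rank`, `cell_barcode`, `reads`,
#'   sorted by descending reads.
#' @export
rank_barcodes <- function(reads) {
  if (inherits(reads, "demux_result")) reads <- reads$reads
  tab <- if (all(c("cell_barcode", "n_reads") %in% names(reads))) {
    tibble(cell_barcode = reads$cell_barcode, reads = reads$n_reads)
  } else {
    reads |> count(.data$cell_barcode, name = "reads")
  }
  tab <- tab |> arrange(dplyr::desc(.data$reads)) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "cell_barcode", "reads")
  structure(tab, class = c("ranked_barcodes", class(tibble())))
}

#' Knee-point cell calling from ranked barcode counts
#'
#' Real cells and ambient barcodes separate as two regimes on the log-log
#' ranked barcode plot; the cell-calling read threshold is placed at the
#' inflection (knee). Two detection methods are offered on the
#' median-smoothed log10(count) vs log10(rank) curve:
#'
#' * `"inflection"` (default): the point of steepest descent — the minimum
#'   of the first derivative, estimated over a fixed log-rank span `delta`
#'   by linear interpolation. The cliff between the cell plateau and the
#'   ambient tail is orders of magnitude steeper than either regime, so the
#'   derivative minimum lands inside it regardless of plateau curvature.
#' * `"distance"`: the point of maximum perpendicular distance from the
#'   chord joining the first and last points. This classic construction
#'   finds the tangency point, which drifts into the cell plateau when the
#'   plateau itself slopes and the ambient tail is deep; it is retained for
#'   comparison.
#'
#' @param ranked A [rank_barcodes()] tibble (or any tibble with
#'   `cell_barcode` and `reads`).
#' @param smooth_window Median-smoothing window (odd; default 15).
#' @param min_barcodes Minimum number of nonzero barcodes required (default
#'   100); below this the distribution cannot support inflection analysis.
#' @param method `"inflection"` or `"distance"` (see above).
#' @param delta Log10-rank half-span for the derivative estimate
#'   (`"inflection"` method; default 0.05).
#' @return A `knee_result`: `threshold_rank`, `threshold_count`,
#'   `called_barcodes` (character vector), `n_called`, and the ranked table.
#' @export
find_knee <- function(ranked, smooth_window = 15, min_barcodes = 100,
                      method = c("inflection", "distance"), delta = 0.05) {
  method <- match.arg(method)
  if (!all(c("cell_barcode", "reads") %in% names(ranked))) {
    ranked <- rank_barcodes(ranked)
  }
  tab <- ranked |> filter(.data$reads > 0) |> arrange(dplyr::desc(.data$reads))
  tab$rank <- seq_len(nrow(tab))
  if (nrow(tab) < min_barcodes) {
    abort(sprintf("need >= %d barcodes with nonzero counts (got %d)",
                  min_barcodes, nrow(tab)))
  }
  if (length(unique(tab$reads)) == 1) abort("no inflection detected: all counts equal")

  x <- log10(tab$rank)
  y <- log10(tab$reads)
  k <- min(smooth_window, nrow(tab))
  if (k %% 2 == 0) k <- k - 1
  ys <- if (k >= 3) as.numeric(runmed(y, k)) else y

  if (method == "distance") {
    # perpendicular distance from the chord (first point -> last point)
    x0 <- x[1]; y0 <- ys[1]; x1 <- x[length(x)]; y1 <- ys[length(ys)]
    dx <- x1 - x0; dy <- y1 - y0
    dist <- abs(dy * x - dx * ys + x1 * y0 - y1 * x0) / sqrt(dx^2 + dy^2)
    knee <- which.max(dist)
    threshold_count <- tab$reads[knee]
  } else {
    # steepest descent of the smoothed curve over a fixed log-rank span;
    # duplicated x (never occurs: ranks are distinct) would break approx
    lo <- stats::approx(x, ys, xout = pmax(x - delta, x[1]), rule = 2)$y
    hi <- stats::approx(x, ys, xout = pmin(x + delta, x[length(x)]), rule = 2)$y
    span <- pmin(x + delta, x[length(x)]) - pmax(x - delta, x[1])
    slope <- (hi - lo) / pmax(span, .Machine$double.eps)
    # only points with the full +/- delta context are candidates, so edge
    # effects at either extreme of the curve cannot masquerade as the cliff
    full <- x - delta >= x[1] & x + delta <= x[length(x)]
    if (!any(full)) full <- rep(TRUE, length(x))
    slope[!full] <- Inf
    steepest <- which.min(slope)
    # threshold at the log-midpoint of the cliff: halfway (in log counts)
    # between the curve just above and just below the steepest point, so
    # neither the cliff top (missing low cells) nor its bottom (admitting
    # top ambient barcodes) is used verbatim
    y_top <- stats::approx(x, ys, xout = max(x[steepest] - delta, x[1]), rule = 2)$y
    y_bot <- stats::approx(x, ys, xout = min(x[steepest] + delta, x[length(x)]), rule = 2)$y
    threshold_count <- 10^((y_top + y_bot) / 2)
    knee <- max(1L, sum(tab$reads >= threshold_count))
  }

  called <- tab$cell_barcode[tab$reads >= threshold_count]
  structure(
    list(threshold_rank = knee,
         threshold_count = threshold_count,
         called_barcodes = called,
         n_called = length(called),
         method = method,
         ranked = tab),
    class = "knee_result"
  )
}

#' @exportS3Method base::print
print.knee_result <- function(x, ...) {
  cat(sprintf("<knee_result> threshold %s reads at rank %s; %s barcodes called\n",
              format(x$threshold_count), format(x$threshold_rank),
              format(x$n_called)))
  invisible(x)
}

#' @export
tidy.knee_result <- function(x, ...) {
  x$ranked |> mutate(called = .data$cell_barcode %in% x$called_barcodes)
}

#' @export
glance.knee_result <- function(x, ...) {
  tibble(threshold_rank = x$threshold_rank,
         threshold_count = x$threshold_count,
         n_called = x$n_called,
         n_barcodes = nrow(x$ranked))
}

#' Collapse reads to UMI counts per cell and probe
#'
#' UMIs collapse reads originating from one captured molecule: duplicate
#' reads (same cell barcode, probe and UMI) count once, so the result is
#' the number of distinct UMIs per (cell, probe). Collapse is exact-match
#' (no UMI-network correction) and idempotent. Reads without a probe
#' assignment are dropped.
#'
#' @param reads A tibble with `cell_barcode`, `probe_id`, `umi` (e.g. from
#'   [assign_probes()]).
#' @return A tibble `cell_barcode`, `probe_id`, `umi_count`.
#' @export
collapse_umis <- function(reads) {
  if (inherits(reads, "demux_result")) reads <- reads$reads
  need <- c("cell_barcode", "probe_id", "umi")
  if (!all(need %in% names(reads))) {
    abort(paste0("reads must carry columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(reads) == 0) {
    return(tibble(cell_barcode = character(0), probe_id = character(0),
                  umi_count = integer(0)))
  }
  reads |>
    filter(!is.na(.data$probe_id)) |>
    distinct(.data$cell_barcode, .data$probe_id, .data$umi) |>
    count(.data$cell_barcode, .data$probe_id, name = "umi_count")
}

#' Build the cell-by-gene count matrix
#'
#' Gene-level UMI counts sum the per-probe UMI counts over each gene's
#' probes; total UMIs are conserved. Cells can be restricted to a called
#' set (e.g. from [find_knee()]).
#'
#' @param probe_counts A [collapse_umis()] table.
#' @param panel A [probe_panel()] mapping probes to genes.
#' @param cells Optional character vector restricting (and ordering) the
#'   cell barcodes, e.g. `knee$called_barcodes`.
#' @return A [count_matrix()] covering every gene in the panel.
#' @export
build_matrix <- function(probe_counts, panel, cells = NULL) {
  stopifnot(inherits(panel, "probe_panel"))
  unknown <- setdiff(unique(probe_counts$probe_id), panel$probe_id)
  if (length(unknown) > 0) {
    abort(paste0("probe id(s) absent from panel: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (!is.null(cells)) {
    probe_counts <- probe_counts |> filter(.data$cell_barcode %in% cells)
  } else {
    cells <- unique(probe_counts$cell_barcode)
  }
  long <- probe_counts |>
    mutate(gene = panel$gene[match(.data$probe_id, panel$probe_id)]) |>
    group_by(.data$cell_barcode, .data$gene) |>
    summarise(count = sum(.data$umi_count), .groups = "drop")
  genes <- unique(panel$gene)
  count_matrix_from_long(long, cells = cells, genes = genes)
}

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Writes `matrix.mtx` (coordinate format, 1-based), `barcodes.tsv` and
#' `features.tsv` into `dir` — the de-facto single-cell exchange format.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  # MatrixMarket convention in single-cell tools: genes x cells
  Matrix::writeMM(Matrix::t(cm$counts), mtx)
  writeLines(rownames(cm$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "features.tsv"))
  invisible(c(matrix = mtx,
              barcodes = file.path(dir, "barcodes.tsv"),
              features = file.path(dir, "features.tsv")))
}

#' Read a count matrix written by [write_matrix()]
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return A [count_matrix()].
#' @export
read_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, features)
  count_matrix(m)
}
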