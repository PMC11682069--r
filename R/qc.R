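#' Sequencing saturation curve
#'
#' Bins cells by depth with a sliding window ([start, start + window),
#' advanced by `step`) and reports the mean number of detected genes per
#' bin. When a `experiment` column is present, per-bin means are computed
#' within each experiment first, then averaged across experiments with a
#' standard deviation — the replicate-level error bars of a saturation plot.
#'
#' @param metrics Per-cell tibble with a depth column (`reads` or
#'   `transcripts`, chosen by `axis`), `genes`, and optionally `experiment`.
#' @param window Window size in depth units (e.g. 20,000 reads).
#' @param step Window step (e.g. 5,000 reads).
#' @param axis `"reads"` or `"transcripts"`.
#' @return A `saturation_curve` tibble: `center`, `start`, `end`,
#'   `mean_genes`, `sd_genes` (`NA` for a single experiment), `n_cells`.
#'   Empty bins are omitted.
#' @export
saturation_curve <- function(metrics, window = 20000, step = 5000,
                             axis = c("reads", "transcripts")) {
  axis <- match.arg(axis)
  if (window <= 0 || step <= 0) abort("window and step must be positive")
  if (!axis %in% names(metrics)) {
    abort(paste0("metrics lacks a '", axis, "' column"))
  }
  depth <- metrics[[axis]]
  if (!"genes" %in% names(metrics)) abort("metrics lacks a 'genes' column")
  has_exp <- "experiment" %in% names(metrics)
  exper <- if (has_exp) metrics$experiment else rep("e1", nrow(metrics))

  starts <- seq(0, max(depth), by = step)
  bins <- purrr::map_dfr(starts, function(s) {
    inb <- depth >= s & depth < s + window
    if (!any(inb)) return(NULL)
    per_exp <- tibble(experiment = exper[inb], genes = metrics$genes[inb]) |>
      group_by(.data$experiment) |>
      summarise(mean_genes = mean(.data$genes), .groups = "drop")
    tibble(
      start = s, end = s + window, center = s + window / 2,
      mean_genes = mean(per_exp$mean_genes),
      sd_genes = if (has_exp && nrow(per_exp) > 1) stats::sd(per_exp$mean_genes) else NA_real_,
      n_cells = sum(inb)
    )
  })
  structure(
    bins[, c("center", "start", "end", "mean_genes", "sd_genes", "n_cells")],
    axis = axis, window = window, step = step,
    class = c("saturation_curve", class(tibble()))
  )
}

#' Classify cells in a mixed-species (barnyard) experiment
#'
#' Labels each cell by its majority species, or as a multiplet when the
#' minor species accounts for at least `minor_fraction_threshold` of the
#' cell's transcripts and at least `minor_count_min` transcripts — a
#' deliberate multi-species mixture makes cross-species multiplets directly
#' observable. The observed cross-species multiplet rate is then corrected
#' for undetectable within-species multiplets and unequal species
#' proportions via [correct_multiplet_rate()].
#'
#' @param cm A [count_matrix()] of raw UMI counts.
#' @param species_map Tibble `gene`, `species` (exactly two species), or a
#'   named character vector `gene -> species`.
#' @param minor_fraction_threshold Minimum minor-species transcript fraction
#'   for a multiplet call (default 0.2).
#' @param minor_count_min Minimum minor-species transcripts for a multiplet
#'   call (default 20).
#' @return A `barnyard_report`: `$cells` (per cell: species counts,
#'   `minor_fraction`, `label`), `$observed_multiplet_rate`,
#'   `$species_proportion_p` (fraction of singlets assigned to the first
#'   species, alphabetically), `$corrected_multiplet_rate`.
#' @export
classify_barnyard <- function(cm, species_map,
                              minor_fraction_threshold = 0.2,
                              minor_count_min = 20) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.character(species_map) && !is.null(names(species_map))) {
    species_map <- tibble(gene = names(species_map), species = unname(species_map))
  }
  genes <- colnames(cm$counts)
  sp_of_gene <- species_map$species[match(genes, species_map$gene)]
  if (any(is.na(sp_of_gene))) {
    abort(paste0("gene(s) missing a species label: ",
                 paste(head(genes[is.na(sp_of_gene)], 5), collapse = ", ")))
  }
  species <- sort(unique(sp_of_gene))
  if (length(species) != 2) abort("barnyard classification needs exactly two species")

  a_cols <- sp_of_gene == species[1]
  count_a <- unname(Matrix::rowSums(cm$counts[, a_cols, drop = FALSE]))
  count_b <- unname(Matrix::rowSums(cm$counts[, !a_cols, drop = FALSE]))
  total <- count_a + count_b
  minor <- pmin(count_a, count_b)
  minor_fraction <- ifelse(total > 0, minor / total, 0)

  is_multiplet <- minor_fraction >= minor_fraction_threshold & minor >= minor_count_min
  label <- ifelse(is_multiplet, "multiplet",
                  ifelse(count_a >= count_b, species[1], species[2]))
  cells <- tibble(
    cell_barcode = rownames(cm$counts),
    count_a = count_a, count_b = count_b,
    minor_fraction = minor_fraction, label = label
  )
  names(cells)[names(cells) == "count_a"] <- paste0("count_", species[1])
  names(cells)[names(cells) == "count_b"] <- paste0("count_", species[2])

  observed <- mean(label == "multiplet")
  singlets <- label != "multiplet"
  p <- if (any(singlets)) mean(label[singlets] == species[1]) else NA_real_
  corrected <- if (!is.na(p) && p > 0 && p < 1 && observed > 0) {
    correct_multiplet_rate(observed, p)
  } else if (observed == 0) 0 else NA_real_

  structure(
    list(cells = cells, species = species,
         observed_multiplet_rate = observed,
         species_proportion_p = p,
         corrected_multiplet_rate = corrected,
         minor_fraction_threshold = minor_fraction_threshold,
         minor_count_min = minor_count_min),
    class = "barnyard_report"
  )
}

#' @exportS3Method base::print
print.barnyard_report <- function(x, ...) {
  cat(sprintf(paste0("<barnyard_report> %d cells (%s vs %s): observed multiplet ",
                     "rate %.2f%%, corrected %.2f%% (p = %.3f)\n"),
              nrow(x$cells), x$species[1], x$species[2],
              100 * x$observed_multiplet_rate,
              100 * x$corrected_multiplet_rate, x$species_proportion_p))
  invisible(x)
}

#' @export
tidy.barnyard_report <- function(x, ...) x$cells

#' @export
glance.barnyard_report <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    observed_multiplet_rate = x$observed_multiplet_rate,
    species_proportion_p = x$species_proportion_p,
    corrected_multiplet_rate = x$corrected_multiplet_rate
  )
}

#' Correct an observed cross-species multiplet rate
#'
#' Only multiplets whose constituent cells differ in species are observable
#' in a barnyard design. If a fraction `p` of cells belongs to species A,
#' a random two-cell multiplet is cross-species with probability
#' `2 p (1 - p)`, so the corrected (actual) rate is
#' `observed / (2 p (1 - p))` — exactly twice the observed rate in a 50:50
#' mixture, and strictly more otherwise.
#'
#' @param observed Observed cross-species multiplet rate (proportion).
#' @param p Species proportion among singlets, strictly between 0 and 1.
#' @return Corrected multiplet rate (proportion).
#' @export
correct_multiplet_rate <- function(observed, p) {
  if (any(observed < 0 | observed > 1)) abort("observed must be a proportion")
  if (any(p <= 0 | p >= 1)) {
    abort("p must be strictly between 0 and 1 (one-species mixtures reveal no multiplets)")
  }
  observed / (2 * p * (1 - p))
}

#' Cell capture (recovery) rate
#'
#' @param input_cells Cells loaded into the assay.
#' @param called_cells Barcodes called as cells downstream.
#' @return A tibble: `input_cells`, `called_cells`, `rate` (proportion),
#'   `percent`. Warns when the rate exceeds 1 (overcalling).
#' @export
capture_rate <- function(input_cells, called_cells) {
  if (input_cells <= 0) abort("input_cells must be positive")
  if (called_cells < 0) abort("called_cells must be >= 0")
  rate <- called_cells / input_cells
  if (rate > 1) warn("capture rate exceeds 100%: more cells called than loaded")
  tibble(input_cells = input_cells, called_cells = called_cells,
         rate = rate, percent = 100 * rate)
}

#' Pseudo-bulk vs bulk correlation
#'
#' Pearson correlation between an aggregated single-cell profile and a bulk
#' profile over their shared gene universe, on log10(count + 1) by default
#' (set `log_transform = FALSE` for raw counts).
#'
#' @param aggregate Named numeric vector (gene -> count) or tibble
#'   `gene`, `count`: summed single-cell counts.
#' @param bulk Same shape: the bulk profile.
#' @param log_transform Apply log10(x + 1) before correlating (default
#'   `TRUE`).
#' @return Pearson r (scalar).
#' @export
pseudobulk_correlation <- function(aggregate, bulk, log_transform = TRUE) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$count, x$gene) else x
  }
  a <- as_vec(aggregate); b <- as_vec(bulk)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) abort("fewer than 3 shared genes")
  a <- a[shared]; b <- b[shared]
  if (log_transform) {
    a <- log10(a + 1); b <- log10(b + 1)
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    abort("zero-variance profile: correlation undefined")
  }
  cor(a, b, method = "pearson")
}

#' Aggregate a count matrix into a pseudo-bulk profile
#'
#' @param cm A [count_matrix()].
#' @param cells Optional subset of cell barcodes to aggregate.
#' @return A tibble `gene`, `count` (column sums).
#' @export
pseudobulk_profile <- function(cm, cells = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  if (!is.null(cells)) m <- m[rownames(m) %in% cells, , drop = FALSE]
  tibble(gene = colnames(m), count = Matrix::colSums(m))
}

#' Per-cell mitochondrial and ribosomal contamination
#'
#' Percentages of each cell's transcripts falling on genes flagged
#' mitochondrial or ribosomal in the probe panel (a gene is flagged when any
#' of its probes is).
#'
#' @param cm A [count_matrix()].
#' @param panel A [probe_panel()] carrying `is_mito` / `is_ribo` flags.
#' @return A tibble: `cell_barcode`, `mito_pct`, `ribo_pct`.
#' @export
contamination_fractions <- function(cm, panel) {
  stopifnot(inherits(cm, "count_matrix"), inherits(panel, "probe_panel"))
  flags <- panel |> group_by(.data$gene) |>
    summarise(is_mito = any(.data$is_mito), is_ribo = any(.data$is_ribo),
              .groups = "drop")
  genes <- colnames(cm$counts)
  mito <- genes %in% flags$gene[flags$is_mito]
  ribo <- genes %in% flags$gene[flags$is_ribo]
  total <- unname(Matrix::rowSums(cm$counts))
  pct <- function(mask) {
    if (!any(mask)) return(rep(0, nrow(cm$counts)))
    s <- unname(Matrix::rowSums(cm$counts[, mask, drop = FALSE]))
    ifelse(total > 0, 100 * s / total, 0)
  }
  tibble(cell_barcode = rownames(cm$counts),
         mito_pct = pct(mito), ribo_pct = pct(ribo))
}
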