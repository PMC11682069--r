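#' Combine per-species probe panels
#'
#' Row-binds panels (e.g. human + mouse whole-transcriptome pools) into one
#' reference for joint probe assignment. Probe ids, gene symbols and
#' sequences must be disjoint across species.
#'
#' @param panels Named list of [probe_panel()]s (names = species).
#' @return A [probe_panel()] named `"combined"`.
#' @export
combine_panels <- function(panels) {
  if (length(panels) == 1) return(panels[[1]])
  tabs <- lapply(panels, function(p) as_tibble(as.data.frame(p)))
  combined <- bind_rows(tabs)
  genes_by_species <- lapply(panels, function(p) unique(p$gene))
  overlap <- Reduce(intersect, genes_by_species)
  if (length(overlap) > 0) {
    abort(paste0("gene symbols shared between species panels: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  probe_panel(combined[, c("probe_id", "gene", "sequence", "attenuation_fold",
                           "is_mito", "is_ribo")], name = "combined")
}

#' Gene-to-species map from per-species panels
#'
#' @param panels Named list of [probe_panel()]s (names = species).
#' @return A tibble `gene`, `species`.
#' @export
species_map_from_panels <- function(panels) {
  bind_rows(lapply(names(panels), function(s) {
    tibble(gene = unique(panels[[s]]$gene), species = s)
  }))
}

#' Pipeline configuration
#'
#' One object carrying every stage parameter with its default; unknown
#' stage parameters are rejected. Scalar fields round-trip through YAML via
#' [write_config()] / [read_config()].
#'
#' @param panels Named list of [probe_panel()]s (names = species), or `NULL`
#'   when `panel_fasta`/`panel_meta` point at files.
#' @param panel_fasta,panel_meta Named character vectors of per-species
#'   panel file paths (parallel names).
#' @param plates_tsv Optional plate whitelist TSV ([read_plates()] format);
#'   when `NULL`, whitelists are generated.
#' @param sim,demux,align,knee,qc,ora Named lists overriding stage defaults
#'   (see [sim_config()], [demultiplex()], [assign_probe()], [find_knee()],
#'   [saturation_curve()]/[classify_barnyard()], [ora_scan()]).
#' @param seed Master seed for the run.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(panels = NULL, panel_fasta = NULL, panel_meta = NULL,
                            plates_tsv = NULL,
                            sim = list(), demux = list(), align = list(),
                            knee = list(), qc = list(), ora = list(),
                            seed = 1L, out_dir = tempfile("splitpool_run_")) {
  defaults <- list(
    sim = list(n_cells = 500, doublet_rate = 0.0109, umi_per_cell = 400,
               umi_dispersion = 4, mean_reads_per_umi = 1.5,
               barcode_error_rate = 0, barcode_offset_rate = 0,
               ambient_read_fraction = 0.05, gene_rate_sdlog = 1.5,
               plate_size = 48),
    demux = list(max_offset = 3, max_mismatch = 1),
    align = list(max_mismatch = 2),
    knee = list(smooth_window = 15, min_barcodes = 100),
    qc = list(saturation_window = 20000, saturation_step = 5000,
              minor_fraction_threshold = 0.2, minor_count_min = 20),
    ora = list(markers = NULL, expression_threshold = 150, fdr_alpha = 5e-4)
  )
  merge_stage <- function(stage, user) {
    unknown <- setdiff(names(user), names(defaults[[stage]]))
    if (length(unknown) > 0) {
      abort(paste0("unknown ", stage, " parameter(s): ",
                   paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults[[stage]], user)
  }
  structure(
    list(panels = panels, panel_fasta = panel_fasta, panel_meta = panel_meta,
         plates_tsv = plates_tsv,
         sim = merge_stage("sim", sim), demux = merge_stage("demux", demux),
         align = merge_stage("align", align), knee = merge_stage("knee", knee),
         qc = merge_stage("qc", qc), ora = merge_stage("ora", ora),
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' Panel and plate objects are not serialized; file paths are. The
#' serializable fields round-trip exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ser <- config[c("panel_fasta", "panel_meta", "plates_tsv", "sim", "demux",
                  "align", "knee", "qc", "ora", "seed", "out_dir")]
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    panel_fasta = unlist(raw$panel_fasta), panel_meta = unlist(raw$panel_meta),
    plates_tsv = raw$plates_tsv,
    sim = raw$sim %||% list(), demux = raw$demux %||% list(),
    align = raw$align %||% list(), knee = raw$knee %||% list(),
    qc = raw$qc %||% list(), ora = raw$ora %||% list(),
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir %||% tempfile("splitpool_run_")
  )
}

#' Run the full pipeline: simulate, demultiplex, count, QC, ORA
#'
#' Executes every stage from one configuration: read simulation, 4-round
#' demultiplexing, probe assignment, knee-based cell calling, UMI collapse
#' into the count matrix, QC metrics (saturation, contamination, capture
#' rate, and barnyard multiplet analysis when two species are configured),
#' and the optional marker-set ORA scan. All artifacts are written under
#' `config$out_dir` and listed, with MD5 checksums, in the returned (and
#' written) run manifest. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest: stage list, artifact paths + checksums, and
#'   headline `metrics` (correctly-barcoded fraction, cells called, mean
#'   genes/cell, multiplet rates when applicable).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  panels <- config$panels
  if (is.null(panels)) {
    if (is.null(config$panel_fasta)) abort("config provides neither panels nor panel files")
    panels <- purrr::imap(config$panel_fasta, function(fa, s) {
      load_panel(fa, config$panel_meta[[s]], name = s)
    })
  }
  scheme <- if (!is.null(config$plates_tsv)) read_plates(config$plates_tsv) else NULL

  ## simulate
  sc <- do.call(sim_config, c(list(panels = panels, scheme = scheme,
                                   seed = config$seed), config$sim))
  sim <- simulate_experiment(sc, file.path(out_dir, "fastq"))

  ## demultiplex
  dm <- demultiplex(sim$fastq, sim$layout, sim$scheme,
                    max_offset = config$demux$max_offset,
                    max_mismatch = config$demux$max_mismatch)
  jsonlite::write_json(glance(dm), file.path(out_dir, "demux_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  ## probe assignment
  combined <- combine_panels(panels)
  reads <- assign_probes(dm, combined, max_mismatch = config$align$max_mismatch)

  ## cell calling + counting
  ranked <- rank_barcodes(reads)
  knee <- find_knee(ranked, smooth_window = config$knee$smooth_window,
                    min_barcodes = config$knee$min_barcodes)
  probe_counts <- collapse_umis(reads)
  cm <- build_matrix(probe_counts, combined, cells = knee$called_barcodes)
  write_matrix(cm, file.path(out_dir, "matrix"))

  ## qc
  metrics <- per_cell_metrics(cm) |>
    left_join(tibble(cell_barcode = ranked$cell_barcode, reads = ranked$reads),
              by = "cell_barcode")
  contam <- contamination_fractions(cm, combined)
  metrics <- left_join(metrics, contam, by = "cell_barcode")
  readr::write_tsv(metrics, file.path(out_dir, "cell_metrics.tsv"))

  sat <- saturation_curve(metrics, window = config$qc$saturation_window,
                          step = config$qc$saturation_step, axis = "reads")
  readr::write_tsv(sat, file.path(out_dir, "saturation.tsv"))

  cap <- capture_rate(config$sim$n_cells, knee$n_called)
  headline <- list(
    fraction_correctly_barcoded = dm$stats$fraction_valid,
    cells_called = knee$n_called,
    mean_genes_per_cell = mean(metrics$genes),
    mean_transcripts_per_cell = mean(metrics$transcripts),
    capture_rate_percent = cap$percent
  )

  barny <- NULL
  if (length(panels) == 2) {
    barny <- classify_barnyard(
      cm, species_map_from_panels(panels),
      minor_fraction_threshold = config$qc$minor_fraction_threshold,
      minor_count_min = config$qc$minor_count_min
    )
    readr::write_tsv(barny$cells, file.path(out_dir, "barnyard_cells.tsv"))
    headline$observed_multiplet_rate <- barny$observed_multiplet_rate
    headline$corrected_multiplet_rate <- barny$corrected_multiplet_rate
  }

  ora <- NULL
  if (!is.null(config$ora$markers)) {
    norm <- cpm_normalize(cm)
    ora <- ora_scan(norm, config$ora$markers,
                    expression_threshold = config$ora$expression_threshold,
                    fdr_alpha = config$ora$fdr_alpha)
    readr::write_tsv(ora, file.path(out_dir, "ora_results.tsv"))
    headline$ora_hits <- sum(ora$hit)
    headline$ora_prevalence_percent <- prevalence(sum(ora$hit), nrow(ora))
  }

  artifacts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  manifest <- list(
    package = "splitpool",
    version = as.character(utils::packageVersion("splitpool")),
    seed = config$seed,
    stages = c("simulate", "demultiplex", "assign_probes", "count", "qc",
               if (!is.null(ora)) "ora"),
    artifacts = tibble(
      path = sub(paste0("^", out_dir, "/?"), "", artifacts),
      md5 = unname(tools::md5sum(artifacts))
    ),
    metrics = headline
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(manifest, list(matrix = cm, knee = knee, demux = dm,
                             barnyard = barny, ora = ora, truth = sim$truth)))
}
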