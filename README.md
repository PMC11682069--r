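# splitpool

Preprocessing and QC for **split-pool barcoded, probe-ligation single-cell
sequencing** in R.

In this assay class, transcripts are detected by probe pairs that ligate
into fixed-length amplifiable products (no reverse transcription), and
cells acquire their identity by passing through three rounds of
distribute–ligate–pool barcoding plus a unique dual index (UDI) added at
PCR — four rounds of 48 barcodes give 48⁴ = 5,308,416 combinations. The
sequencing output is paired FASTQ in which one read is a complete probe
copy and the other carries the barcode chain and a UMI.

splitpool is for method developers and analysts who need the complete,
testable path from such reads to a QC'd count matrix:

* a **ground-truthed simulator** (paired FASTQ + truth tables, including
  mixed-species "barnyard" designs, doublets, ambient background, barcode
  substitution and positional-offset errors),
* a **4-round demultiplexer** tolerating ±3 nt offsets and 1 substitution
  per barcode, with explicit (|offset|, mismatches) tie-breaking and
  ambiguity discard,
* **probe assignment** by unique-best Hamming match against the panel
  (exact hash + k-mer seeding; brute-force oracle in the tests),
* **knee-point cell calling** from the ranked barcode plot (derivative
  inflection by default, chord distance as an option),
* **UMI collapse** to a sparse cells × genes matrix (MatrixMarket output),
* **QC**: sequencing saturation curves, barnyard multiplet-rate estimation
  with the correction `corrected = observed / (2p(1−p))`, capture rate,
  pseudo-bulk Pearson concordance, mito/ribo contamination,
* **rare-cell identification** by per-cell marker-set overrepresentation:
  CPM normalization (10⁶), expression threshold (150), hypergeometric
  upper tail `P(X ≥ k)` over the detected-gene universe, BH FDR.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
ggplot2 `plot_*()`/`autoplot()` functions; the full pipeline runs from one
config via `run_pipeline()` (a thin CLI lives in `inst/scripts/`).

## Worked example

Simulate a 200-cell two-species mixture with barcode errors, demultiplex,
call cells, count, and run the barnyard analysis:

```r
library(splitpool)

set.seed(1)
panel_hs <- probe_panel(tibble::tibble(
  probe_id = sprintf("hs_p%03d", 1:120),
  gene     = sprintf("hs_g%03d", rep(1:90, length.out = 120)),
  sequence = apply(matrix(sample(c("A","C","G","T"), 120*50, TRUE), 120), 1,
                   paste0, collapse = "")
), name = "human")
panel_mm <- probe_panel(tibble::tibble(
  probe_id = sprintf("mm_p%03d", 1:100),
  gene     = sprintf("mm_g%03d", rep(1:80, length.out = 100)),
  sequence = apply(matrix(sample(c("A","C","G","T"), 100*50, TRUE), 100), 1,
                   paste0, collapse = "")
), name = "mouse")

cfg <- sim_config(panels = list(human = panel_hs, mouse = panel_mm),
                  n_cells = 200, doublet_rate = 0.02, umi_per_cell = 150,
                  plate_size = 12, barcode_error_rate = 0.01,
                  barcode_offset_rate = 0.1, seed = 7,
                  layout = read_layout(insert_length = 50))
sim  <- simulate_experiment(cfg, file.path(tempdir(), "demo"))
dm   <- demultiplex(sim$fastq, sim$layout, sim$scheme)
dm
#> <demux_result> 47475 reads, 47475 valid (100.0% correctly barcoded)

knee <- find_knee(rank_barcodes(dm), min_barcodes = 50)
knee
#> <knee_result> threshold 26.1669 reads at rank 200; 200 barcodes called

combined <- combine_panels(cfg$panels)
cm <- build_matrix(collapse_umis(assign_probes(dm, combined)), combined,
                   cells = knee$called_barcodes)
cm
#> <count_matrix> 200 cells x 170 genes, 8371 nonzero entries

head(per_cell_metrics(cm), 3)
#> # A tibble: 3 × 3
#>   cell_barcode    transcripts genes
#>   <chr>                 <dbl> <int>
#> 1 W07_W08_W12_W09         544   113
#> 2 W05_W10_W10_W07         454    61
#> 3 W12_W03_W07_W10         434    65

classify_barnyard(cm, species_map_from_panels(cfg$panels))
#> <barnyard_report> 200 cells (human vs mouse): observed multiplet rate 2.50%,
#>   corrected 5.02% (p = 0.528)

capture_rate(200, knee$n_called)$percent
#> [1] 100
```

Reading the output: every read's four barcodes were resolved despite the
injected 1% substitution and 10% offset errors (the whitelists are
generated at pairwise Hamming distance ≥ 3, so single substitutions are
always correctable); the knee threshold separates the 200 true cells from
the ambient background exactly; per-cell `genes` counts genes with UMI
count > 0 and `transcripts` is the UMI total; the barnyard report labels
cells with ≥ 20% / ≥ 20 minor-species transcripts as multiplets and
corrects the observed cross-species rate by 1/(2p(1−p)) for the
undetectable within-species multiplets (≈ 2× at a 50:50 mix — here 5 of
200 barcodes, so the small-sample estimate runs above the configured 2%).
`plot_knee(knee)` and `autoplot()` on the barnyard report draw the
standard diagnostic figures.

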