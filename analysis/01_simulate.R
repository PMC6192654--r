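#!/usr/bin/env Rscript
# Build the synthetic study panels: the default two-class panel (promoters
# GC-shifted +10 points, planted determinant pool), a matched null panel
# (no planting, no shift) for calibration, and a three-species panel with a
# fully shared promoter pool for the transfer analysis.
#
# Outputs: results/panels/<name>/ (FASTA, BED, truth and conservation TSVs).

library(seqdet)

seed <- 20181005  # publication date of the study this workflow emulates
dir.create("results/panels", recursive = TRUE, showWarnings = FALSE)

message("study panel: 2 species x 7 Mb, 300 enhancers + 300 promoters each")
study <- generate_panel(panel_spec(seed = seed),
                        outdir = "results/panels/study")
print(head(planted_or_estimates(study)[, c("species", "region_class", "kmer",
                                           "target_or", "realized_ratio")]))

message("null panel: 2 species x 1 Mb, 200 fixed-length regions per class")
null_spec <- panel_spec(
  n_species = 2, chrom_length = 1e6,
  region_class_params = list(
    enhancer = list(n_regions = 200, length_mean = 1000, length_sd = 0,
                    fg_gc_shift = 0),
    promoter = list(n_regions = 200, length_mean = 1000, length_sd = 0,
                    fg_gc_shift = 0)),
  determinant_pool = default_determinant_pool(0, 0)[0, ],
  seed = seed + 1)
invisible(generate_panel(null_spec, outdir = "results/panels/null"))

message("contrast panel: both classes unshifted, planted pool only")
contrast_spec <- panel_spec(
  n_species = 1, chrom_length = 7e6,
  region_class_params = list(
    enhancer = list(n_regions = 300, length_mean = 2000, length_sd = 400,
                    fg_gc_shift = 0),
    promoter = list(n_regions = 300, length_mean = 2000, length_sd = 400,
                    fg_gc_shift = 0)),
  seed = seed + 3)
invisible(generate_panel(contrast_spec, outdir = "results/panels/contrast"))

message("transfer panel: 3 species, shared promoter pool at OR 3")
transfer_spec <- panel_spec(
  n_species = 3, chrom_length = 2.2e6,
  region_class_params = list(
    promoter = list(n_regions = 200, length_mean = 2000, length_sd = 300,
                    fg_gc_shift = 0)),
  determinant_pool = default_determinant_pool(0, 10),
  sharing = 1, seed = seed + 2)
invisible(generate_panel(transfer_spec, outdir = "results/panels/transfer"))

message("panels written under results/panels/")
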