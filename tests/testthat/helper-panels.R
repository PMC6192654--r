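# Shared synthetic panels, built once per test run and cached.

.panel_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.panel_cache[[key]])) .panel_cache[[key]] <- force(expr)
  .panel_cache[[key]]
}

# Small two-class panel for fast structural tests.
small_panel_spec <- function(seed = 1, ...) {
  panel_spec(
    n_species = 1,
    chrom_length = 5e5,
    region_class_params = list(
      enhancer = list(n_regions = 40, length_mean = 500, length_sd = 50,
                      fg_gc_shift = 0),
      promoter = list(n_regions = 40, length_mean = 500, length_sd = 50,
                      fg_gc_shift = 0.10)),
    determinant_pool = default_determinant_pool(3, 3),
    seed = seed, ...)
}

small_panel <- function(seed = 1) {
  cached(paste0("small", seed), generate_panel(small_panel_spec(seed)))
}

# Null panel at the calibration-study scale: 2 species x 1 Mb, 200 fixed-
# length regions per class, no planting, no GC shift.
null_panel_spec <- function(seed) {
  panel_spec(
    n_species = 2,
    chrom_length = 1e6,
    region_class_params = list(
      enhancer = list(n_regions = 200, length_mean = 1000, length_sd = 0,
                      fg_gc_shift = 0),
      promoter = list(n_regions = 200, length_mean = 1000, length_sd = 0,
                      fg_gc_shift = 0)),
    determinant_pool = default_determinant_pool(0, 0)[0, ],
    seed = seed)
}

# Planted-recovery panel: 300 x 2 kb regions per class, 10 enhancer k-mers at
# OR 1.5 and 10 promoter k-mers at OR 3, no GC shift in either class.
recovery_panel_spec <- function(seed) {
  panel_spec(
    n_species = 1,
    chrom_length = 7e6,
    region_class_params = list(
      enhancer = list(n_regions = 300, length_mean = 2000, length_sd = 400,
                      fg_gc_shift = 0),
      promoter = list(n_regions = 300, length_mean = 2000, length_sd = 400,
                      fg_gc_shift = 0)),
    seed = seed)
}

# Default study panel (promoter +0.10 GC shift, planted pool) for prediction
# tests.
study_panel <- function(seed = 1) {
  cached(paste0("study", seed), generate_panel(panel_spec(seed = seed)))
}

# Small full-pipeline configuration used by the reproducibility checks.
tiny_config <- function(seed = 5) {
  spec <- panel_spec(
    n_species = 2,
    chrom_length = 6e5,
    region_class_params = list(
      enhancer = list(n_regions = 50, length_mean = 800, length_sd = 100,
                      fg_gc_shift = 0),
      promoter = list(n_regions = 50, length_mean = 800, length_sd = 100,
                      fg_gc_shift = 0.10)),
    determinant_pool = default_determinant_pool(4, 4, or_enhancer = 3,
                                                or_promoter = 6),
    conserved_frac = 0.02,
    seed = seed)
  pipeline_config(spec, k_min = 6, k_max = 7, min_count = 30,
                  sample_n = 500, n_folds = 5, seed = seed)
}

# Pairs with backgrounds for one species/class of a panel.
panel_pairs <- function(panel, species, region_class) {
  filter_missing(build_backgrounds(
    pairs_from_panel(panel, species, region_class)))
}

# Determinant calls for one species/class.
panel_determinants <- function(panel, species, region_class,
                               k_min = 6, k_max = 8, ...) {
  call_species_determinants(
    build_count_table(panel_pairs(panel, species, region_class),
                      k_min, k_max), ...)
}
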