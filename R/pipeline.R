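# End-to-end orchestration: simulate -> regions -> count -> enrich -> common
# -> sample -> train -> predict -> factor, with deterministic per-stage seeds
# and a manifest of outputs.

#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults matching the reference
#' workflow: fragment lengths 6-15, background offset 100 kb, count filter
#' 100, FDR 0.05, 10,000 sampled determinants, 10 CV folds.
#'
#' @param spec A [panel_spec()] describing the synthetic panel to run on.
#' @param k_min,k_max Fragment length range.
#' @param offset Foreground-background distance (bp).
#' @param min_count Strict count filter for testing eligibility.
#' @param q_max FDR threshold.
#' @param sample_n Determinants sampled for model input.
#' @param n_folds CV folds.
#' @param seed Master seed; per-stage seeds derive from it via [stage_seed()].
#' @param low_gc Also fit low-GC (GC <= 0.5) determinant models.
#' @param matched_null Also fit matched non-determinant baseline models.
#' @param drop_conserved Remove conserved regions before analysis.
#' @param tfbs_slope,tfbs_noise_sd Synthetic TFBS annotation parameters for
#'   the factor-model stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec,
                            k_min = 6, k_max = 15,
                            offset = 1e5,
                            min_count = 100,
                            q_max = 0.05,
                            sample_n = 10000,
                            n_folds = 10,
                            seed = 1,
                            low_gc = FALSE,
                            matched_null = FALSE,
                            drop_conserved = FALSE,
                            tfbs_slope = -0.3,
                            tfbs_noise_sd = 0.05) {
  stopifnot(inherits(spec, "panel_spec"), k_min >= 1, k_max >= k_min)
  structure(list(spec = spec, k_min = k_min, k_max = k_max, offset = offset,
                 min_count = min_count, q_max = q_max, sample_n = sample_n,
                 n_folds = n_folds, seed = as.integer(seed),
                 low_gc = low_gc, matched_null = matched_null,
                 drop_conserved = drop_conserved, tfbs_slope = tfbs_slope,
                 tfbs_noise_sd = tfbs_noise_sd),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic panel
#'
#' Executes all stages in order, writing every stage's tables under `outdir`
#' and a manifest (file checksums, seeds, configuration echo) at the end.
#' Re-running with the same configuration reproduces every output
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory for stage tables and the manifest.
#' @return Invisibly, a list with the in-memory stage results: `panel`,
#'   `pairs`, `determinants`, `common`, `class_comparison`, `samples`,
#'   `models`, `evaluations`, `factor_fits`, `manifest`.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec
  stage <- function(name) message("[seqdet] stage: ", name)

  stage("simulate")
  panel_dir <- file.path(outdir, "panel")
  panel <- generate_panel(spec, outdir = panel_dir)
  classes <- names(spec$region_class_params)
  sp_names <- names(panel$species)

  stage("regions")
  pairs <- list()
  for (s in sp_names) for (cls in classes) {
    p <- load_regions(file.path(panel_dir, sprintf("%s_%s.bed", s, cls)),
                      file.path(panel_dir, paste0(s, ".fa")),
                      species = s, region_class = cls)
    p <- build_backgrounds(p, offset = config$offset)
    p <- filter_missing(p)
    if (config$drop_conserved)
      p <- filter_conserved(p, panel$conservation)
    pairs[[paste(s, cls, sep = ".")]] <- p
  }
  summaries <- do.call(rbind, lapply(pairs, summarize_regions))
  rownames(summaries) <- NULL
  write_tsv(summaries, file.path(outdir, "region_summary.tsv"))
  pairs_tab <- do.call(rbind, lapply(pairs, function(p) {
    d <- as.data.frame(p)
    d[, setdiff(names(d), c("fg_seq", "bg_seq"))]
  }))
  rownames(pairs_tab) <- NULL
  write_tsv(pairs_tab, file.path(outdir, "pairs.tsv"))

  stage("count")
  tables <- lapply(pairs, build_count_table,
                   k_min = config$k_min, k_max = config$k_max)

  stage("enrich")
  determinants <- lapply(tables, call_species_determinants,
                         min_count = config$min_count, q_max = config$q_max)
  for (nm in names(determinants))
    write_tsv(determinants[[nm]],
              file.path(outdir, sprintf("determinants_%s.tsv", nm)))

  stage("common")
  common <- list()
  for (cls in classes) {
    per_sp <- tables[paste(sp_names, cls, sep = ".")]
    names(per_sp) <- sp_names
    common[[cls]] <- call_common_determinants(per_sp,
                                              min_count = config$min_count,
                                              q_max = config$q_max)
    write_tsv(common[[cls]],
              file.path(outdir, sprintf("common_determinants_%s.tsv", cls)))
  }

  stage("compare")
  class_comparison <- list()
  if (all(c("enhancer", "promoter") %in% classes)) {
    for (s in sp_names) {
      enh <- determinants[[paste(s, "enhancer", sep = ".")]]
      pro <- determinants[[paste(s, "promoter", sep = ".")]]
      enh <- enh[enh$is_determinant, , drop = FALSE]
      pro <- pro[pro$is_determinant, , drop = FALSE]
      if (nrow(enh) && nrow(pro))
        class_comparison[[s]] <- compare_classes(enh, pro)
    }
    if (length(class_comparison)) {
      cmp_tab <- do.call(rbind, lapply(names(class_comparison), function(s) {
        cc <- class_comparison[[s]]
        data.frame(species = s, wilcoxon_stat = cc$wilcoxon_stat,
                   wilcoxon_p = cc$wilcoxon_p, t_stat = cc$t_stat,
                   t_p = cc$t_p, mean_or_enhancer = cc$mean_or["enhancer"],
                   mean_or_promoter = cc$mean_or["promoter"])
      }))
      write_tsv(cmp_tab, file.path(outdir, "class_comparison.tsv"))
    }
  }

  stage("sample")
  samples <- list()
  for (nm in names(determinants)) {
    det <- determinants[[nm]][determinants[[nm]]$is_determinant, ,
                              drop = FALSE]
    if (!nrow(det)) next
    samples[[nm]] <- stratified_sample(det, n = config$sample_n,
                                       seed = stage_seed(config$seed,
                                                         paste0("sample.", nm)))
    write_tsv(samples[[nm]][, c("kmer", "length", "gc", "gc_bin", "or_value",
                                "sample_seed")],
              file.path(outdir, sprintf("sample_%s.tsv", nm)))
    if (config$low_gc && any(samples[[nm]]$gc <= 0.5)) {
      lg <- low_gc_subset(det, n = config$sample_n,
                          seed = stage_seed(config$seed,
                                            paste0("lowgc.", nm)))
      samples[[paste0(nm, ".lowgc")]] <- lg
      write_tsv(lg[, c("kmer", "length", "gc", "gc_bin", "or_value",
                       "sample_seed")],
                file.path(outdir, sprintf("sample_lowgc_%s.tsv", nm)))
    }
  }

  stage("train")
  models <- list()
  evaluations <- list()
  for (nm in names(samples)) {
    base_nm <- sub("\\.lowgc$", "", nm)
    feats <- build_feature_matrix(pairs[[base_nm]], samples[[nm]]$kmer)
    fit <- fit_lasso_cv(feats, n_folds = config$n_folds,
                        seed = stage_seed(config$seed, paste0("train.", nm)))
    models[[nm]] <- fit$model
    evaluations[[paste0(nm, ".same")]] <-
      c(list(train = nm, test = base_nm, type = "same"), fit$evaluation)
  }

  stage("predict")
  for (nm in names(models)) {
    base_nm <- sub("\\.lowgc$", "", nm)
    parts <- strsplit(base_nm, ".", fixed = TRUE)[[1]]
    cls <- parts[2]
    for (s2 in setdiff(sp_names, parts[1])) {
      target <- paste(s2, cls, sep = ".")
      ev <- cross_species_predict(models[[nm]], pairs[[target]])
      evaluations[[paste(nm, target, sep = "->")]] <-
        c(list(train = nm, test = target, type = "inter"),
          ev[c("roc_auc", "pr_auc", "n_pos", "n_neg")])
    }
  }
  for (nm in names(pairs)) {
    gc_ev <- gc_only_model(pairs[[nm]], n_folds = config$n_folds,
                           seed = stage_seed(config$seed,
                                             paste0("gconly.", nm)))
    evaluations[[paste0(nm, ".gc_only")]] <-
      list(train = nm, test = nm, type = "gc_only",
           roc_auc = gc_ev$roc_auc, pr_auc = gc_ev$pr_auc)
  }
  if (config$matched_null) {
    for (nm in names(samples)) {
      if (grepl("\\.lowgc$", nm)) next
      mn <- tryCatch(
        matched_null_model(pairs[[nm]], determinants[[nm]], samples[[nm]],
                           n_folds = config$n_folds,
                           seed = stage_seed(config$seed,
                                             paste0("null.", nm))),
        error = function(e) NULL)
      if (!is.null(mn))
        evaluations[[paste0(nm, ".matched_null")]] <-
          c(list(train = nm, test = nm, type = "matched_null"),
            mn$evaluation)
    }
  }
  eval_tab <- do.call(rbind, lapply(names(evaluations), function(nm) {
    e <- evaluations[[nm]]
    data.frame(id = nm, train = e$train, test = e$test, type = e$type,
               roc_auc = e$roc_auc, pr_auc = e$pr_auc,
               stringsAsFactors = FALSE)
  }))
  write_tsv(eval_tab, file.path(outdir, "evaluations.tsv"))

  stage("factor")
  factor_fits <- list()
  for (nm in names(samples)) {
    if (grepl("\\.lowgc$", nm)) next
    det <- samples[[nm]]
    if (nrow(det) < 10 || sd(gc_content(det$kmer)) == 0) next
    ann <- generate_tfbs_annotations(det$kmer,
                                     gc_tfbs_slope = config$tfbs_slope,
                                     noise_sd = config$tfbs_noise_sd,
                                     seed = stage_seed(config$seed,
                                                       paste0("tfbs.", nm)))
    ft <- tryCatch(fit_or_model(det, ann), error = function(e) NULL)
    if (is.null(ft)) next
    factor_fits[[nm]] <- ft
    tab <- ft$coefficients
    tab$variant <- ft$variant
    tab$r_squared <- ft$r_squared
    tab$n <- ft$n
    write_tsv(tab, file.path(outdir, sprintf("factor_model_%s.tsv", nm)))
  }

  stage("manifest")
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("seqdet")),
    seed = config$seed,
    config = config_echo(config),
    outputs = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outdir, files))),
      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, pairs = pairs, determinants = determinants,
                 common = common, class_comparison = class_comparison,
                 samples = samples, models = models,
                 evaluations = evaluations, factor_fits = factor_fits,
                 manifest = manifest))
}

config_echo <- function(config) {
  cfg <- unclass(config)
  spec <- unclass(cfg$spec)
  spec$determinant_pool <- NULL
  cfg$spec <- spec
  cfg
}
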