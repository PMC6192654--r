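#!/usr/bin/env Rscript
# LASSO prediction of regulatory regions from determinant relative
# frequencies: stratified 10,000-determinant samples, 10-fold CV penalty
# selection, same- and cross-species ROC/PR-AUC, and the GC-only, low-GC and
# matched-null baselines.
#
# Reads results/panels/study and results/determinants_*.tsv (run scripts 01
# and 02 first); writes results/prediction_aucs.tsv.

library(seqdet)

panel_dir <- "results/panels/study"
seed <- 20181005
species <- c("sp1", "sp2")
classes <- c("enhancer", "promoter")

pairs <- list()
for (s in species) for (cls in classes) {
  p <- load_regions(file.path(panel_dir, sprintf("%s_%s.bed", s, cls)),
                    file.path(panel_dir, paste0(s, ".fa")),
                    species = s, region_class = cls)
  pairs[[paste(s, cls, sep = ".")]] <- filter_missing(build_backgrounds(p))
}

rows <- list()
add <- function(train, test, model_kind, ev) {
  rows[[length(rows) + 1]] <<- data.frame(
    train = train, test = test, model = model_kind,
    roc_auc = ev$roc_auc, pr_auc = ev$pr_auc)
  message(sprintf("%-22s -> %-14s %-12s ROC-AUC %.3f (PR %.3f)",
                  train, test, model_kind, ev$roc_auc, ev$pr_auc))
}

models <- list()
for (nm in names(pairs)) {
  det <- read.table(sprintf("results/determinants_%s.tsv", nm),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  dd <- det[det$is_determinant, , drop = FALSE]
  samp <- stratified_sample(dd, n = 10000, seed = seed)
  fit <- fit_lasso_cv(build_feature_matrix(pairs[[nm]], samp$kmer),
                      seed = seed)
  models[[nm]] <- fit$model
  add(nm, nm, "determinants", fit$evaluation)
  # baselines on the same training set
  add(nm, nm, "gc_only", gc_only_model(pairs[[nm]], seed = seed))
  mn <- try(suppressWarnings(matched_null_model(pairs[[nm]], det, samp,
                                                seed = seed)), silent = TRUE)
  if (!inherits(mn, "try-error")) add(nm, nm, "matched_null", mn$evaluation)
  if (any(dd$gc <= 0.5)) {
    lg <- low_gc_subset(dd, n = 10000, seed = seed)
    lfit <- fit_lasso_cv(build_feature_matrix(pairs[[nm]], lg$kmer),
                         seed = seed)
    add(nm, nm, "low_gc_determinants", lfit$evaluation)
  }
}

# cross-species transfer: a model trained on one species applied to the other
for (cls in classes) {
  for (a in species) for (b in setdiff(species, a)) {
    ev <- cross_species_predict(models[[paste(a, cls, sep = ".")]],
                                pairs[[paste(b, cls, sep = ".")]])
    add(paste(a, cls, sep = "."), paste(b, cls, sep = "."), "determinants",
        ev)
  }
}

out <- do.call(rbind, rows)
write.table(out, "results/prediction_aucs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/prediction_aucs.tsv")
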