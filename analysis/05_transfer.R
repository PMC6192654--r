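#!/usr/bin/env Rscript
# Cross-species model transfer on the three-species shared-pool panel:
# discover determinants per species, train per-species LASSO models, and
# evaluate every ordered species pair. With a fully shared planted pool the
# inter-species AUC should match the same-species AUC (relative AUC ~ 1).
#
# Reads results/panels/transfer (run script 01 first); writes
# results/transfer_aucs.tsv.

library(seqdet)

panel_dir <- "results/panels/transfer"
seed <- 20181005
species <- c("sp1", "sp2", "sp3")

pairs <- list(); models <- list(); same <- c()
for (s in species) {
  p <- load_regions(file.path(panel_dir, sprintf("%s_promoter.bed", s)),
                    file.path(panel_dir, paste0(s, ".fa")),
                    species = s, region_class = "promoter")
  pairs[[s]] <- filter_missing(build_backgrounds(p))
  det <- call_species_determinants(build_count_table(pairs[[s]], 6, 8))
  dd <- det[det$is_determinant, , drop = FALSE]
  samp <- stratified_sample(dd, n = 10000, seed = seed)
  fit <- fit_lasso_cv(build_feature_matrix(pairs[[s]], samp$kmer),
                      seed = seed)
  models[[s]] <- fit$model
  same[s] <- fit$evaluation$roc_auc
  message(sprintf("%s: %d determinants, same-species CV ROC-AUC %.3f",
                  s, nrow(dd), same[s]))
}

rows <- list()
for (a in species) for (b in setdiff(species, a)) {
  ev <- cross_species_predict(models[[a]], pairs[[b]])
  rows[[paste(a, b)]] <- data.frame(
    train = a, test = b, same_roc_auc = same[a],
    inter_roc_auc = ev$roc_auc, inter_pr_auc = ev$pr_auc,
    relative_auc = ev$roc_auc / same[a])
  message(sprintf("%s -> %s: ROC-AUC %.3f (relative %.3f)", a, b,
                  ev$roc_auc, ev$roc_auc / same[a]))
}
out <- do.call(rbind, rows)
write.table(out, "results/transfer_aucs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/transfer_aucs.tsv")
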