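# Penalised logistic prediction of regulatory regions from determinant
# relative frequencies, with cross-validated penalty selection, ROC/PR
# evaluation, cross-species transfer, and GC-only / matched-null baselines.

#' Build a feature matrix of determinant relative frequencies
#'
#' One row per foreground region (label 1) and per retained background
#' (label 0); one column per determinant k-mer; entries are per-region
#' relative frequencies (occurrences / valid windows of that length).
#'
#' @param pairs A `region_pairs` table with sequences.
#' @param kmers Character vector of determinant k-mers (the column order).
#' @return Object of class `feature_matrix`: list with `x` (numeric matrix),
#'   `y` (0/1 labels), `region_id`.
#' @export
build_feature_matrix <- function(pairs, kmers) {
  df <- as.data.frame(pairs)
  stopifnot(nrow(df) > 0, length(kmers) > 0)
  has_bg <- !is.na(df$bg_seq)
  seqs <- c(df$fg_seq, df$bg_seq[has_bg])
  y <- c(rep(1L, nrow(df)), rep(0L, sum(has_bg)))
  ids <- c(paste0(df$region_id, ":fg"), paste0(df$region_id[has_bg], ":bg"))
  x <- pattern_frequencies(seqs, kmers)$freq
  rownames(x) <- ids
  structure(list(x = x, y = y, region_id = ids), class = "feature_matrix")
}

#' ROC-AUC by the rank (Mann-Whitney) formulation
#'
#' `AUC = (R1 - n1(n1+1)/2) / (n1 n0)` where R1 is the rank sum of positive
#' scores with mean ranks for ties; equals the concordant-pair fraction with
#' ties counted 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC-AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC
#'
#' Ranks rows by decreasing score (tied scores grouped), computes precision
#' at each distinct recall step, and integrates by the trapezoidal rule.
#' Positive class is label 1.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || sum(labels == 0) == 0)
    stop("both classes required for PR-AUC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  recall <- c(0, recall)
  precision <- c(precision[1], precision)
  sum(diff(recall) * (head(precision, -1) + precision[-1]) / 2)
}

# Label-stratified fold assignment, deterministic given seed.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Fit an L1-penalised logistic model with cross-validated penalty
#'
#' Columns are standardised (mean 0, sd 1; constant columns dropped with a
#' flag) and the standardisation parameters frozen into the model for later
#' transfer. Folds are stratified by label. The penalty path is fit once on
#' the full data (>= 50 log-spaced values from the all-zero point downward);
#' the optimal penalty maximises the mean held-out ROC-AUC, and the model is
#' refit on all rows at that penalty. The same-species evaluation is the mean
#' held-out ROC-AUC and PR-AUC at the optimal penalty.
#'
#' @param features A `feature_matrix` (or list with `x`, `y`).
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param nlambda Number of penalty values on the path (default 60).
#' @return List with `model` (class `seqdet_model`: nonzero coefficients,
#'   intercept, penalty, frozen standardisation, selected-column names) and
#'   `evaluation` (mean CV `roc_auc`, `pr_auc`, per-fold values, `n_pos`,
#'   `n_neg`).
#' @export
fit_lasso_cv <- function(features, n_folds = 10, seed = 1, nlambda = 60) {
  x <- features$x; y <- features$y
  if (length(unique(y)) < 2) stop("both classes required to fit a model")
  if (ncol(x) == 0) stop("feature matrix has no columns")
  if (nrow(x) < n_folds) stop("fewer rows than folds")
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  keep <- scales > 0
  if (!any(keep)) stop("all feature columns are constant")
  n_dropped <- sum(!keep)
  xs <- scale(x[, keep, drop = FALSE], centers[keep], scales[keep])
  full <- glmnet::glmnet(xs, y, family = "binomial", standardize = FALSE,
                         nlambda = nlambda)
  path <- full$lambda
  fold <- stratified_folds(y, n_folds, seed)
  auc_fold <- matrix(NA_real_, n_folds, length(path))
  heldout <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- glmnet::glmnet(xs[tr, , drop = FALSE], y[tr], family = "binomial",
                          standardize = FALSE, lambda = path)
    sc <- predict(fit, xs[!tr, , drop = FALSE], s = path)
    heldout[[f]] <- list(scores = sc, y = y[!tr])
    for (j in seq_along(path))
      auc_fold[f, j] <- roc_auc(sc[, j], y[!tr])
  }
  mean_auc <- colMeans(auc_fold)
  j_opt <- which.max(mean_auc)  # first max = largest penalty on ties
  lambda_opt <- path[j_opt]
  fold_roc <- auc_fold[, j_opt]
  fold_pr <- vapply(heldout, function(h) pr_auc(h$scores[, j_opt], h$y),
                    numeric(1))
  beta <- as.numeric(coef(full, s = lambda_opt))
  model <- structure(list(
    intercept = beta[1],
    beta = setNames(beta[-1], colnames(xs)),
    lambda_opt = lambda_opt,
    centers = centers[keep], scales = scales[keep],
    kmers = colnames(xs),
    n_selected = sum(beta[-1] != 0),
    n_dropped_constant = n_dropped,
    n_folds = n_folds, seed = seed), class = "seqdet_model")
  evaluation <- list(roc_auc = mean(fold_roc), pr_auc = mean(fold_pr),
                     fold_roc_auc = fold_roc, fold_pr_auc = fold_pr,
                     n_pos = sum(y == 1), n_neg = sum(y == 0))
  list(model = model, evaluation = evaluation)
}

#' Evaluate a fitted model on a feature matrix
#'
#' Scores are the linear predictor on the model's frozen standardisation;
#' columns missing from the matrix are filled with 0 before standardisation
#' (their count is reported). ROC-AUC uses the rank formulation with tie
#' correction; PR-AUC is trapezoidal.
#'
#' @param model A `seqdet_model`.
#' @param features A `feature_matrix` whose columns cover the model's k-mers.
#' @return List with `roc_auc`, `pr_auc`, `n_pos`, `n_neg`,
#'   `n_missing_columns`.
#' @export
evaluate <- function(model, features) {
  x <- features$x; y <- features$y
  if (length(unique(y)) < 2) stop("both classes required for evaluation")
  m <- match(model$kmers, colnames(x))
  n_missing <- sum(is.na(m))
  xa <- matrix(0, nrow(x), length(model$kmers),
               dimnames = list(rownames(x), model$kmers))
  xa[, !is.na(m)] <- x[, m[!is.na(m)], drop = FALSE]
  xs <- scale(xa, model$centers, model$scales)
  scores <- drop(model$intercept + xs %*% model$beta)
  list(roc_auc = roc_auc(scores, y), pr_auc = pr_auc(scores, y),
       n_pos = sum(y == 1), n_neg = sum(y == 0),
       n_missing_columns = n_missing, scores = scores)
}

#' Apply a model trained on one species to another species
#'
#' Counts the training species' determinant k-mers in the target species'
#' regions, applies the frozen training standardisation, and evaluates; the
#' inter-species prediction of the workflow.
#'
#' @param model A `seqdet_model` trained on species A.
#' @param pairs `region_pairs` of species B.
#' @return Evaluation list as from [evaluate()].
#' @export
cross_species_predict <- function(model, pairs) {
  features <- build_feature_matrix(pairs, model$kmers)
  evaluate(model, features)
}

#' GC-content-only baseline model
#'
#' Unpenalised logistic regression with the region GC fraction as the single
#' covariate, evaluated by stratified k-fold cross-validation; the
#' composition-only reference the determinant models must beat.
#'
#' @param pairs A `region_pairs` table with backgrounds.
#' @param n_folds CV folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List with `roc_auc`, `pr_auc`, per-fold values, and `degenerate`
#'   (TRUE when GC has zero variance, in which case AUC is 0.5).
#' @export
gc_only_model <- function(pairs, n_folds = 10, seed = 1) {
  df <- as.data.frame(pairs)
  has_bg <- !is.na(df$bg_seq)
  gcv <- c(gc_fraction(df$fg_seq), gc_fraction(df$bg_seq[has_bg]))
  y <- c(rep(1L, nrow(df)), rep(0L, sum(has_bg)))
  if (sd(gcv) == 0)
    return(list(roc_auc = 0.5, pr_auc = mean(y), degenerate = TRUE))
  fold <- stratified_folds(y, n_folds, seed)
  d <- data.frame(y = y, gc = gcv)
  roc <- pr <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    fit <- glm(y ~ gc, binomial, data = d[fold != f, ])
    sc <- predict(fit, newdata = d[fold == f, ], type = "link")
    roc[f] <- roc_auc(sc, y[fold == f])
    pr[f] <- pr_auc(sc, y[fold == f])
  }
  list(roc_auc = mean(roc), pr_auc = mean(pr), fold_roc_auc = roc,
       fold_pr_auc = pr, degenerate = FALSE)
}

#' Matched-null (non-determinant) baseline model
#'
#' Samples tested-but-not-significant fragments matching the determinant
#' set's GC-bin x length distribution, then fits and evaluates exactly as
#' [fit_lasso_cv()]; isolates how much of the determinant model's accuracy is
#' explained by composition alone.
#'
#' @param pairs A `region_pairs` table.
#' @param results Full result table from [call_species_determinants()] (the
#'   non-significant rows form the sampling pool).
#' @param determinant_set The determinant sample whose GC x length
#'   distribution is matched (e.g. from [stratified_sample()]).
#' @param n_folds,seed Passed to the fold assignment and the matching draw.
#' @return List with `model`, `evaluation`, `matched_kmers`, and
#'   `n_shortfall` (cells that could not be fully matched; a warning is
#'   raised when nonzero).
#' @export
matched_null_model <- function(pairs, results, determinant_set,
                               n_folds = 10, seed = 1) {
  pool <- results[!results$is_determinant, , drop = FALSE]
  if (!nrow(pool)) stop("no non-significant fragments available for matching")
  pool$gc_bin <- gc_bin(pool$gc)
  want <- table(gc_bin(determinant_set$gc), determinant_set$length)
  picked <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(want)), function(i) {
      unlist(lapply(seq_len(ncol(want)), function(j) {
        nw <- want[i, j]
        if (nw == 0) return(character(0))
        cand <- pool$kmer[pool$gc_bin == as.integer(rownames(want))[i] &
                            pool$length == as.integer(colnames(want))[j]]
        if (length(cand) <= nw) cand else sample(cand, nw)
      }), use.names = FALSE)
    }), use.names = FALSE)
  })
  shortfall <- nrow(determinant_set) - length(picked)
  if (shortfall > 0)
    warning("matched-null pool short by ", shortfall,
            " fragment(s); partial match used")
  if (!length(picked)) stop("matched-null pool is empty after matching")
  features <- build_feature_matrix(pairs, picked)
  fit <- fit_lasso_cv(features, n_folds = n_folds, seed = seed)
  c(fit, list(matched_kmers = picked, n_shortfall = shortfall))
}
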