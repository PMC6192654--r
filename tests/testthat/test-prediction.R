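# Feature matrices, AUC computations, LASSO CV, transfer, baselines.

test_that("ROC-AUC equals brute-force pair counting, with tie handling", {
  set.seed(51)
  for (r in 1:50) {
    n <- sample(10:60, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))  # rounded scores force ties
    expect_equal(roc_auc(s, y), pair_count_auc(s, y), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(2, 1), c(1, 0)), 1)
  # invariance under strictly increasing transforms
  set.seed(52)
  s <- rnorm(100)
  y <- rbinom(100, 1, 0.4)
  expect_equal(roc_auc(s, y), roc_auc(exp(s), y))
  expect_equal(roc_auc(s, y), roc_auc(rank(s), y))
})

test_that("ROC-AUC agrees with pROC on random score vectors", {
  set.seed(53)
  y <- rbinom(300, 1, 0.5)
  s <- rnorm(300) + y
  oracle <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(s, y), as.numeric(oracle), tolerance = 1e-12)
})

test_that("PR-AUC handles perfect and degenerate orderings", {
  expect_equal(pr_auc(c(2, 1), c(1, 0)), 1)
  expect_equal(pr_auc(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  # ranking worst-first: precision rises to the prevalence
  low <- pr_auc(c(1, 2), c(1, 0))
  expect_lt(low, 0.6)
  expect_error(pr_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("feature matrices hold per-region relative frequencies", {
  set.seed(54)
  chrom <- paste0("AAAA", random_dna(40, gc = 0.8), collapse = "")
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(chr1 = chrom)), fa)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t4\tr1", bed)
  pairs <- build_backgrounds(load_regions(bed, fa, "s", "enhancer"),
                             offset = 4)
  fm <- build_feature_matrix(pairs, c("AA", "GGGGGG"))
  expect_identical(dim(fm$x), c(2L, 2L))
  expect_identical(fm$y, c(1L, 0L))
  expect_equal(fm$x["r1:fg", "AA"], 1)          # 3 of 3 windows
  expect_equal(fm$x["r1:fg", "GGGGGG"], 0)
  # spot-check against an independent scan on a synthetic panel
  panel <- small_panel(seed = 3)
  pp <- panel_pairs(panel, "sp1", "promoter")[1:20, ]
  kms <- c("ACGTAC", "GGCGC")
  fm2 <- build_feature_matrix(pp, kms)
  i <- 7
  for (w in kms) {
    naive <- naive_count_kmers(pp$fg_seq[i], nchar(w))
    cnt <- unname(naive$counts[w])
    if (is.na(cnt)) cnt <- 0
    expect_equal(fm2$x[i, w], cnt / naive$total)
  }
})

test_that("a perfectly separating column yields CV AUC 1 and survives refit", {
  set.seed(55)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  x <- cbind(sep = y, noise = matrix(runif(n * 5), n))
  colnames(x) <- c("sep", paste0("n", 1:5))
  fit <- fit_lasso_cv(list(x = x, y = y), n_folds = 5, seed = 1)
  expect_equal(fit$evaluation$roc_auc, 1)
  expect_equal(fit$evaluation$pr_auc, 1)
  expect_true(fit$model$beta["sep"] > 0)
  # training-matrix evaluation is deterministic and perfect
  ev <- evaluate(fit$model, list(x = x, y = y))
  expect_equal(ev$roc_auc, 1)
})

test_that("label permutation on null features gives chance-level CV AUC", {
  set.seed(56)
  aucs <- vapply(1:3, function(r) {
    n <- 600
    x <- matrix(runif(n * 30), n, dimnames = list(NULL, paste0("c", 1:30)))
    y <- sample(rep(c(0, 1), each = n / 2))
    fit_lasso_cv(list(x = x, y = y), seed = r)$evaluation$roc_auc
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) <= 0.07))
})

test_that("single-class input and empty matrices are rejected", {
  x <- matrix(runif(40), 20)
  colnames(x) <- c("a", "b")
  expect_error(fit_lasso_cv(list(x = x, y = rep(1, 20))), "both classes")
  expect_error(fit_lasso_cv(list(x = x[, 0], y = rep(c(0, 1), 10))),
               "no columns")
  expect_error(evaluate(structure(list(), class = "seqdet_model"),
                        list(x = x, y = rep(1, 20))), "both classes")
})

test_that("identity transfer reproduces same-matrix evaluation", {
  panel <- study_panel(seed = 1)
  pp <- panel_pairs(panel, "sp1", "promoter")
  det <- cached("det_sp1_pro", panel_determinants(panel, "sp1", "promoter"))
  dd <- det[det$is_determinant, ][1:50, ]
  fm <- build_feature_matrix(pp, dd$kmer)
  fit <- fit_lasso_cv(fm, seed = 2)
  direct <- evaluate(fit$model, fm)
  via_transfer <- cross_species_predict(fit$model, pp)
  expect_equal(via_transfer$roc_auc, direct$roc_auc, tolerance = 1e-12)
  expect_equal(via_transfer$pr_auc, direct$pr_auc, tolerance = 1e-12)
  expect_identical(via_transfer$n_missing_columns, 0L)
})

test_that("missing model columns are zero-filled and flagged", {
  set.seed(57)
  n <- 80
  x <- matrix(runif(n * 3), n, dimnames = list(NULL, c("AAA", "CCC", "GGG")))
  y <- rep(c(0, 1), n / 2)
  x[, "AAA"] <- x[, "AAA"] + 0.3 * y
  fit <- fit_lasso_cv(list(x = x, y = y), n_folds = 5, seed = 1)
  ev <- evaluate(fit$model, list(x = x[, c("AAA", "CCC")], y = y))
  expect_identical(ev$n_missing_columns, 1L)
})

test_that("GC-only baseline detects a composition shift and not its absence", {
  panel <- study_panel(seed = 1)
  pro <- gc_only_model(panel_pairs(panel, "sp1", "promoter"), seed = 1)
  enh <- gc_only_model(panel_pairs(panel, "sp1", "enhancer"), seed = 1)
  expect_gt(pro$roc_auc, 0.7)
  expect_lt(abs(enh$roc_auc - 0.5), 0.07)
})

test_that("matched-null sampling respects the GC x length distribution", {
  panel <- study_panel(seed = 1)
  pp <- panel_pairs(panel, "sp1", "promoter")
  det <- cached("det_sp1_pro", panel_determinants(panel, "sp1", "promoter"))
  dd <- det[det$is_determinant, ]
  samp <- stratified_sample(dd, n = 200, seed = 3)
  mn <- suppressWarnings(matched_null_model(pp, det, samp, seed = 3))
  expect_true(all(mn$matched_kmers %in% det$kmer[!det$is_determinant]))
  # matched fragments reproduce the sampled GC-bin x length cells
  pool_cells <- paste(gc_bin(gc_content(mn$matched_kmers)),
                      nchar(mn$matched_kmers))
  want_cells <- paste(gc_bin(samp$gc), samp$length)
  extra <- setdiff(unique(pool_cells), unique(want_cells))
  expect_identical(extra, character(0))
  expect_identical(mn$matched_kmers, suppressWarnings(
    matched_null_model(pp, det, samp, seed = 3))$matched_kmers)
})
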