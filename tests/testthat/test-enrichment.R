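# 2x2 enrichment statistics, FDR, CMH, and determinant calling.

test_that("odds ratios follow the cross-product formula with zero-cell handling", {
  expect_equal(odds_ratio(20, 80, 10, 90), 2.25)
  expect_equal(odds_ratio(5, 5, 5, 5), 1)
  expect_equal(odds_ratio(0, 10, 5, 5), (0.5 * 5.5) / (10.5 * 5.5))
  # swapping the table's columns inverts the OR
  set.seed(31)
  t4 <- random_tables(200, cell_max = 80, min_cell = 1)
  expect_equal(odds_ratio(t4[[1]], t4[[2]], t4[[3]], t4[[4]]),
               1 / odds_ratio(t4[[2]], t4[[1]], t4[[4]], t4[[3]]))
})

test_that("chi-square matches stats::chisq.test without continuity correction", {
  exact <- chi2_test(30, 70, 10, 90)
  oracle <- chisq.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                       correct = FALSE)
  expect_equal(exact$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(exact$p, oracle$p.value, tolerance = 1e-12)
  # observed == expected
  flat <- chi2_test(10, 10, 10, 10)
  expect_identical(c(flat$statistic, flat$p), c(0, 1))
  # doubling all cells doubles the statistic
  expect_equal(chi2_test(60, 140, 20, 180)$statistic, 2 * exact$statistic)
  # degenerate margins flagged
  z <- chi2_test(0, 0, 5, 5)
  expect_true(z$degenerate)
  expect_identical(c(z$statistic, z$p), c(0, 1))
  set.seed(32)
  t4 <- random_tables(300, cell_max = 150, min_cell = 1)
  got <- chi2_test(t4[[1]], t4[[2]], t4[[3]], t4[[4]])
  for (i in sample(300, 50)) {
    o <- suppressWarnings(chisq.test(
      matrix(c(t4[[1]][i], t4[[2]][i], t4[[3]][i], t4[[4]][i]), 2,
             byrow = TRUE), correct = FALSE))
    expect_equal(got$statistic[i], unname(o$statistic), tolerance = 1e-9)
  }
})

test_that("Fisher p-values match stats::fisher.test by enumeration", {
  expect_equal(fisher_test(1, 9, 1, 9), 1)
  expect_equal(fisher_test(3, 1, 1, 3),
               fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_test(0, 5, 5, 0),
               fisher.test(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  set.seed(33)
  t4 <- random_tables(200, cell_max = 25)
  got <- fisher_test(t4[[1]], t4[[2]], t4[[3]], t4[[4]])
  for (i in seq_len(200)) {
    m <- matrix(c(t4[[1]][i], t4[[2]][i], t4[[3]][i], t4[[4]][i]), 2,
                byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(got[i], fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_identical(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_identical(bh_fdr(0.037), 0.037)
  set.seed(34)
  for (r in 1:20) {
    p <- runif(50)^2
    q <- bh_fdr(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("species determinant calling routes tests and applies the filter", {
  panel <- small_panel(seed = 3)
  tab <- build_count_table(panel_pairs(panel, "sp1", "promoter"), 6, 6)
  res <- call_species_determinants(tab, min_count = 20)
  expect_true(all(res$total_count > 20))
  # routing: all expecteds >= 5 never use Fisher
  n1p <- tab$per_k[["6"]]$N1plus
  n2p <- tab$per_k[["6"]]$N2plus
  min_e <- pmin(n1p, n2p) *
    pmin(res$total_count, n1p + n2p - res$total_count) / (n1p + n2p)
  expect_true(all(res$test[min_e >= 5] == "chi2"))
  expect_true(all(res$test[min_e < 5] == "fisher"))
  # determinant definition
  expect_identical(res$is_determinant,
                   res$q <= 0.05 & res$or_value > 1)
  # impossible filter yields empty result with warning
  expect_warning(empty <- call_species_determinants(tab, min_count = Inf),
                 "no fragment passed")
  expect_identical(nrow(empty), 0L)
})

test_that("CMH equals the (N-1)/N-scaled Pearson statistic on one stratum", {
  set.seed(35)
  t4 <- random_tables(1000, cell_max = 100, min_cell = 1)
  cmh <- seqdet:::cmh_stat_vec(matrix(t4[[1]], nrow = 1),
                               matrix(t4[[2]], nrow = 1),
                               matrix(t4[[3]], nrow = 1),
                               matrix(t4[[4]], nrow = 1))
  pear <- chi2_test(t4[[1]], t4[[2]], t4[[3]], t4[[4]])
  n <- t4[[1]] + t4[[2]] + t4[[3]] + t4[[4]]
  expect_equal(cmh$statistic, pear$statistic * (n - 1) / n,
               tolerance = 1e-9)
})

test_that("CMH accumulates strata and matches mantelhaen.test", {
  flat <- cmh_test(list(matrix(c(10, 10, 10, 10), 2, byrow = TRUE),
                        matrix(c(5, 5, 5, 5), 2, byrow = TRUE)))
  expect_identical(c(flat$statistic, flat$p), c(0, 1))
  # duplicated stratum doubles the statistic
  one <- cmh_test(list(matrix(c(30, 70, 10, 90), 2, byrow = TRUE)))
  two <- cmh_test(rep(list(matrix(c(30, 70, 10, 90), 2, byrow = TRUE)), 2))
  expect_equal(two$statistic, 2 * one$statistic, tolerance = 1e-12)
  set.seed(36)
  for (r in 1:50) {
    arr <- array(sample(1:60, 4 * 3, replace = TRUE), dim = c(2, 2, 3))
    tabs <- lapply(1:3, function(i) arr[, , i])
    got <- cmh_test(tabs)
    oracle <- mantelhaen.test(arr, correct = FALSE)
    expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-9)
  }
  # strata with total <= 1 are skipped
  sk <- cmh_test(list(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                      matrix(c(0, 0, 0, 1), 2, byrow = TRUE)))
  expect_identical(sk$n_skipped, 1)
  expect_equal(sk$statistic, one$statistic)
})

test_that("common determinants require eligibility and OR > 1 everywhere", {
  mk_table <- function(n11, n21, n1p = 5000, n2p = 5000) {
    structure(list(species = "s", region_class = "promoter",
                   k_min = 6, k_max = 6,
                   per_k = list(`6` = list(
                     counts = data.frame(kmer = c("AAAAAA", "CCCCCC"),
                                         N11 = n11, N21 = n21,
                                         stringsAsFactors = FALSE),
                     N1plus = n1p, N2plus = n2p))),
              class = "kmer_count_table")
  }
  # strong in both species
  res <- call_common_determinants(list(a = mk_table(c(300, 200), c(150, 190)),
                                       b = mk_table(c(310, 150), c(140, 160))),
                                  min_count = 100)
  aa <- res[res$kmer == "AAAAAA", ]
  expect_true(aa$is_common)
  expect_equal(aa$min_or, min(aa$or_a, aa$or_b))
  # OR < 1 in one species vetoes regardless of q
  res2 <- call_common_determinants(list(a = mk_table(c(400, 200), c(100, 190)),
                                        b = mk_table(c(100, 150), c(400, 160))),
                                   min_count = 100)
  expect_false(res2[res2$kmer == "AAAAAA", "is_common"])
  # eligibility: below min_count in one species excludes the fragment
  res3 <- call_common_determinants(list(a = mk_table(c(300, 200), c(150, 190)),
                                        b = mk_table(c(30, 150), c(20, 160))),
                                   min_count = 100)
  expect_false("AAAAAA" %in% res3$kmer)
  # single species: common set equals the species OR>1 calls
  res4 <- call_common_determinants(list(a = mk_table(c(300, 200), c(150, 190))),
                                   min_count = 100)
  sp <- call_species_determinants(mk_table(c(300, 200), c(150, 190)),
                                  min_count = 100)
  expect_setequal(res4$kmer[res4$is_common], sp$kmer[sp$is_determinant])
})

test_that("class comparison contrasts OR distributions and lengths", {
  enh <- data.frame(or_value = rep(1.2, 100), length = rep(9, 100))
  pro <- data.frame(or_value = rep(3.0, 100), length = rep(9, 100))
  cc <- compare_classes(enh, pro)
  expect_lt(cc$wilcoxon_p, 0.01)
  expect_identical(unname(cc$t_stat), 0)
  same <- compare_classes(pro, pro)
  expect_equal(same$wilcoxon_p, 1)
  expect_error(compare_classes(enh[0, ], pro), "nrow")
})
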