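# TOMTOM parsing and the log2(OR) ~ GC + TFBS (+ interaction) model.

write_tomtom_fixture <- function() {
  path <- tempfile(fileext = ".tsv")
  header <- paste("Query_ID", "Target_ID", "Optimal_offset", "p-value",
                  "E-value", "q-value", "Overlap", "Query_consensus",
                  "Target_consensus", "Orientation", sep = "\t")
  rows <- c(
    sprintf("CAGCCC\tM%03d\t0\t%g\t1\t0.5\t6\tCAGCCC\tNNN\t+", 1:18,
            seq(1e-4, 0.049, length.out = 18)),
    sprintf("CAGCCC\tM%03d\t0\t%g\t1\t0.9\t6\tCAGCCC\tNNN\t+", 19:25,
            seq(0.2, 0.9, length.out = 7)),
    "AAATTT\tM900\t0\t0.004\t1\t0.1\t6\tAAATTT\tNNN\t+",
    "malformed\trow",
    "# comment line")
  writeLines(c(header, rows), path)
  path
}

test_that("TOMTOM parsing yields hit counts, frequencies and min-P", {
  ann <- parse_tomtom(write_tomtom_fixture(), n_motifs_db = 641,
                      queries = c("CAGCCC", "AAATTT", "GGGGGG"))
  cag <- ann[ann$kmer == "CAGCCC", ]
  expect_identical(cag$n_hits, 18L)
  expect_equal(cag$tfbs_frequency, 18 / 641, tolerance = 1e-12)
  expect_equal(round(100 * cag$tfbs_frequency, 1), 2.8)  # 18 of 641 hits
  expect_equal(cag$minus_log10_minP, -log10(1e-4), tolerance = 1e-9)
  aaa <- ann[ann$kmer == "AAATTT", ]
  expect_identical(aaa$n_hits, 1L)
  # absent query gets zeros
  ggg <- ann[ann$kmer == "GGGGGG", ]
  expect_identical(c(ggg$n_hits, ggg$tfbs_frequency, ggg$minus_log10_minP),
                   c(0, 0, 0))
  expect_identical(attr(ann, "n_skipped"), 1L)
  expect_error(parse_tomtom(write_tomtom_fixture(), n_motifs_db = 0),
               "positive")
})

test_that("noiseless main-effects data are recovered exactly", {
  set.seed(61)
  d <- data.frame(gc = runif(60, 0.1, 0.9), tfbs = runif(60, 0, 0.2))
  d$log2_or <- 0.5 * d$gc + 0.4 * d$tfbs
  fit <- suppressWarnings(fit_or_model(d))  # perfect fit warns in summary.lm
  expect_identical(fit$variant, "main-effects")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["gc"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(est["tfbs"]), 0.4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("the interaction is kept iff significant at p < 0.05", {
  set.seed(62)
  d <- data.frame(gc = runif(400, 0.1, 0.9), tfbs = runif(400, 0, 0.3))
  d$log2_or <- 1 + 2 * d$gc + 3 * d$tfbs - 8 * d$gc * d$tfbs + rnorm(400, 0, 0.3)
  with_int <- fit_or_model(d)
  expect_identical(with_int$variant, "interaction")
  expect_lt(with_int$interaction_p_full, 0.05)
  expect_true("gc:tfbs" %in% with_int$coefficients$term)
  d2 <- d
  d2$log2_or <- 1 + 2 * d2$gc + 3 * d2$tfbs + rnorm(400, 0, 0.5)
  no_int <- fit_or_model(d2)
  expect_identical(no_int$variant,
                   if (no_int$interaction_p_full < 0.05) "interaction"
                   else "main-effects")
  expect_gte(no_int$interaction_p_full, 0.05)
})

test_that("Type III SSR matches car::Anova and R-squared its definition", {
  set.seed(63)
  d <- data.frame(gc = runif(200, 0.1, 0.9), tfbs = runif(200, 0, 0.3))
  d$log2_or <- 1 + 2 * d$gc + 3 * d$tfbs - 8 * d$gc * d$tfbs +
    rnorm(200, 0, 0.3)
  fit <- fit_or_model(d)
  oracle <- car::Anova(fit$fit, type = 3)
  want <- oracle[c("gc", "tfbs", "gc:tfbs"), "Sum Sq"]
  got <- fit$coefficients$ssr[match(c("gc", "tfbs", "gc:tfbs"),
                                    fit$coefficients$term)]
  expect_equal(got, want, tolerance = 1e-9)
  sst <- sum((d$log2_or - mean(d$log2_or))^2)
  sse <- sum(residuals(fit$fit)^2)
  expect_equal(fit$r_squared, 1 - sse / sst, tolerance = 1e-12)
  # residual orthogonality to the design
  X <- model.matrix(fit$fit)
  expect_true(max(abs(crossprod(X, residuals(fit$fit)))) < 1e-8)
})

test_that("degenerate designs are rejected with the offending column named", {
  d <- data.frame(gc = rep(0.5, 30), tfbs = runif(30), log2_or = rnorm(30))
  expect_error(fit_or_model(d), "gc")
  d2 <- data.frame(gc = runif(30), tfbs = rep(0.1, 30), log2_or = rnorm(30))
  expect_error(fit_or_model(d2), "tfbs")
  expect_error(fit_or_model(data.frame(gc = runif(5), tfbs = runif(5),
                                       log2_or = rnorm(5))), "at least 10")
})

test_that("GC-TFBS relationship recovers engineered correlations", {
  kmers <- default_determinant_pool(15, 15)$kmer
  ann <- generate_tfbs_annotations(kmers, gc_tfbs_slope = -0.5, noise_sd = 0,
                                   intercept = 0.6)
  rel <- gc_tfbs_relationship(data.frame(kmer = kmers), ann)
  expect_equal(rel$pearson_r, -1, tolerance = 1e-9)
  flat <- generate_tfbs_annotations(kmers, gc_tfbs_slope = 0, noise_sd = 0)
  rel2 <- gc_tfbs_relationship(data.frame(kmer = kmers), flat)
  expect_true(rel2$degenerate)
  ctrl <- gc_tfbs_relationship(data.frame(kmer = kmers[1:10]), ann,
                               controls = data.frame(kmer = kmers[11:15]))
  expect_identical(sum(!ctrl$points$is_determinant), 5L)
})

test_that("simulated factor data hit the requested R-squared", {
  r2 <- vapply(1:10, function(sd) {
    sim <- simulate_factor_data(2000, beta = c(6.4, 22.65, -41.84),
                                r_squared = 0.36, seed = sd)
    summary(lm(log2_or ~ gc + tfbs + gc:tfbs, data = sim))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.36), 0.03)
})

test_that("partial residuals isolate the TFBS effect after GC removal", {
  set.seed(64)
  kmers <- default_determinant_pool(20, 20)$kmer
  ann <- generate_tfbs_annotations(kmers, seed = 3)
  det <- data.frame(kmer = kmers, or_value = 2^rnorm(length(kmers), 1, 0.3))
  pr <- gc_partial_residuals(det, ann)
  expect_setequal(unique(pr$gc_group), c("low_gc", "high_gc"))
  # residuals of a GC-only regression are orthogonal to GC
  expect_lt(abs(cor(pr$partial_residual, pr$gc)), 1e-9)
})
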