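# Synthetic TFBS annotations and factor-model simulation.

#' Generate synthetic TFBS annotations for a set of k-mers
#'
#' Emulates motif-comparison summaries: each k-mer receives a TFBS frequency
#' (the proportion of database motifs it would significantly match) drawn as a
#' clipped linear function of its GC content with (typically negative) slope
#' plus Gaussian noise, reproducing the negative GC-TFBS relationship seen in
#' real motif databases. A `minus_log10_minP` column is emitted as a strictly
#' increasing transform of the frequency, so the two measures share their rank
#' order.
#'
#' @param kmers Character vector of determinant k-mers (ACGT only, non-empty).
#' @param gc_tfbs_slope Slope of TFBS frequency on GC content (default -0.3).
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param intercept Baseline TFBS frequency at GC = 0 (default 0.3).
#' @param seed Integer seed.
#' @return Data frame with `kmer`, `gc`, `tfbs_frequency`, `minus_log10_minP`.
#' @export
generate_tfbs_annotations <- function(kmers, gc_tfbs_slope = -0.3,
                                      noise_sd = 0.05, intercept = 0.3,
                                      seed = 1) {
  if (!length(kmers)) stop("kmers must be non-empty")
  if (any(grepl("[^ACGT]", kmers))) stop("kmers must contain only A, C, G, T")
  gc <- gc_content(kmers)
  with_seed(seed, {
    freq <- intercept + gc_tfbs_slope * gc + rnorm(length(gc), 0, noise_sd)
    freq <- pmin(pmax(freq, 0), 1)
    data.frame(kmer = kmers, gc = gc, tfbs_frequency = freq,
               minus_log10_minP = 1 + 6 * freq,
               stringsAsFactors = FALSE)
  })
}

#' Simulate determinant effect sizes from a known factor model
#'
#' Draws (GC content, TFBS frequency) covariates and generates
#' `log2(OR) = b0 + b1*GC + b2*TFBS + b3*GC:TFBS + e` with the residual
#' standard deviation set so the population R-squared of the fit equals
#' `r_squared`. Used to test parameter recovery of [fit_or_model()] at
#' published coefficient values.
#'
#' @param n Number of determinants.
#' @param beta Coefficients `c(b1_gc, b2_tfbs, b3_interaction)`; set the third
#'   to 0 for a main-effects truth.
#' @param intercept Model intercept (default 0).
#' @param r_squared Target coefficient of determination in (0, 1).
#' @param gc_range Range of the uniform GC-content draw.
#' @param tfbs_slope,tfbs_noise_sd Passed to the TFBS covariate: TFBS
#'   frequency is linear in GC with this slope plus noise, clipped to \[0, 1\].
#' @param seed Integer seed.
#' @return Data frame with `gc`, `tfbs`, `log2_or`, `or`.
#' @export
simulate_factor_data <- function(n, beta, intercept = 0, r_squared = 0.36,
                                 gc_range = c(0.2, 0.9), tfbs_slope = -0.25,
                                 tfbs_noise_sd = 0.04, seed = 1) {
  stopifnot(length(beta) == 3, n >= 10, r_squared > 0, r_squared < 1)
  with_seed(seed, {
    gc <- runif(n, gc_range[1], gc_range[2])
    tfbs <- pmin(pmax(0.3 + tfbs_slope * gc +
                        rnorm(n, 0, tfbs_noise_sd), 0), 1)
    mu <- intercept + beta[1] * gc + beta[2] * tfbs + beta[3] * gc * tfbs
    sd_res <- sqrt(var(mu) * (1 - r_squared) / r_squared)
    log2_or <- mu + rnorm(n, 0, sd_res)
    data.frame(gc = gc, tfbs = tfbs, log2_or = log2_or, or = 2^log2_or)
  })
}
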