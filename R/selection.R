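# Stratified sampling of determinants by GC-content bin x length.

#' GC content of k-mers
#'
#' `(#G + #C) / length`, vectorised. Errors on characters outside A/C/G/T
#' (determinants never contain N).
#'
#' @param kmer Character vector of k-mers.
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(kmer) {
  if (any(grepl("[^ACGT]", kmer)))
    stop("k-mers must contain only A, C, G, T")
  (nchar(kmer) - nchar(gsub("[GC]", "", kmer))) / nchar(kmer)
}

#' GC bin index
#'
#' Ten uniform intervals: bin 1 is \[0, 0.1\] (closed at both ends), later
#' bins are half-open `(0.1, 0.2], ..., (0.9, 1.0]`.
#'
#' @param gc Numeric vector of GC fractions in \[0, 1\].
#' @return Integer bin index 1-10.
#' @export
gc_bin <- function(gc) {
  stopifnot(all(gc >= 0 & gc <= 1))
  pmax(1L, as.integer(ceiling(gc * 10 - 1e-12)))
}

# Largest-remainder (Hamilton) apportionment of n among strata of sizes
# sizes; quotas never exceed stratum sizes (shortfall redistributed by
# remainder order).
largest_remainder_quota <- function(sizes, n) {
  share <- n * sizes / sum(sizes)
  quota <- floor(share)
  rem <- share - quota
  short <- n - sum(quota)
  if (short > 0) {
    # largest remainder first; ties go to the smaller stratum
    ord <- order(-rem, sizes, seq_along(sizes))
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  }
  # rounding can push a quota past its stratum; move the excess down the
  # remainder order
  over <- quota > sizes
  while (any(over)) {
    excess <- sum(quota[over] - sizes[over])
    quota[over] <- sizes[over]
    room <- which(quota < sizes)
    ord <- room[order(-rem[room], sizes[room], room)]
    i <- 1
    while (excess > 0 && i <= length(ord)) {
      add <- min(excess, sizes[ord[i]] - quota[ord[i]])
      quota[ord[i]] <- quota[ord[i]] + add
      excess <- excess - add
      i <- i + 1
    }
    over <- quota > sizes
  }
  as.integer(quota)
}

#' Stratified sample of determinants
#'
#' Stratifies determinants by GC bin x fragment length and samples uniformly
#' without replacement within strata, with per-stratum quotas proportional to
#' stratum size (largest-remainder rounding). When the pool holds at most `n`
#' determinants, all are returned. Deterministic given `seed`.
#'
#' @param determinants Determinant data frame (needs `kmer`, `length`, `gc`
#'   columns, e.g. from [call_species_determinants()]).
#' @param n Target sample size (default 10,000).
#' @param seed Integer seed.
#' @return The sampled rows, with `gc_bin` and `sample_seed` columns added.
#' @export
stratified_sample <- function(determinants, n = 10000, seed = 1) {
  stopifnot(nrow(determinants) > 0,
            all(c("kmer", "length", "gc") %in% names(determinants)))
  determinants$gc_bin <- gc_bin(determinants$gc)
  if (nrow(determinants) <= n) {
    out <- determinants
  } else {
    key <- interaction(determinants$gc_bin, determinants$length, drop = TRUE)
    strata <- split(seq_len(nrow(determinants)), key)
    sizes <- lengths(strata)
    quota <- largest_remainder_quota(sizes, n)
    idx <- with_seed(seed, {
      unlist(lapply(seq_along(strata), function(i) {
        if (quota[i] == 0) return(integer(0))
        if (quota[i] >= sizes[i]) return(strata[[i]])
        strata[[i]][sample.int(sizes[i], quota[i])]
      }), use.names = FALSE)
    })
    out <- determinants[sort(idx), , drop = FALSE]
  }
  out$sample_seed <- seed
  rownames(out) <- NULL
  out
}

#' Low-GC subset of determinants
#'
#' Restricts to determinants with GC content `<= gc_max` (inclusive) before
#' stratified sampling; the "low-GC determinants" model input.
#'
#' @inheritParams stratified_sample
#' @param gc_max Inclusive GC threshold (default 0.5).
#' @return The sampled low-GC rows.
#' @export
low_gc_subset <- function(determinants, gc_max = 0.5, n = 10000, seed = 1) {
  keep <- determinants$gc <= gc_max
  if (!any(keep))
    stop("no determinants with GC <= ", gc_max)
  stratified_sample(determinants[keep, , drop = FALSE], n = n, seed = seed)
}
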