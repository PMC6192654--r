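# Sliding-window k-mer counting.

#' Count all k-mers in a set of sequences
#'
#' Slides a k-bp window 1 bp at a time from the 5' to the 3' end of each
#' sequence; overlapping occurrences are all counted. Windows containing any
#' non-ACGT character (missing data) are skipped and excluded from the total,
#' so frequencies stay composition-honest.
#'
#' @param sequences Character vector of (uppercase) DNA sequences.
#' @param k Window length (integer, 1-31).
#' @return List with `counts` (named numeric vector, k-mers sorted
#'   lexicographically) and `total` (number of valid windows).
#' @export
count_kmers <- function(sequences, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k))
    stop("k must be a positive integer")
  kmer_spectrum_cpp(as.character(toupper(sequences)), as.integer(k))
}

#' Build the foreground/background k-mer count table
#'
#' Aggregates k-mer counts over all foreground sequences (N11, with total
#' valid windows N1plus) and all background sequences (N21, N2plus) for every
#' k in `k_min:k_max`. Pairs whose background was discarded are excluded from
#' both sides, keeping the 2x2 margins comparable.
#'
#' @param pairs A `region_pairs` table with backgrounds built.
#' @param k_min,k_max Fragment length range (defaults 6 and 15).
#' @return Object of class `kmer_count_table`: list with `species`,
#'   `region_class`, and per-k entries `counts` (data frame kmer/N11/N21),
#'   `N1plus`, `N2plus`.
#' @export
build_count_table <- function(pairs, k_min = 6, k_max = 15) {
  df <- as.data.frame(pairs)
  if (!nrow(df)) stop("empty pair list")
  keep <- !is.na(df$bg_seq)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no pairs with retained backgrounds")
  stopifnot(k_min >= 1, k_max >= k_min)
  per_k <- lapply(k_min:k_max, function(k) {
    fg <- count_kmers(df$fg_seq, k)
    bg <- count_kmers(df$bg_seq, k)
    kmers <- sort(unique(c(names(fg$counts), names(bg$counts))))
    n11 <- fg$counts[kmers]
    n21 <- bg$counts[kmers]
    n11[is.na(n11)] <- 0
    n21[is.na(n21)] <- 0
    stopifnot(sum(n11) == fg$total, sum(n21) == bg$total)  # conservation
    list(counts = data.frame(kmer = kmers, N11 = as.numeric(n11),
                             N21 = as.numeric(n21), stringsAsFactors = FALSE,
                             row.names = NULL),
         N1plus = fg$total, N2plus = bg$total)
  })
  names(per_k) <- as.character(k_min:k_max)
  structure(list(species = df$species[1], region_class = df$region_class[1],
                 k_min = k_min, k_max = k_max, per_k = per_k),
            class = "kmer_count_table")
}

#' Relative frequency of a k-mer in one sequence
#'
#' Occurrences divided by the number of valid (N-free) windows of that length.
#' A sequence with no valid windows yields 0 with attribute `degenerate`.
#'
#' @param sequence A single DNA string.
#' @param kmer The fragment to count (ACGT only).
#' @return A fraction in \[0, 1\].
#' @export
relative_frequency <- function(sequence, kmer) {
  stopifnot(length(sequence) == 1, length(kmer) == 1)
  res <- pattern_counts_cpp(toupper(sequence), toupper(kmer))
  valid <- res$valid_windows[1, 1]
  if (valid == 0) return(structure(0, degenerate = TRUE))
  res$counts[1, 1] / valid
}

# Occurrence counts and relative frequencies of a pattern set across many
# sequences. Returns counts and freq matrices (sequences x patterns).
pattern_frequencies <- function(sequences, patterns) {
  res <- pattern_counts_cpp(toupper(sequences), toupper(patterns))
  valid <- res$valid_windows[, match(nchar(patterns), res$k), drop = FALSE]
  freq <- res$counts / valid
  freq[!is.finite(freq)] <- 0
  colnames(freq) <- patterns
  colnames(res$counts) <- patterns
  list(counts = res$counts, freq = freq)
}
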