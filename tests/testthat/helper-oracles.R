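# Independent brute-force oracles used to check the package's statistics.

# Naive sliding-window k-mer counter: plain substring extraction of every
# window, windows containing any non-ACGT character dropped, then tabulation.
naive_count_kmers <- function(seqs, k) {
  all_wins <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    wins <- substring(s, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)
    all_wins <- c(all_wins, wins[!grepl("[^ACGT]", wins)])
  }
  tab <- table(all_wins)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  list(counts = counts[sort(names(counts))], total = length(all_wins))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct Benjamini-Hochberg step-up computation.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# ROC-AUC by exhaustive pair counting (ties count 1/2).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Random DNA string, optionally with N runs stippled in.
random_dna <- function(n, gc = 0.41, n_runs = 0, run_len = 20) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
  if (n_runs > 0) {
    for (i in seq_len(n_runs)) {
      at <- sample.int(n - run_len, 1)
      x[at:(at + run_len - 1)] <- "N"
    }
  }
  paste(x, collapse = "")
}

# Random 2x2 tables (vectors n11, n12, n21, n22) with cells <= cell_max.
random_tables <- function(n, cell_max = 200, min_cell = 0) {
  replicate(4, sample(min_cell:cell_max, n, replace = TRUE),
            simplify = FALSE)
}

# GC fraction of DNA strings (N-aware).
gc_of <- function(x) {
  up <- toupper(x)
  nchar(gsub("[^GC]", "", up)) / nchar(gsub("[^ACGT]", "", up))
}
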