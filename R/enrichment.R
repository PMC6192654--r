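# Per-fragment enrichment statistics: odds ratios, chi-square with Fisher
# fallback, BH-FDR, determinant calling, and the Cochran-Mantel-Haenszel
# common-determinant test across species.

#' Odds ratio of a 2x2 table
#'
#' `(N11*N22)/(N12*N21)`. When any cell is zero, the Haldane-Anscombe
#' correction (0.5 added to every cell) is applied to the reported OR; tests
#' always use the raw counts. Vectorised over tables.
#'
#' @param n11,n12,n21,n22 Cell counts (foreground target, foreground other,
#'   background target, background other).
#' @return Numeric vector of odds ratios.
#' @export
odds_ratio <- function(n11, n12, n21, n22) {
  n11 <- as.numeric(n11); n12 <- as.numeric(n12)
  n21 <- as.numeric(n21); n22 <- as.numeric(n22)
  zero <- n11 == 0 | n12 == 0 | n21 == 0 | n22 == 0
  adj <- ifelse(zero, 0.5, 0)
  ((n11 + adj) * (n22 + adj)) / ((n12 + adj) * (n21 + adj))
}

#' Pearson chi-square test of a 2x2 table
#'
#' Statistic `sum((O-E)^2/E)` without continuity correction, df = 1,
#' upper-tail p. A zero margin yields statistic 0, p = 1, flagged degenerate.
#' Vectorised over tables.
#'
#' @inheritParams odds_ratio
#' @return List with `statistic`, `p`, `degenerate`.
#' @export
chi2_test <- function(n11, n12, n21, n22) {
  n11 <- as.numeric(n11); n12 <- as.numeric(n12)
  n21 <- as.numeric(n21); n22 <- as.numeric(n22)
  n1p <- n11 + n12; n2p <- n21 + n22
  np1 <- n11 + n21; np2 <- n12 + n22
  npp <- n1p + n2p
  degenerate <- n1p == 0 | n2p == 0 | np1 == 0 | np2 == 0
  e11 <- n1p * np1 / npp; e12 <- n1p * np2 / npp
  e21 <- n2p * np1 / npp; e22 <- n2p * np2 / npp
  stat <- (n11 - e11)^2 / e11 + (n12 - e12)^2 / e12 +
    (n21 - e21)^2 / e21 + (n22 - e22)^2 / e22
  stat[degenerate] <- 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[degenerate] <- 1
  list(statistic = stat, p = p, degenerate = degenerate)
}

#' Fisher's exact test of a 2x2 table (two-sided)
#'
#' Exact p by hypergeometric enumeration over all tables with the observed
#' margins, summing the probabilities of tables no more probable than the
#' observed one (point-probability method, as in `stats::fisher.test`).
#' Vectorised over tables.
#'
#' @inheritParams odds_ratio
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_test <- function(n11, n12, n21, n22) {
  n <- length(n11)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- n11[i] + n12[i]          # foreground windows
    nn <- n21[i] + n22[i]         # background windows
    kk <- n11[i] + n21[i]         # fragment total
    support <- max(0, kk - nn):min(kk, m)
    d <- dhyper(support, m, nn, kk)
    d_obs <- dhyper(n11[i], m, nn, kk)
    p[i] <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_(j>=i) p_(j) * m / j`, clipped to 1, in the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Call species sequence determinants from a count table
#'
#' Fragments whose combined count (N11 + N21) strictly exceeds `min_count`
#' are tested for over-representation with the chi-square test, routed to
#' Fisher's exact test whenever any expected cell is below 5. P-values are
#' BH-adjusted jointly across all tested fragments of all lengths, and a
#' fragment is called a determinant when `q <= q_max`, its odds ratio exceeds
#' 1, and it passed the count filter.
#'
#' @param table A `kmer_count_table`.
#' @param min_count Strict lower bound on N11 + N21 (default 100, i.e. tested
#'   only if it appeared over 100 times).
#' @param q_max FDR threshold (default 0.05).
#' @return Data frame with one row per tested fragment: `kmer`, `length`,
#'   `gc`, `N11`, `N21`, `total_count`, `or_value`, `test`, `p`, `q`,
#'   `is_determinant`.
#' @export
call_species_determinants <- function(table, min_count = 100, q_max = 0.05) {
  stopifnot(inherits(table, "kmer_count_table"))
  rows <- lapply(names(table$per_k), function(kc) {
    e <- table$per_k[[kc]]
    tot <- e$counts$N11 + e$counts$N21
    keep <- tot > min_count
    if (!any(keep)) return(NULL)
    data.frame(kmer = e$counts$kmer[keep],
               length = as.integer(kc),
               N11 = e$counts$N11[keep], N21 = e$counts$N21[keep],
               N1plus = e$N1plus, N2plus = e$N2plus,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    warning("no fragment passed the count filter (min_count = ", min_count,
            ")")
    return(data.frame(kmer = character(0), length = integer(0),
                      gc = numeric(0), N11 = numeric(0), N21 = numeric(0),
                      total_count = numeric(0), or_value = numeric(0),
                      test = character(0), p = numeric(0), q = numeric(0),
                      is_determinant = logical(0)))
  }
  n11 <- rows$N11; n12 <- rows$N1plus - rows$N11
  n21 <- rows$N21; n22 <- rows$N2plus - rows$N21
  tot <- n11 + n21
  npp <- rows$N1plus + rows$N2plus
  min_e <- pmin(rows$N1plus, rows$N2plus) * pmin(tot, npp - tot) / npp
  use_fisher <- min_e < 5
  p <- numeric(nrow(rows))
  if (any(!use_fisher))
    p[!use_fisher] <- chi2_test(n11[!use_fisher], n12[!use_fisher],
                                n21[!use_fisher], n22[!use_fisher])$p
  if (any(use_fisher))
    p[use_fisher] <- fisher_test(n11[use_fisher], n12[use_fisher],
                                 n21[use_fisher], n22[use_fisher])
  q <- bh_fdr(p)
  or <- odds_ratio(n11, n12, n21, n22)
  res <- data.frame(kmer = rows$kmer, length = rows$length,
                    gc = gc_content(rows$kmer),
                    N11 = n11, N21 = n21, total_count = tot,
                    or_value = or,
                    test = ifelse(use_fisher, "fisher", "chi2"),
                    p = p, q = q,
                    is_determinant = q <= q_max & or > 1,
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, res$p, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cochran-Mantel-Haenszel test across strata
#'
#' Score-form CMH statistic for a common odds ratio across K 2x2 strata:
#' `[sum_k (N11k - E11k)]^2 / sum_k Var_k` with
#' `Var_k = N1+k N2+k N+1k N+2k / (N++k^2 (N++k - 1))`, no continuity
#' correction, df = 1, upper-tail p. Strata with total <= 1 are skipped (and
#' counted in `n_skipped`).
#'
#' @param tables List of 2x2 matrices (rows foreground/background, columns
#'   target/other), one per stratum (species).
#' @return List with `statistic`, `p`, `n_skipped`.
#' @export
cmh_test <- function(tables) {
  stopifnot(length(tables) >= 1)
  m <- vapply(tables, function(t) c(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
              numeric(4))
  res <- cmh_stat_vec(matrix(m[1, ], ncol = 1), matrix(m[2, ], ncol = 1),
                      matrix(m[3, ], ncol = 1), matrix(m[4, ], ncol = 1))
  list(statistic = res$statistic[1], p = res$p[1],
       n_skipped = res$n_skipped[1])
}

# Vectorised CMH across fragments: each argument is a strata x fragments
# matrix of cell counts.
cmh_stat_vec <- function(n11, n12, n21, n22) {
  # double arithmetic: margin products overflow 32-bit integers easily
  storage.mode(n11) <- storage.mode(n12) <- "double"
  storage.mode(n21) <- storage.mode(n22) <- "double"
  n1p <- n11 + n12; n2p <- n21 + n22
  np1 <- n11 + n21; np2 <- n12 + n22
  npp <- n1p + n2p
  ok <- npp > 1
  e11 <- n1p * np1 / pmax(npp, 1)
  v <- n1p * n2p * np1 * np2 / (pmax(npp, 2)^2 * (pmax(npp, 2) - 1))
  d <- n11 - e11
  d[!ok] <- 0
  v[!ok] <- 0
  num <- colSums(d)
  den <- colSums(v)
  stat <- ifelse(den > 0, num^2 / den, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[den == 0] <- 1
  list(statistic = stat, p = p, n_skipped = colSums(!ok))
}

#' Call common sequence determinants across species
#'
#' A fragment is eligible when its combined count exceeds `min_count` in
#' every species. Eligible fragments are tested with the CMH test across
#' species strata; p-values are BH-adjusted jointly, and a fragment is a
#' common determinant when `q <= q_max` and its per-species odds ratio
#' exceeds 1 in every species. The minimum per-species OR is recorded.
#'
#' @param tables Named list of `kmer_count_table` objects, one per species
#'   (same region class).
#' @param min_count Strict per-species count filter (default 100).
#' @param q_max FDR threshold (default 0.05).
#' @return Data frame with `kmer`, `length`, `gc`, per-species `or_<species>`
#'   columns, `min_or`, `cmh_stat`, `p`, `q`, `is_common`.
#' @export
call_common_determinants <- function(tables, min_count = 100, q_max = 0.05) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "kmer_count_table")))
  sp <- names(tables) %||% sprintf("sp%d", seq_along(tables))
  ks <- names(tables[[1]]$per_k)
  per_k <- lapply(ks, function(kc) {
    ents <- lapply(tables, function(t) t$per_k[[kc]])
    eligible <- Reduce(intersect, lapply(ents, function(e) {
      e$counts$kmer[e$counts$N11 + e$counts$N21 > min_count]
    }))
    if (!length(eligible)) return(NULL)
    eligible <- sort(eligible)
    n11 <- vapply(ents, function(e) {
      i <- match(eligible, e$counts$kmer)
      e$counts$N11[i]
    }, numeric(length(eligible)))
    n21 <- vapply(ents, function(e) {
      i <- match(eligible, e$counts$kmer)
      e$counts$N21[i]
    }, numeric(length(eligible)))
    n11 <- matrix(n11, ncol = length(sp)); n21 <- matrix(n21, ncol = length(sp))
    n1p <- vapply(ents, `[[`, numeric(1), "N1plus")
    n2p <- vapply(ents, `[[`, numeric(1), "N2plus")
    n12 <- sweep(-n11, 2, n1p, `+`)
    n22 <- sweep(-n21, 2, n2p, `+`)
    ors <- matrix(odds_ratio(n11, n12, n21, n22), ncol = length(sp))
    cmh <- cmh_stat_vec(t(n11), t(n12), t(n21), t(n22))
    out <- data.frame(kmer = eligible, length = as.integer(kc),
                      gc = gc_content(eligible), stringsAsFactors = FALSE)
    colnames(ors) <- paste0("or_", sp)
    out <- cbind(out, ors)
    out$min_or <- apply(ors, 1, min)
    out$cmh_stat <- cmh$statistic
    out$p <- cmh$p
    out
  })
  res <- do.call(rbind, per_k)
  if (is.null(res) || !nrow(res))
    return(data.frame(kmer = character(0), length = integer(0),
                      gc = numeric(0), min_or = numeric(0),
                      cmh_stat = numeric(0), p = numeric(0), q = numeric(0),
                      is_common = logical(0)))
  res$q <- bh_fdr(res$p)
  all_or_gt1 <- apply(res[, paste0("or_", sp), drop = FALSE] > 1, 1, all)
  res$is_common <- res$q <= q_max & all_or_gt1
  res <- res[order(res$q, res$p, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare enhancer and promoter determinant sets
#'
#' Two-sided Wilcoxon rank-sum test on the odds-ratio distributions and a
#' two-sided pooled-variance t-test on determinant lengths, plus the summary
#' means; the enhancer-vs-promoter contrast of effect sizes.
#'
#' @param enh,pro Determinant result data frames (from
#'   [call_species_determinants()]), usually restricted to
#'   `is_determinant == TRUE`.
#' @return List with `wilcoxon_stat`, `wilcoxon_p` (on ORs), `t_stat`, `t_p`
#'   (on lengths), `mean_or`, and `mean_length` per class.
#' @export
compare_classes <- function(enh, pro) {
  stopifnot(nrow(enh) > 0, nrow(pro) > 0)
  w <- suppressWarnings(wilcox.test(pro$or_value, enh$or_value,
                                    alternative = "two.sided"))
  if (is.na(w$p.value)) w$p.value <- 1  # fully tied distributions
  pooled_var <- 0
  if (nrow(enh) > 1 || nrow(pro) > 1)
    pooled_var <- ((nrow(enh) - 1) * var(enh$length) * (nrow(enh) > 1) +
                     (nrow(pro) - 1) * var(pro$length) * (nrow(pro) > 1)) /
      (nrow(enh) + nrow(pro) - 2)
  tt <- if (nrow(enh) > 1 && nrow(pro) > 1 && pooled_var > 0) {
    t.test(enh$length, pro$length, var.equal = TRUE)
  } else {
    # degenerate length spread: equal means give t = 0, p = 1
    delta <- mean(enh$length) - mean(pro$length)
    list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
         p.value = if (delta == 0) 1 else 0)
  }
  list(wilcoxon_stat = unname(w$statistic), wilcoxon_p = w$p.value,
       t_stat = unname(tt$statistic), t_p = tt$p.value,
       mean_or = c(enhancer = mean(enh$or_value),
                   promoter = mean(pro$or_value)),
       mean_length = c(enhancer = mean(enh$length),
                       promoter = mean(pro$length)))
}
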