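# Relating determinant effect sizes to GC content and TFBS frequency:
# TOMTOM output parsing, the log2(OR) linear model with the interaction-drop
# rule and Type III partial sums of squares, and the GC-TFBS relationship.

#' Parse TOMTOM motif-comparison output into TFBS annotations
#'
#' For each query k-mer: `n_hits` is the number of motif comparisons with
#' p < 0.05, `tfbs_frequency = n_hits / n_motifs_db`, and `minus_log10_minP`
#' comes from the smallest p-value. Queries listed in `queries` but absent
#' from the file get frequency 0 and `minus_log10_minP` 0, flagged via
#' `n_hits = 0`. Comment lines and malformed rows are skipped (their count is
#' attached as attribute `n_skipped`).
#'
#' @param tomtom_tsv Path to a TOMTOM-format TSV (columns including
#'   `Query_ID`, `Target_ID`, `p-value`).
#' @param n_motifs_db Number of motifs in the database compared against
#'   (e.g. 641 for HOCOMOCOv10_HUMAN).
#' @param queries Optional character vector of query ids that must appear in
#'   the output even when TOMTOM reported no rows for them.
#' @param p_threshold Significance threshold on the comparison p-value
#'   (default 0.05).
#' @return Data frame with `kmer`, `n_hits`, `n_motifs_db`, `tfbs_frequency`,
#'   `minus_log10_minP`.
#' @export
parse_tomtom <- function(tomtom_tsv, n_motifs_db, queries = NULL,
                         p_threshold = 0.05) {
  if (n_motifs_db <= 0) stop("n_motifs_db must be positive")
  lines <- readLines(tomtom_tsv)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no rows in TOMTOM file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  qcol <- grep("^Query", header)[1]
  pcol <- grep("^p[-._ ]?value$", header, ignore.case = TRUE)[1]
  if (is.na(qcol) || is.na(pcol))
    stop("TOMTOM header must contain Query_ID and p-value columns")
  body <- fields[-1]
  nf <- length(header)
  ok <- lengths(body) == nf
  pv <- suppressWarnings(vapply(body[ok], function(f) as.numeric(f[pcol]),
                                numeric(1)))
  qid <- vapply(body[ok], `[[`, character(1), qcol)
  good <- !is.na(pv)
  n_skipped <- sum(!ok) + sum(!good)
  qid <- qid[good]; pv <- pv[good]
  ids <- unique(c(qid, queries))
  out <- do.call(rbind, lapply(ids, function(id) {
    p <- pv[qid == id]
    data.frame(kmer = id,
               n_hits = sum(p < p_threshold),
               n_motifs_db = n_motifs_db,
               tfbs_frequency = sum(p < p_threshold) / n_motifs_db,
               minus_log10_minP = if (length(p)) -log10(min(p)) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Linear model of determinant effect size on GC and TFBS frequency
#'
#' Ordinary least squares of `log2(OR)` on GC content, a TFBS measure, and
#' their interaction. When the interaction is not significant at p = 0.05
#' (strictly: kept only if p < 0.05), the model is refit with main effects
#' only. Type III partial sums of squares are computed by refitting without
#' each term (SSE of the reduced model minus SSE of the full model).
#'
#' @param determinants Data frame with `kmer` and `or_value` (or `or`)
#'   columns; at least 10 rows after joining with annotations. Alternatively
#'   a pre-assembled design with numeric `gc`, `tfbs` and `log2_or` columns
#'   (e.g. from [simulate_factor_data()]), in which case `annotations` is
#'   ignored.
#' @param annotations TFBS annotation data frame (from [parse_tomtom()] or
#'   [generate_tfbs_annotations()]) with `kmer` plus `tfbs_frequency` and/or
#'   `minus_log10_minP`; `NULL` when `determinants` is a pre-assembled design.
#' @param tfbs_measure Which TFBS measure to use: `"frequency"` (default) or
#'   `"minus_log10_minP"`.
#' @return Object of class `factor_model_fit`: list with `variant`
#'   ("interaction" or "main-effects"), `coefficients` (per-term estimate,
#'   SE, p, Type III SSR), `r_squared`, `residual_sd`, `n`,
#'   `interaction_p_full`, and the fitted `lm` object.
#' @export
fit_or_model <- function(determinants, annotations = NULL,
                         tfbs_measure = c("frequency", "minus_log10_minP")) {
  tfbs_measure <- match.arg(tfbs_measure)
  if (is.null(annotations) &&
      all(c("gc", "tfbs", "log2_or") %in% names(determinants))) {
    d <- determinants[, c("gc", "tfbs", "log2_or")]
  } else {
    or <- determinants$or_value %||% determinants$or
    d <- data.frame(kmer = determinants$kmer, log2_or = log2(or),
                    stringsAsFactors = FALSE)
    mcol <- if (tfbs_measure == "frequency") "tfbs_frequency" else
      "minus_log10_minP"
    m <- match(d$kmer, annotations$kmer)
    d$tfbs <- annotations[[mcol]][m]
    d$gc <- gc_content(d$kmer)
  }
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    stop("need at least 10 determinants with OR and TFBS annotation")
  for (v in c("gc", "tfbs"))
    if (sd(d[[v]]) == 0)
      stop("degenerate (constant) design column: ", v)
  full <- lm(log2_or ~ gc + tfbs + gc:tfbs, data = d)
  if (full$rank < 4)
    stop("collinear design: ",
         paste(names(which(is.na(coef(full)))), collapse = ", "))
  p_int <- summary(full)$coefficients["gc:tfbs", 4]
  # a saturated/noiseless fit has no residual variance: treat as NS
  if (is.na(p_int)) p_int <- 1
  if (p_int < 0.05) {
    fit <- full
    variant <- "interaction"
    reduced <- list(gc = lm(log2_or ~ tfbs + gc:tfbs, data = d),
                    tfbs = lm(log2_or ~ gc + gc:tfbs, data = d),
                    `gc:tfbs` = lm(log2_or ~ gc + tfbs, data = d))
  } else {
    fit <- lm(log2_or ~ gc + tfbs, data = d)
    variant <- "main-effects"
    reduced <- list(gc = lm(log2_or ~ tfbs, data = d),
                    tfbs = lm(log2_or ~ gc, data = d))
  }
  sse <- function(m) sum(residuals(m)^2)
  sm <- summary(fit)$coefficients
  terms_out <- names(reduced)
  coefs <- data.frame(
    term = terms_out,
    estimate = sm[terms_out, 1], se = sm[terms_out, 2], p = sm[terms_out, 4],
    ssr = vapply(reduced, function(m) sse(m) - sse(fit), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(variant = variant, coefficients = coefs,
                 r_squared = summary(fit)$r.squared,
                 residual_sd = summary(fit)$sigma,
                 n = nrow(d), interaction_p_full = p_int,
                 fit = fit, data = d),
            class = "factor_model_fit")
}

#' Relationship between GC content and TFBS frequency
#'
#' Pearson correlation (two-sided p) between determinant GC content and TFBS
#' frequency, plus the scatter table for plotting; control fragments, when
#' given, are appended with `is_determinant = FALSE`.
#'
#' @param determinants Data frame with `kmer` (determinant k-mers).
#' @param annotations TFBS annotations covering the k-mers.
#' @param controls Optional data frame of non-determinant k-mers with `kmer`.
#' @return List with `pearson_r`, `p`, `degenerate`, and `points` (gc, tfbs,
#'   is_determinant).
#' @export
gc_tfbs_relationship <- function(determinants, annotations, controls = NULL) {
  pts <- function(df, flag) {
    m <- match(df$kmer, annotations$kmer)
    data.frame(kmer = df$kmer, gc = gc_content(df$kmer),
               tfbs = annotations$tfbs_frequency[m],
               is_determinant = flag, stringsAsFactors = FALSE)
  }
  d <- pts(determinants, TRUE)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 annotated determinants")
  points <- if (!is.null(controls)) rbind(d, pts(controls, FALSE)) else d
  if (sd(d$gc) == 0 || sd(d$tfbs) == 0)
    return(list(pearson_r = NA_real_, p = NA_real_, degenerate = TRUE,
                points = points))
  ct <- cor.test(d$gc, d$tfbs, method = "pearson")
  list(pearson_r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE,
       points = points)
}

#' Partial residuals of log2(OR) after removing the GC effect
#'
#' Regresses log2(OR) on GC content alone and returns the residuals with the
#' TFBS measure and a high/low GC split at 0.5, the table behind
#' partial-residual scatterplots of the TFBS effect.
#'
#' @inheritParams fit_or_model
#' @param gc_split GC threshold separating the low- and high-GC groups
#'   (default 0.5).
#' @return Data frame with `kmer`, `gc`, `gc_group`, `tfbs`,
#'   `partial_residual`.
#' @export
gc_partial_residuals <- function(determinants, annotations,
                                 tfbs_measure = c("frequency",
                                                  "minus_log10_minP"),
                                 gc_split = 0.5) {
  tfbs_measure <- match.arg(tfbs_measure)
  or <- determinants$or_value %||% determinants$or
  mcol <- if (tfbs_measure == "frequency") "tfbs_frequency" else
    "minus_log10_minP"
  m <- match(determinants$kmer, annotations$kmer)
  d <- data.frame(kmer = determinants$kmer, log2_or = log2(or),
                  gc = gc_content(determinants$kmer),
                  tfbs = annotations[[mcol]][m], stringsAsFactors = FALSE)
  d <- d[complete.cases(d), , drop = FALSE]
  d$partial_residual <- residuals(lm(log2_or ~ gc, data = d))
  d$gc_group <- ifelse(d$gc <= gc_split, "low_gc", "high_gc")
  d[, c("kmer", "gc", "gc_group", "tfbs", "partial_residual")]
}
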