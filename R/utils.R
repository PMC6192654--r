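# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Every pipeline stage draws its randomness from a seed derived
#' deterministically from the master seed and the stage name, so that stages
#' are reproducible independently of each other.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master_seed)) * 7919 + h * 104729) %% 2147483646 + 1)
}

# GC fraction of a DNA string (vectorised); counts G/C among A/C/G/T only.
gc_fraction <- function(x) {
  up <- toupper(x)
  gc <- nchar(gsub("[^GC]", "", up))
  acgt <- nchar(gsub("[^ACGT]", "", up))
  ifelse(acgt == 0, NA_real_, gc / acgt)
}

# Fraction of characters that are not A/C/G/T (the missing-data measure).
n_fraction <- function(x) {
  up <- toupper(x)
  1 - nchar(gsub("[^ACGT]", "", up)) / nchar(up)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
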