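# Foreground/background region construction.
#
# A "region pairs" table holds one row per regulatory (foreground) region,
# with its same-length background segment placed `offset` bp away on the same
# chromosome: downstream first, upstream as fallback, absent (flagged) when
# neither fits. Coordinates are 0-based half-open throughout, matching BED.

pair_columns <- c("region_id", "species", "region_class", "chrom",
                  "fg_start", "fg_end", "fg_seq",
                  "bg_start", "bg_end", "bg_seq",
                  "bg_flag", "bg_n_frac", "overlap_frac", "conserved")

new_region_pairs <- function(df, genome) {
  attr(df, "genome") <- genome
  class(df) <- c("region_pairs", "data.frame")
  df
}

# data.frame subsetting drops custom attributes; re-attach them.
restore_pairs <- function(df, template) {
  new_region_pairs(as.data.frame(df), attr(template, "genome"))
}

#' Load regions from BED against a genome FASTA
#'
#' Reads one region class for one species: each BED record becomes a region
#' pair row with the foreground sequence extracted (uppercased) and no
#' background yet. Region ids come from the BED name field, or are synthesized
#' as `chrom:start-end`.
#'
#' @param bed_path BED file (0-based half-open; >= 3 columns).
#' @param fasta_path Genome FASTA for the same species.
#' @param species Species label.
#' @param region_class Region class label (e.g. "enhancer", "promoter").
#' @return A `region_pairs` data frame (backgrounds absent), carrying the
#'   genome as an attribute for later background construction.
#' @export
load_regions <- function(bed_path, fasta_path, species, region_class) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  genome <- toupper(as.character(dna))
  gr <- as.data.frame(rtracklayer::import(bed_path, format = "BED"))
  if (nrow(gr) == 0)
    return(new_region_pairs(empty_pairs(), genome))
  chrom <- as.character(gr$seqnames)
  start0 <- gr$start - 1L
  end0 <- gr$end
  ids <- gr$name
  if (is.null(ids)) ids <- rep(NA_character_, nrow(gr))
  ids <- ifelse(is.na(ids) | !nzchar(ids),
                sprintf("%s:%d-%d", chrom, start0, end0), ids)
  missing_chrom <- setdiff(unique(chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from FASTA: ",
         paste(missing_chrom, collapse = ", "))
  clen <- nchar(genome)[chrom]
  bad <- which(start0 < 0 | end0 > clen | start0 >= end0)
  if (length(bad))
    stop("BED record out of chromosome bounds: ",
         paste(sprintf("%s:%d-%d (%s)", chrom[bad], start0[bad], end0[bad],
                       ids[bad]), collapse = "; "))
  df <- data.frame(
    region_id = ids, species = species, region_class = region_class,
    chrom = chrom, fg_start = start0, fg_end = end0,
    fg_seq = substring(genome[chrom], start0 + 1, end0),
    bg_start = NA_real_, bg_end = NA_real_, bg_seq = NA_character_,
    bg_flag = "pending", bg_n_frac = NA_real_, overlap_frac = NA_real_,
    conserved = FALSE, stringsAsFactors = FALSE)
  new_region_pairs(df, genome)
}

empty_pairs <- function() {
  data.frame(region_id = character(0), species = character(0),
             region_class = character(0), chrom = character(0),
             fg_start = numeric(0), fg_end = numeric(0),
             fg_seq = character(0), bg_start = numeric(0),
             bg_end = numeric(0), bg_seq = character(0),
             bg_flag = character(0), bg_n_frac = numeric(0),
             overlap_frac = numeric(0), conserved = logical(0),
             stringsAsFactors = FALSE)
}

#' Region pairs directly from an in-memory synthetic panel
#'
#' Convenience constructor equivalent to writing the panel to disk and calling
#' [load_regions()] on its FASTA/BED output.
#'
#' @param panel A `seqdet_panel`.
#' @param species Species name within the panel.
#' @param region_class Region class to extract.
#' @return A `region_pairs` data frame (backgrounds absent).
#' @export
pairs_from_panel <- function(panel, species, region_class) {
  stopifnot(inherits(panel, "seqdet_panel"), species %in% names(panel$species))
  sp <- panel$species[[species]]
  r <- sp$regions[sp$regions$region_class == region_class, , drop = FALSE]
  if (!nrow(r)) return(new_region_pairs(empty_pairs(), sp$genome))
  cons <- panel$conservation
  df <- data.frame(
    region_id = r$region_id, species = species, region_class = region_class,
    chrom = r$chrom, fg_start = r$start, fg_end = r$end,
    fg_seq = substring(sp$genome[r$chrom], r$start + 1, r$end),
    bg_start = NA_real_, bg_end = NA_real_, bg_seq = NA_character_,
    bg_flag = "pending", bg_n_frac = NA_real_, overlap_frac = NA_real_,
    conserved = cons$conserved[match(r$region_id, cons$region_id)],
    stringsAsFactors = FALSE)
  df$conserved[is.na(df$conserved)] <- FALSE
  rownames(df) <- NULL
  new_region_pairs(df, sp$genome)
}

#' Construct same-length backgrounds for region pairs
#'
#' Places each background `offset` bp downstream of its foreground
#' (`[end + offset, end + offset + length)`); if that exceeds the chromosome
#' the upstream side is tried; if neither fits the background is absent and
#' the pair flagged. The fraction of each background overlapped by any
#' foreground of the same species and class is recorded (regions are kept,
#' not rejected, when they overlap).
#'
#' @param pairs A `region_pairs` table with foreground sequences.
#' @param offset Distance in bp between foreground and background (default
#'   100,000).
#' @return The table with `bg_*` columns filled in.
#' @export
build_backgrounds <- function(pairs, offset = 1e5) {
  stopifnot(inherits(pairs, "region_pairs"))
  genome <- attr(pairs, "genome")
  if (!nrow(pairs)) return(pairs)
  clen <- nchar(genome)[pairs$chrom]
  len <- pairs$fg_end - pairs$fg_start
  down_s <- pairs$fg_end + offset
  down_ok <- down_s + len <= clen
  up_s <- pairs$fg_start - offset - len
  up_ok <- up_s >= 0
  pairs$bg_start <- ifelse(down_ok, down_s, ifelse(up_ok, up_s, NA_real_))
  pairs$bg_end <- pairs$bg_start + len
  pairs$bg_flag <- ifelse(down_ok, "downstream",
                          ifelse(up_ok, "upstream", "no_room"))
  has_bg <- !is.na(pairs$bg_start)
  pairs$bg_seq[has_bg] <- substring(genome[pairs$chrom[has_bg]],
                                    pairs$bg_start[has_bg] + 1,
                                    pairs$bg_end[has_bg])
  pairs$bg_n_frac[has_bg] <- n_fraction(pairs$bg_seq[has_bg])
  # overlap of each background with any same-species/class foreground
  pairs$overlap_frac <- 0
  for (i in which(has_bg)) {
    same <- pairs$chrom == pairs$chrom[i]
    ov <- pmin(pairs$fg_end[same], pairs$bg_end[i]) -
      pmax(pairs$fg_start[same], pairs$bg_start[i])
    pairs$overlap_frac[i] <- sum(pmax(ov, 0)) / len[i]
  }
  pairs$overlap_frac[!has_bg] <- NA_real_
  pairs
}

#' Drop backgrounds with too many missing nucleotides
#'
#' Backgrounds whose fraction of non-ACGT (missing) bases strictly exceeds
#' `max_missing_frac` are removed (the background becomes absent, flagged
#' "missing"); foregrounds are never removed. Idempotent.
#'
#' @param pairs A `region_pairs` table with backgrounds built.
#' @param max_missing_frac Strict threshold on the background N fraction
#'   (default 0.5, i.e. "greater than 50 percent missing" is discarded).
#' @return The filtered table.
#' @export
filter_missing <- function(pairs, max_missing_frac = 0.5) {
  stopifnot(inherits(pairs, "region_pairs"))
  if (!nrow(pairs)) return(pairs)
  drop <- !is.na(pairs$bg_n_frac) & pairs$bg_n_frac > max_missing_frac
  pairs$bg_start[drop] <- NA_real_
  pairs$bg_end[drop] <- NA_real_
  pairs$bg_seq[drop] <- NA_character_
  pairs$bg_flag[drop] <- "missing"
  pairs
}

#' Remove conserved regions
#'
#' Drops pairs flagged as conserved in the supplied table (region id ->
#' logical). Region ids absent from the table are treated as non-conserved;
#' their count is attached as attribute `n_unknown` and reported in a warning.
#'
#' @param pairs A `region_pairs` table.
#' @param conservation_table Data frame with columns `region_id`, `conserved`.
#' @return The table restricted to non-conserved pairs.
#' @export
filter_conserved <- function(pairs, conservation_table) {
  stopifnot(inherits(pairs, "region_pairs"),
            all(c("region_id", "conserved") %in% names(conservation_table)))
  if (!nrow(pairs)) return(pairs)
  m <- match(pairs$region_id, conservation_table$region_id)
  n_unknown <- sum(is.na(m))
  if (n_unknown > 0)
    warning(n_unknown, " region id(s) absent from conservation table; ",
            "treated as non-conserved")
  conserved <- conservation_table$conserved[m]
  conserved[is.na(conserved)] <- FALSE
  pairs$conserved <- conserved
  out <- restore_pairs(pairs[!conserved, , drop = FALSE], pairs)
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Summarize region pairs
#'
#' Per species and class: foreground count, retained-background count, mean
#' and SD (n-1 denominator) of foreground lengths, and conserved counts. A
#' single region yields SD 0 with `sd_defined = FALSE`.
#'
#' @param pairs A `region_pairs` table (several species/classes may be
#'   row-bound together).
#' @return A data frame, one row per species x class.
#' @export
summarize_regions <- function(pairs) {
  df <- as.data.frame(pairs)
  if (!nrow(df))
    return(data.frame(species = character(0), region_class = character(0),
                      n_foreground = integer(0),
                      n_background_retained = integer(0),
                      length_mean = numeric(0), length_sd = numeric(0),
                      sd_defined = logical(0), n_conserved = integer(0),
                      prop_conserved = numeric(0)))
  key <- interaction(df$species, df$region_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    len <- g$fg_end - g$fg_start
    data.frame(species = g$species[1], region_class = g$region_class[1],
               n_foreground = nrow(g),
               n_background_retained = sum(!is.na(g$bg_start)),
               length_mean = mean(len),
               length_sd = if (nrow(g) > 1) sd(len) else 0,
               sd_defined = nrow(g) > 1,
               n_conserved = sum(g$conserved),
               prop_conserved = mean(g$conserved),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
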