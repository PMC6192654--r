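# Synthetic multi-species panel generator.
#
# Genomes are i.i.d. nucleotide sequences at a given GC content; foreground
# (regulatory) regions are re-drawn at a GC content shifted by fg_gc_shift and
# then receive planted determinant k-mers at a rate calibrated so that each
# k-mer's expected foreground/background frequency ratio equals its target
# odds ratio. Every region reserves a same-length background segment exactly
# `offset` bp downstream, and the layout guarantees that foregrounds and
# reserved backgrounds never overlap.

#' Default planted-determinant pool
#'
#' Draws a reproducible pool of determinant 6-mers: enhancer k-mers planted
#' at a modest odds ratio and promoter k-mers at a larger one, mirroring the
#' promoter > enhancer effect-size contrast the pipeline is designed to
#' detect.
#'
#' K-mer composition is constrained so that the planted truth is actually
#' recoverable at desk-scale panel sizes (hundreds of ~2 kb regions, ~6e5
#' windows per side). Two analytic requirements drive the defaults:
#' \itemize{
#'   \item eligibility: a fragment is only tested when it appears more than
#'     100 times, so a planted k-mer's expected background count must not be
#'     too small (rules out GC counts >= 5 per 6-mer at background GC ~0.41);
#'   \item artifact control: each insertion of k-mer w also increments the
#'     overlapping "shifted" k-mers (w's flanks), so the number of insertions
#'     needed to reach the target OR must stay small enough that no flank
#'     variant accumulates a significant excess of its own (rules out very
#'     AT-rich, i.e. very abundant, k-mers for large target ORs).
#' }
#' Enhancer k-mers default to 1-2 GC bases (abundant, so an OR of 1.5 is
#' reliably detectable); promoter k-mers mix 4 and 3 GC bases (moderately
#' rare, so an OR of 3 needs few insertions), the GC-3 half sitting inside
#' the low-GC band (GC <= 0.5) so that low-GC determinant models carry
#' planted motif signal rather than composition alone.
#'
#' No k-mer in the pool is a substring of another (so occurrence counts do
#' not leak between planted determinants) and homopolymers are excluded.
#'
#' @param n_enhancer,n_promoter Number of k-mers planted per class.
#' @param or_enhancer,or_promoter Target odds ratios per class.
#' @param kmer_length K-mer length (default 6).
#' @param enhancer_gc,promoter_gc Allowed numbers of G/C bases per k-mer for
#'   each class (sampled uniformly when several values are given).
#' @param seed Integer seed for the pool draw.
#' @return A data frame with columns `kmer`, `target_or`, `region_class`.
#' @export
default_determinant_pool <- function(n_enhancer = 10, n_promoter = 10,
                                     or_enhancer = 1.5, or_promoter = 3,
                                     kmer_length = 6,
                                     enhancer_gc = c(1, 2),
                                     promoter_gc = c(4, 3),
                                     seed = 101) {
  with_seed(seed, {
    ngc <- c(sample(rep(enhancer_gc, length.out = n_enhancer)),
             sample(rep(promoter_gc, length.out = n_promoter)))
    kmers <- draw_distinct_kmers(rep(kmer_length, n_enhancer + n_promoter),
                                 ngc = ngc, existing = character(0))
  })
  data.frame(
    kmer = kmers,
    target_or = c(rep(or_enhancer, n_enhancer), rep(or_promoter, n_promoter)),
    region_class = c(rep("enhancer", n_enhancer), rep("promoter", n_promoter)),
    stringsAsFactors = FALSE
  )
}

# Draw k-mers of the given lengths (and, optionally, exact G/C counts) such
# that no k-mer (new or existing) is a substring of any other and none is a
# homopolymer. Uses the current RNG.
draw_distinct_kmers <- function(lengths, ngc = NULL, existing = character(0)) {
  out <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    repeat {
      if (is.null(ngc)) {
        cand <- paste(sample(bases, len, replace = TRUE), collapse = "")
      } else {
        ch <- rep("", len)
        gc_pos <- sample.int(len, ngc[i])
        ch[gc_pos] <- sample(c("G", "C"), ngc[i], replace = TRUE)
        ch[-gc_pos] <- sample(c("A", "T"), len - ngc[i], replace = TRUE)
        cand <- paste(ch, collapse = "")
      }
      pool <- c(existing, out)
      clash <- length(unique(strsplit(cand, "")[[1]])) == 1 ||
        any(vapply(pool, function(p) {
          grepl(cand, p, fixed = TRUE) || grepl(p, cand, fixed = TRUE)
        }, logical(1)))
      if (!clash) break
    }
    out <- c(out, cand)
  }
  out
}

#' Specify a synthetic multi-species panel
#'
#' Collects and validates all parameters of the synthetic study: number of
#' species, genome size, background GC content, per-class region counts,
#' lengths and foreground GC shift, the planted-determinant pool, the fraction
#' of the pool shared by all species, and the master seed.
#'
#' Defaults emulate the scale of the mammalian liver enhancer/promoter study
#' the pipeline is modelled on: regions around 2 kb, backgrounds 100 kb away,
#' promoter foregrounds shifted +10 GC percentage points over their
#' backgrounds, and promoter determinants planted at larger odds ratios than
#' enhancer determinants.
#'
#' @param n_species Number of species (independent genomes).
#' @param chrom_length Chromosome length in bp.
#' @param n_chroms Chromosomes per genome.
#' @param background_gc Background GC fraction in (0, 1).
#' @param regional_gc_sd Standard deviation of the per-region-pair local GC
#'   level (default 0.06). Each foreground and its reserved background share
#'   a local composition drawn around `background_gc`, emulating the
#'   isochore-scale regional GC correlation (~100 kb) that motivates placing
#'   backgrounds nearby: GC then separates foregrounds from backgrounds only
#'   through `fg_gc_shift`, not perfectly. Set 0 for a strictly homogeneous
#'   genome.
#' @param region_class_params Named list (`enhancer`, `promoter`), each a list
#'   with `n_regions`, `length_mean`, `length_sd`, `fg_gc_shift`.
#' @param determinant_pool Data frame from [default_determinant_pool()] (or
#'   shaped like it); may have zero rows for a null panel.
#' @param sharing Fraction in \[0, 1\] of the pool planted identically in all
#'   species; the remainder is replaced per species by fresh k-mers with the
#'   same length and target odds ratio.
#' @param offset Foreground-to-background distance in bp (default 100,000).
#' @param n_stipple_rate Probability that a reserved background receives a run
#'   of N (missing) bases covering 30-90% of its length; exercises the
#'   missing-data filter. Default 0.
#' @param conserved_frac Fraction of regions flagged as conserved in the
#'   emitted conservation table. Default 0.
#' @param min_length Minimum region length (shorter draws are truncated up).
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_species = 2,
                       chrom_length = 7e6,
                       n_chroms = 1,
                       background_gc = 0.41,
                       regional_gc_sd = 0.06,
                       region_class_params = list(
                         enhancer = list(n_regions = 300, length_mean = 2000,
                                         length_sd = 400, fg_gc_shift = 0),
                         promoter = list(n_regions = 300, length_mean = 2000,
                                         length_sd = 400, fg_gc_shift = 0.10)
                       ),
                       determinant_pool = default_determinant_pool(),
                       sharing = 1,
                       offset = 1e5,
                       n_stipple_rate = 0,
                       conserved_frac = 0,
                       min_length = 200,
                       seed = 1) {
  stopifnot(n_species >= 1, n_chroms >= 1, chrom_length > 0,
            background_gc > 0, background_gc < 1,
            regional_gc_sd >= 0, regional_gc_sd < 0.25,
            sharing >= 0, sharing <= 1, offset > 0,
            n_stipple_rate >= 0, n_stipple_rate <= 1,
            conserved_frac >= 0, conserved_frac <= 1,
            min_length >= 1)
  if (is.null(names(region_class_params)) ||
      !all(nzchar(names(region_class_params))))
    stop("region_class_params must be a named list of region classes")
  for (cls in names(region_class_params)) {
    p <- region_class_params[[cls]]
    stopifnot(p$n_regions >= 1, p$length_mean >= min_length, p$length_sd >= 0)
    if (p$fg_gc_shift + background_gc < 0 || p$fg_gc_shift + background_gc > 1)
      stop("fg_gc_shift + background_gc must lie in [0, 1] (class ", cls, ")")
  }
  if (nrow(determinant_pool) > 0) {
    stopifnot(all(c("kmer", "target_or", "region_class") %in%
                    names(determinant_pool)))
    if (any(grepl("[^ACGT]", determinant_pool$kmer)))
      stop("planted k-mers must contain only A, C, G, T")
    kl <- nchar(determinant_pool$kmer)
    if (any(kl < 6 | kl > 15)) stop("planted k-mers must be 6-15 bp")
    if (!all(is.finite(determinant_pool$target_or)) ||
        any(determinant_pool$target_or <= 0))
      stop("target_or must be finite and > 0")
    if (!all(determinant_pool$region_class %in% names(region_class_params)))
      stop("determinant_pool region_class values must match region classes")
  }
  spec <- list(n_species = as.integer(n_species),
               chrom_length = as.numeric(chrom_length),
               n_chroms = as.integer(n_chroms),
               background_gc = background_gc,
               regional_gc_sd = regional_gc_sd,
               region_class_params = region_class_params,
               determinant_pool = determinant_pool,
               sharing = sharing,
               offset = as.numeric(offset),
               n_stipple_rate = n_stipple_rate,
               conserved_frac = conserved_frac,
               min_length = as.integer(min_length),
               seed = as.integer(seed))
  class(spec) <- "panel_spec"
  # fail fast if the layout cannot host the regions
  invisible(panel_layout(spec))
  spec
}

# Region-length range the layout must accommodate; length draws are clipped
# to mean +/- 4 sd (and to >= min_length), so the slot search can use the
# exact attainable range.
panel_length_range <- function(spec) {
  lo <- min(vapply(spec$region_class_params,
                   function(p) p$length_mean - 4 * p$length_sd, numeric(1)))
  hi <- max(vapply(spec$region_class_params,
                   function(p) p$length_mean + 4 * p$length_sd, numeric(1)))
  c(max(spec$min_length, floor(lo)), ceiling(hi))
}

# Uniform-slot layout. Foreground i sits at the start of slot i (slot size S);
# its reserved background starts `length + offset` later. S is chosen so that
# for every admissible length L in [min_length, Lmax]:
#   (L + offset) mod S  >=  Lmax            (background clears the slot's
#   (Lmax + offset) mod S + Lmax  <=  S      foreground and the next one)
# with floor((L + offset)/S) constant over the range, which also keeps
# backgrounds mutually disjoint. An explicit capacity error is raised when the
# genome cannot host all regions.
panel_layout <- function(spec) {
  rng <- panel_length_range(spec)
  lmin <- rng[1]
  lmax <- rng[2]
  off <- spec$offset
  s_lo <- 2 * lmax + (lmax - lmin) + 1
  s_hi <- max(s_lo + 10 * lmax, 6 * lmax)
  slot <- NA_integer_
  for (S in s_lo:s_hi) {
    m0 <- floor((lmin + off) / S)
    r_min <- lmin + off - m0 * S
    r_max <- lmax + off - m0 * S
    if (r_min >= lmax && r_max + lmax <= S) { slot <- S; break }
  }
  if (is.na(slot))
    stop("panel layout infeasible: no slot size separates foregrounds from ",
         "backgrounds at offset ", off)
  n_slots <- floor((spec$chrom_length - off - 2 * lmax) / slot)
  if (n_slots < 1)
    stop("panel layout infeasible: chromosome of ", spec$chrom_length,
         " bp holds no region at offset ", off)
  n_regions <- sum(vapply(spec$region_class_params, `[[`, numeric(1),
                          "n_regions"))
  capacity <- n_slots * spec$n_chroms
  if (n_regions > capacity)
    stop("panel capacity error: ", n_regions, " regions requested but the ",
         "genome holds at most ", capacity,
         " (slot ", slot, " bp, ", n_slots, " slots/chromosome)")
  list(slot = slot, n_slots = n_slots, lmax = lmax)
}

# Per-window occurrence probability of a k-mer under an i.i.d. composition
# with GC fraction g (vectorised over g).
kmer_iid_prob <- function(kmer, g) {
  ngc <- nchar(gsub("[^GC]", "", kmer))
  k <- nchar(kmer)
  (g / 2)^ngc * ((1 - g) / 2)^(k - ngc)
}

#' Generate a synthetic multi-species panel
#'
#' Builds one genome per species, places the foreground regions and their
#' reserved backgrounds, plants the determinant pool, and records the realized
#' occurrence counts of every planted k-mer (the truth table). Deterministic
#' given `spec$seed`: the same spec yields byte-identical output.
#'
#' Planting: the number of copies of k-mer w inserted into a class's
#' foregrounds is Poisson with mean `(target_or * p_bg - p_fg) * W_fg`, where
#' `p_bg`/`p_fg` are the analytic per-window occurrence probabilities under
#' the background/foreground composition and `W_fg` the total foreground
#' window count, so the expected foreground/background frequency ratio equals
#' the target odds ratio. Insertions replace existing bases at uniformly
#' random non-overlapping positions.
#'
#' @param spec A [panel_spec()].
#' @param outdir Optional directory; when given, FASTA/BED/TSV/JSON files are
#'   written via [write_panel()].
#' @return An object of class `seqdet_panel`: list with `spec`, `species`
#'   (per-species genome and region table), `truth` (realized counts per
#'   planted k-mer), `conservation`, and `species_pools`.
#' @export
generate_panel <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  layout <- panel_layout(spec)
  bases <- c("A", "C", "G", "T")
  gc <- spec$background_gc
  p_bg <- c(`A` = (1 - gc) / 2, `C` = gc / 2, `G` = gc / 2, `T` = (1 - gc) / 2)
  classes <- names(spec$region_class_params)
  sp_names <- sprintf("sp%d", seq_len(spec$n_species))

  panel <- with_seed(spec$seed, {
    # --- per-species planted pools (sharing applied per class) -------------
    pool <- spec$determinant_pool
    species_pools <- lapply(sp_names, function(s) pool)
    names(species_pools) <- sp_names
    if (nrow(pool) > 0 && spec$sharing < 1 && spec$n_species > 1) {
      for (cls in classes) {
        idx <- which(pool$region_class == cls)
        if (!length(idx)) next
        n_shared <- round(spec$sharing * length(idx))
        redraw <- idx[seq_along(idx) > n_shared]
        for (s in sp_names) {
          if (!length(redraw)) next
          taken <- unlist(lapply(species_pools, function(df) df$kmer),
                          use.names = FALSE)
          species_pools[[s]]$kmer[redraw] <-
            draw_distinct_kmers(nchar(pool$kmer[redraw]),
                                ngc = nchar(gsub("[^GC]", "",
                                                 pool$kmer[redraw])),
                                existing = taken)
        }
      }
    }

    species <- list()
    truth <- list()
    conservation <- list()
    for (s in sp_names) {
      # --- region plan ----------------------------------------------------
      plan <- do.call(rbind, lapply(classes, function(cls) {
        p <- spec$region_class_params[[cls]]
        len <- round(rnorm(p$n_regions, p$length_mean, p$length_sd))
        lo <- max(spec$min_length, floor(p$length_mean - 4 * p$length_sd))
        hi <- ceiling(p$length_mean + 4 * p$length_sd)
        len <- pmin(pmax(len, lo), hi)
        data.frame(region_class = cls,
                   region_id = sprintf("%s_%s_%04d", s, cls,
                                       seq_len(p$n_regions)),
                   length = len, stringsAsFactors = FALSE)
      }))
      plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
      slot_global <- seq_len(nrow(plan)) - 1L
      plan$chrom_i <- slot_global %/% layout$n_slots + 1L
      plan$start <- (slot_global %% layout$n_slots) * layout$slot
      plan$end <- plan$start + plan$length
      plan$chrom <- sprintf("chr%d", plan$chrom_i)
      plan$bg_start <- plan$end + spec$offset
      plan$bg_end <- plan$bg_start + plan$length

      # local (isochore-like) GC level shared by each foreground and its
      # reserved background
      max_shift <- max(vapply(spec$region_class_params, `[[`, numeric(1),
                              "fg_gc_shift"), 0)
      plan$local_gc <- pmin(pmax(rnorm(nrow(plan), gc, spec$regional_gc_sd),
                                 0.02), 0.98 - max_shift)

      # --- genome composition --------------------------------------------
      chroms <- lapply(seq_len(spec$n_chroms), function(ci)
        sample(bases, spec$chrom_length, replace = TRUE, prob = p_bg))
      for (i in seq_len(nrow(plan))) {
        cls <- plan$region_class[i]
        shift <- spec$region_class_params[[cls]]$fg_gc_shift
        gfg <- plan$local_gc[i] + shift
        ci <- plan$chrom_i[i]
        if (gfg != gc) {
          pfg <- c((1 - gfg) / 2, gfg / 2, gfg / 2, (1 - gfg) / 2)
          chroms[[ci]][(plan$start[i] + 1):plan$end[i]] <-
            sample(bases, plan$length[i], replace = TRUE, prob = pfg)
        }
        if (plan$local_gc[i] != gc) {
          glo <- plan$local_gc[i]
          plo <- c((1 - glo) / 2, glo / 2, glo / 2, (1 - glo) / 2)
          chroms[[ci]][(plan$bg_start[i] + 1):plan$bg_end[i]] <-
            sample(bases, plan$length[i], replace = TRUE, prob = plo)
        }
      }

      # --- N stippling into reserved backgrounds --------------------------
      if (spec$n_stipple_rate > 0) {
        hit <- runif(nrow(plan)) < spec$n_stipple_rate
        for (i in which(hit)) {
          len <- plan$length[i]
          run <- max(1L, round(runif(1, 0.3, 0.9) * len))
          at <- plan$bg_start[i] + sample.int(len - run + 1L, 1) - 1L
          ci <- plan$chrom_i[i]
          chroms[[ci]][(at + 1):(at + run)] <- "N"
        }
      }

      # --- planting -------------------------------------------------------
      sp_pool <- species_pools[[s]]
      for (cls in classes) {
        rows <- which(sp_pool$region_class == cls)
        if (!length(rows)) next
        regs <- plan[plan$region_class == cls, , drop = FALSE]
        shift <- spec$region_class_params[[cls]]$fg_gc_shift
        occupied <- vector("list", nrow(regs))  # planted intervals per region
        for (r in rows) {
          w <- sp_pool$kmer[r]
          k <- nchar(w)
          wins <- regs$length - k + 1
          W1 <- sum(wins)
          # window-weighted expected rates under the realized local
          # compositions of this class's pairs
          wt <- wins / W1
          pb <- sum(wt * kmer_iid_prob(w, regs$local_gc))
          pf <- sum(wt * kmer_iid_prob(w, regs$local_gc + shift))
          lambda <- max(0, (sp_pool$target_or[r] * pb - pf) * W1)
          n_ins <- rpois(1, lambda)
          wchars <- strsplit(w, "")[[1]]
          placed <- 0L
          tries <- 0L
          while (placed < n_ins && tries < 50L * max(n_ins, 1L)) {
            tries <- tries + 1L
            ri <- sample.int(nrow(regs), 1, prob = wins)
            pos <- sample.int(wins[ri], 1) - 1L          # 0-based in region
            iv <- c(pos, pos + k)                        # half-open
            prev <- occupied[[ri]]
            if (!is.null(prev) &&
                any(iv[1] < prev[, 2] & iv[2] > prev[, 1])) next
            occupied[[ri]] <- rbind(prev, iv, deparse.level = 0)
            ci <- regs$chrom_i[ri]
            at <- regs$start[ri] + pos
            chroms[[ci]][(at + 1):(at + k)] <- wchars
            placed <- placed + 1L
          }
        }
      }

      genome <- vapply(chroms, paste, character(1), collapse = "")
      names(genome) <- sprintf("chr%d", seq_len(spec$n_chroms))

      # --- realized truth counts ------------------------------------------
      if (nrow(sp_pool) > 0) {
        for (cls in classes) {
          rows <- which(sp_pool$region_class == cls)
          if (!length(rows)) next
          regs <- plan[plan$region_class == cls, , drop = FALSE]
          fg <- substring(genome[regs$chrom], regs$start + 1, regs$end)
          bg <- substring(genome[regs$chrom], regs$bg_start + 1, regs$bg_end)
          pats <- sp_pool$kmer[rows]
          cf <- pattern_counts_cpp(fg, pats)
          cb <- pattern_counts_cpp(bg, pats)
          kmatch <- match(nchar(pats), cf$k)
          truth[[paste(s, cls)]] <- data.frame(
            species = s, region_class = cls, kmer = pats,
            target_or = sp_pool$target_or[rows],
            fg_count = colSums(cf$counts), bg_count = colSums(cb$counts),
            fg_windows = colSums(cf$valid_windows)[kmatch],
            bg_windows = colSums(cb$valid_windows)[kmatch],
            stringsAsFactors = FALSE)
        }
      }

      if (spec$conserved_frac > 0) {
        n_cons <- round(spec$conserved_frac * nrow(plan))
        flagged <- plan$region_id[sample.int(nrow(plan), n_cons)]
      } else flagged <- character(0)
      conservation[[s]] <- data.frame(
        region_id = plan$region_id,
        conserved = plan$region_id %in% flagged,
        stringsAsFactors = FALSE)

      regions <- plan[order(plan$chrom_i, plan$start),
                      c("region_id", "region_class", "chrom", "start", "end")]
      rownames(regions) <- NULL
      species[[s]] <- list(genome = genome, regions = regions)
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(species = character(0), region_class = character(0),
                 kmer = character(0), target_or = numeric(0),
                 fg_count = numeric(0), bg_count = numeric(0),
                 fg_windows = numeric(0), bg_windows = numeric(0))
    rownames(truth) <- NULL
    conservation <- do.call(rbind, conservation)
    rownames(conservation) <- NULL
    structure(list(spec = spec, species = species, truth = truth,
                   conservation = conservation,
                   species_pools = species_pools),
              class = "seqdet_panel")
  })
  if (!is.null(outdir)) write_panel(panel, outdir)
  panel
}

#' Write a panel to disk
#'
#' Emits, per species, a genome FASTA and one BED6 file per region class
#' (0-based half-open; name = region id; strand "+"), plus the truth table and
#' conservation table as TSV and the spec echo as JSON.
#'
#' @param panel A `seqdet_panel`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_panel <- function(panel, outdir) {
  stopifnot(inherits(panel, "seqdet_panel"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(panel$species)) {
    sp <- panel$species[[s]]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sp$genome),
                                file.path(outdir, paste0(s, ".fa")))
    for (cls in unique(sp$regions$region_class)) {
      r <- sp$regions[sp$regions$region_class == cls, , drop = FALSE]
      bed <- data.frame(r$chrom, format(r$start, scientific = FALSE,
                                        trim = TRUE),
                        format(r$end, scientific = FALSE, trim = TRUE),
                        r$region_id, 0L, "+")
      write.table(bed, file.path(outdir, sprintf("%s_%s.bed", s, cls)),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  write_tsv(panel$truth, file.path(outdir, "truth.tsv"))
  write_tsv(panel$conservation, file.path(outdir, "conservation.tsv"))
  spec <- panel$spec
  spec$determinant_pool <- NULL
  jsonlite::write_json(c(unclass(spec),
                         list(determinant_pool = panel$spec$determinant_pool)),
                       file.path(outdir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Realized odds-ratio estimates for planted k-mers
#'
#' Frequency-ratio estimate (foreground rate over background rate) of every
#' planted k-mer from the truth table's realized counts; the Monte-Carlo check
#' that planting hits its target.
#'
#' @param panel A `seqdet_panel`.
#' @return The truth table with a `realized_ratio` column appended.
#' @export
planted_or_estimates <- function(panel) {
  t <- panel$truth
  t$realized_ratio <- (t$fg_count / t$fg_windows) /
    (pmax(t$bg_count, 0.5) / t$bg_windows)
  t
}
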