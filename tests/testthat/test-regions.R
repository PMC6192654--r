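# Region loading, background construction, filters, summaries.

write_fixture <- function(chrom_seqs, bed_rows) {
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chrom_seqs), fa)
  bed <- tempfile(fileext = ".bed")
  writeLines(bed_rows, bed)
  list(fa = fa, bed = bed)
}

test_that("load_regions extracts foreground coordinates and sequences", {
  set.seed(11)
  chrom <- random_dna(1000)
  fx <- write_fixture(c(chr1 = chrom), "chr1\t100\t400\te1")
  pairs <- load_regions(fx$bed, fx$fa, "spX", "enhancer")
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$fg_start, 100L)
  expect_identical(pairs$fg_end, 400L)
  expect_identical(nchar(pairs$fg_seq), 300L)
  expect_identical(pairs$fg_seq, substr(chrom, 101, 400))
  expect_identical(pairs$region_id, "e1")
})

test_that("load_regions handles empty BED and rejects out-of-bounds records", {
  set.seed(12)
  fx <- write_fixture(c(chr1 = random_dna(1000)), character(0))
  expect_identical(nrow(load_regions(fx$bed, fx$fa, "s", "enhancer")), 0L)
  fx2 <- write_fixture(c(chr1 = random_dna(1000)), "chr1\t900\t1200\tbad")
  expect_error(load_regions(fx2$bed, fx2$fa, "s", "enhancer"),
               "out of chromosome bounds.*bad")
  fx3 <- write_fixture(c(chr1 = random_dna(1000)), "chr9\t0\t100\tx")
  expect_error(load_regions(fx3$bed, fx3$fa, "s", "enhancer"), "chr9")
})

test_that("backgrounds are placed downstream, upstream as fallback, or absent", {
  set.seed(13)
  chrom <- random_dna(400000)
  fx <- write_fixture(c(chr1 = chrom), c(
    "chr1\t200000\t203000\tmid",    # room downstream
    "chr1\t350000\t353000\tlate",   # downstream blocked, upstream free
    "chr1\t10\t3010\tearly"))       # no room either side? downstream fits
  pairs <- build_backgrounds(load_regions(fx$bed, fx$fa, "s", "enhancer"),
                             offset = 1e5)
  mid <- pairs[pairs$region_id == "mid", ]
  expect_identical(c(mid$bg_start, mid$bg_end), c(303000, 306000))
  expect_identical(mid$bg_flag, "downstream")
  expect_identical(mid$bg_seq, substr(chrom, 303001, 306000))
  late <- pairs[pairs$region_id == "late", ]
  expect_identical(late$bg_flag, "upstream")
  expect_identical(c(late$bg_start, late$bg_end), c(247000, 250000))
  # short chromosome: neither side fits
  fx2 <- write_fixture(c(chr1 = random_dna(150000)), "chr1\t50000\t53000\tx")
  p2 <- build_backgrounds(load_regions(fx2$bed, fx2$fa, "s", "enhancer"),
                          offset = 1e5)
  expect_true(is.na(p2$bg_start))
  expect_identical(p2$bg_flag, "no_room")
})

test_that("missing-data filter drops backgrounds strictly above 50% N", {
  set.seed(14)
  base <- strsplit(random_dna(210000), "")[[1]]
  # fg [0,1000); bg lands at [101000,102000)
  over <- base; over[101001:101501] <- "N"   # 501 N of 1000
  at <- base;   at[101001:101500] <- "N"     # exactly 500 N
  for (cs in list(list(seq = over, drop = TRUE),
                  list(seq = at, drop = FALSE))) {
    fx <- write_fixture(c(chr1 = paste(cs$seq, collapse = "")),
                        "chr1\t0\t1000\tr1")
    p <- filter_missing(build_backgrounds(
      load_regions(fx$bed, fx$fa, "s", "promoter"), offset = 1e5))
    expect_identical(is.na(p$bg_seq), cs$drop)
  }
  # idempotence
  panel <- small_panel(seed = 3)
  pp <- panel_pairs(panel, "sp1", "promoter")
  expect_identical(filter_missing(pp), pp)
})

test_that("conserved-region filter removes flagged pairs and warns on unknowns", {
  panel <- small_panel(seed = 3)
  pp <- panel_pairs(panel, "sp1", "promoter")
  ids <- pp$region_id
  tab <- data.frame(region_id = ids,
                    conserved = seq_along(ids) <= 3)
  out <- filter_conserved(pp, tab)
  expect_identical(nrow(out), nrow(pp) - 3L)
  expect_warning(
    all_kept <- filter_conserved(pp, tab[0, ]),
    "absent from conservation table")
  expect_identical(nrow(all_kept), nrow(pp))
  none <- filter_conserved(pp, transform(tab, conserved = TRUE))
  expect_identical(nrow(none), 0L)
})

test_that("region summaries report counts, mean and n-1 SD", {
  set.seed(15)
  chrom <- random_dna(400000)
  fx <- write_fixture(c(chr1 = chrom),
                      c("chr1\t1000\t2000\ta", "chr1\t50000\t53000\tb"))
  p <- build_backgrounds(load_regions(fx$bed, fx$fa, "s", "enhancer"),
                         offset = 1e5)
  s <- summarize_regions(p)
  expect_identical(s$n_foreground, 2L)
  expect_equal(s$length_mean, 2000)
  expect_equal(s$length_sd, sd(c(1000, 3000)), tolerance = 1e-12)
  one <- summarize_regions(restrict <- p[1, , drop = FALSE])
  expect_identical(one$length_sd, 0)
  expect_false(one$sd_defined)
})

test_that("retained backgrounds mirror foreground lengths and genome slices", {
  panel <- small_panel(seed = 3)
  for (cls in c("enhancer", "promoter")) {
    pp <- panel_pairs(panel, "sp1", cls)
    has <- !is.na(pp$bg_start)
    expect_true(all((pp$bg_end - pp$bg_start)[has] ==
                      (pp$fg_end - pp$fg_start)[has]))
    genome <- panel$species$sp1$genome
    expect_identical(pp$fg_seq,
                     unname(substring(genome[pp$chrom], pp$fg_start + 1,
                                      pp$fg_end)))
    expect_identical(pp$bg_seq[has],
                     unname(substring(genome[pp$chrom[has]],
                                      pp$bg_start[has] + 1, pp$bg_end[has])))
  }
})

test_that("stippled N runs are confined to backgrounds and trigger the filter", {
  spec <- small_panel_spec(seed = 9, n_stipple_rate = 0.5)
  panel <- generate_panel(spec)
  pp <- build_backgrounds(pairs_from_panel(panel, "sp1", "promoter"))
  expect_false(any(grepl("N", pp$fg_seq, fixed = TRUE)))
  expect_true(any(grepl("N", pp$bg_seq, fixed = TRUE)))
  kept <- filter_missing(pp)
  expect_true(any(kept$bg_flag == "missing"))
  expect_true(all(kept$bg_n_frac[!is.na(kept$bg_seq)] <= 0.5))
})
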