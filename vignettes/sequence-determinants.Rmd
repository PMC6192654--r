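---
title: "Methods: discovering and transferring regulatory sequence determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and transferring regulatory sequence determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `seqdet`, the design of
its synthetic-data generator, and the numerical and design choices a
maintainer would want to know about. The package's subject is the
"sequence determinant" analysis of regulatory regions: finding k-mers that
statistically separate enhancers and promoters from their local genomic
background, and asking whether the predictive information they carry
transfers between species even though the regions themselves do not align.

## The statistical model

**Enrichment.** For a k-mer *w* and a set of region pairs, the unit of
observation is the sliding window (1-bp step). The 2×2 table counts windows
equal to *w* versus all other windows of the same length, in foregrounds
versus backgrounds; windows containing a non-ACGT character are excluded
from both numerator and denominator, so frequencies remain
composition-honest in the presence of missing bases. The effect size is the
odds ratio OR = N₁₁N₂₂/(N₁₂N₂₁); when any cell is zero the reported OR uses
the Haldane–Anscombe +0.5 correction but the test always uses raw counts.
The test is Pearson's χ² without continuity correction, routed to the
two-sided Fisher exact test (point-probability method) whenever any
expected cell is below 5. The omission of the Yates correction is
deliberate: it keeps the single-stratum χ² consistent with the
Cochran–Mantel–Haenszel score statistic used for the cross-species test,
which equals (N−1)/N times the Pearson statistic on one stratum.

Windows overlap, so neighbouring window outcomes are not independent and
the nominal χ² calibration is approximate. The package treats the
Benjamini–Hochberg step as a pragmatic multiplicity control, applied
jointly across all fragment lengths within one species × class (the
stricter of the two possible readings of a per-length versus joint family),
and the null-panel calibration test below measures the realised false
discovery behaviour directly rather than assuming it.

**Eligibility.** Only fragments whose combined count strictly exceeds 100
are tested. This mirrors the practical observation that almost all long
fragments occur once or twice (at k = 15 nearly all windows are unique), and
it has a structural consequence the synthetic design must respect: a
fragment whose expected count sits below the threshold is *untestable*, no
matter how strong its planted effect.

**Common determinants.** A fragment eligible in every species is tested with
the CMH statistic [Σₖ(N₁₁ₖ−E₁₁ₖ)]²/ΣₖVarₖ, Varₖ =
N₁₊ₖN₂₊ₖN₊₁ₖN₊₂ₖ/(N₊₊ₖ²(N₊₊ₖ−1)), df = 1, no continuity correction; strata
with total ≤ 1 are skipped with a flag. The common-determinant call
additionally requires the per-species OR to exceed 1 in *every* species —
a deliberately conservative "all species" rule.

**Prediction.** Each foreground/background region is one binary observation
(foreground = 1); each determinant contributes its per-region relative
frequency (occurrences over valid windows of its length). Columns are
standardised and the standardisation parameters are frozen into the model,
so a model transferred to another species scores new regions on the
training scale (re-standardising on the test species would leak test
information into the transfer). Penalty selection maximises the mean
held-out ROC-AUC over label-stratified 10-fold CV along a ≥ 50-value
log-spaced path starting from the all-zero penalty; ties prefer the larger
penalty. ROC-AUC uses the rank (Mann–Whitney) formulation with mean ranks
for ties; PR-AUC integrates precision over distinct recall steps by the
trapezoidal rule with tied scores grouped.

**Effect-size factors.** log₂(OR) is regressed on GC content, a TFBS
measure (frequency of significant motif-database hits, or −log₁₀min(P)),
and their product. The interaction is retained only when its p-value in the
full fit is strictly below 0.05; otherwise the main-effects model is
refit — the rule is a pure function of that single p-value, and a
zero-residual (saturated) fit is treated as "not significant". Type III
partial sums of squares are computed by explicit refits without each term;
at these problem sizes (thousands of rows, 3 terms) the cost of refitting
is negligible and the result is definitionally transparent.

## The synthetic-data generator

The generator exists so that every downstream claim can be tested against
known truth. It emulates, per species:

* an i.i.d. nucleotide genome at `background_gc` (default 0.41, a
  mammalian-like value);
* a per-region-pair *local* GC level (`regional_gc_sd`, default 0.06)
  shared by a foreground and its reserved background. This mimics the
  isochore-scale regional GC correlation that motivates taking backgrounds
  only 100 kb away in the first place. It matters for one specific reason:
  without it, a +0.10 foreground GC shift makes region GC a perfect
  classifier of 2-kb regions (binomial noise at that length is ~1 GC point),
  whereas the phenomenon being modelled is a GC-only baseline that is
  informative but clearly below the determinant models. Because the local
  level is shared within a pair, it cancels from the paired
  foreground-background contrast and leaves null calibration intact;
* foreground regions whose composition is shifted by `fg_gc_shift`
  (promoters +0.10 by default, matching the observed average
  foreground-background GC difference; enhancers 0);
* planted determinant k-mers. For k-mer *w* with target odds ratio *r*, the
  number of inserted copies is Poisson with mean
  (r·p_bg − p_fg)·W_fg, where p_bg/p_fg are the analytic per-window
  occurrence probabilities under the realised local compositions and W_fg
  the total foreground window count — so the expected
  foreground/background frequency ratio equals *r* as a population
  parameter. Insertions replace existing bases at uniformly random,
  non-overlapping positions, keeping window totals exact.

**Region layout.** Foregrounds sit at the starts of uniform slots of size S,
with the reserved background of each region exactly `offset` bp downstream
of its end. S is searched so that, over the whole attainable length range,
(length + offset) mod S keeps every background inside the empty part of a
slot. This makes all foregrounds and backgrounds pairwise disjoint by
construction, at the cost of a packing density of roughly one region per
3 × (max length): the default two-class panel (2 × 300 regions of mean 2 kb,
SD 400 bp truncated at ±4 SD) therefore lives on a 7-Mb chromosome, and the
1-Mb null-calibration panels use 200 fixed-length 1-kb regions per class
(fixed lengths maximise the number of fragments that clear the count
filter; under the null the length distribution is irrelevant). The regular
slot spacing is a simplification — real regions cluster — but none of the
statistics consume inter-region distances.

**The planted pool.** Defaults: ten enhancer 6-mers at OR 1.5 and ten
promoter 6-mers at OR 3, the promoter > enhancer ordering being the
effect-size contrast the analysis is designed to detect. K-mer composition
is constrained by two analytic requirements at the default panel scale
(~6×10⁵ windows per side):

* *eligibility* — the expected background count must exceed ~25 so that the
  total clears the >100 filter at OR 3 (this rules out ≥5 GC bases per
  6-mer);
* *artifact control* — every insertion of *w* also increments the
  overlapping "shifted" k-mers that share 5 bases of *w* plus one flanking
  base, and the constituent k-mers of any longer planted k-mer inherit its
  full insertion count. The insertion count must therefore stay small
  enough that no such variant accumulates a significant excess of its own
  (this rules out very abundant, AT-rich k-mers at large target ORs, and
  rules out planted 7-mers entirely at this scale).

Enhancer k-mers use 1–2 GC bases (abundant, so OR 1.5 is reliably
detectable); promoter k-mers mix 4 and 3 GC bases. The GC-3 half sits at
GC = 0.5, inside the inclusive low-GC band, so that the low-GC determinant
model carries planted motif signal — the synthetic analogue of real low-GC
determinants being informative motifs rather than composition proxies.
Residual flank artifacts do appear among called determinants (they are
genuinely enriched sub-signals, not false positives of the test), which is
why planted-recovery checks match on the planted k-mers themselves.

**What the generator does not emulate.** Repeats, CpG islands as discrete
elements, transposable elements, genes, phylogenetic relatedness of the
genomes (species are independent draws; "sharing" of the pool is the only
cross-species coupling), ChIP-seq peak-calling noise, and strandedness
(regions are forward-strand literals; no reverse-complement collapsing, a
`--canonical`-style merge being intentionally absent because the counting
convention treats a k-mer and its reverse complement as distinct signals).
Passing tests therefore demonstrate that the *pipeline* recovers what was
planted under its own assumptions — not that real enhancers follow an
i.i.d. composition model.

## Numerical choices and degenerate inputs

* Counts are accumulated in doubles end-to-end; margin products inside the
  CMH variance are forced to double precision (they overflow 32-bit
  integers at realistic scales).
* Fisher p-values sum hypergeometric point probabilities ≤ the observed one
  inflated by 1+10⁻⁷, matching the reference implementation's tolerance.
* Backgrounds are placed downstream first, upstream as fallback, flagged
  absent when neither fits; backgrounds with strictly more than 50% missing
  bases are dropped (exactly 50% is retained). Pairs that lose their
  background are excluded from both sides of the count table, keeping the
  2×2 margins comparable; their foregrounds still appear as prediction
  rows.
* Stratified sampling uses largest-remainder (Hamilton) apportionment with
  ties going to the smaller stratum; quotas never exceed stratum sizes,
  with any rounding excess redistributed down the remainder order.
* Constant feature columns are dropped (flagged) before standardisation;
  columns missing at transfer are zero-filled before the standardisation
  shift and counted in the evaluation.
* All randomness flows from explicit seeds; package functions restore the
  caller's RNG state, and the pipeline derives per-stage seeds from one
  master seed by stage-name hashing, so re-running a configuration is
  byte-identical (verified by manifest checksums).

## Validation study sizes

The shipped validation uses: 20 null panels (2 species × 1 Mb, 200 regions
per class, k 6–8) for calibration; 20 planted panels (300 × 2-kb regions
per class, no GC shift) for OR recovery and the class contrast; 3 study
panels (defaults, promoter +0.10 GC shift) for the prediction orderings;
2 × 20 three-species panels for transfer (shared versus disjoint pools);
and 100 replicates of the factor-model recovery at n = 1342 with
generating coefficients (6.40, 22.65, −41.84) and R² 0.36 — coefficient
magnitudes taken from the published human-promoter fit so that recovery is
tested at a realistic signal-to-noise. These sizes give the property checks
comfortable Monte-Carlo margins while keeping a full run at desk scale.

## Known limitations

* The enrichment tests inherit the usual overlap-dependence caveat of
  sliding-window counting; highly periodic k-mers (near-homopolymers) have
  clumped occurrences and slightly anti-conservative single-fragment
  p-values. The null-panel check bounds the practical consequence.
* The frequency-ratio planting calibration targets the odds ratio of rare
  fragments (OR ≈ frequency ratio); for extremely abundant fragments the
  two diverge, another reason the default pool avoids the AT-rich extreme.
* `low_gc_subset` and the matched-null sampler can return fewer fragments
  than requested on small panels; both warn and proceed with the partial
  set.
* Cross-species transfer assumes the test species' regions are scored with
  the training species' standardisation; if the two species differ grossly
  in background composition the frozen scale is a modelling choice, not a
  neutral one.
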