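# seqdet — sequence determinants of regulatory regions

Epigenomic profiling (H3K27ac, H3K4me3 ChIP-seq) maps enhancers and
promoters genome-wide, and comparative studies show that their *locations*
diverge rapidly between mammals. Yet regulatory regions can be predicted
from sequence alone with high accuracy — which suggests that the short
sequence fragments encoding regulatory potential are themselves conserved
even where the regions are not. `seqdet` implements the full analysis
pipeline behind that question, for computational biologists who want to run
it, test it, or stress it on data with known truth:

1. **Exhaustive search.** Every k-mer (k = 6…15) is counted in 1-bp sliding
   windows over foreground regions (enhancers or promoters) and same-length
   background segments placed 100 kb away on the same chromosome. For each
   fragment a 2×2 table (N₁₁, N₁₂, N₂₁, N₂₂) is tested with the Pearson χ²
   test (Fisher's exact test when any expected cell < 5); fragments with
   total count > 100, BH-FDR Q ≤ 0.05 and odds ratio
   OR = N₁₁N₂₂/(N₁₂N₂₁) > 1 are *species sequence determinants*.
2. **Common determinants.** Fragments eligible in every species are tested
   with the Cochran–Mantel–Haenszel statistic
   \[Σₖ(N₁₁ₖ−E₁₁ₖ)\]² / Σₖ Varₖ across species strata; a *common
   determinant* has CMH Q ≤ 0.05 and per-species OR > 1 in **all** species.
3. **Prediction.** 10,000 determinants are sampled with stratification by
   GC-content bin ([0–0.1], (0.1–0.2], …) × length; their per-region
   relative frequencies feed an L1-penalised (LASSO) logistic model with the
   penalty chosen by 10-fold cross-validated ROC-AUC. Models are evaluated
   same-species (CV ROC/PR-AUC) and cross-species (a model trained on
   species A scored on species B with frozen standardisation), against
   GC-only, low-GC-determinant (GC ≤ 0.5) and GC/length-matched
   non-determinant baselines.
4. **Effect-size factors.** Determinant effect sizes are modelled as
   log₂(OR) ~ GC + TFBS + GC×TFBS (the interaction dropped when not
   significant at p = 0.05), with Type III partial sums of squares; TFBS
   frequencies come from TOMTOM-format motif-comparison output or a
   synthetic annotation generator.

Real mammalian ChIP-seq inputs are deliberately out of scope: every stage is
driven by a **synthetic multi-species genome generator** that plants
determinant k-mers at known target odds ratios, shifts promoter foreground
GC by a configurable amount (+10 points by default), gives each
foreground/background pair a shared local "isochore" GC level, and emits
FASTA/BED plus a truth table — so recovery, calibration and transfer can be
measured exactly.

## Worked example

```r
library(seqdet)

spec  <- panel_spec(seed = 42)          # 2 species, 300 enhancers + 300 promoters
panel <- generate_panel(spec)

pairs <- filter_missing(build_backgrounds(
  pairs_from_panel(panel, "sp1", "promoter")))
det   <- call_species_determinants(build_count_table(pairs, 6, 8))
dd    <- det[det$is_determinant, ]
nrow(det); nrow(dd)
#> [1] 5432
#> [1] 1524

samp <- stratified_sample(dd, n = 10000, seed = 3)
fit  <- fit_lasso_cv(build_feature_matrix(pairs, samp$kmer), seed = 7)
fit$evaluation$roc_auc
#> [1] 0.9762222
gc_only_model(pairs, seed = 7)$roc_auc
#> [1] 0.8898333
```

Of 5,432 testable fragments, 1,524 are called promoter determinants (the
+10-point GC shift makes GC-rich k-mers genuinely enriched, alongside the
ten planted k-mers at OR 3). The LASSO model separates promoters from their
backgrounds with CV ROC-AUC ≈ 0.98, while region GC content alone reaches
only ≈ 0.89 — determinants carry information beyond composition.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the whole study on synthetic
panels and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the study, null, contrast and transfer panels |
| `02_discover_determinants.R` | exhaustive search, common determinants, enhancer-vs-promoter OR contrast |
| `03_predict.R` | LASSO models, baselines, cross-species AUC matrix |
| `04_factor_model.R` | GC/TFBS effect-size model + parameter-recovery simulation |
| `05_transfer.R` | three-species shared-pool transfer (relative AUC ≈ 1) |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

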