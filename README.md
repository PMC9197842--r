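# chromarch

Multi-scale chromatin architecture analysis for binned Hi-C contact
maps, written for epigenomics studies that track how genome
organization changes across conditions — developmental stages, diets,
treatments — and how those changes relate to gene regulation.

From per-chromosome sparse contact matrices, chromarch computes:

* **Von Neumann entropy** of the log-contact correlation matrix
  (`VNE = -Σ λ̄ᵢ ln λ̄ᵢ` over the normalized eigenvalue spectrum):
  a per-chromosome measure of structural disorder.
* **A/B compartments**: PC1 of the O/E correlation matrix at coarse
  resolution, oriented by GC/gene density; the fine-scale **A-B index**
  `(Ī_A − Ī_B)/(Ī_A + Ī_B)`; replicate consensus (> half agreeing);
  **compartmentalization strength** `AA·BB/AB²`; saddle plots; and
  stage-to-stage switch regions.
* **TADs** by directionality-index HMM
  (`DI = sign(B−A)·((A−E)²/E + (B−E)²/E)`) and insulation-score minima,
  merged into one partition; consensus TADs across samples; and the
  **D-score** (intra-TAD contacts / all contacts touching the TAD).
* **Regulatory potential**: promoter–enhancer interactions from 5-kb
  maps with a distance-decay null, per-gene
  **RPS = Σ log₁₀(Iₙ)** over interacting enhancers (Iₙ > 1), ROSE-style
  super/regular/poised enhancer classes, and the differential-RPS rule
  (|log₂FC| > 2 and |ΔRPS| > 3).
* **Integration**: chromosome form–function phase portraits (Fiedler
  number × mean TPM), exact Wilcoxon rank-sum tests, and trait-SNP
  enrichment scores `(k/L_r)/(K/L_g)` with χ² tests.

A first-class synthetic-data module plants compartments, TADs and loops
with serialized ground truth, so the entire pipeline is testable without
any external data.

## Worked example

Simulate a two-stage series in which structure solidifies (noise falls,
compartment contrast and TAD boost rise), then run the full analysis:

```r
library(chromarch)

cfg <- smoke_config(seed = 1)        # 1 chromosome, 2 stages x 2 replicates
sim <- simulate_stage_series(cfg)
res <- analyze_stage_series(sim = sim)

res$vne
#> # A tibble: 2 × 4
#>   stage chromosome   vne n_bins
#>   <int> <chr>      <dbl>  <int>
#> 1     1 chrS1       2.76    120
#> 2     2 chrS1       2.59    120

res$strength
#> # A tibble: 2 × 6
#>   stage chromosome    AA    BB    AB strength
#>   <int> <chr>      <dbl> <dbl> <dbl>    <dbl>
#> 1     1 chrS1       1.12  1.15 0.866     1.71
#> 2     2 chrS1       1.27  1.30 0.718     3.19
```

Entropy falls from stage 1 to stage 2 (2.76 → 2.59 nats: the map is
becoming more ordered) while compartmentalization strength nearly
doubles (1.71 → 3.19: within-class contacts strengthen relative to
cross-class ones) — exactly the planted trend. Domains carry their
connectivity scores:

```r
head(res$dscore, 4)
#> # A tibble: 4 × 5
#>   chrom start_bin end_bin d_score stage
#>   <chr>     <int>   <int>   <dbl> <int>
#> 1 chrS1         0      28   0.416     1
#> 2 chrS1        28      37   0.257     1
#> 3 chrS1        37      50   0.324     1
#> 4 chrS1        50      57   0.263     1

attr(res$switches, "switched_bp")
#> [1] 580000
```

580 kb switched compartment between the stages — the generator flipped
600 kb, and `detect_switches()` recovers it from the consensus calls.
`plot_saddle()`, `plot_track()` and `plot_phase_portrait()` draw the
standard figures; `tidy()`/`glance()` methods return tidy summaries.

A thin command-line wrapper is installed with the package
(`exec/chromarch`): `chromarch simulate --preset smoke --seed 1 --out DIR`
writes the synthetic inputs (triplet maps, chrom.sizes, truth.json),
`chromarch analyze` additionally writes the result tables as TSV.

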