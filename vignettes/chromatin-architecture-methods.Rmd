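---
title: "Quantifying multi-scale chromatin architecture with chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-scale chromatin architecture with chromarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromarch)
```

## What the package measures

Hi-C experiments yield, per chromosome, a symmetric matrix of contact
counts between fixed-width genomic bins. chromarch quantifies the
hierarchy of structure in such matrices at four scales, with the
statistics developmental chromatin studies report:

* **Global disorder** — the Von Neumann entropy (VNE) of the correlation
  matrix of the log contact map at 100-kb resolution. A perfectly
  coherent (rank-1) correlation structure has entropy 0; fully
  incoherent structure approaches `ln n`. In maturing tissue, mean VNE
  falls as architecture solidifies.
* **A/B compartments** — the leading eigenvector (PC1) of the O/E
  correlation matrix at 100 kb, oriented by GC content or gene density
  and refined to 20 kb by the A-B index: the normalized contrast between
  a bin's mean O/E contact with A- versus B-classified coarse bins.
  Compartmentalization strength is `AA * BB / AB^2` over class-pair
  means of O/E; saddle plots visualize the same segregation.
* **TADs** — called twice, by a 3-state Gaussian HMM on the
  directionality index (DI) and by insulation-score (IS) minima, then
  merged; domain connectivity is the D-score, the fraction of a domain's
  cis contacts staying inside it.
* **Regulatory wiring** — promoter-enhancer interactions (PEIs) from
  5-kb maps, summarized per gene as the regulatory potential score
  `RPS = sum(log10 In)` over interacting enhancers, with enhancer
  activity classes (super/regular/poised) from rank-ordered H3K27ac
  signal, and cross-modality statistics (form-function phase portraits,
  exact Wilcoxon tests, trait-SNP enrichment).

## Normalization

Raw maps are balanced to equal row sums by the symmetric
diagonal-scaling fixed point (`kr_balance()`): `diag(b) A diag(b)` with
unmasked row sums 1, converged when the coefficient of variation of row
sums drops below `1e-6` (cap 1000 iterations). Bins with zero marginal
are masked first — the scaling diverges on empty rows; a coverage
quantile mask is available but off by default. The target row sum is a
free scale; 1 is used throughout, and statistics that need count-scale
values (the PEI intensities, below) rescale explicitly.

Across samples, distance-stratified quantile normalization
(`quantile_normalize()`) replaces each diagonal stratum's sorted
non-zero values by rank-wise means across samples. Both normalizations
are named by the source study without an ordering; balancing is applied
first here because strength and saddle statistics require balanced
inputs. Whether quantile normalization should act on matrix entries or
only on derived statistics is genuinely open; entry-level,
distance-stratified normalization is this package's documented choice
and sits behind a flag. With unequal non-zero counts per stratum the
mean quantile function is linearly interpolated (the limma convention).

## Numerical choices

* **VNE**: eigenvalues of the correlation matrix are clamped at 0 before
  normalization (the matrix is PSD up to round-off); entropy uses
  natural logs; `0 ln 0 = 0`. The log pseudocount defaults to one
  raw-count-equivalent rescaled through the balancing biases, keeping
  zeros finite without distorting large entries.
* **DI**: the source study cites but does not print the DI formula; the
  signed chi-square form
  `sign(B - A) ((A-E)^2/E + (B-E)^2/E)`, `E = (A+B)/2`, over the ten
  bins on each side is adopted and stated so tests are well defined.
  Because DI is heavy-tailed (near-zero interior, chi-square spikes at
  boundaries), HMM emissions are fit on `sign(DI) sqrt(|DI|)` — a
  monotone, sign-preserving transform that stabilizes the Gaussian EM
  without changing which bins count as upstream- or downstream-biased.
  EM uses quantile initialization, a variance floor, and falls back to
  quantile thresholds with a warning if it fails to converge.
* **IS**: window 500 kb (25 bins at 20 kb), boundary prominence at
  least 0.1 — common insulation practice, config-exposed; the study
  names neither. A boundary must additionally be the minimum within 4
  bins on each side, which suppresses shallow interior dips. Windows
  with zero contact are floored at half the smallest positive window
  mean so a fully insulated junction scores a deep finite minimum.
* **Ties**: a PC1 or A-B index of exactly 0 is labelled Un rather than
  inflating either class. The 80% purity rule for consensus-TAD status
  is inclusive (exactly 80% counts). Replicate consensus requires
  strictly more than half of the replicates (4 of 6).
* **PEI calling** (`call_peis_simple()`) is a deliberately simple
  surrogate for hierarchical-background callers: per-distance null
  moments are estimated from all bins of the chromosome (upper 0.5%
  trimmed so genuine loops do not inflate the null), a negative
  binomial (Poisson when not overdispersed) upper tail is computed on
  raw counts — a normal tail badly underestimates p on sparse far
  diagonals — and Benjamini-Hochberg correction is applied per
  promoter. There is no hierarchical domain background and no 20-Mb
  windowing. Intensities `In` are observed minus expected on the
  balanced matrix, rescaled to count units so the `In > 1` inclusion
  rule for RPS has its intended meaning; `log10` of intensities at or
  below 1 would be non-positive or undefined, so they are excluded
  (a clamp-to-1 alternative is available).
* **Differential RPS**: `|log2 FC| > 2` and `|delta RPS| > 3`, both
  strict; an RPS of exactly 0 is replaced by 0.1 inside the fold change
  only.
* **Phase portraits**: axes (Fiedler number of the contact network;
  mean TPM) are z-normalized per chromosome across stages with the
  population (1/n) standard deviation, so two stages on one axis sit at
  z = +/-1 and are distance 2 apart. The Fiedler number uses the
  unnormalized Laplacian of the largest connected component (a
  normalized variant is available); the source method's own scaling is
  not reproduced in the study, so commensurable axes require a declared
  choice.
* **Exact Wilcoxon**: full enumeration of group assignments for
  `n + m <= 12` with mid-rank ties; tie-corrected, continuity-corrected
  normal approximation beyond.

## The synthetic generator

`sim_config()` / `simulate_stage_series()` plant the structures the
pipeline is meant to recover: a bin-pair probability model
`P(i,j) ~ (1 + |i-j|)^-alpha (1 + s c_i c_j) beta^[same TAD]` times
loop boosts, mixed with uniform noise at weight `w`, sampled
multinomially. Defaults are a desk-scale study: two 30-Mb chromosomes
at 20-kb working resolution, 2e6 contacts per replicate, 6 replicates
over 4 stages, with `w` falling (0.35 to 0.05) and `s` (0.25 to 0.55)
and `beta` (1.6 to 2.2) rising across stages — the generative analogue
of architecture solidifying during development. Decay `alpha = 1` is a
typical contact-decay slope; planted TADs span 300 kb-1 Mb; loops are
implanted only at >= 20 kb separation so the PEI distance filter is
exercised. Expression is linked generatively
(`log TPM = mu + a 1[A] + b link + c RPS + noise`), SE clusters are
runs of high-signal peaks within the ROSE merge gap, and SNPs are drawn
with a planted density ratio inside enhancer footprints.

What the generator does **not** emulate: polymer physics, single-cell
heterogeneity, translocations, copy-number effects, mappability
artifacts, or realistic peak shapes. Passing recovery tests therefore
demonstrates correctness of the estimators under a known sampling
model, not performance on tissue Hi-C; headline values from deep
sequencing experiments (tens of billions of contacts) are not
reproducible at these problem sizes, and the test suite asserts
recovery of *planted* structure instead.

Problem sizes used by the tests and the acceptance script — 300 bins at
100 kb for entropy, 1500 bins at 20 kb for compartments and TADs, 1200
bins at 5 kb for PEIs, 10 seeds per property — were chosen as the
smallest sizes at which the sampling properties stabilize.

## Known limitations

* One chromosome per contact-map object; inter-chromosomal matrices are
  out of scope.
* The PEI caller is a surrogate; its calls should not be compared
  call-for-call against hierarchical-background callers on real data.
* The DI HMM assumes three states with Gaussian emissions on the
  transformed scale; exotic DI distributions may favor the IS caller,
  which is why both are run and merged.
* Consensus TADs use greedy boundary clustering (+/-1 bin); pathological
  boundary jitter beyond that tolerance splits clusters.
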