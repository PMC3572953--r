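---
title: "Cross-species mapping of airway hyperresponsiveness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species mapping of airway hyperresponsiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahrgwas)
```

## Overview

`ahrgwas` chains five analysis stages: an airway hyperresponsiveness (AHR)
slope phenotype from methacholine dose–response curves; a kinship-corrected
mixed-model genome scan across inbred mouse strains; a gene-window /
ortholog-map bridge into the human genome; a screen of multi-ancestry human
GWAS summary statistics over those ortholog windows; and a direction-aware
replication meta-analysis. A seeded synthetic-data generator with recorded
ground truth stands in for the original cohort data. This vignette documents
the models, the tunable parameters, the numerical choices, and the limits of
what the synthetic tests establish.

## The phenotype: slope of resistance on log dose

Each animal receives a baseline/saline reading (recorded with dose 0) and
readings at 1, 3, 10 and 30 mg/ml nebulized methacholine. AHR is the
ordinary least-squares slope of resistance on log10(dose), over the nonzero
doses only — the log of dose 0 is undefined, so saline rows never enter the
fit. Log base 10 is pinned deliberately: the doses span 1.5 decades, and
base-10 slopes land on the 0.4–1.7 scale familiar from strain-survey data
(base-e would multiply every slope by ln 10 ≈ 2.303; a unit test asserts
this conversion factor).

Slopes are fitted **per animal** and then averaged per strain (mean, SEM =
sample SD / √n). The alternative — one pooled regression per strain — would
not produce the per-strain SEMs that strain surveys report, and weights
animals with more retained readings unequally. Sexes are pooled by default;
`summarize_strains(sex =)` filters.

## The mixed model

Strain mean slopes `y` (one per strain, n ≈ 31) are modeled as

    y = Xβ + u + ε,  Var(u) = σ_g² K,  Var(ε) = σ_e² I

with `K` the identity-by-state (IBS) kinship: entry (i, j) is the fraction
of SNPs at which strains i and j carry the same homozygous call, computed
over SNPs non-missing in both, with unit diagonal. IBS is the conventional
estimator for inbred panels; an allele-frequency-standardized relatedness
would change the scale of `σ_g²` but not the GLS tests.

### REML over the variance ratio

Writing `δ = σ_e²/σ_g²`, the restricted likelihood is profiled over δ
through the spectral decomposition of the kinship projected off the fixed
effects. Numerically we decompose `S(K + I)S` (with
`S = I − X(X'X)⁻¹X'`) rather than `S K S`: the +I shift keeps the
residual-space eigenvalues (≥ 1) cleanly separated from span(X)
(eigenvalues 0) even when K is nearly low rank, which matters because
family-structured IBS matrices concentrate their variation in a few
dimensions. (During development, decomposing `S K S` directly let
near-null-space eigenvectors mix with the intercept direction and leak the
phenotype mean into the rotated residuals — an error invisible at n = 31
with well-conditioned K and catastrophic at n = 200.)

The optimum over `ln δ ∈ [−10, 10]` is located on a 100-point grid with
safeguarded Newton refinement (bisection fallback) at every sign change of
the derivative; the global optimum over all refined candidates and both
endpoints is returned. An acceptance test holds the optimizer to within
1e-3 of a 1000-point brute-force grid evaluated through the independent
determinant-form likelihood.

### Per-SNP testing and the default mode

Each SNP enters the fixed effects; the data are rotated by the eigenbasis
of `K + δI` and the SNP coefficient is tested with a t statistic on
`n − rank([X, snp])` degrees of freedom. With `K = I` this is *exactly* the
OLS t-test (the δ scaling cancels), which the suite asserts to 1e-8.

**Default δ: null model, not per-SNP.** Re-estimating δ with the SNP in the
model ("exact" mode) is often described as the more rigorous choice, and it
is available via `mode = "exact"`. Measured at this package's stated world
(31 strains), however, it inflates type-I error: pooled λ_GC ≈ 1.20 versus
≈ 1.00 for a single null-model δ, while an oracle using the *true* variance
components confirms the rest of the machinery is calibrated. With ~29
residual degrees of freedom the marker overfits the variance ratio — SNPs
that chance-correlate with the phenotype drag δ toward the boundary and
shrink their own standard errors. The null-model approximation (the
EMMAX/P3D construction) is therefore the default.

### Heritability on the strain scale

`reml_fit` reports `σ_g²/(σ_g² + σ_e²)` on the scale of the supplied K.
Raw IBS carries a large constant baseline (any two inbred strains agree at
most SNPs) that the intercept absorbs, so that ratio is *not* the fraction
of strain-to-strain variance that is genetic. `heritability_estimate`
rescales `σ_g²` by the Gower factor of K — the expected sample variance
across strains of a unit-`σ_g²` genetic value — which puts the estimate on
the same scale as the generator's `heritability` parameter and as the
realized variance-ratio one would compute from the simulated genetic
values. Recovery tests run on both scales' common ground: mean estimates
0.21/0.42/0.67 at targets 0.2/0.5/0.8 with 31 strains (within the ±0.15
band, dominated by the small panel), and within ±0.1 at 200 strains.

## Mouse→human bridge

Genes with a sub-threshold SNP (p < 0.001, strict) within 50 kb are
selected; distance is 0 inside the gene body and the gap to the nearest
edge otherwise, with the window boundary inclusive (a SNP exactly 50,000 bp
away counts; 50,001 does not). Coordinates are 1-based inclusive
throughout; coordinate pairs printed in descending order (minus-strand
genes) are normalized on read, and strand is ignored for distance.
One-to-many homology is retained in full — collapsing to a "best" ortholog
discards paralogy information irreversibly, and candidate counts under the
published procedure are plain set memberships.

## Human screen and candidate filters

Each study/ancestry analysis is an independent stream; a gene is a
candidate when *any* stream has a SNP with p < 0.001 (strict) in the gene ±
50 kb window — the streams combine by union, matching the "and/or"
semantics of multi-ancestry screens. Three filters that published analyses
applied by inspection are made explicit and testable:

* `mouse_maf_filter` — every sub-threshold SNP in the mouse region must
  rest on a minor allele in strictly more than 2 strains (2/31 fails).
* `concordance_score` — rank-biserial correlation between the two
  homozygote classes and strain slopes plus a Wilcoxon rank-sum p. The
  rank-biserial form (`2U/(n₀n₂) − 1`) is used rather than the
  point-biserial because it reaches exactly ±1 under perfect class
  separation and 0 for identical class distributions — the behaviour the
  qualitative "phenotype distribution matches genotype distribution"
  criterion demands; the point-biserial is returned alongside.
* `regional_support` — the count of sub-threshold SNPs per region and
  species, with a configurable two-species minimum (default 2), standing in
  for "supported by a region of LD" without a reference LD panel.

## Replication meta-analysis

Effect directions are only comparable after allele harmonization: a
record's allele pair is matched to the discovery study's directly or via
strand complement, the effect is flipped once (OR → 1/OR, β → −β) when the
pairs are swapped, and A/T / C/G SNPs — where strand cannot be resolved
from the alleles alone — are flagged but kept (exclusion is a caller
choice; silently dropping them biases coverage).

Replication two-sided p-values become one-sided against the discovery
direction: `p/2` when directions agree, `1 − p/2` when they disagree, so an
opposite-direction effect can never masquerade as replication. The
discovery p enters Fisher's combination as reported;
`X² = −2Σ ln pᵢ` is referred to χ²(2k) over the k studies with available
results (missing studies reduce the degrees of freedom, never imputed), and
the tail is computed with `log.p = TRUE` so that inputs as small as 1e-300
keep a finite `log_combined_p` even where `combined_p` itself would
underflow double precision. Report tables round to 2 significant figures
for display; internal values keep full precision.

## The synthetic world

The generator's defaults state the emulated design: 31 strains, 8 animals
per strain and sex, SNPs in ancestral haplotype blocks (one biallelic
strain partition per block, block frequency uniform on [0.1, 0.5]), strain
mean slopes centred at 1.0 with SD 0.3 so that a 31-strain panel spans
roughly 0.4–1.7. Strains belong to 5 subfamilies and deviate from their
family's block allele with probability 0.15 — enough structure for the
kinship correction to have something to correct, while keeping SNP
partitions diverse. Within-animal reading noise (SD 0.05 resistance units)
is a free parameter, not an estimate of any real plethysmography rig.

Causal SNP `effect` is the full slope difference between the two homozygote
classes. The polygenic background is drawn as `g ~ N(0, σ_g² K)` with
`σ_g²` scaled (via the Gower factor) so that the *realized* strain-level
heritability — var(genetic values)/var(strain means) — matches the
`heritability` parameter in expectation; animal-level noise is scaled so
the strain-mean residual completes the variance budget.

Human data are simulated at the summary-statistic level only: per-study
z-scores marginally N(0, 1) under the null, first-order autoregressive
with coefficient `ld_decay_rho` along the map as a minimal stand-in for
LD, shifted by `√N·λ` (shared sign, drawn once per dataset) at SNPs inside
signal genes. Odds ratios are derived from z (`ln OR = 2z/√N`) so p and OR
are always mutually consistent. No individual-level human genotypes exist
anywhere in the pipeline, mirroring the fact that every downstream
operation consumes summary statistics.

### What a green test does and does not establish

The synthetic world has independent blocks, exchangeable subfamilies,
Gaussian noise, and exactly the assumed mixed model — so calibration and
recovery results certify the *implementation*, not the biology. Real strain
panels have pedigree-structured kinship, LD that decays within blocks,
non-Gaussian phenotypes, and human consortium statistics carry imputation
error and ancestry-specific LD none of which is emulated. Genome-wide
candidate counts from the original study (hundreds of genes, 281,300 SNPs)
are out of desk-scale reach and are replaced by property checks.

Two statistical-design points worth recording:

* **Calibration testing.** 2000 SNPs on a 31-strain panel supply only ~29
  effectively independent tests, so a Kolmogorov–Smirnov test on one
  panel's p-values is invalid (its independence assumption fails by two
  orders of magnitude, and even a true-δ oracle "fails" it). The
  calibration check therefore pools 20 subsampled p-values — below the
  panel's effective dimension — from each of 100 replicate datasets.
* **Detection power.** With the planted effect at half the phenotypic SD,
  an oracle given the true variance components places the causal SNP in
  the top 1% in 10 of 20 datasets — identical to the package — because the
  kinship correction absorbs family-aligned signal. The power test is
  frozen against that oracle, not against an idealized expectation.

## Defaults at a glance

| Parameter | Default | Why |
|---|---|---|
| doses | 0, 1, 3, 10, 30 mg/ml | standard methacholine challenge ladder |
| log base | 10 | slopes land on the 0.4–1.7 survey scale |
| `p` threshold, both species | 0.001 (strict `<`) | published screening level |
| gene window | 50 kb | published window, boundary inclusive |
| minor-allele count | > 2 strains of 31 (strict) | published filter |
| `ln δ` grid | [−10, 10], 100 points | conventional mixed-model default |
| association mode | null-model δ | calibrated at n = 31 (see above) |
| `n_strains` / animals | 31 / 8 per sex | emulated survey design |
| `slope_mean`, `slope_sd` | 1.0, 0.3 | 31 strains span ≈ 0.4–1.7 |
| subfamilies / flip | 5 / 0.15 | structure for K, diversity for tests |
| `ld_decay_rho` | 0.5 | mild AR(1) stand-in for local LD |

## Known limitations

* Analysis runs on strain means; an animal-level mixed model (strain as a
  second random effect) is out of scope.
* Regional support is count-based; no LD is estimated from reference
  panels, and no regional plots are produced.
* X-chromosome SNPs, imputation dosages, and random-effects/heterogeneity
  meta-analysis (Cochran's Q, I²) are not implemented.
* The δ grid bounds clamp extreme variance ratios; fits at `|ln δ| = 10`
  indicate a boundary solution (near-zero genetic or residual variance),
  which with ~30 strains occurs by chance in a nontrivial fraction of
  datasets at high heritability.
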