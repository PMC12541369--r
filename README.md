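# meiofoci

Quantification toolkit for meiotic recombination studies in *C. elegans*
germlines: nanoscale shape-model selection for late recombination foci,
diffraction-limited focus classification around crossover-designation
sites, SNP-interval crossover mapping, and the cohort statistics that
connect them. Synthetic-data generators emulate every input, so the whole
pipeline is testable without external data.

It is aimed at microscopists and meiosis researchers who have
single-molecule localization (SMLM) tables, spot/anchor tables from
SIM/STED imaging, or five-marker progeny genotypes, and want the
published quantification rules as reusable, tested functions.

## What it computes

**Shape-model selection.** A filtered localization cloud (z inside a
600 nm window, lateral precision ≤ 15 nm, axial ≤ 25 nm) is fitted by
maximum likelihood to two 5-parameter ellipse models — uniform density
along the perimeter (*hollow ring*) or over the interior (*filled*), each
convolved per-localization with a Gaussian of that localization's
precision:

```
f_hollow(p_i) = (1/L)    ∮ N(p_i − s; σ_i² I) ds
f_filled(p_i) = (1/πab)  ∫_E N(p_i − q; σ_i² I) dq
```

Models are compared by the small-sample-corrected AIC per localization,

```
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1),   normAICc = AICc / n,
```

and the focus is *filled* only when `normAICc_filled < normAICc_hollow`
(ties → hollow). With equal `k` and `n` this is provably a likelihood
comparison, which the test suite asserts.

**Focus sites.** Spots detected by difference-of-Gaussians + sub-pixel
anisotropic Gaussian fits join a COSA-1 anchor within 150 nm (inclusive,
nearest anchor, index tie-break) and sites are categorized by
multiplicity (singlet/doublet/triplet/multi) or by shape, where a single
spot with fitted σ ≥ 75.12 nm in x *or* y is an elongated singlet.

**Recombination mapping.** Crossovers are called at phase transitions
between adjacent non-missing calls across five ordered SNP markers (A–E,
Bristol/Hawaiian); per-interval frequencies, the overall recombinant
fraction, and 0/1/2/3+ crossover-class tallies follow, with two-sided
Fisher's exact comparisons between cohorts.

**Statistics.** Self-contained `fisher_exact()` (sum of hypergeometric
point probabilities ≤ observed) and `mann_whitney()` (exact enumeration
for small tie-free samples, tie- and continuity-corrected normal
approximation otherwise), plus viability/male-frequency and zone-wise
focus-count summaries.

## Worked example

Simulate a hollow-ring localization cloud, classify it, and summarize a
classified cohort:

```r
library(meiofoci)

cloud <- gen_focus_localizations("hollow",
  ellipse_params(full_major_axis = 65, full_minor_axis = 35),
  n_loc = 500, precision_xy = 5, precision_z = 10, seed = 42)

classify_focus(cloud)
#> <focus_classification> focus_1: hollow (normAICc hollow 16.1654, filled 16.5690)
```

The hollow model wins (lower normAICc) and its fit recovers the
generating geometry — 65.2 × 34.1 nm full axes against the true 65 × 35:

```r
classify_focus(cloud)$fit_hollow
#> <shape_fit: hollow> n = 500, logLik = -4036.28, normAICc = 16.1654, axes 65.2 x 34.1 nm, theta 0.036
```

Group-level bookkeeping with pairwise Fisher tests (here the published
hollow/filled counts, 13 of 21 vs 4 of 15):

```r
counts <- data.frame(
  genotype = rep(c("wt", "K275R"), c(21, 15)),
  label = c(rep("hollow", 13), rep("filled", 8),
            rep("hollow", 4), rep("filled", 11)))
hollow_fraction(counts)
#> $summary
#>   genotype  n n_hollow pct_hollow
#> 1       wt 21       13       61.9
#> 2    K275R 15        4       26.7
#> $pairwise
#>   group_1 group_2 odds_ratio    p_value
#> 1      wt   K275R    4.46875 0.04892796
```

61.9% vs 26.7% hollow foci, p = 0.049: the wild type is more than twice
as likely to show an open-ring focus. Crossover mapping on a simulated
10,000-progeny cohort recovers the interval frequencies it was
parameterized with:

```r
g <- gen_genotype_cohort(10000, c(0.098, 0.278, 0.014, 0.181), seed = 1)
cohort_recombination(g)
#> <cohort_recombination> 10000 scored chromatids (10000 usable per-interval)
#>   overall recombinant: 4776/10000 = 47.76%
#>   interval  n_co n_usable frequency
#> 1 AB         986    10000    0.0986
#> 2 BC        2837    10000    0.284
#> 3 CD         126    10000    0.0126
#> 4 DE        1810    10000    0.181
```

A thin command-line wrapper over the same functions lives at
`inst/cli/meiofoci.R` (subcommands `pipeline`, `classify-smlm`,
`map-recombination`, `reproduce`).

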