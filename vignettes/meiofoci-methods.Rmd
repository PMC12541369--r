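---
title: "Quantifying meiotic recombination foci: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic recombination foci: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiofoci)
```

# Scope

`meiofoci` packages the quantification machinery used to characterize
meiotic crossover sites in *C. elegans* germlines at three scales:

1. **Nanoscale (SMLM)** — single-molecule localization clouds of late
   recombination foci (MSH-5) are classified as *hollow elliptical rings*
   or *filled ellipses* by likelihood fits and small-sample-corrected AIC.
2. **Diffraction-limited imaging** — HIM-6 / RMH-1 foci detected in 2-D
   images are grouped around COSA-1 crossover-designation sites within a
   colocalization radius and categorized as singlets, elongated singlets,
   doublets, triplets, or larger clusters.
3. **Genetics and cohort statistics** — crossovers are mapped from five
   ordered SNP markers on chromosome V in Bristol/Hawaiian hybrid progeny,
   and group comparisons use self-contained two-sided Fisher's exact and
   Mann-Whitney U tests.

Because raw microscopy and progeny data for this assay family are not
generally available as deposited datasets, the package ships generators
that simulate every input with the statistical structure the analyses
assume. The generators are first-class, tested code: every downstream
module is exercised against synthetic ground truth.

# The shape-selection model

A localization cloud is a set of points $(x_i, y_i, z_i)$ with
per-localization precisions $\sigma_i$ (lateral) and $\sigma_{z,i}$
(axial). After filtering — z inside a 600 nm window centered on the cloud
median, $\sigma_i \le 15$ nm, $\sigma_{z,i} \le 25$ nm, all bounds
inclusive — the lateral coordinates are fitted to two generative models,
each an ellipse with center $(c_x, c_y)$, semi-axes $a \ge b$, and
orientation $\theta$:

* **hollow** — uniform line density along the perimeter, and
* **filled** — uniform area density over the interior,

in both cases convolved with an isotropic Gaussian of SD $\sigma_i$, so
each localization is evaluated under its own measurement blur:

$$
f_{\mathrm{hollow}}(p_i) = \frac{1}{L}\oint
\mathcal{N}(p_i - s;\, \sigma_i^2 I)\, \mathrm{d}s,
\qquad
f_{\mathrm{filled}}(p_i) = \frac{1}{\pi a b}\int_E
\mathcal{N}(p_i - q;\, \sigma_i^2 I)\, \mathrm{d}q .
$$

Both models have $k = 5$ free parameters. Model choice uses the
small-sample-corrected AIC normalized per localization,

$$
\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}, \qquad
\mathrm{normAICc} = \mathrm{AICc}/n,
$$

and a focus is labeled **filled** only when
$\mathrm{normAICc}_{\mathrm{filled}} < \mathrm{normAICc}_{\mathrm{hollow}}$;
exact ties go to hollow, following the strict inequality in the decision
rule. Because both models share $k$ and $n$, any monotone transformation
of AICc — including the choice of normalization constant — leaves the
label unchanged; the decision is equivalent to comparing log-likelihoods.
The suite asserts this equivalence directly, which is why the per-$n$
normalization choice (the exact constant used by upstream SMLM tools is
not published) is harmless here.

## Numerical choices

* **Quadrature.** The perimeter convolution integral uses 256 equally
  spaced parameter points weighted by local arc length (a periodic
  midpoint rule); the interior uses a 32 × 32 tensor Gauss-Legendre grid
  in (radius, angle) mapped to the ellipse. At these sizes both densities
  integrate to 1 within 1% on a generous grid (asserted in tests), which
  is the accuracy scale that matters for a 2-parameter model comparison.
* **Initialization.** Center at the coordinate-wise median, full axes
  65 × 35 nm, orientation from the principal direction of the
  coordinates. The axis figures are read as *full* axis lengths
  (semi-axes 32.5 / 17.5 nm); the alternative semi-axis reading only
  changes the optimizer's starting point, not its optimum, and the
  default is configurable.
* **Optimizer.** Derivative-free Nelder-Mead from the single stated
  initialization, semi-axes bounded to [5, 500] nm via penalty,
  parameters canonicalized so $a \ge b$ and $\theta \in [0, \pi)$. A
  guard returns the initialization if a step ever degrades the
  likelihood, so the fitted log-likelihood never falls below its starting
  value.
* **2-D fitting.** Foci enter this analysis in frontal or near-frontal
  view, so z carries no shape information and is used only for
  filtering; the z-window center is the cloud median because the assay
  defines only a window width, not an absolute focal plane.
* **No background term.** The default likelihood has no uniform
  background component (none is described for the original fits); the
  hollow ring likewise has zero intrinsic width, with apparent width
  arising from localization precision. Both choices are the most
  parsimonious reading and keep the two models strictly comparable at
  $k = 5$.

## What the synthetic clouds do and do not emulate

`gen_focus_localizations()` draws model points uniformly from the
perimeter (by inverse arc-length sampling) or interior (by the
$\sqrt{u}$ radial map), displaces each by its own drawn precision, and
optionally mixes in uniform background over a square ROI (default
half-width 200 nm). Precisions follow a truncated lognormal — median 8 nm
lateral / 15 nm axial, truncated at the 15 / 25 nm filter bounds — which
reproduces the right-skewed precision spread of real SMLM data while
keeping most localizations usable. z coordinates sit in a Gaussian slab
(SD 30 nm). Not emulated: emitter blinking and multi-frame kinetics,
astigmatic z-PSF calibration, drift, or chromatin texture. Passing tests
therefore demonstrate correct *inference given the generative model*, not
robustness to every artifact of real acquisitions; the localization count
per focus (default 500) is a plausible scale, not a published value.

Benchmarks run at fixed, stated sizes: label recovery uses 100 clouds per
class at 500 localizations, 5 nm precision, and no background, with a
≥ 90% agreement threshold; parameter recovery uses 20 clouds of 1000
near-noiseless perimeter points (80 × 40 nm, $\theta = 0.3$) with ±5%
axis and ±0.05 rad tolerances.

# Diffraction-limited focus analysis

Spot detection is a generic band-pass pipeline: difference-of-Gaussians
response at scales $(\sigma, 1.6\sigma)$ tuned to the expected spot
width, 8-neighbor local maxima above a gate set at half the response a
threshold-amplitude spot would produce, then sub-pixel refinement by
least-squares fit of an anisotropic Gaussian plus constant offset in a
window of half-width $3.5\sigma$. The fitted center is confined to 2.5 px
around its candidate so an overlapping neighbor cannot capture the fit.
The *classification rules* are the part meant for reuse:

* a single fitted spot is an **elongated singlet** when
  $\sigma_x \ge 75.12$ nm *or* $\sigma_y \ge 75.12$ nm (inclusive; the
  threshold is stored verbatim as an opaque, tool-derived constant);
* spots join a COSA-1 anchor's site when within **150 nm** (inclusive;
  "within a radius" is read as $\le$), the nearest anchor wins, and
  exact ties go to the lower anchor index — the tie rule is this
  package's choice since shared proximity is not specified upstream;
* sites are categorized by **multiplicity** (1/2/3/≥4 members →
  singlet/doublet/triplet/multi) or by **shape** (one member →
  singlet vs elongated singlet; two or more → doublet, with no upper
  member bound).

Nucleus segmentation is out of scope: nuclei arrive as precomputed
normalized gonad positions, which `zone_partition()` bins into equal
half-open zones (last bin closed) from the distal end, 4 zones for
meiotic-entry-to-late-pachynema scoring or 7 from the distal tip.

# Crossover mapping

Each progeny contributes exactly one scored chromatid (the maternal
chromosome V of the hybrid oocyte), so worm counts are chromatid counts.
A crossover is recorded wherever adjacent non-missing marker calls
differ. The **overall recombination frequency** is the fraction of scored
chromatids with at least one observed transition — the only definition
consistent with the published 65/215 = 30.23% bookkeeping — while
**per-interval frequencies** divide interval counts by chromatids usable
for per-interval assignment. Missing calls are this package's design
territory (the assay description predates them): a transition spanning a
missing marker is assigned to the composite interval and excludes that
chromatid from per-interval counts only; chromatids with fewer than two
readable markers are dropped with a message. Even numbers of exchanges
between adjacent markers are invisible at marker resolution and are
documented, not corrected.

The cohort generator draws interval crossovers independently — no
interference — because the assay consumes only per-interval frequencies,
and the double-crossover rate then becomes a recoverable diagnostic
rather than an input. Default interval probabilities (0.098, 0.278,
0.014, 0.181) are the published wild-type values, and recovery within 3
binomial SDs at $n = 10{,}000$ is part of the acceptance suite. Marker
base-pair coordinates in `marker_map()` are illustrative placeholders
spanning chromosome V (only marker *order* enters any computation).

# Statistics

`fisher_exact()` sums hypergeometric point probabilities (via `dhyper`)
over all same-margin tables no more probable than the observed one — the
convention of mainstream statistical software; mid-p and tail-doubling
conventions differ and are deliberately not used, because only this
convention reproduces the published p-values the suite anchors to. A
relative tolerance of $10^{-7}$ guards probability ties against floating
point. Zero-margin tables report p = 1 with a warning and an undefined
odds ratio; otherwise the odds ratio is the sample cross-product ratio,
infinity-aware.

`mann_whitney()` enumerates the exact U null distribution for tie-free
samples with $\max(n_1, n_2) \le 8$ (doubling the smaller tail) and
otherwise applies the normal approximation with tie and continuity
corrections — the behavior of standard packages at the sample sizes the
cohort analyses use, with the exact branch retained for oracle testing.
Both tests are verified against exhaustive enumeration oracles (all 2 × 2
tables with total ≤ 20; full permutation distributions up to
$n_1 = n_2 = 6$) and the null rejection rate of the approximation is
property-tested to sit near its nominal 5%.

One documented discrepancy: among the published recombination
comparisons, the value 0.0012 is printed both for wild type vs the
helicase-dead mutant and for the null vs helicase-dead comparison. The
printed group counts reproduce 0.0012 only for the latter (120/255 vs
58/184); the wild-type comparison computes to $2.2 \times 10^{-4}$ under
every standard two-sided convention. `reproduce_paper_tables()` reports
the computed value beside the printed one so the inconsistency stays
visible rather than being absorbed.

`viability_metrics()` takes hatched larvae over laid eggs per worm
(unfertilized eggs are excluded upstream) and reports male frequency
among *hatched offspring* — the denominator is not stated upstream, and
offspring is the reading adopted here.

# Pipeline and reproducibility

`run_pipeline()` validates its configuration strictly (unknown keys and
out-of-range thresholds are rejected by name), derives every per-focus
seed from the master seed, and stamps all data outputs with the seed and
a configuration hash. Data outputs (tables and the JSON summary) are
byte-identical across re-runs of the same configuration; the run log is
the one exception, carrying wall-clock timestamps for provenance, so the
idempotence contract covers the data bundle rather than the log. All
thresholds that affect results are echoed into the log.

# Known limitations

* Shape classification is validated on the generative families it fits;
  real foci with partial rings, anisotropic background, or merged
  neighbors have no ground truth here.
* The spot detector is a generic DoG + Gaussian-fit pipeline, not a
  re-implementation of any specific tool's internals; near the two-point
  resolution limit it shows the usual inward localization bias for
  merging pairs.
* Recombination mapping cannot see even exchange counts within an
  interval, and composite-interval handling of missing data is a
  convention, not an inference.
* The Mann-Whitney normal approximation is what large-cohort comparisons
  use; exact enumeration is only engaged at small, tie-free sizes.
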