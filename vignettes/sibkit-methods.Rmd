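---
title: "Methods: sibling-pair recombination detection and sibling score statistics"
author: "sibkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sibling-pair recombination detection and sibling score statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two full siblings inherit, at every genomic position, one of two paternal
chromatids and one of two maternal chromatids. Writing the father's strands
as $Y_a, Y_b$ and the mother's as $X_a, X_b$, the joint state of a sibling
pair at a locus is one of $16$ ordered chromatid patterns, which collapse
into three region types:

* **type 1** — identical by descent (IBD) on both parental sides
  (4 patterns): the siblings' genotypes agree at essentially every marker;
* **type 2** — IBD on exactly one side (8 patterns);
* **type 3** — IBD on neither side (4 patterns).

At a random point each side matches with probability $1/2$ independently,
so the stationary genome fractions are $1/4$, $1/2$, $1/4$. Crossing a
region boundary changes the local sibling-vs-sibling genotype similarity
abruptly, and each boundary is caused by exactly one crossover in one of
the four meioses (two sperm, two eggs) behind the pair. Boundaries of
type-1 regions (1↔2 transitions) are conspicuous because similarity drops
from near 100% to a much lower level; 2↔3 transitions separate two already
dissimilar regions and are not practically detectable. Since a crossover
produces a 1↔2 boundary exactly when the *other* parental side happens to
match — probability $1/2$ — the method sees half of all crossovers. This
factor of 2 is applied when converting call counts into genetic map
lengths.

## The detector

For a candidate boundary between markers $i-1$ and $i$, count the
identical-in-state loci between the siblings in the flanking windows of
$N$ markers: $N_-$ in $[i-N, i-1]$ and $N_+$ in $[i, i+N-1]$. The
indicator is

$$ Z = \frac{N_+ - N_-}{a + \left(N - \max(N_+, N_-)\right)} $$

with a small positive offset $a$ keeping the denominator positive. The
numerator is large in magnitude when the windows disagree strongly; the
denominator is small when at least one window is nearly fully identical,
which is the signature of a type-1 region. $|Z|$ therefore peaks sharply
at 1↔2 boundaries and stays near zero inside homogeneous regions and at
2↔3 boundaries. We take the sign convention directly from the formula:
$Z > 0$ means the **right** window is the more similar one, i.e. the scan
is entering a type-1 region left-to-right (`gain_identity`). Descriptions
of the sign in prose sources can be found stated the other way around; the
formula is unambiguous and we follow it.

Calling proceeds by scanning all valid $i$, keeping local maxima of $|Z|$
at or above a threshold $\theta$, and greedily suppressing non-maximal
peaks within `min_sep` markers (ties broken toward the smaller index). The
reported interval is the marker gap bracketing the peak (0-based
half-open), with the midpoint used for binning.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `N` | 50 markers | flanking window size |
| `a` | 2 | denominator offset, $0 < a \ll N$ |
| `theta` | 5 | calling threshold on $|Z|$ |
| `min_sep` | `N` | minimum marker separation between calls |
| `min_overlap` | 0.8 | minimum fraction of co-observed loci per window |
| `maf_min` | 0.05 | MAF filter applied before scanning |

The defaults were chosen by grid calibration (`calibrate_detector()`)
against ground truth on simulated cohorts: with common variants in linkage
equilibrium a type-2 window has expected similarity
$\mathbb{E}[N_\pm/N] = \mathbb{E}_p\!\left[p^2+(1-p)^2\right] \approx 0.64$
under MAF $\sim U(0.05, 0.5)$, so a clean 1↔2 boundary scores
$|Z| \approx (N - 0.64N)/(a) \approx 9$ at $N = 50, a = 2$, comfortably
above $\theta = 5$, while interior fluctuations sit far below it (the
denominator is $\approx a + 0.36N$ there). Larger windows buy robustness
against genotyping error — isolated mismatches in an IBD window shrink
$N_\pm$ by 1 each — at the price of resolution and of merging nearby
boundaries; the calibration tests confirm the F1 surface is flat across
$N \in [25, 100]$ at realistic error rates. Rare variants are filtered
because runs of rare alleles are usually shared identical-in-state even
without IBD, mimicking type-1 similarity.

### Known losses of the detector

Three mechanisms make detector-based map lengths undercount slightly
(2–3% in our simulations, matching the deficit that sibling-derived maps
show against pedigree-based reference maps):

1. **chromosome ends** — no calls are possible within $N$ markers of an
   end, and telomeric recombination rates are high in real genomes;
2. **boundary clusters** — two boundaries closer than `min_sep` markers
   yield one call; this is most pronounced inside hotspots, where
   boundaries concentrate physically;
3. **window contamination** — a second crossover inside a flanking window
   degrades the peak.

No end-region correction is applied. Consequently the package's map
*estimator* is validated on truth-level boundary catalogs (where its only
error is sampling noise), while the detector is validated by its recall
(≥ 95% of interior 1↔2 boundaries at genotyping error rate $10^{-3}$) and
by a dedicated test pinning the undercount into the $[0.90, 1.00]$ ratio
band.

## From calls to genetic maps

With $B_c$ catalogued boundaries on chromosome $c$ over $n$ pairs, the
sex-averaged per-meiosis length is

$$ \widehat{\text{cM}}_c = 100 \cdot \frac{B_c}{2n}, \qquad
   \widehat{\text{SE}}_c = 100 \cdot \frac{\sqrt{B_c}}{2n}, $$

because each pair contributes four meioses of which half the crossovers
are visible ($4 \times \tfrac12 = 2$). The standard error assumes Poisson
counts; reference tables for this quantity do not state their SE method,
so this is our assumption. Cumulative maps are running sums of binned
counts rescaled to end at $\widehat{\text{cM}}_c$; density histograms are
raw per-bin counts. Group comparisons of per-individual break counts use
the normal test $z = \bar d / (\sigma_0 / \sqrt{n})$ against a null mean
and SD taken from a reference population.

## The simulator

`simulate_sib_pairs()` is the ground-truth engine behind every other
module:

* **maps** — crossovers per meiosis are Poisson with mean equal to the map
  length in Morgans, positions uniform in cumulative-cM space and mapped
  to bp by inverse interpolation (so hotspots attract breaks). An optional
  stationary gamma-renewal process (shape $\nu \ge 1$, unit mean rate per
  Morgan) models crossover interference; it is off by default because
  interference is a small effect at typical genome-wide break counts, and
  crucially it does not couple the four meioses of a pair, so boundary
  locations remain independent draws.
* **parents** — phased haplotypes with per-variant MAF
  $\sim U(0.05, 0.5)$ (the detector's intended operating range) in linkage
  equilibrium; effect sizes $\beta_j \sim N(0, 1)$.
* **assortative mating** — couples are formed by noisy rank-matching of
  parental polygenic scores, with the noise level calibrated iteratively
  until the realized score correlation is within 0.005 of the target $m$.
* **offspring** — four independent meioses per pair; genotypes are gamete
  sums; genotyping error replaces a dosage with a uniformly chosen
  different dosage at rate $\varepsilon \le 0.05$; phenotypes are
  $y = S + e$ with $e \sim N\!\left(0, V\tfrac{1-h^2}{h^2}\right)$ so that
  $\mathrm{Var}(S)/\mathrm{Var}(y) = h^2$.
* **truth** — crossover positions, start chromatids and (derivably)
  per-marker inheritance vectors are retained for every gamete, so region
  types, boundary transitions and genome fractions can be computed exactly
  in continuous bp space, free of marker discretisation.

What the simulator deliberately does **not** emulate: linkage
disequilibrium between variants, population structure, sex chromosomes,
mutation, imputation artifacts, and dosage-to-hard-call conversion.
Passing tests therefore demonstrate correctness of the algorithms under
the stated generative model, not robustness to every artifact of real
biobank arrays — most notably, LD makes rare-variant clusters and
near-IBD stretches more common in real data than here, which is exactly
why the MAF filter and the calibration-on-family-data workflow exist.

## Sibling score statistics

For additive scores $S_i = \sum_j G_{ij}\beta_j$:

* **√2 law** — sibling differences $\Delta S$ have half the variance of
  random-pair differences $\Delta U$ under random mating, i.e.
  $\sqrt2\,\sigma(\Delta S)/\sigma(\Delta U) = 1$; the package computes
  both the variance ratio and this normalized ratio with a seeded
  bootstrap SE. Random pairs are drawn by a seeded shuffle that forbids
  known sibling pairs.
* **assortativity** — inverted from
  $\mathrm{cov}(S_1, S_2) = \tfrac{V}{2}(1+m)$ with a closed-form
  leave-one-pair-out jackknife SE. $V$ is the score variance of the
  general *mating* population. The simulator applies a single round of
  assortment to a linkage-equilibrium base population, so its offspring
  generation is not yet at assortative-mating equilibrium: using the
  offspring variance as $V$ would attenuate $\hat m$ toward $m/2$
  (offspring variance $V_p(1+m/2)$ versus sibling covariance
  $V_p(1+m)/2$). At equilibrium — the situation of real cohort data — the
  two variances coincide. The estimator therefore takes $V$ as an
  explicit argument, and the recovery tests supply the parental-generation
  variance.
* **heritability** — the average of $\mathrm{Var}(S)/\mathrm{Var}(y)$ and
  $\mathrm{corr}(S, y)^2$; phenotypes are assumed pre-adjusted for
  covariates upstream.
* **families and centering** — sibling edges are closed transitively into
  families (connected components, with parent-child edges filtered out).
  Scores can be centered on the family sibling mean or on the midparent;
  sib-mean centering removes slightly more variance because the sibling
  mean equals the midparent only in the large-sibship limit.

## Absolute risk and the health index

Case-control scores are modelled as a two-component normal mixture with
equal SDs, $\phi(x) = (1-\pi)N(x;\mu_0,\sigma) + \pi N(x;\mu_1,\sigma)$,
where $\pi$ is the *lifetime* risk (an external epidemiological input —
cohort prevalence is never substituted for it) and $\sigma$ is estimated
from controls, the larger class. The posterior case probability

$$ r(x) = \left[1 + \frac{1-\pi}{\pi}
   \frac{N(x;\mu_0,\sigma)}{N(x;\mu_1,\sigma)}\right]^{-1} $$

is evaluated in log space (the density ratio is
$\exp\{(\mu_1-\mu_0)(x - \tfrac{\mu_0+\mu_1}{2})/\sigma^2\}$, which
overflows naive evaluation in the tails). The health index
$I = \sum_d l_d(\rho_d - r_d(x_d))$ weights per-disease risk reductions by
average lifespan impact $l_d$ (years); it is additive across diseases,
ignores disease covariances by construction, and is *nonlinear* in the
underlying scores, so sibling index distributions need not show the √2
compression — and two parents who are each a high-risk outlier on a
different disease can both score below every one of their
midparent-clustered offspring. The shipped multi-disease configuration is
explicitly synthetic/illustrative; published index parameterizations are
not reproduced here.

## Numerical and design choices

* Coordinates are 1-based bp internally (VCF/map convention); all exported
  intervals are 0-based half-open (BED convention). Boundary positions are
  reported as marker-gap midpoints with the full bracket retained, since
  resolution is intrinsically limited to inter-marker gaps.
* Inverse map interpolation at a zero-rate (flat) stretch returns the
  rightmost bp of the stretch.
* Peak plateaus keep their first index; suppression ties keep the larger
  $|Z|$, then the smaller index.
* The parent-informed quartet oracle uses sites where one parent is
  heterozygous and the other homozygous; transmitted-allele agreement
  between siblings toggles exactly at the paternal (resp. maternal)
  crossover union. Under genotyping error the agreement sequence is
  smoothed by a running majority vote over an odd window (default 5
  informative sites; even-split ties cannot occur with odd windows, which
  is why even windows are rejected). Mendelian-inconsistent sites are
  skipped and counted.
* Missing dosages: pairwise-complete window counts rescaled to $N$, with
  windows below 80% co-observation skipped; in scoring, missing dosages
  fall back to the variant mean.

## Problem sizes used in the test suite

Simulation sizes were chosen to keep each statistical band at least
~2–3 sampling SDs wide at its stated tolerance: 500 pairs on an 800 cM
4-chromosome genome for region-fraction laws; 500 pairs × 10,000 markers
for detector recall at $\varepsilon = 10^{-3}$; 500 pairs on the 3,338 cM
22-autosome genome for the breaks-per-individual total; 1,000 pairs for
map recovery on a 267.8 cM hotspot chromosome; 20,000 pairs for the √2,
assortativity and heritability recoveries.

## Limitations

* The detector targets SNP-array-like marker densities; at very sparse
  maps the window spans too much genetic distance and nearby boundaries
  merge.
* Sex-specific (maternal vs paternal) maps are not identifiable from
  sibling pairs alone and are out of scope.
* 2↔3 boundaries are not called, by design; the factor-2 correction
  assumes the 1↔2 subset is representative, which crossover independence
  guarantees.
* The assortativity inversion assumes the additive model and a correctly
  chosen reference variance $V$ (see above); disease-score assortativity
  estimates on real data can be negative for reasons this package does not
  interpret.
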