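---
title: "Models and methods behind barwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barwalk)
library(dplyr)
```

`barwalk` implements the computational machinery of barcoded two-step
evolution experiments in budding yeast: lineage-tracking simulation, pooled
competition fitness assays across serial-transfer regimes, UMI-deduplicated
barcode counting, fitness inference against neutral references, decomposition
of fitness into growth-phase performances, pleiotropy statistics, inversion
of the beneficial distribution of fitness effects (DFE), and
recurrence-based mutation annotation. This vignette explains the models, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The growth cycle and the forward fitness model

In glucose-limited batch culture a yeast population passes through lag
(~4 h), glucose fermentation (~16 h), the diauxic shift (~20 h in), ethanol
respiration, and finally stationary phase once carbon is exhausted. A
serial-transfer regime determines how many hours of each phase a population
experiences per cycle:

```{r}
default_regimes()[["3D"]]
```

The 1-Day cycle is lag 4 h + fermentation 16 h + respiration 4 h; the 2-Day
cycle appends 24 h of respiration; the 3-Day cycle another 12 h of
respiration plus 12 h stationary; the 5-Day cycle another 48 h stationary.

A genotype is summarized by a *phase profile*: per-hour selection
coefficients in fermentation (`fer`), respiration (`res`) and stationary
phase (`sta`), natural-log based and relative to the common ancestor. Lag
contributes zero for every genotype by construction; correspondingly the 4
lag hours are excluded from the fermentation divisor. Per-cycle fitness
under a regime is the schedule-weighted sum,

$$s_{\text{cycle}} = 16\,\text{fer} + h_{\text{res}}\,\text{res} +
  h_{\text{sta}}\,\text{sta},$$

so the regime *differences* isolate single phases: 2-Day minus 1-Day fitness
is exactly 24 h of respiration, 5-Day minus 3-Day exactly 48 h of
stationary performance. All selection coefficients in the package are per
cycle, not per generation; generations per cycle (~8 for the 2-Day regime)
is reporting metadata only.

`decompose_performances()` inverts this map from measured fitness:

- `res = (f2 - f1)/24`, `fer = (f1 - 4*res)/16`, `sta = (f5 - f3)/48`.

Because the 1-Day fitness appears in both the respiration and the
fermentation formula, shared 1-Day noise would induce an artificial negative
correlation between the two performances. The replicate-splitting rule feeds
respiration from the second 1-Day replicate and fermentation from the first.
This removes the direct coupling — fermentation's own flask is independent of
the respiration estimate — though a small residual covariance,
$-( \sigma_{f2}^2 + \sigma_{f1b}^2 )/2304$ from the $-4\,\text{res}/16$
correction term, is unavoidable and is documented rather than hidden; the
measurement-error resampling below treats the two axes as independent, which
this residual justifies to good approximation. When only one 1-Day replicate
exists it serves both formulas with a warning and the induced covariance is
reported (`cov_fer_res`).

Standard errors propagate first order through the linear forms; a
Monte-Carlo resampling oracle in the test suite confirms them to within 5%.

## Fitness inference from barcode counts

A lineage's per-cycle selection coefficient over an interval is its
log-frequency change per cycle plus the population mean fitness:
$\hat s = \Delta \ln f / \Delta t + \bar x$. Mean fitness is inferred from
the decline of pooled neutral reference lineages,
$\bar x = -\ln\!\big(F_N(t_1)/F_N(t_0)\big)/\Delta t$ with $F_N$ the *summed*
neutral frequency — the count-weighted estimator, which has lower variance
than averaging per-lineage estimates. The two 60-lineage neutral pools are
treated as one 120-lineage set by default. Operationally, $\bar x$ is the
per-cycle log factor by which neutral lineages decline; in a discrete-cycle
model this equals $\ln \sum_i f_i e^{s_i}$, which exceeds the
frequency-weighted mean $\sum_i f_i s_i$ slightly when very fit lineages are
common (Jensen's inequality). The simulator records the latter as its truth
track; the distinction only matters under strong adaptive takeover.

Numerical choices:

- **Pseudocount 0.5** added to every count before frequency computation
  keeps zero-count endpoints finite without biasing large counts; estimates
  driven entirely by pseudocounts are flagged (`zero-endpoints`), never
  silently dropped.
- **Error model.** The variance of each interval endpoint combines
  sequencing counting noise $1/n$ *and*, when a finite `bottleneck` is
  given, multinomial cell sampling at the serial transfer $1/(f_{\rm cell}
  N_b)$. In designs where the ancestral barcode is depleted by restriction
  digestion before sequencing, non-ancestor read counts exceed cell counts
  more than tenfold, so read counts alone would understate the error;
  supplying `ancestor_read_retention` lets the package restore cell
  fractions before computing the bottleneck term. `bottleneck = Inf`
  recovers the counting-noise-only model.
- **Depletion-invariance.** Ancestor depletion rescales every lineage's read
  frequency by a common per-sample factor; since the same factor enters the
  neutral-based mean-fitness estimate, it cancels exactly in $\hat s$.

Fitness in these assays is frequency dependent: strongly adaptive mutants
depress others' apparent fitness once they dominate. `select_intervals()`
therefore admits only intervals whose starting ancestor cell fraction is at
least 0.80, and caps the 2-Day condition to its first interval — the
convention under which "2-Day fitness" is reported throughout.
`frequency_dependence_diagnostic()` quantifies the effect as percent
deviation from each mutant's earliest usable estimate against the
adaptive-class fraction. The earliest interval serves as the reference
because an external published reference is not assumed available.

## The synthetic-data generator

`simulate_fitness_assay()` and `simulate_evolution()` generate the data the
analysis assumes. The study conditions are the defaults: a pool that is 94%
ancestor, two 2% neutral pools and a 2% adaptive pool (a 5% variant is one
argument away); two replicate flasks for 1-/2-Day and three for 3-/5-Day
conditions; six transfers for 1-/2-Day and two for 3-/5-Day assays; 22
transfers for 2-Day evolution; establishment probability $s/c$ with
offspring-number variance $c = 3.5$; detectable lineage size $n_0 = 1000$
cells; ancestor read retention 0.01 under the restriction digest (not
applied to evolution tracking, which skips the digest). The transfer
bottleneck defaults to $10^6$ cells for desk-scale work; the study-scale
$5\times 10^7$ is available by argument. Where the design left a value open
we fixed one realistic choice once: adaptive-pool profiles are drawn
uniformly (fer in [0, 0.02]/h, res in [0, 0.03]/h, sta in [−0.01, 0]/h),
spanning per-cycle 2-Day fitness up to ~1.0, the range over which adaptive
mutants in this system are observed; PCR duplication per molecule is
geometric; UMIs within a sample tag molecules uniquely (the 8-bp space is
vastly larger than per-barcode molecule counts, and collision modelling is
out of scope).

Stochasticity enters only at transfers (multinomial bottleneck) and
sequencing (multinomial reads): within-cycle growth is deterministic, which
is accurate for populations of $10^6$ cells and more. Optional
Dirichlet-multinomial overdispersion is deliberately *not* the default.
Established mutant sub-lineages start at their conditional establishment
size $c/s$ cells and inherit the parental barcode — mutations surface as
lineage-level fitness changes, exactly as barcode tracking sees them.

What passing tests on this generator do and do not show: the generator
reproduces the sampling structure (bottleneck and sequencing multinomials,
UMI duplication, index hopping, ancestor depletion) but not chimeric reads,
quality-score structure, plate effects, or genuinely frequency-dependent
selection; recovery results on simulated data therefore validate the
estimators' internal consistency, not robustness to every artefact of real
libraries.

## Barcode counting and the metagrid

Reads follow the amplicon layout `[pad][UMI 8bp][inline index][anchor]
[barcode][anchor]`. Extraction locates the constant anchors allowing up to 2
substitutions each, slices the flanked fields, and corrects the inline index
to its unique nearest library index within Hamming distance 1 (as
sequencers' demultiplexers do); parsing failures are data with reasons
(`missing-anchor`, `short-read`, `bad-index`), not exceptions. Each sample
owns a unique (Illumina, inline) index *combination*, so reads whose
combination is absent from the sample sheet while both components are
present are recognized as index hopping and excluded. Barcodes map to their
unique nearest whitelist entry within Levenshtein distance 2 — indels
included, because amplicon indels occur and a random 26-mer whitelist is
sparse; ties are discarded. Counts are distinct UMIs per sample and barcode
(exact match by default; a directional Hamming-1 collapse is optional).

Well assignment (the "metagrid" rule) is majority vote with three
thresholds, checked in order: at least 200 reads in the well, top barcode at
least 60% of them, and top strictly more than 1.5 times the second. The
ratio uses raw read counts by default, matching the protocol's order of
operations; UMI counts can be passed instead. Read conservation (assigned +
discarded + hopped + unmatched + invalid = total) holds exactly and is
enforced in the tests.

## Pleiotropy statistics

Performance changes relative to the parental strain classify each mutant
into a quadrant: improving both fermentation and respiration (pleiotropic
adaptation), respiration only, fermentation only, or neither. "Improve"
means strictly positive; a zero change is non-improvement (the boundary has
probability zero under resampling). The parental reference is the mean of
the parent's neutral-haploid lineages (SE = sd/√n), or a designated barcoded
lineage when no neutral siblings exist.

Uncertainty on quadrant proportions comes from resampling: each of B = 1000
draws redraws every mutant's (Δfer, Δres) from Gaussians at its standard
errors, reclassifies, and tallies proportions; the standard deviation across
draws is the reported uncertainty. Group comparisons (e.g., first-step vs
second-step both-improve fractions) use paired resamples with add-one
smoothing, $p = (1 + \#\{p_A \ge p_B\})/(B+1)$, so the smallest attainable
p is $1/(B+1)$ and the test is never anticonservatively zero.

Contingency tests use an exact two-sided Fisher test implemented by
point-probability summation (all tables at fixed margins with probability
not exceeding the observed one, with a $10^{-7}$ relative tie tolerance);
the test suite proves it equivalent to exhaustive enumeration for every
table with total up to 30. Selection-pressure checks use the partial
correlation of two variables given a third via the correlation-matrix
identity, with p from the t distribution on $n-3$ degrees of freedom; the
residual-regression route is the independent oracle in the tests.

Mutant classes combine the benomyl plate assay with fitness clustering:
membership within 3 SE-normalized units of the neutral-haploid or
pure-diploid centroid in every condition overrides the plate call (the
"large cluster" of the original analysis, formalized as a diagonal
Mahalanobis radius since no formal rule was stated). `PAB1` mutants are
benomyl-sensitive and get overridden by respiration performance relative to
parent: below 0.06/h means adaptive haploid, at or above means high-fitness
diploid. Significance of individual performance changes uses the
two-standard-error rule.

## DFE inversion

The density $\mu(s)$ of beneficial mutation rates is inferred by counting
established, detectable mutant lineages per selection-coefficient bin and
dividing by a detection kernel

$$K(s) = \frac{s}{c}\, N_e \int_0^{\tau(s)} e^{-X(t)}\,dt, \qquad
  \tau(s) = \min\!\Big(T,\; T - \tfrac1s \ln\tfrac{n_0 s}{c}\Big),$$

where $X(t)$ is the cumulative mean fitness $\int_0^t \bar x$ (an
instantaneous variant $e^{-\bar x(t)}$ is selectable — the source formula
for this quantity is ambiguous, so both are exposed and the cumulative form
is the default). $s/c$ is the establishment probability, $N_e e^{-X(t)}$
the shrinking pool of background cells on which new first-step mutations
arise, and $\tau(s)$ the latest origination time from which an established
lineage of size ~$c/s$ can still reach the detectable size $n_0$ by the end,
growing at rate $s$. Inversion is per bin:
$\hat\mu = \text{count}/(K(s_{\rm mid})\,\Delta s)$, with exact Poisson
intervals; the default grid is 25 log-spaced bins over [0.05, 5] per cycle.

Numerics: $X$ is accumulated by trapezoid on a dense grid containing the
cycle knots (exact for piecewise-linear mean-fitness tracks and linear
ramps), and the outer integral uses adaptive quadrature at relative
tolerance $10^{-8}$ with a dense-trapezoid fallback for kinked integrands.

One consistency subtlety is worth stating plainly. The simulator flags a
mutation `detected` by the kernel's own deadline rule (established and
arising before $\tau(s)$), and separately records each sub-lineage's
realized peak size. Under weak interference the two agree; under the strong
clonal interference of a desk-scale point-mass run (about three
establishments per cycle at $s = 1$), realized growth proceeds at
$s - \bar x(t)$ and lags the deadline rule by roughly a factor two. The
kernel inherits this limitation from its derivation, which treats the focal
lineage's growth as unaffected by the mean fitness it must outrun; users
inverting real data where mean fitness rises steeply within the assay
window should treat $\hat\mu$ as accurate to within a small factor, not a
percentage.

## Mutation annotation

Post-variant-calling rules, consuming a flat variant table: a position key
shared by at least two clones of one low-complexity barcode group, or by
every sequenced clone of a parental strain, marks a *preexisting* variant
(arisen during strain construction) and is excluded downstream unless its
gene is independently causal. A gene hit by non-preexisting variants in at
least four distinct clones is causal by recurrence — distinct clones, not
distinct variants, are counted (configurable); genes sharing a pathway with
a recurrence-causal gene are causal by pathway extension, using a curated
CSV mapping (Ras/PKA, TOR/Sch9, RTG, TCA, mitochondrial biogenesis, HOG)
that callers can replace. Gene effect is loss-of-function when any
stop-gained or frameshift variant is present, modification-of-function when
only missense or nearby non-genic variants are, and undetermined otherwise.

## Problem sizes used in tests and the acceptance script

The shipped checks run at desk scale, chosen as the smallest sizes at which
the statistical properties under test are comfortably resolved: assays with
221 lineages at depth $10^4$–$10^6$ and bottleneck $10^6$; evolution runs of
22 transfers at bottleneck $10^6$ over 100 seeds for the DFE recovery;
resampling with B = 1000–2000; read-level checks on a few hundred to a few
thousand synthetic reads. The study-scale bottleneck ($5\times10^7$) and
effective size ($7\times10^7$) remain available through configuration.

## Known limitations

- The branching-process posterior machinery used for per-lineage inference
  in evolution experiments (FitMut-style) is out of scope; lineage fitness
  here is the log-slope estimator with neutral correction.
- The error model treats endpoints as independent; the shared-bottleneck
  covariance between the two endpoints of an interval is neglected, making
  the reported SEs mildly conservative.
- Log-count bias of order $1/(2\,n_{\rm cells})$ per lineage is not
  corrected; it is negligible at realistic bottlenecks but visible if a
  lineage is carried by only tens of cells.
- The kernel-vs-realized-growth gap above applies to any DFE inversion in a
  regime of strong clonal interference.
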