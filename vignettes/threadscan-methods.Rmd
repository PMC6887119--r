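---
title: "threadscan: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{threadscan: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threadscan)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite does not itself
compute.

## 1. RT-stop crosslink mapping

**Model.** In an RTTS library, reverse transcriptase initiates 3′ of the
region of interest and runs toward the 5′ end of 18S rRNA until it falls
off at a crosslink adduct. The enzyme stops one nucleotide 3′ of the
adduct, so the crosslinked nucleotide is the 5′-adjacent position to the
5′ end of the aligned read: a read at 1-based position *p* increments the
site count at *p − 1*. Reads at *p* = 1 have no 5′-adjacent nucleotide
and contribute only to the read total. This is a pure termination model;
read-through (polymerase slipping past the adduct) is available in the
simulator as a geometric tail but defaults to zero, because the site
caller makes no attempt to deconvolve smearing.

**Assumptions.** Only sense-strand alignments are informative (the cDNA
is antisense to the rRNA; orientation is normalized at ingestion and
reverse-strand records are skipped into a per-profile report). Soft
clipping is irrelevant by construction: the aligned 5′ end after clipping
is where synthesis stopped mapping. No background subtraction is applied;
contrasts between libraries use `compare_profiles()`, which compares
depth-normalized rates with a pseudocount of 1 so disjoint supports stay
finite. Duplicate reads are not collapsed by default — the library
protocol ends in PCR, but the site statistic is a ranking, and collapsing
identical starts is a caller flag rather than a default because the true
duplication rate is unknowable from the alignments alone.

**Parameters.** `top_sites(k = 18)` mirrors the conventional display of
the 18 strongest sites; ties break deterministically (count descending,
then position ascending) so tests and re-runs are stable. The helix map
defaults to the four ES6S intervals (A 681–735, B 740–793, C–D 795–864,
E 865–910, gaps allowed between them); any non-overlapping interval set
can be substituted. Coordinates are 1-based inclusive everywhere inside
the package — matching rRNA nucleotide numbering — and are converted to
0-based half-open only in the bedGraph/BED writers.

## 2. Translation-efficiency quantification

**Model.** TE of a gene in a condition is the ratio of its normalized
abundance in the polysomal fraction to that in the monosomal fraction,
with means taken over replicates and a half-count pseudocount on both
terms. The treatment effect is `log2(TE_control / TE_treated)`, so
positive FC TE means the treatment reduced translation. Classification
uses the asymmetric published thresholds (> 1 down, < −0.7 up) gated at
p-adj < 0.05; both thresholds and the significance level are arguments.

**Normalization.** Size factors are median-of-ratios over reference rows
(spike-ins by default, `norm = "all-genes"` as fallback): factor_j =
median_i counts[i,j] / geomean_i(counts[i,·]), rows containing any zero
excluded, and the factor vector rescaled to geometric mean 1. The rescale
pins the arbitrary global scale; all ratios between factors — the only
identifiable quantity — are unaffected.

**Testing: the one place we overrode the plan.** The original design
called for Welch's t on per-replicate log2 TE. Implementing it showed
that with 3 replicates per fraction and condition and a count dispersion
of 0.05, the per-replicate log2 TE has a standard deviation of ~0.46
*even at infinite sequencing depth* (two NB counts enter each ratio), so
a 4-fold TE shift yields t ≈ 5.4 on ~4 degrees of freedom — a p-value
near 0.006 that Benjamini–Hochberg at 10% prevalence cannot pass, giving
single-digit sensitivity. This is a property of the unmoderated test, not
of the data. The default is therefore a moderated t in the empirical-Bayes
tradition of small-n RNA-seq analysis: pooled two-group variances are
shrunk toward a common prior fitted by moment matching on log s² (the
prior degrees of freedom d0 recovered by trigamma inversion), and the
statistic is referred to t on d0 + d_g degrees of freedom. The in-package
implementation is validated against `limma::squeezeVar` in the unit
tests. `method = "welch"` and an exact/Monte-Carlo label-permutation
variant remain available.

**Filters.** Genes with fewer than 10 raw counts summed over samples are
dropped before testing; the threshold is an argument. The source protocol
does not state its filter, and 10 is the conventional floor below which
neither the ratio nor its variance is meaningful.

## 3. 5′ UTR features and statistics

**Motif semantics.** A G-quadruplex hit is a chain of `n_tracts` (4)
maximal G-runs of length ≥ `tract_length` (3, or 2 for the weak variant)
whose successive gaps (loops) are 1–12 nt. Matching is greedy
left-to-right over non-overlapping chains; G-tracts are extended
maximally, so loops never begin or end inside a qualifying G-run, and a
qualifying run is never skipped into a loop. Alternative overlapping
registers are not enumerated because every downstream statistic consumes
presence/absence per UTR. The (GGC/A) motif is a maximal tandem run of
GG[C|A] units (mixed C/A allowed) of at least `min_repeats` (4 = the
12-mer; 5 = the 15-mer). These tandem-run semantics are a declared
stand-in for position-weight consensus motifs that are not fully
published; both scanners are proven equal to independent brute-force
enumerators on random strings in the acceptance suite. U and T are
everywhere equivalent.

**Structure proxy.** `structure_score()` is the Nussinov dynamic program:
the maximum number of nested Watson–Crick + GU pairs with a minimum
hairpin loop of 3 nt. It is a monotone proxy for structure content — all
the group comparisons need — not a free energy; externally computed
folding energies can be joined per UTR instead
(`structure = "external"`). Full nearest-neighbor thermodynamics is out
of scope.

**TOP rule.** A transcript is flagged 5′ TOP when it starts with C
followed by ≥ 4 consecutive pyrimidines. TOP membership has no single
published definition; this standard rule is configurable via
`min_tract`.

**Statistics.** Mann–Whitney U uses midranks; for pooled n ≤ 16 the
two-sided p is exact by complete enumeration of group assignments
(reproducing `wilcox.test(exact = TRUE)`), otherwise a tie-corrected
normal approximation with continuity correction. The worst disagreement
between the two branches at n = 8 vs 8 is ~0.011 and occurs at p ≈ 0.95,
where it is immaterial. Motif enrichment is Pearson's χ² without
continuity correction on the 2×2 class-by-presence table (zero margins
are an error, not a silent NaN). Feature PCA standardizes columns, drops
zero-variance features with a warning, and fixes loading signs so the
dominant loading of each component is positive — determinism that plain
SVD does not provide.

## 4. Scanning kinetics

**FTT estimator.** Full-translation time is read from a continuous
luciferase recording as: threshold = mean + 3·SD of the first 3 points
(the pre-signal baseline); onset = first time with ≥ 2 consecutive
points above threshold; FTT = the x-intercept (at baseline level) of a
least-squares line through the first 4 above-threshold points, clamped
to no earlier than the last below-threshold time. The multiplier, window
and fit size are arguments. The estimator is exactly invariant under
uniform scaling of the signal and equivariant under time shifts, and on
noiseless piecewise-linear curves it recovers the onset exactly — which
is why the acceptance tolerance max(half the sampling interval, 0.2 min)
is met with margin at the 3-minute sampling the assay uses. A curve that
never exceeds threshold returns a structured "no detectable translation"
result (`detected = FALSE`), distinct from any numeric FTT.

**Synergy.** Dose–response tables are fitted to the median-effect
equation on its linearizing scale, log(fa/(1−fa)) = m·log d − m·log Dm;
points with fa outside (0,1) carry no information on that scale and are
excluded with a warning. The combination index is the mutually exclusive
Chou–Talalay form CI = d1/D1 + d2/D2 with D_i = Dm_i (fa/(1−fa))^(1/m_i);
the variant with the d1·d2/(D1·D2) cross term is behind `cross_term`
because the source analyses do not state which form was used and the
exclusive form is the common default.

## 5. Solvent-side geometry

The mRNA path 3′ of the entry channel is modelled as fully stretched
single-stranded RNA: distance = (position − 11) × 4.5 Å. No 3D
coordinates are computed — this is exactly the one-parameter projection
used to place crosslink positions on the 40S surface, and whether the
real path curves is unknowable from this model. Positions upstream of
+11 return signed negative distances with a warning rather than an
error, since "inside the channel" is a meaningful answer.

The duplex finder searches only contiguous, perfect, antiparallel
complementarity between an oligo and an rRNA window — the RNase H
protection logic: the enzyme cuts where a DNA–RNA heteroduplex actually
formed. GU wobble is off in DNA–RNA mode (not an RNase H substrate) and
optional for RNA–RNA questions. Ties go to the longest stretch, then the
smallest rRNA start, then the smallest oligo start.

## 6. What the synthetic data does and does not emulate

The generators produce every input the pipeline consumes, with noise
models chosen as the *minimal* ones matching each assay's variance
structure: multinomial read allocation with uniform background for RTTS;
negative-binomial counts for polysome profiling; i.i.d. base draws at a
target GC with verbatim motif planting for UTR sets; Gaussian baseline
noise around a piecewise-linear rise for recordings; Gaussian noise on
the median-effect curve for titrations. Everything is bit-reproducible
given the seed.

Stated-world defaults that the source material does not pin down, chosen
once: RTTS sequencing depth (the expected planted + background total;
depths per library were never published); gene baseline means lognormal
around 200 counts (a realistic bulk RNA-seq spread); spike-in means
lognormal around 500; and spike-in dispersion 0.002, separate from the
biological gene dispersion (default 0.05) — spike-ins are added to
purified RNA before library construction, so they carry technical,
near-Poisson variance only, and the pipeline's spike-null invariant
(median |FC TE| < 0.1) is a property of exactly that fact.

Deliberately not emulated: read sequences and sequencing errors (FASTQ
level), PCR duplication structure, sucrose-gradient optics, isoform
mixtures, correlated gene–gene expression, luciferase maturation
kinetics, and any real 18S sequence (the duplex tests construct
synthetic targets and label them as such). A green test therefore
establishes that the estimators recover what was planted under the
assumed noise model — not that the noise model is a complete description
of the assays.

## 7. Numerical conventions and degenerate inputs

* Pseudocounts: 0.5 on normalized counts before ratios/logs (half-count
  convention); 1 on raw counts in profile comparison.
* p-values are clamped into (0, 1]; a zero-variance gene with equal
  means is p = 1 by the no-signal convention, with unequal means it is
  the smallest positive double rather than 0.
* `dispersion = 0` in the count simulator is the deterministic limit —
  counts equal their means exactly, no rounding — so closed-form
  identities (spike doubling under a doubled size factor) hold exactly
  in tests.
* Empty profiles give `region_fraction` 0; empty position sets give
  empty contact tables; `n_reads = 0` still emits a truth table.
* All tie-breaks (site ranking, duplex selection, PCA signs) are
  deterministic and documented, so identical inputs give identical
  outputs across platforms.

## 8. Known limitations

The moderated test shares variance across genes but still tests each
gene marginally; it does not model the mean–dispersion relation of
counts as an NB GLM would, and at 2 replicates per group its power
depends strongly on the homogeneity of log2 TE variances. The Nussinov
score saturates for long GC-rich UTRs (it counts pairs, not energy).
The G4 scanner's no-skip chaining can miss a quadruplex whose loop
contains an unused qualifying G-run — a deliberate trade for unambiguous,
enumerable semantics. FTT estimation assumes the baseline window truly
precedes onset; recordings that start after translation has begun return
a clamped, biased estimate. The reported headline numbers of the source
study (counts of regulated genes, group GC/energy medians, absolute FTT
values) depend on deposited raw data and unreleased recordings and are
outside what synthetic data can or should reproduce.
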