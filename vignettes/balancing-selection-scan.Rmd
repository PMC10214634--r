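---
title: "Scanning for balancing selection: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for balancing selection: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balsel)
```

## The problem

Long-term balancing selection maintains two (or more) alleles at
intermediate frequency for timescales that can exceed the depth of the
neutral coalescent.  Around such a polymorphism, linked neutral variants
accumulate on both allelic backgrounds, producing a local excess of
intermediate-frequency SNPs, elevated nucleotide diversity, positive
Tajima's D, deep haplotype clades, and — relative to interspecific
divergence — an excess of polymorphism.  `balsel` implements a scan that
exploits each of these signals in turn on phased diploid resequencing data
(tens of individuals), with a coalescent simulator that makes every stage
testable against closed-form expectations.

The pipeline mirrors a two-stage design used in empirical scans of gene
families: a genome-wide, per-SNP allele-frequency-correlation statistic
shortlists genes against an *empirical* control-gene null, and the
shortlisted genes are then subjected to a likelihood-based
polymorphism/divergence test, window diversity profiling, LD-block calling
and haplotype networks.

## The beta statistic

For a core SNP at folded frequency $x_0$ (the minor-allele fraction,
$x = \min(c, n-c)/n$), the scan scores the SNPs within $\pm w/2$ bp
(default $w = 2000$) by their frequency similarity to the core:

$$\beta \;=\; \hat\theta_\beta - \hat\theta_{W,\mathrm{win}}, \qquad
\hat\theta_\beta = \frac{\sum_{i \ne 0} s(x_i, x_0)}{A(x_0)}, \qquad
s(x, y) = \Bigl(1 - \frac{|x - y|}{0.5}\Bigr)^p,$$

with $p = 2$ by default.  The normaliser
$A(y) = \sum_{k} s(k/n, y)\, e(k)$ and the window Watterson term
$\hat\theta_{W,\mathrm{win}} = m / \sum_k e(k)$ (with $m$ the neighbour
count and $e(k) = 1/k + 1/(n-k)$, $2/n$ at $k = n/2$) both sum only over
folded classes at or above the minor-allele-frequency floor (default
0.15).  Two consequences follow:

* the MAF filter does not itself bias the statistic — both estimators are
  normalised over exactly the frequency classes that survive it;
* the core SNP is excluded from both sums.  Including it would add a
  similarity of exactly 1 to $\hat\theta_\beta$ and one count to the
  Watterson term, and since $A(y) \le \sum_k e(k)$ these contributions do
  not cancel: the statistic would carry a strictly positive offset under
  neutrality.  With the core excluded, $E[\beta] = 0$ exactly whenever
  flanking frequencies are independent draws from the neutral folded
  spectrum.

**What "neutral" means for this calibration.**  The zero-mean property
holds under linkage equilibrium among window SNPs.  On a single
non-recombining genealogy, neighbouring frequencies are correlated with
the core through the shared tree even under neutrality, and the window
mean of $\beta$ is positive (at $n = 62$, $\theta_\mathrm{win} = 10$ the
offset is around $+2$).  This is not a defect of the statistic but a
property of fully linked windows; it affects candidate and control genes
alike, and the outlier call is made against the *empirical* control
distribution, which absorbs it.  The package therefore provides two
neutral generators: `simulate_neutral_locus()` (one genealogy per locus,
the realistic within-gene case) and `simulate_le_window()` (independent
folded-spectrum draws, the free-recombination limit), and the calibration
tests use the latter, while power, standardisation and end-to-end
calibration tests use the former.

**Standardisation.**  Mutation-rate heterogeneity along the genome moves
$\beta$'s scale.  A per-bp Watterson map is computed in fixed 10 kb tiles
(origin 0 per contig), each divided by the tile's *effective length* —
tile size minus the union of repeat and gap masks; fully masked tiles are
explicitly missing, never zero.  The standardised statistic is

$$\beta_\mathrm{std} = \frac{\beta}{\hat\theta_\mathrm{tile} \times
L_\mathrm{eff}(\mathrm{window})},$$

i.e. raw $\beta$ over the expected mutation supply of its own window,
which is dimensionless and comparable across genes.  SNPs within 1 kb of
an indel are masked (`"indel"`), as are cores without a theta tile
(`"no-theta"`), with fully masked windows (`"zero-eff"`) and windows with
no neighbour (`"empty-window"`).  A gene is summarised by the maximum
$\beta_\mathrm{std}$ over its unmasked SNPs, and called an outlier when
that maximum reaches the nearest-rank 95th percentile of the control-gene
maxima (ties count as outliers; nearest-rank avoids interpolation-scheme
ambiguity).

## The coalescent generators

*Neutral locus*: the standard Hudson coalescent without recombination —
exponential waiting times at rate $\binom{k}{2}$, mutations
$\mathrm{Poisson}(\theta L_\mathrm{tree}/2)$ placed uniformly on branches
under infinite sites, positions uniform on the locus.  This reproduces
$E[S] = \theta a_n$ and $E[\pi_\mathrm{total}] = \theta$ exactly, which
the test suite checks against Monte-Carlo standard errors.

*Balanced locus*: a two-class structured coalescent, the standard
strong-selection approximation for an old balanced polymorphism.  Sampled
haplotypes join class A with probability $f_\mathrm{eq}$ (default 0.5);
within a class of relative size $f$ pairs coalesce at rate
$\binom{k}{2}/f$; lineages exchange classes at rate $m_\mathrm{switch}$
(default 0.05); at $t_\mathrm{balance}$ (default 8, in units of $2N$
generations — i.e. several coalescent depths, an *old* polymorphism) the
structure dissolves into a panmictic coalescent.  One extra "balanced
site" column recording the class assignment is inserted at the locus
midpoint.  As $m_\mathrm{switch} \to \infty$ or $t_\mathrm{balance} \to
0$ the model collapses to the neutral coalescent, which is tested.  Note
that with appreciable $m_\mathrm{switch}$, some sampled lineages genuinely
switch backgrounds, so the sampled class labels and the deep clades need
not coincide — tests of clade recovery therefore run in the slow-exchange
regime ($m_\mathrm{switch} = 0.01$).

*Synthetic genome*: one gene per 10 kb tile on one contig, per-tile
$\theta$ log-normal (default median 0.005/bp, $\sigma_{\log} = 0.5$; no
empirical per-bp rate was available for the study system, so the median
was fixed once at a typical rodent nuclear value, which also makes the
default 2 kb window's mutation supply $\theta_\mathrm{win} = 10$), gene
lengths uniform on 1–10 kb, repeat/gap intervals and indel points
scattered per tile, and a truth table recording role, balanced flag and
tile $\theta$.  Deliberately *not* emulated: recombination within loci
(the scan's statistics do not require it and linked-block behaviour can be
exercised by concatenating independent segments), demography (growth,
bottlenecks, structure), sequencing error, ascertainment bias, and
genotype-likelihood uncertainty.  Passing tests therefore demonstrate the
statistical machinery, not robustness to those real-data features.

*HKA datasets* are drawn directly from the Poisson model the fitter
assumes (below), giving a clean parameter-recovery loop.

## The maximum-likelihood HKA test

Each locus $l$ contributes two independent Poisson counts: segregating
sites and divergent sites versus an outgroup,

$$S_l \sim \mathrm{Poisson}(k_l\,\theta_l\,a_{n_l}), \qquad
D_l \sim \mathrm{Poisson}(\theta_l\,(T + k_l)),$$

where $T$ is the shared divergence-time parameter and $k_l$ a per-locus
selection parameter, fixed at 1 for the 20-locus neutral reference panel
and free for the candidate.  $k$ is interpreted as a multiplier of the
locus's effective coalescent depth: it scales polymorphism *and* the
ancestral-polymorphism share of divergence (the "+$k$" term) but not the
split time $T$.  Because the original program's exact parameterisation is
not restated in the source we reimplement from, the alternative reading —
$k$ on polymorphism only, $D_l \sim \mathrm{Poisson}(\theta_l(T+1))$ — is
available via `k_on_divergence = FALSE` throughout (generator and fitter
share the switch; mixing the two inflates $\hat k$ to
$T k/(T + 1 - k)$ and is exactly the kind of mismatch the recovery tests
would catch).

For fixed $(T, k)$ the profile MLE of each $\theta_l$ is closed-form,
$\hat\theta_l = (S_l + D_l)/(k_l a_l + T + k_l)$, so the neutral fit is a
1-D bounded search over $T$ and the selection fit a low-dimensional
search over $(T, \log k)$ from five log-spaced $k$ starts in $[0.02,
50]$.  This deterministic optimiser replaces the original chain-based
maximiser; a Metropolis-style chain over the same likelihood
(`hka_fit_chain()`) is kept for cross-checking and agrees with the
optimiser in the tests.  The likelihood-ratio statistic
$\max(0, 2(\ell_1 - \ell_0))$ is referred to $\chi^2$ with one degree of
freedom per free $k$.  Type-I error at the study's design (20 neutral
loci, $\theta_l \in [5, 50]$, $T = 2$, $n = 62$) was verified calibrated
(5.3% at $\alpha = 0.05$ over 3000 null datasets during development; the
acceptance suite checks 500 at the exact binomial band).  A single locus
admits the exact solution $\hat\theta = S/a$, $\hat T = D/\hat\theta - 1$,
which the optimiser reproduces to $10^{-6}$.

Multiple testing is reported as a Bonferroni column over the number of
genes actually scanned (computed from the data, not hard-coded); no FDR
machinery.

## LD blocks and haplotype networks

$D' = |D|/D_\mathrm{max}$ is computed by direct haplotype counting.  Its
confidence bounds come from the multinomial likelihood of the four
two-site haplotype counts evaluated on a 1001-point $D'$ grid at fixed
observed margins, normalised to a weight distribution whose 5th/95th
percentiles are the bounds — a deterministic stand-in for the original
method's under-specified CI procedure; halving the grid moves the bounds
by well under 0.01.  Pairs are "strong LD" when the CI is within
$[0.70, 1]$ with upper bound $\ge 0.98$, "strong recombination" when the
upper bound is $< 0.90$ (the published defaults, all exposed in
`ld_block_config()`), and blocks are SNP runs where $\ge 95\%$ of
informative pairs are strong LD, taken greedily longest-first without
overlap.  SNPs below MAF 0.15 are removed first.

Median-joining networks use $\varepsilon = 0$: unique haplotypes are
linked by the minimum-spanning network (union of all minimum spanning
trees, keeping ties), per-column majority medians of node-neighbour
triplets are added to a fixpoint, and unsampled vectors that end with
fewer than three connections are pruned (they shorten no path).  Ties in
three-way median columns fall back to the first sequence of the triplet;
multi-allelic characters are reduced to presence/absence of the
non-reference allele.  `two_group_separation()` reports the largest
bridge on the network's minimum-spanning backbone and the observed
frequency on each side — a descriptive statistic of "two deep haplotype
groups", not a test.  Networks are built from a user-specified sub-region
(region selection is a config input, never inferred).

## Pipeline rules and numerical choices

* Window tiling is anchored at the region start; a final truncated window
  is emitted only when at least 25% of a window size would otherwise be
  uncovered (deterministic, testable; with the default 2000/500 preset the
  grid always covers the region, so no truncated window arises).
* The short-gene preset (500 bp windows, 50 bp steps) triggers when a
  gene is shorter than four window sizes; the trigger is configurable.
* Tajima's D on an empty window is flagged `NA`, never an error; a
  fully-masked window's per-site statistics are likewise `NA`.
* The ML-HKA stage runs only on beta outliers by default (`hka_all =
  TRUE` for exploration); an outlier without polymorphism/divergence
  input carries the explicit skip reason `"no-hka-input"`.
* The repeat-overlap SNP filter for the beta input is exposed as a config
  choice and off by default: repeat-region SNPs are assumed handled by
  upstream variant filtering, while repeat length is always excluded from
  effective lengths.
* Every filter stage logs counts in and out; reports are byte-identical
  across reruns of the same config and seed (no timestamps).
* Candidate-versus-control calibration: with nearest-rank percentiles on
  $m$ controls, an exchangeable candidate exceeds the $q = 95$ threshold
  with probability $(m + 1 - \lceil 0.95 m\rceil)/(m+1)$, which equals
  exactly 0.05 at $m = 99$; the end-to-end calibration tests use 99
  controls so the expected outlier count among 5 candidates is 0.25 per
  run with no discretisation offset.

## Problem sizes in the test suite

The acceptance checks run at: 2000 linkage-equilibrium windows (beta
calibration); 500 + 500 loci (power AUC); 500 null and 500 $k = 2.72$
HKA datasets (calibration and recovery); 5000 neutral loci (estimator
bias); a 150-gene $\theta$-heterogeneous genome (standardisation); and
200 all-neutral 104-gene genomes (end-to-end null calibration).  These
sizes put Monte-Carlo standard errors comfortably inside the asserted
tolerances while keeping the whole suite runnable on a laptop in minutes.

## Known limitations

* The beta statistic here fixes a specific folded similarity kernel and
  unbiased normaliser; numerical equality with external scan tools is out
  of scope (their exact kernel/normalisation differs in unpublished
  details), though the defining calibration and power properties are the
  same.
* Without recombination in the generator, LD blocks inside a simulated
  locus are trivially maximal; block-calling behaviour on recombining
  data is exercised only through constructed fixtures.
* The HKA model treats $S$ and $D$ as independent Poisson counts — the
  classical approximation; overdispersion from genealogical noise is not
  modelled (it is part of why empirical nulls are used upstream).
* The divergence counter compares one randomly chosen (seed-controlled)
  ingroup haplotype to the outgroup, matching the upstream protocol it
  reimplements, rather than averaging over haplotypes.
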