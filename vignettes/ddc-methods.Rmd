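---
title: "Methods: quantifying neutral subfunctionalization after gene duplication"
author: "ddcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neutral subfunctionalization after gene duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcquant)
```

This vignette documents the models behind `ddcquant`, the tunable
parameters and their defaults, what the synthetic-data generators emulate
(and deliberately do not), and the numerical and design decisions taken
where the methodology left genuine choices open.

## 1. Selection coefficients from competition counts

### Model

Two strains carrying different fluorophores compete in batch culture. With
red-cell frequency $R$ and green frequency $G = 1-R$, the deterministic
dynamic is $dR/dt = sRG$ with $t$ in generations, whose solution is the
logistic curve

$$R(t) = \frac{R(0)e^{st}}{(1-R(0)) + R(0)e^{st}},
\qquad \mathrm{logit}\,R(t) = \mathrm{logit}\,R(0) + st .$$

`logisticTrajectory()` works entirely on the log-odds scale, so extreme
frequencies never underflow. Flow cytometry counts $n_t$ cells per
timepoint (default 50{,}000, at generations 20 and 40, matching a
1024-fold daily dilution = 10 doublings/day), each cell an independent
red/green draw, giving a product-binomial likelihood. Its maximum is a
binomial logistic regression of red counts on generations:
`estimateSMLE()` uses iteratively reweighted least squares (deviance
tolerance $10^{-10}$, 200 iterations, non-convergence flagged); for exactly
two timepoints `estimateSClosedForm()` returns the identical answer in
closed form as the log-odds-ratio slope. Standard errors are delta-method
values from the log-odds regression; the assay's calls never use them
(they are informational — the replicate structure carries the inference).

Assumptions inherited from the assay design: no drift (the experiment is
short relative to the effective population size, about $3\times10^5$ by
the harmonic-mean calculation in `estimateNe()`), no new mutations during
the competition, transitive fitness ($s$ differences compose additively),
and generations taken as given by the dilution schedule.

### Censoring and calls

* total cells at any timepoint < 50 → `equally_lethal`, s = 0;
* either channel < 50 at **any** assayed timepoint (strongly deleterious
  genotypes are already undetectable at generation 20) → `censored_low`,
  reported at the signed bound |s| = 0.3;
* otherwise estimate.

The order matters: equal lethality is checked first, so no estimator ever
sees a zero count. The detection-limit rule — expected minority frequency
below 1/50{,}000 at generation 40 from $R(0)=0.5$ — solves by bisection to
$s = -0.2705$, not $-0.3$; the package reports the computed root and keeps
0.3 strictly as the reporting/censoring convention. These two numbers are
deliberately not reconciled.

Effects are called on fluorophore-swapped replicate pairs:
`deleterious`/`beneficial` only when **every** replicate exceeds
|s| ≥ 0.005 on the same side, `inconsistent` when signs disagree with at
least one exceeding the threshold, otherwise `no_detectable_effect`; a
negatively censored replicate forces `deleterious`. The 0.005 threshold
sits above the measured resolution (1.96 × null SD ≈ 0.0033) to absorb
day-to-day condition changes.

## 2. Synthetic competition data

`simulateCompetition()` draws one Gaussian perturbation of $s$ per well
(not per timepoint): replicate-to-replicate variation comes from
well-level growth conditions and background genetic differences, which
persist across both timepoints of a well. Its SD defaults to
`calibrateBioSd()`, which subtracts the estimator's binomial counting
variance from the target null-screen SD of 0.0017:

```{r}
calibrateBioSd()
```

so that a simulated 64-well null screen reproduces a fitted-s SD of
≈ 0.0017 by construction — the quantity is calibrated, then *measured*
downstream, never assigned. Counts are exact binomial draws from the
logistic trajectory; there is no simulation of cytometry events, gating,
doublets, drift or within-assay mutation. Passing tests therefore show
correctness of the estimator under the model's own noise structure, not
robustness to gating artefacts or non-logistic growth.

Screens are the full cross-product of green × red genotype lists
(8 × 8 = 64 wells; the 16 contamination-control wells are carried as a
count only, since their composition is not specified). The true
coefficient of a well is $s_{\text{red}} - s_{\text{green}}$, matching the
estimator's red-vs-green orientation; the matrix assembled for clustering
(`screenMatrix()`) negates this so that entry $(g,h)$ is genotype $g$'s
coefficient relative to $h$, and the transpose off-diagonals are the
fluorophore-swapped replicates.

## 3. Fitness classes and the landscape

### Clustering

`clusterFitnessClasses()` uses average-linkage agglomeration on
pairwise-complete Euclidean distance, rescaled by $\sqrt{p/p_{\rm obs}}$
so that missing competitions (wells not performed) do not shrink
distances. Ties in agglomeration are made deterministic by lexicographic
row ordering.

Flat classes cut the dendrogram at height $\sqrt{p}\cdot 0.005$: two
groups are distinct classes when their average profile distance exceeds
what a just-callable fitness difference (the 0.005 call threshold in every
competition) would generate. We chose this over the more common
largest-gap cut after finding the latter structurally unable to separate
nested plateaus: with classes at $s \in \{0, -0.015, \le -0.3\}$ the
bub1-like split dominates every gap statistic (absolute or relative) and
always returns two classes, collapsing a wild-type/mad3-like distinction
that is resolved at ten times the assay noise. The noise-scaled cut
recovers all three plateaus and still returns a single class for a matrix
of zeros. The class count is capped at 6.

### Landscape graph

Genotypes are element sets at the *BUB1* and *MAD3* loci
(`AlleleSpec`/`GenotypeSpec`); edges are single evolutionary events:
duplication (the occupied allele copied into the empty locus, running
under the new locus's promoter — promoter divergence is folded into the
duplication event and promoter-change events are otherwise excluded, since
promoter evolution was not assayed), loss of exactly one element, or loss
of a whole gene. No event re-creates an element. Degenerations are
therefore irreversible and the element/gene-loss subgraph is acyclic; the
one reversible step is the duplication itself, whose inverse is a
whole-gene loss (the single-copy ⇄ duplicated 2-cycle). The path search
carries a visited-node guard, so enumeration terminates on the full graph,
and is verified against independent graph-library path enumeration in the
tests.

Edge contrasts compose through the wild-type reference,
$s_{c,p} = s_{c,\mathrm{WT}} - s_{p,\mathrm{WT}}$ per replicate, when no
direct competition exists; a censored child makes the contrast censored;
an edge with no estimable contrast is labelled `unknown` and poisons any
path through it (`indeterminate`), never silently neutral. In the
synthetic rerun each biological replicate is the mean of two
technical-replicate wells before calling — mirroring the technical
re-assay of key genotypes in this kind of screen — because single-well
replicates at the 0.005 threshold produce ~2% spurious `inconsistent`
calls per truly neutral edge, enough to sever the one neutral path in
roughly one screen in ten.

`isAbsorbing()` implements the no-valley-crossing rule: a state is
absorbing when every outgoing single step is deleterious. A node with no
outgoing edges is vacuously absorbing (convention, documented here: the
claim of interest concerns the extant genotype, whose exits exist and are
all deleterious).

The bundled genotype set (`ddcGenotypeSet()`) is a synthetic
reconstruction: no complete table of assayed element compositions exists,
so the set encodes the published landscape's structure — single-copy
protein, duplication, a four-degeneration neutral backbone to the
extant-like pair, and the extant node's deleterious neighbours — with
fitness classes assigned by a presence rule (KEN1 somewhere ⇒ Mad3-side
checkpoint function; kinase domain somewhere ⇒ Bub1-side function). It is
labelled synthetic throughout and is not ground truth.

## 4. Constraint scanning

### Phylogenetic HMM

Emissions are Felsenstein-pruning column log-likelihoods under a
reversible empirical amino-acid model — exchangeabilities × stationary
frequencies, normalised to one expected substitution/site per unit branch
length, computed via the spectral decomposition of the π-symmetrised rate
matrix. The packaged default is the published WAG matrix (plain-text PAML
lower-triangle format, parser in `parseRateMatrix()`); the underlying
methodology names no substitution model, so the choice is isolated behind
`PhyloModel`. Gaps are missing data (partial-likelihood vectors of one).
Branch lengths are taken as given on the input tree and never
re-estimated.

The two rate states are conserved ($\rho_c < 1$, default 0.2) and
background ($\rho_b = 1$). Default self-transitions are 0.95; when
parameters are unknown, `fitHMM()` runs Baum–Welch with the conserved rate
re-optimised each iteration by bounded 1-D search, with 10 random restarts
— all these hyper-parameters are package decisions, as the methodology's
HMM details are not restated anywhere usable. Decoding thresholds the
forward–backward posterior at 0.5 (not Viterbi) with a minimum run length
of 3 columns, favouring short-motif sensitivity; each reported region's
rate is then re-fitted by bounded likelihood maximisation. Coordinates are
0-based half-open alignment columns everywhere.

### Relaxation test

Regions decoded on the pre-duplication sub-alignment are mapped through
shared rows into the full alignment (`mapRegions()`; identical ungapped
content enforced; regions fully gapped in a paralog are flagged
unalignable, not tested). `lrtConstraintChange()` compares one shared rate
multiplier against pre-/post-duplication rates, optimised by
golden-section search (tolerance $10^{-6}$, bound $\rho \le 10$, hits
flagged); the two-rate fit starts at the one-rate optimum, so
$\ln L_2 \ge \ln L_1$ holds by construction and the statistic
$2\Delta\ln L$ is referred to $\chi^2_1$. "Inside the post-duplication
clade" includes the stem branch leading to the flagged node, in both the
generator and the test — the duplication occurs along the stem, and using
one convention in both places keeps the null calibration exact (the
simulated type-I error at the 5% threshold is 4–6% over 1000 regions).
Multiple testing across region × clade tests uses Benjamini–Hochberg (the
original analysis does not state its procedure; FDR control is the
field-standard choice for this many-regions setting).

## 5. Exact count statistics

`fisherExact2x2()` enumerates the hypergeometric support in log space and
sums the probabilities of all tables no more probable than the observed
one (relative tolerance $10^{-7}$) — the probability-mass convention for
two-sided exactness, stated here because conventions differ; the all-zero
table returns p = 1 by convention. Sectoring comparisons keep the raw
sectored/white denominators and star at P < 0.001. Localization fractions
count both-compartment cells toward either marginal; bootstrap CIs are
percentile-based over cell resampling (for a single fraction this is an
exact binomial resample, which is how it is computed), and pairwise
comparisons use Holm–Bonferroni — again a package decision where only
"corrected for multiple testing" is specified.

## 6. Problem sizes and numerical choices

The shipped tests and the acceptance driver use: 64-well null screens;
8-genotype three-class screens, with 100 independent screens for the
recovery rate; 1000 simulated wells per operating point for estimator
calibration; 1000 simulated 30-column regions on an 8-taxon tree for the
LRT null; 50 seeds of 200-column, 4-taxon alignments (depth ≈ 1
substitution/site) for decoder recovery. These sizes put Monte-Carlo error
comfortably inside every asserted tolerance while keeping a full run in
the low minutes on one CPU.

Numerical safeguards: all frequency arithmetic in log-odds space; pruning
partial likelihoods rescaled per column only when they approach the
double-precision floor; transition probabilities clamped at zero and
row-renormalised after the spectral reconstruction; bisection brackets
checked before use; the LRT statistic floored at 0 (nested models).

## 7. Known limitations

* The competition generator is the inference model plus well-level
  Gaussian noise; it cannot reveal misspecification (non-logistic growth,
  gating errors, fluorophore cost asymmetries).
* The landscape encodes presence/absence of whole elements; partial
  degeneration, epistasis beyond the two-locus composition rule, and
  promoter evolution are out of scope.
* The constraint scanner assumes a correct, fixed alignment and tree;
  alignment error masquerades as rate variation.
* Censored fitness values enter clustering at the ±0.3 bound, so distances
  involving strongly deleterious genotypes are lower bounds.
* With n = 8 rows per screen, class-mean estimates carry ~0.001–0.002
  absolute error; the three-class structure is robust but mean values
  should be read at that precision.
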