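---
title: "Composite-likelihood demographic inference from the blockwise SFS"
author: "blockLik"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-likelihood demographic inference from the blockwise SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockLik)
```

## The model

A genome partitioned into blocks of fixed length $L$ can be summarized by
the *blockwise site frequency spectrum* (bSFS): for each block, the vector
$\underline{k}$ of mutation counts per joint-SFS class (singletons in each
population, shared polymorphisms, fixed differences, ...), and across
blocks the histogram $n_{\underline{k}}$ of these vectors. Unlike the
plain SFS, which depends only on expected branch lengths, the bSFS retains
the variation of genealogies across blocks, and therefore linkage
information at the block scale. Only unphased data are needed, because
mutation classes are defined by branch classes (how many sampled lineages
in each population a branch is ancestral to), not by individual branches.
Without an outgroup the spectrum is *folded*: each class vector is pooled
with its complement, and we represent the pooled class by the
lexicographically smaller vector.

Under the infinite-sites assumption, conditional on a genealogy with total
branch length $t_i$ in class $i$, the number of class-$i$ mutations in a
block is Poisson with rate $\theta t_i$, where
$\theta = 4 N_{\mathrm{ref}} \mu E$ is the block-scaled mutation rate and
$E$ the number of callable bases per block. The probability of a blockwise
configuration given branch lengths is the product of these Poisson terms;
classes with $t_i = 0$ contribute 1 when $k_i = 0$ and annihilate the
product otherwise. With intra-block recombination the block's history is
an ancestral recombination graph (ARG); its marginal genealogies with
spans $w_p$ are reduced to the span-weighted average class lengths
$t_{i,A} = \frac{1}{L}\sum_p w_p\, t_{i,p}$, after which the same Poisson
product applies with $t_{i,A}$ in place of $t_i$. This reduction is the
only genealogical information the likelihood ever sees, which is what
makes the approach scale: each simulated ARG contributes to the
probability of *every* configuration.

The likelihood of a parameter vector $\Theta$ is approximated by Monte
Carlo: sample $\mathcal{M}$ ARGs from the coalescent with recombination
under $\Theta$, average the conditional configuration probabilities over
the draws, and weight log-probabilities by the observed block counts:

$$\hat p(\underline{k}) = \frac{1}{\mathcal{M}} \sum_{d=1}^{\mathcal{M}}
  p(\underline{k} \mid \underline{t}_d), \qquad
  \ln \mathcal{L}(\Theta) = \sum_{\underline{k}}
  n_{\underline{k}} \ln \hat p(\underline{k}).$$

Treating blocks as independent makes this a *composite* likelihood: the
point estimate is consistent, but physical linkage between blocks means
the curvature overstates confidence, which is why uncertainty comes from a
parametric bootstrap on linked data rather than from the likelihood
surface.

### Configuration space and lumping

For analyses over a complete configuration table, per-class counts are
capped at some $k_{\max}$ and all larger counts pooled into one tail class
whose probability is the upper Poisson tail (computed via the complemented
regularized incomplete gamma function, stable for large $k_{\max}$). This
guarantees the table of probabilities sums to one exactly for every single
ARG, and hence for the Monte-Carlo average — a property the test suite
asserts to $10^{-12}$. When tabulating data, the default is instead to
compute probabilities only for configurations actually observed, with no
cap. For a folded two-populations-by-two-genomes sample at
$k_{\max} = 4$, excluding configurations whose classes cannot co-occur on
a single non-recombining genealogy (a shared polymorphism together with a
fixed difference), 396 configurations remain:

```{r enumerate}
lay <- sampleLayout(c(2, 2), blockLength = 2000, effectiveLength = 1600)
nrow(configMatrix(enumerateConfigurations(lay, 4, noRecombination = TRUE)))
```

The incompatibility is established by exhaustive enumeration of labeled
topologies, not hard-coded; the same routine generalizes to any sample of
up to seven genomes.

## The ARG sampler

No installed R package simulates the structured coalescent with
recombination, so the package implements it in C++ (Rcpp): Hudson-style
ancestral-material tracking with population splits (viewed backward as
lineage joins), instantaneous size changes, exponential growth,
continuous migration and admixture pulses. Conventions, fixed once and
used everywhere:

* time in units of $4 N_{\mathrm{ref}}$ generations, backward from the
  present (constructors for the small reference histories used in
  analytic comparisons accept $2 N_e$-unit times and divide by two, the
  convention in which those models are usually stated — this prevents
  silent factor-of-two errors);
* the pair-coalescence rate in a population of relative size $f$ is
  $2/f$;
* a continuous migration rate stated forward in time as "$M = 4Nm$
  migrants from A to B" moves lineages from B to A backward in time at
  per-lineage rate $M$;
* an admixture pulse of fraction $f$ from donor A into recipient B sends
  each of B's lineages to A with probability $f$ at the pulse time,
  backward in time;
* recombination breakpoints are continuous within the block, with total
  rate $\rho = 4 N_{\mathrm{ref}}\, r (L - 1)$ over the $L - 1$
  inter-site gaps, and the per-lineage rate proportional to the extent of
  carried ancestral material (trapped material included).

These conventions were validated against an independent coalescent
implementation during development; within the package they are pinned by
closed-form checks (pairwise coalescence times, the $1/i$ scaling of
neutral class lengths, the geometric blockwise law below) and by the
congruent/incongruent genealogy fractions of a two-population
isolation-with-migration history, which the acceptance script recomputes.

A useful closed form for testing: for a pairwise sample from a single
constant-size population without recombination, integrating the Poisson
likelihood over the exponential coalescence time gives
$P(k) = \theta^k / (1+\theta)^{k+1}$. Monte-Carlo estimates converge to
this law as $\mathcal{M}$ grows, and the repeated-evaluation standard
deviation of the log-likelihood shrinks like $1/\sqrt{\mathcal{M}}$; both
are asserted in the test suite.

## Tabulation choices

* Blocks are half-open, 0-based `[start, start + L)` windows per contig.
* A block is retained iff at least $qL$ bases (default $q = 0.8$) are
  callable in all individuals, and exactly the *first* $qL$ passing bases
  are used, so every retained block has the same effective length
  $E = qL$.
* Sites with any missing genotype are dropped from their block;
  multi-allelic sites violate infinite sites and are dropped; both are
  counted and reported, never silent.
* Polarized tabulation requires the VCF `AA` field and refuses to guess.
* Serialized class order is deterministic: lexicographic in the class
  vectors (canonical representatives for folded data).

The *composite* bSFS (cbSFS) pools configurations over genome subsamples
(for example every pair of consecutive diploids, or all subsets of two
diploids per population), so that arbitrarily large samples can be
analyzed at small-sample cost. Each block contributes one configuration
per subsample, and identical configurations from different subsamples of
the same block are all counted; a scheme consisting of exactly the full
sample reproduces the plain bSFS, table-exactly.

## Optimization

The Monte-Carlo likelihood is noisy, so gradients are unreliable; the
search is derivative-free and two-staged. The global stage is a
controlled random search (CRS2 with local mutation, written in R) over
broad bounds; the local stage runs replicated Nelder-Mead simplexes
(Brent in one dimension) inside bounds narrowed to the envelope of the
global replicate bests, expanded by 25% in log space. Positive parameters
(sizes, times, rates) are searched on log scale; growth rates and
admixture fractions on linear scale. Infeasible points — outside bounds
or violating ordering constraints such as "the admixture pulse precedes
the split" — return a rejection sentinel that the optimizers skip without
stopping, rather than a penalized value from an augmented-Lagrangian
scheme; for box-plus-ordering constraints the two behave identically at
the optimum and the rejection rule is simpler to reason about. Within a
stage, evaluations reuse common random numbers (the same ARG draws per
replicate) so each replicate optimizes a deterministic surface; fresh
draws are taken between replicates and for the final re-evaluation.

The reference protocol evaluates 50,000 ARGs per point in 10 global
replicates, 500,000 in 20 local replicates, and reports the best point
re-evaluated with $10^6$ ARGs; a single `scale` argument shrinks all
three for pilot runs. The package's own test suite exercises a reduced
protocol (300-2,000 ARGs per evaluation, 3-4 replicates per stage,
20,000 blocks of 2 kb) chosen so that the full recovery-plus-bootstrap
experiment completes in a few minutes; at that scale the four free
parameters of the two-population divergence model are recovered within
two bootstrap standard deviations of the truth. Observed configurations
that receive zero Monte-Carlo mass are floored at
$1/(10\mathcal{M})$ and counted in the result, so a vanishing tail
penalizes a parameter point without producing $-\infty$; the count is
reported whenever the floor triggers.

## Synthetic data and experiments

The generator simulates blockwise data under any model in the family:
independent blocks for power studies, or long contiguous stretches
(default 0.5 Mb, as in the bootstrap design the method was introduced
with) cut into consecutive blocks, so that the between-block correlation
the composite likelihood ignores is present in the bootstrap replicates —
a deliberately conservative design. Mutations are placed by a Poisson
process on the ARG's branch records under infinite sites; for
genotype-level output, positions are drawn uniformly over the callable
bases and discretized to distinct integers (collisions redrawn). Marginal
per-block expectations of stretch-linked and unlinked simulations agree;
only the cross-block covariance differs.

What the generator deliberately does not emulate: heterogeneity of
mutation and recombination rates across blocks (the likelihood assumes
exchangeable blocks), gene conversion, selection, sequencing error and
genotype-calling artifacts. Passing recovery tests on these simulations
therefore demonstrates correctness of the inference machinery under the
model's own assumptions, not robustness to the ways real data violate
them.

The parametric bootstrap re-fits each replicate with local searches only,
started around the fitted point, and reports per-parameter standard
deviations (sample SD, $n-1$) and MCLE $\pm 2$SD intervals. The
misspecification driver compares candidate models on data simulated under
a known truth, either by full fits or by point evaluations at the true
values — including "R-variant" candidates whose split time is replaced by
the true admixture time, the comparison that shows split-plus-admixture
histories become indistinguishable from clean splits when the two events
are close.

## Numerical choices

* Per-ARG configuration probabilities are computed in log space and
  exponentiated; the Monte-Carlo average is accumulated with compensated
  (Kahan) summation in linear space, because the estimator is an
  arithmetic mean of probabilities, not of log-probabilities.
* The Poisson tail of the lumped class uses the complemented regularized
  incomplete gamma rather than one-minus-partial-sum.
* The simulator caps iterations and reports the offending scaled event
  list if a model leaves lineages unable to coalesce (for example two
  populations with neither migration nor a join).
* Sample size is capped at 40 genomes (branch classes are tracked as
  64-bit masks); the cbSFS is the intended route for larger samples.

## Open choices made here

* Whether the original tool bounds the admixture-before-split ordering or
  merely initializes inside it is not documented; the constraint is
  enforced here.
* Whether zero-mass observed configurations are floored or dropped is not
  documented; they are floored (configurably) and the count is reported.
* The cbSFS counts a configuration once per subsample, without
  deduplicating identical subsample configurations within a block.
* Tabulation defaults to observed-configurations-only (no $k_{\max}$),
  with lumping available when a complete probability table is wanted.

## Limitations

Composite-likelihood confidence requires the bootstrap; the likelihood
surface alone is overconfident under linkage. Block length is a fixed,
arbitrary choice: too short discards linkage information, too long makes
single blocks span many genealogies; the combinatorics also grow quickly
with sample size, which is where the cbSFS helps. Growth-rate and
migration parameters near bounds can be weakly identified at desk-scale
Monte-Carlo budgets; the two-stage search reports per-replicate traces so
disagreement between replicates is visible rather than averaged away.
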