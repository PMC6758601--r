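---
title: "Detecting introgression with partitioned D-statistics and Quartet Sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgression with partitioned D-statistics and Quartet Sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RAD-seq phylogenies of rapid radiations routinely recover well-supported
clades whose *relationships to each other* differ between datasets and
inference methods.  Two biological processes produce such discordance:
incomplete lineage sorting (ILS), which is stochastic and symmetric, and
introgression, which is directional and asymmetric.  `pentad` implements the
two complementary ways of telling them apart at clade level, together with a
simulator that generates RAD-like data where the truth is known:

1. **Partitioned five-taxon D-statistics** quantify the asymmetry of
   discordant biallelic site patterns and attribute it to one donor
   sub-lineage, the other, or their common ancestor.
2. **Quartet Sampling** measures, branch by branch, how often randomly
   sampled quartets support the focal topology (QC), how skewed the two
   discordant alternatives are (QD, the ILS-vs-introgression signature),
   how informative the data are (QI), and which taxa behave roguishly (QF).

## The partitioned D model

Take five groups arranged as `(((P1, P2), (P3a, P3b)), O)`.  Samples within
each clade are pooled into one population, and each biallelic site
contributes through its *derived-allele frequencies*
`(p1, p2, p3a, p3b, pO)`, polarized so that the outgroup's minor allele is
derived.  The six discordant patterns in which a derived allele is shared
between the P3 side and exactly one of P1/P2 are accumulated as products of
frequencies, e.g.

$$w_{ABBAA} = (1-p_1)\,p_2\,p_{3a}\,(1-p_{3b})\,(1-p_O),$$

so totals are fractional when lineages are polymorphic ("A" = ancestral,
"B" = derived, positions ordered P1, P2, P3a, P3b, O).  The three statistics
are normalized differences of paired totals:

$$D_1 = \frac{n_{ABBAA} - n_{BABAA}}{n_{ABBAA} + n_{BABAA}},\qquad
  D_2 = \frac{n_{ABABA} - n_{BAABA}}{n_{ABABA} + n_{BAABA}},\qquad
  D_{12} = \frac{n_{ABBBA} - n_{BABBA}}{n_{ABBBA} + n_{BABBA}}.$$

Under ILS alone each D has expectation zero; introgression between `P3a` and
`P2` drives `D1` positive, between `P3a` and `P1` negative, `D2` reads the
same way for `P3b`, and `D12` captures alleles donated by the common
ancestor of `P3a` and `P3b`.  Note that the `D12` numerator uses the ABBBA
class (derived allele in both P3 sub-lineages and exactly one of P1/P2);
result tables that label this column "ABAAA" are using a misprinted header
for the same quantity, since an ABAAA site is an uninformative autapomorphy.

Significance comes from a nonparametric bootstrap over loci (the exchangeable
unit in RAD data): loci are resampled with replacement, D recomputed per
replicate, and `Z = |D| / SD(D_boot)`.  The per-locus pattern subtotals are
sufficient statistics for this resampling, so the implementation precomputes
them once; this is numerically identical to re-running the whole pipeline on
each replicate.  The default threshold is `z* = 2.55` with 1000 replicates.
When a denominator is zero the statistic is reported as 0 with a flag, and a
zero bootstrap SD is reported as `Z = Inf` with a degeneracy flag, so result
tables stay total.

Two locus-level rules control which sites count.  A site is usable only if,
at its locus, *every* clade involved in the test retains at least one third
of its samples (the minimum-coverage rule familiar from RAD assembly
filters), and only if every role has at least one called genotype at the
site.  Sites where the pooled outgroup frequency is exactly 0.5 are dropped:
the outgroup then carries no orientation information.  Residual outgroup
polymorphism below 0.5 is down-weighted smoothly by the `(1 - p_O)` factor
rather than discarded.  All usable SNPs per locus contribute by default;
`pattern_counts(..., snps = "one_per_locus")` trades information for strict
between-site independence, for users worried about intra-locus linkage.

Configurations are enumerated from the clade tree: every assignment in which
`{P1, P2}` and `{P3a, P3b}` are sister pairs and the pairs are themselves
sisters, with everything else pooled into `O` — 8 ordered assignments per
balanced quartet, collapsible to 4 with `canonical = TRUE`.  The tests for
different configurations share data and are *not* independent; `pentad`
reports all of them and leaves multiplicity interpretation to the analyst,
with `interpret_d()` translating signs into donor/recipient statements.

## Quartet Sampling

Each internal branch of an unrooted binary focal tree splits the taxa into
four subsets.  A replicate samples one taxon per subset (accepting the draw
only if all six pairwise alignment overlaps meet `min_overlap`, retrying up
to `max_attempts` times), then resolves the quartet by maximum likelihood
under JC69: the three unrooted topologies are scored by Felsenstein pruning
over site-pattern counts, with the five branch lengths optimized by cyclic
one-dimensional search (tolerance `1e-6`, at most 25 sweeps).  The replicate
is informative when the best topology beats the runner-up by at least
`lnl_cutoff` (default 2) log-likelihood units; exact ties are uninformative.
A Fitch-parsimony engine is provided as a fast, independent alternative and
as the cross-check used in the test suite.

With `t0` concordant and `t1`, `t2` discordant informative counts
(`s = t0 + t1 + t2`, `p_i = t_i/s`):

* `QC = 1 + sum p_i log3 p_i` when the concordant topology has the
  plurality, negated otherwise; `QC = 1` means unanimous support, `0`
  maximal confusion, negative values counter-support.
* `QD = 1 - |t1 - t2|/(t1 + t2)`: near 1 when the two discordant topologies
  are balanced (the ILS signature), near 0 when one alternative dominates
  (the introgression signature).  Other monotone skew measures exist; this
  complement-of-skew form is used because it is exact at both endpoints and
  linear in between.
* `QI = s / n` over successfully drawn replicates.  Scoring against
  successful rather than attempted draws keeps QI a statement about the
  *data's* decisiveness, with overlap failures reported separately per
  branch rather than folded into informativeness.
* `QF(taxon)`: over all informative replicates containing the taxon, the
  fraction concordant — low values flag rogue taxa.

Branch results are serialized into Newick node labels as `QC/QD/QI` strings
(undefined values rendered `-`, so a unanimous branch prints `1/-/1`).

## The synthetic-data generator

`generate_dataset()` composes four stages, each deterministic given the
master seed (per-stage substreams are derived at fixed offsets, so stages
are reproducible in isolation):

1. **Gene trees** from the multispecies coalescent on a species tree with
   node times in coalescent units (2N generations) and per-branch relative
   population sizes: within a population of k lineages, coalescence at rate
   `k(k-1)/2 / N`.  Admixture pulses are simulated backward in time as
   lineage reassignment — at the pulse time each lineage in the recipient
   branch jumps to the donor branch with probability `fraction` — which is
   the standard, exact and cheap encoding of an instantaneous admixture
   event.
2. **Sequences** under JC69 with no rate heterogeneity and no indels; the
   statistics under test are model-light, and a minimal substitution model
   keeps analytic oracles (pairwise JC distances, expected variable-column
   counts) available for validation.
3. **Dropout**: each (sample, locus) pair is erased independently with
   probability `dropout` (optionally per clade), emulating whole-locus
   RAD dropout.  Mutation-at-cut-site dropout, reference bias and
   sequencing error are deliberately not modeled; the goal is to exercise
   the coverage rules and filter cascade, not to emulate a sequencer.
4. **SNP extraction**: biallelic variable columns become a dosage matrix;
   `filter_min_samples()` applies the minimum-samples-per-locus rule and
   `filter_cascade()` tabulates locus count, concatenated length and SNP
   count over a threshold series.

Samples are haploid by default; two haploid samples can stand in for a
diploid, since every downstream statistic consumes pooled allele
frequencies and ploidy is presentation.

### Default study design

The default configuration (`five_clade_config()`) emulates the structure the
clade-level analysis assumes: five ingroup clades `I`, `II`, `III`, `IV`,
`V` plus an outgroup `OG` on `((((I,II),(III,IV)),V),OG)`, four haploid
samples per clade, 500 loci of 64 bp, 20% dropout.  Split times (coalescent
units): `III|IV` at 1.0, `I|II` at 1.5, the two pairs joining at 2.5, `V` at
3.5, `OG` at 5.0.  The `(I,II)` split is deliberately deeper than
`(III,IV)` so that a tip branch of one pair coexists in time with the
ancestor branch of the other pair, making ancestral-introgression scenarios
expressible.  The mutation rate (0.0055 per site per coalescent unit) was
chosen so a 64-bp locus carries ~10 SNPs, the density typical of
moderately filtered RAD assemblies.  No divergence-time estimates exist for
the empirical system this design abstracts, so the times are generic
coalescent-unit choices, not a calibrated history.

Introgression scenarios used in validation place a *recent* pulse
(`t = 0.1`, fraction 0.3) from a P3 tip into `P2` for the tip-introgression
case — recent, because the longer an introgressed lineage resides in the
donor branch the more its signal leaks into the sister sub-lineage and the
ancestral class, which is a property of the model rather than of the
estimator — and an ancestral pulse at `t = 1.2` from the `(III,IV)` ancestor
branch (which exists from 1.0 to 2.5) into the `II` tip branch (which
persists to 1.5).

### What passing tests do and do not show

The generator reproduces the statistical skeleton the analysis relies on —
coalescent gene-tree discordance with known expectations, directional
allele sharing after pulses, hierarchical missingness, fractional weighted
counts — so green tests demonstrate that the estimators recover known
truth under the model's own assumptions at desk scale.  They do not
demonstrate robustness to assembly error, paralogy, sequencing error, rate
heterogeneity, or selection, none of which are simulated.

## Numerical choices and degenerate inputs

* Weighted counts are plain double sums; the per-locus decomposition keeps
  bootstrap resampling exact.
* `D = 0` (flagged) on zero denominators; `Z = Inf` (flagged) on zero
  bootstrap SD; both keep tables total rather than propagating NaN.
* Multiallelic VCF records are dropped, not decomposed: the five-taxon
  pattern algebra is defined on biallelic sites.
* Allele-tally ties in `alignment_to_snps()` break alphabetically, making
  SNP extraction order-independent (polarization later re-orients alleles
  anyway, so the tie-break cannot affect D).
* Quartet likelihood optimization is bounded to branch lengths in
  `[0, 10]` substitutions/site; exact likelihood ties between topologies
  are declared uninformative rather than broken arbitrarily.
* VCF positions are 1-based (the format's convention); alignment locus
  bounds are 0-based half-open internally.

## Problem sizes used in the validation suite

Calibration and recovery checks in the test suite run at deliberately
moderate sizes, chosen as the smallest designs whose expected effects are
well separated from their Monte-Carlo noise: 200 null datasets (500 loci x
64 bp) for type-I calibration of Z with 300 bootstrap replicates; 50
replicate datasets per introgression scenario; Quartet Sampling limit
checks at 100 replicates per branch on 8-taxon trees with 150 loci.  The
analysis defaults exposed to users remain 1000 bootstrap replicates and 500
quartet draws per branch.

## Known limitations

* Clade pooling assumes free intra-clade exchangeability; strong internal
  structure within a pooled clade dilutes but does not bias D.
* D tests over nested configurations share data; no multiplicity
  correction is applied, matching standard practice, and the output
  documents this.
* The JC69 quartet engine is deliberately minimal; strongly
  rate-heterogeneous data would call for a richer engine (the engine is
  pluggable).
* The simulator does not model linkage between loci, nor within-locus
  recombination (each locus is one non-recombining gene tree, the standard
  RAD approximation).
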