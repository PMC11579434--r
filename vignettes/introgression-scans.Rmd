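---
title: "Detecting and characterizing introgression across a radiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing introgression across a radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

When a clade radiates quickly, most gene trees disagree with the species
tree because ancestral polymorphism persists across short internodes
(incomplete lineage sorting, ILS). Hybridization adds a second source of
discordance — introgressed loci group the recipient with its donor — and
the statistical task is to separate the two. `introscan` implements a
family of complementary scans that do this from per-locus gene trees and
alignments on a rooted species tree:

* **rooted-triplet (RT) tests** on gene-tree topology counts,
* **ABBA-BABA D-statistics** on thinned biallelic site patterns with
  block-jackknife significance,
* an **f-branch summary** that assigns the signal to terminal *and*
  internal branches,
* **divergence-based polarization (DIP)** of the direction of gene flow,
* **collapsing** of correlated significant tests into discrete
  hybridization events,

plus a multispecies-coalescent (MSC) simulator with hybrid edges that
generates data with known introgression histories, used throughout the
test suite.

## Rooted-triplet tests

For a sister pair (P1, P2) and a third taxon P3, every gene tree
containing all three plus the outgroup is classified into the major
topology (P1,P2), or one of the two minor topologies (P1,P3) and (P2,P3).
Under the MSC without gene flow the two minor topologies are exchangeable,
so their counts follow Binomial(minor1 + minor2, 1/2). We use the exact
two-sided binomial probability (not a normal approximation — after
family-wise correction at 0.001 the decisive counts can be small), and
Holm–Bonferroni over all tests of one scan invocation. The scan family is
one test per (sister pair × other ingroup tip).

For a significant test the introgression proportion is estimated as

$$\hat\gamma = \frac{\text{minor}_2 - \text{minor}_1}
                  {\text{major} + \text{minor}_1 + \text{minor}_2},
\qquad \text{minor}_2 \ge \text{minor}_1 ,$$

attributed to the pairing of P3 with the sister-pair member carried by
minor₂. For an instantaneous pulse of proportion $\gamma$ whose moved
lineage spends $t'$ coalescent units alone with the donor lineage, the
estimator's expectation is $\gamma(1 - e^{-t'})$
(`expected_rt_gamma()`); the simulator reproduces this law and the test
suite checks it at 50,000 loci.

Unresolved pruned topologies (polytomies after support collapsing) are
excluded from all three counts — resolving them at random would dilute
real signal and manufacture none. Gene-tree branches below a support
threshold can be contracted first (`collapse_low_support()`); edges
without any support annotation are never contracted, since absence of an
annotation is not evidence of low support.

## Site-pattern tests

Per-locus alignments are concatenated (taxa absent from a locus are
gap-padded), and for every trio of ingroup taxa arranged to match the
species tree, biallelic sites without gaps or ambiguity in the four
relevant rows are extracted, thinned greedily left-to-right to at least
500 bp spacing (linked sites carry little independent information), and
classified into ABBA / BABA / BBAA with the outgroup allele as the
ancestral state. D = (ABBA − BABA)/(ABBA + BABA); significance comes from
a delete-one block jackknife over 40 contiguous blocks of near-equal
size, a two-sided normal p-value on Z = D/SE, and Holm adjustment over
the scan. Trios where every jackknife block carries an identical D (for
example ABBA > 0 with BABA = 0 at low counts) are reported with infinite
Z and flagged rather than dropped; with informative data this does not
occur. A per-trio flag records when ABBA exceeds BBAA — the site pattern
produced by gene flow outnumbering the one produced by vertical
inheritance, a useful diagnostic for strong or ancestral events.

Each taxon contributes a single haploid sequence, so "allele frequencies"
are 0/1 and pattern counts are integer tallies; sites where the outgroup
carries the globally minor allele still polarize by the outgroup state.
f₄-ratios are deliberately not implemented: the γ estimates from the
triplet tests play that role everywhere downstream, including inside the
f-branch summary.

## f-branch

Correlated trios blur the picture when the true event involved an
ancestral lineage. The f-branch summary assigns signal to every branch
$b$ (terminal or internal, root excluded):

$$f_b(b, P3) = \operatorname{median}_{A \in \mathrm{desc}(\mathrm{sister}(b))}
   \left[ \min_{B \in \mathrm{desc}(b)} \; s(A, B, P3) \right]$$

where the score $s$ is the signed triplet γ: positive when the excess
minor pairing joins $B$ with P3, negative when it joins $A$. Trios tested
but not significant score 0 (the conservative imputation — scoring them
NA would bias medians upward; a flag switches to NA-skipping), untested
trios are NA and are skipped inside min and median; a cell with no
defined term, or a branch with no sister, is NA. The root's two child
branches are each other's sisters. In `run_scan()` the score provider is
built from triplet tests over *all* tree-arranged trios, Holm-corrected
within that family, so the f-branch stage is self-contained even when no
alignments are supplied.

## Direction of gene flow

DIP reasons from pairwise divergences stratified by gene-tree topology
class. For a framing (P1, P2; P3), class C holds concordant loci, D23
the loci grouping P2 with P3, and D13 those grouping P1 with P3. The
basic contrast Δ12 = mean(d12 | D23) − mean(d12 | C) is positive under
introgression *and* under pure ILS (discordant loci coalesce deeper), so
inference uses the ILS-corrected contrast

$$\Delta_{12}^{corr} = \overline{d_{12}}^{\,D23} - \overline{d_{12}}^{\,D13},$$

which has expectation zero under pure ILS because the two discordant
classes are exchangeable under P1 ↔ P2 relabeling (the package asserts
this antisymmetry exactly). Significance is assessed by a locus
bootstrap.

The sign semantics deserve care, and we derived them from the pulse
model rather than folklore. When P2 donates into P3, the introgressed
loci land in D23 with an *ordinary* sister divergence d12 — P2's own
lineage never leaves its branch — so the D23 stratum mean drops below
the D13 control and the contrast is strongly negative. When P3 donates
into P2, d12 at introgressed loci remains deep (the recipient's lineage
traces the donor's branch), and the contrast moves only weakly (it is
the coalescent 2/3-unit gap between two- and three-lineage joining
depths, not a topological shift). A significantly *positive* contrast is
the mirror image and implicates P1 as the donor into P3. A single
framing therefore localizes the recipient to the third slot; calling the
direction between a pair (x, y) requires the corrected contrast in both
candidate-recipient framings — (sister(x), x; y) and (sister(y), y; x) —
which is how `run_scan()` proceeds (the double-framing strategy).

Because both framings can reach significance, the framings are compared
with a recipient-enriched statistic: within D23, loci whose cherry
divergence d23 is at or below the stratum median are predominantly
introgressed rather than deep-coalescing, and the contrast of their d12
against the D13 control separates the two directions by roughly twice
the species-tree depth gap instead of the 2/3-unit coalescent residue.
This purified contrast is slightly negative under the null by
construction (conditioning on a shallow cherry selects slightly shallower
joining depths), so it is used strictly for *comparing* framings after at
least one corrected contrast is significant, never as a detection
statistic. With no significant contrast the event keeps a bidirectional
arrow — the same convention the scans' outputs use for "no evidence of
asymmetry", and events whose donor-side control stratum is starved of
ILS loci (a long-stemmed donor cherry leaves almost no discordant
control loci) honestly resolve to "bidirectional" rather than to a
guess.

p-distance is the default divergence: the radiations this is built for
are young, distances are small, and p-distance is monotone in the JC
distance there; patristic distances on the gene trees are available by
flag for tree-only workflows.

## Event collapsing

Significant triplet tests implicate unordered taxon pairs. Pairs sharing
one side are merged into an ancestral event when the tips on the other
side form a species-tree clade with at least two of them independently
significant against the same partner; a clade member that was testable
against that partner but not significant blocks the merge. The event is
placed on the clade's stem branch and labelled with the full clade, its
γ is the f-branch-style median-of-minima over the supporting tests'
estimates, and the same grouping is then applied on the partner side.
Events whose pair set is contained in another event's (the same edge
seen from the other orientation) are dropped. Chains A↔B, B↔C, A↔C in
which the A↔C estimate is the smallest are flagged as bridge candidates
— a pattern that arises when a promiscuous intermediate ferries alleles
between taxa that never hybridized — but never deleted automatically:
on simulated data with a strong planted edge the package itself
reproduces such indirect signals, which is a faithful property of
triplet scans, not an artifact to hide.

## The simulator

`simulate_gene_trees()` implements the MSC on a species tree with
instantaneous-pulse admixture: tracing tipward-to-rootward, lineages
co-resident in a branch coalesce at rate 1 per pair per coalescent unit,
and at a hybrid pulse each lineage on the recipient branch jumps to the
donor branch independently with probability γ (bidirectional edges
exchange simultaneously). The pulse formulation matches the γ
interpretation of every downstream estimator, which is why continuous
migration was not used. `simulate_alignments()` evolves i.i.d. sites
under JC69 along each gene tree, with coalescent branch lengths
multiplied by a single rate knob (substitutions per site per coalescent
unit). Random streams are keyed per locus by (seed, locus index), so any
subset of loci reproduces bit-identically regardless of the total count.

`costus_like_preset()` fixes the study-scale conditions: 54 ingroup tips
(27 cherries on a caterpillar backbone with 0.25-unit internodes —
pervasive ILS), one outgroup at 15 coalescent units (guaranteeing
correct rooting and near-fixed ancestral alleles), 756 loci of 1951 bp,
rate 0.005 substitutions/site/unit, and three hybrid edges with γ =
0.10, 0.22, 0.45 (two tip-to-tip, one into the stem of a cherry). The
rate was chosen so that a trio's thinned biallelic SNP table lands near
2,900 sites, the order observed in real exon-capture workflows of this
design; the edge placements are illustrative, since no empirical joint
values of γ and branch length exist to emulate.

What the generator does *not* emulate: intralocus recombination,
demographic size changes, gene-tree estimation error, sequencing error,
multiple samples per species, and rate variation across sites or
lineages. Passing tests on this generator therefore demonstrate
statistical correctness of the estimators under the MSC-with-pulses
model, not robustness to those real-data complications; the triplet
machinery in particular inherits the known sensitivity of gene-tree
methods to estimation error, which upstream support-collapsing only
partially mitigates.

## Numerical choices and problem sizes

* Exact binomial tails via `pbinom`, doubled and capped at 1; the
  degenerate zero-minor test has p = 1 and is retained in the Holm
  family (conservative).
* Jackknife blocks are contiguous in concatenated coordinate order with
  sizes differing by at most one SNP; D is computed from pattern counts
  and per-block aggregation consistently (asserted in tests).
* Thinning is greedy left-to-right on 0-based concatenated coordinates;
  reports print 1-based positions.
* Tie minor1 = minor2 gives γ = 0, p = 1. Trio arrangement places the
  species-tree sister pair in the (P1, P2) slots lexicographically, then
  reports with P1/P2 swapped where needed so D ≥ 0.
* The f-branch concordance threshold in reports defaults to 0.04, below
  which allele-sharing signal is treated as weak; it is a declared
  reporting convention, not an estimated quantity.
* The test suite runs the preset end to end at full scale (756 × 1951 bp,
  54 + 1 taxa, all 24,804 trios), the estimator-consistency check at
  50,000 loci, null calibration at 50 seeds × 1,000 loci, and direction
  recovery at 20 replicates per direction with 2,000 loci of 500 bp —
  sizes at which every Monte-Carlo tolerance in the suite is set by the
  corresponding binomial or bootstrap standard error.

The package's functions are the interface; `run_scan()` over a
`scan_config()` is the single entry point that chains every stage and
writes deterministic TSV reports plus a manifest, and a shell-level
wrapper would add nothing over `Rscript -e` with those two calls.

## Known limitations

* Triplet tests only see gene flow that changes topology frequencies;
  flow between true sisters, or from a donor clade's stem into its own
  descendants' tests, is invisible to them.
* Direction calls require ILS loci in the control stratum; donor pairs
  with long stems (little ILS) cannot be polarized and are reported
  bidirectional.
* The D-statistic stage flags but does not model correlated trios; its
  significance count is expected to exceed the triplet scan's, as it
  does on real radiations.
* Sites are polarized by a single outgroup state; misassigned ancestral
  states at fast-evolving sites inflate both ABBA and BABA
  symmetrically under the null but can bias D when divergence to the
  outgroup is large.
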