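---
title: "Detecting crossovers and gene conversions in a three-generation pedigree"
author: "pedrecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting crossovers and gene conversions in a three-generation pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedrecomb)
```

## The problem and the approach

Whole-genome sequencing of a complete three-generation pedigree — four
grandparents, two F1 parents and several F2 offspring — makes individual
meiotic recombination events directly observable. Because the F1 parents'
chromosomes can be phased against their own parents' genotypes, every
allele an F1 transmits to an F2 offspring can (at suitable sites) be traced
to one grandparent. Along a transmitted chromosome these grandparent-of-
origin labels form *haploblocks*; a switch between adjacent haploblocks is
a crossover (CO), localized to the interval between the two flanking
informative markers. A *single* site whose label disagrees with its
surrounding block, by contrast, is the signature of a non-crossover (NCO)
gene-conversion tract that covered that one marker.

`pedrecomb` implements this analysis end to end for an avian (ZW) pedigree:
site-level quality filtering, informative-site extraction and phasing,
haploblock construction with error pruning, CO interval calling, an NCO
filter cascade with weak/strong (GC-bias) direction classification, and the
downstream statistics — sex-specific genetic maps, crossover interference,
hot-spot permutation tests, genomic feature association, and the
transmission-distortion test for GC-biased gene conversion (gBGC). A
synthetic-pedigree simulator with full ground truth makes every stage
testable without any external data.

## Phasing rules

A site is *informative* for one parental side when

* the transmitting F1 parent is heterozygous, and
* its two parents' genotypes differ so that each F1 allele is attributable
  to exactly one grandparent (one grandparent homozygous for one allele and
  the other carrying the alternative).

Transmission to an offspring is *traceable* unless the F1's partner and the
offspring are both heterozygous, in which case either F1 allele could have
been transmitted. A site may be informative for both sides at once; it is
then used once per side, independently. Missing genotypes in any of the
five individuals relevant to a side make the site uninformative for that
side (a conservative choice). Labels are stored as fixed integer codes
(1 = grandfather, 2 = grandmother of the side) so downstream comparisons
are exact.

Sex chromosomes follow ZW semantics: females are hemizygous on the Z
outside the ~0.6 Mb pseudoautosomal region (PAR), so female genotypes there
are haploid, the maternal side yields no informative sites outside the PAR,
and a female offspring's haploid Z allele is resolved on the paternal side
directly.

## Haploblock pruning and crossover calling

Maximal runs of identical labels become blocks. Following the assumption of
at most one recombination event per Mb, an *interior* block that would
imply two label switches within 1 Mb and contains fewer than `minSites = 3`
sites is treated as a phasing/genotyping artifact and removed; same-label
flanks then merge, and the rule is re-applied to a fixed point
(deterministically: the leftmost violating block is removed first). A
switch is only localized between two markers, so the distance between a
block's two implied switches is measured between the *expected* switch
positions, i.e. the midpoints of the two flanking marker intervals — for a
single-site block, half the distance between its neighbours. This measure
matters in sparse marker regions, where a single mis-mapped site would
otherwise masquerade as a pair of crossovers just over the window
threshold. Removed single-site blocks become NCO candidates; removed
multi-site blocks go to a suspect log (they are neither COs nor single-site
NCO events; conservatively we call neither).

Crossovers are called between adjacent blocks with different labels and
localized to the half-open interval `(left, right]` between the outermost
sites of the two blocks; `length = right - left` is the resolution.
Intervals overlapping assembly gaps are flagged and excluded from the
gap-free resolution median. No event is called before the first or after
the last informative site of a chromosome — crossovers there are
undetectable, a power limitation rather than an error.

## The NCO filter cascade

Each candidate must pass, as a pure conjunction (the trace order is fixed
only for reporting): the strict 90% recalibration tranche; no indel within
10 bp; no more than 3 called SNPs in a 30 bp window; no more than 2
phase-deviating sites in a 5 kb window on the same offspring/side sequence
(both windows centred on the candidate — the anchoring is our choice, the
thresholds are the published ones); no reads supporting a third allele; a
minor-allele read fraction of at least 25% in every heterozygous
individual (candidates without allele-depth data are removed with a
dedicated trace code); and absence of the all-females-heterozygous /
all-males-homozygous-reference pattern that arises when reads from the
female-specific W chromosome mis-map to a male-derived assembly.

Surviving events are classified by conversion direction: W>S when a weak
allele (A/T) was replaced by a strong allele (G/C), S>W in the opposite
case, "neither" for weak:weak or strong:strong pairs. The transmission
test counts W>S against S>W events, tests the strong-transmission
probability against 0.5 with an exact two-sided binomial test
(`binom.test` convention), reports the Clopper–Pearson 95% CI (an exact
method; the published interval is consistent with it at two decimals), and
converts the estimate to the distortion `c = 2p - 1`. With the
reconstructed published counts this gives:

```{r}
transmissionBias(c(rep("W>S", 135), rep("S>W", 94)))
```

The printed exact p-value (0.008) differs from the published 0.012; the
reconstruction of the 135/94 split from the rounded 59% of 229 sites is
the likely cause, and we report the computed value rather than guessing at
the original counts.

## Downstream statistics

* **Genetic maps.** `mapDistance()` is 100 × events / meioses.
  Per-chromosome distances are sex-averaged over all 10 meioses; the Z
  chromosome uses paternal events over the same denominator (only male
  meiosis recombines along the full Z), and sex-specific genome totals use
  the 5 same-sex meioses. Both conventions are exposed because published
  per-chromosome tables and sex-specific totals use different ones.
* **Interference.** The coefficient of coincidence tiles chromosomes with
  1 Mb windows and compares observed double-CO counts in window pairs at
  each separation with the product of the windows' marginal CO
  probabilities. Bins with zero expectation are reported as undefined, not
  zero.
* **Hot spots.** The statistic is the number of cross-meiosis event pairs
  within 100 kb; permutation replicates redraw each event's midpoint
  uniformly on its own chromosome, preserving per-chromosome and
  per-meiosis counts, with p = (1 + #replicates ≥ observed)/(1 + n).
* **Feature association.** The genome is split into promoter (2 kb
  upstream of the TSS, strand-aware), first exon, first intron, other
  exons, other introns and intergenic DNA, with overlaps resolved by that
  precedence. Each event interval contributes weight proportional to its
  overlap; Fisher tests compare rounded event weights against category
  sizes in kb (integer margins are required, and the rounding is
  documented output).
* **Chromosome ends.** Distances are folded as min(midpoint, length −
  midpoint); the sex comparison uses a rank-sum test whose z score is the
  tie-corrected normal approximation, with the one-sided p testing whether
  male events lie closer to the ends.
* Event *point* locations for these statistics default to interval
  midpoints (exposed as the `crossoverMidpoints()` step); the choice is
  immaterial for intervals a few kb wide against Mb-scale windows.
* No multiple-testing correction is applied anywhere, matching the
  analysis style the pipeline mirrors.

## The simulator: what it emulates and what it does not

`simulatePedigree()` draws founder haplotypes at a configurable
segregating-site density, simulates founder→F1 and F1→F2 meioses, and
emits genotypes under an error model. Only the ten F1→F2 meioses are
observable by phasing, so only their crossovers and conversion tracts are
recorded as ground truth.

* **Crossovers** follow a stationary gamma-renewal process along the
  chromosome (stationarity by starting the process ten mean spacings
  before the origin). The shape ν controls interference: ν = 1 is Poisson
  (none), larger ν suppresses nearby doubles; the default ν = 5 reproduces
  a coincidence profile that is well below 1 at short range and rises
  toward 1, the qualitative published pattern. Rates are *gamete* rates in
  cM/Mb (defaults 2.28 female / 3.56 male, the published estimates).
* **Obligate CO** is available as rejection-resampling of empty
  chromosomes but is off by default: the obligate chiasma is a property of
  the four-chromatid bivalent, and the single transmitted chromatid shows
  any given chiasma only half the time — consistent with pedigree
  observations of roughly equal numbers of recombinant and non-recombinant
  microchromosome transmissions. With conditioning off, simulated map
  length is exactly the configured cM, which the map-consistency tests
  verify.
* **Female Z meiosis** places crossovers and conversion tracts only inside
  the PAR, at its own rate (default 67 cM/Mb, the published PAR estimate —
  not the genome-wide female rate, and not subject to obligate-CO
  conditioning). Sons receive the mother's Z-carrying product, daughters
  the W-carrying product; daughters are therefore haploid on the non-PAR Z.
* **NCO tracts** start as a Poisson process (default 0.1 initiations per
  Mb per meiosis — a placeholder, as no direct estimate exists for this
  system; the detected published counts imply ≥ 0.026 at unknown detection
  power) with geometric lengths (default mean 500 bp; single-site
  detection makes the exact value non-critical). At heterozygous
  weak:strong sites inside a tract the strong allele is transmitted with
  probability (1 + c)/2 (default c = 0.18, the published estimate); at
  weak:weak or strong:strong heterozygous sites either allele with
  probability 1/2. Tracts landing within 1 bp of a same-meiosis crossover
  breakpoint are discarded, keeping the two event types distinct in the
  truth tables.
* **The error model** has independent channels for genotype miscalls,
  missing calls, Poisson depth, a low-GQ fraction, and a W-contamination
  channel that overwrites autosomal sites with the diagnostic
  all-females-het / all-males-hom-ref pattern (truth-tagged so the
  corresponding NCO filter can be tested exactly). When every stochastic
  channel is zero, emission is deterministic (DP = mean depth, GQ = 99,
  exact allele-depth splits) so that a clean simulation passes the quality
  filters completely — the Poisson tails of a realistic depth model would
  otherwise remove a handful of sites per million.

What the simulator does *not* emulate: real linkage-disequilibrium
structure among founder haplotypes (alleles are drawn independently per
site), read-level artifacts (alignment, base quality), indels and
structural variation, repeat architecture (masks can be supplied or drawn
as random interval sets), and realistic gene models
(`simulateGeneAnnotation()` produces simple non-overlapping multi-exon
genes sufficient to exercise the feature statistics). Passing tests on
synthetic data therefore demonstrate the correctness of the *algorithms*
under the stated generative model, not the field performance of the
pipeline on a real resequenced pedigree.

## Numerical and design choices

* Intervals are half-open `(left, right]` in 1-based bp internally; VCF
  positions are 1-based at the boundary, BED-style inputs 0-based
  half-open as usual for those formats.
* Pruning removes the leftmost violating block first; the fixed point is
  insensitive to this for all cases we enumerate in tests, but the rule
  makes runs bit-reproducible.
* Two truth breakpoints falling in the same marker interval cancel (no
  observable label switch) and are excluded from the recovery denominator
  as unobservable; an odd-sized group counts as one expected event.
* The permutation p-value is discrete. Calibration checks against the
  continuous uniform therefore use configurations whose pair-count
  statistic takes many values (hundreds of events); with a handful of
  events the p-value has large atoms and a KS check would reject for
  discreteness alone, which is a property of the check, not a bias of the
  test.
* Degenerate inputs are handled explicitly: zero-expectation coincidence
  bins are `NA`; a paired GC test with all-zero differences returns p = 1;
  region sets covering none or all of the genome are errors; an empty
  event set gives a hot-spot p of 1.
* Fisher tests on event-versus-bp tables round bp margins to kb units —
  contingency tables need integers — and the output records both raw and
  rounded quantities.

## Problem sizes

The default desk-scale layout is three chromosomes (20 Mb, 8 Mb, and a
15 Mb Z with a 0.6 Mb PAR) at a segregating-site density of 1e-4 per bp
(~4,300 sites), chosen so that a full simulate→detect→statistics run takes
about a second. The recovery studies in the test suite use 100 such
pedigrees at a genotype-error rate of 1e-3; the gBGC recovery study uses a
single 10 Mb chromosome at density 5e-4 with an elevated NCO initiation
rate so each replicate yields ~40 weak:strong conversions; interference
calibration uses a 50 Mb chromosome at 4 cM/Mb over 200 pedigrees. At this
scale the marker spacing (tens of kb) is roughly 40-fold sparser than in
the real study, so simulated CO resolution medians are ~100 kb rather than
~1.5 kb; resolution scales inversely with marker density and is exercised
qualitatively (resolution classes, gap handling), not quantitatively.

## Known limitations

* Multi-site conversion tracts covering two or more adjacent informative
  sites are logged as suspects, not called as NCO events; published event
  sets treat NCOs as single sites and the ambiguity is documented there
  too.
* Gene-conversion tracts at CO events are invisible when only one meiotic
  product is observed; the pipeline does not attempt them.
* CO/NCO relative frequencies are not reported: the stringent NCO filters
  remove an unknown fraction of true events, so the ratio would be
  biased.
* The detection power for crossovers near chromosome ends is limited by
  the outermost informative sites; undetectable terminal events are
  excluded from recovery denominators rather than imputed.
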