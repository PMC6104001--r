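---
title: "Tracking forward-reverse mutation cycles across tumor stages"
author: "frcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking forward-reverse mutation cycles across tumor stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcycle)
```

## The biological question

In staged same-patient sampling of solid tumors, four tissues are
commonly compared: white blood cells (B, the germline control), nontumor
tissue taken more than 2 cm from the tumor (N), paratumor tissue within
2 cm (P), and the tumor itself (T); time-series designs (sequential
culture samples) and tumor-metastasis trios use the same machinery. At a
base position, the residue is called a major allele (M) when it matches
the reference genome and a minor allele (m) otherwise, giving the
genotype classes MM, Mm, mm, and the rare mn (a heterozygote of two
non-reference bases). Transitions between stages are then gains of
heterozygosity (GOH-M: MM to Mm; GOH-m: mm to Mm) or losses (LOH-M: Mm
to MM; LOH-m: Mm to mm).

Two phenomena make this interesting. First, many forward mutations
arising early (B to N) are *reversed* at a later stage — a
forward-reverse cycle. Second, when a heterozygote created by a forward
GOH later loses heterozygosity, the partition of products between MM and
mm is heavily biased toward restoring the specific germline homozygote
that produced the heterozygote in the first place — a *lineage effect*.
The same logic applies to window copy-number status (U/G/L per stage
versus B), where reversion orders such as GUG and LUL are over-represented
relative to the non-restoring LUG and GUL. This package implements the
full analysis chain — genotype filtering, transition tracking, patch
diagrams, reversal-split mutational profiles, the 26-order CNV serial
taxonomy, and SNV-CNV co-localization — together with a simulator that
generates staged inputs with known ground truth.

## Genotype calling filters

Per-sample site calls are filtered before any cross-stage comparison
(`classifyGenotype`):

* a site is usable only with read depth above 8;
* MM requires the reference-matching allele at frequency at least 0.95;
* heterozygotes (Mm, or mn when both alleles mismatch the reference)
  require the top allele between 0.30 and 0.70 and quality-by-depth
  QD at least 4;
* mm requires the non-reference allele at frequency at least 0.95 and
  QD at least 20;
* strand bias FS at most 20 applies to every class.

Calls in the undefined band (top allele fraction in (0.70, 0.95)) are
excluded: no genotype class is defined there, matching the per-sample
logic of the filtering scheme. Missing QD or FS annotations fail any
criterion that bounds them (the conservative reading). Sites with a
third allele above 5% frequency are excluded and counted. A locus
enters the analysis only when it passes these filters in *every* stage
of the case (`intersectCase`), which guarantees that an apparent
transition is never an artifact of differential callability.

## Patch diagrams and lineage statistics

`buildPatchDiagram` builds one rooted tree per origin genotype (MM, mm,
Mm at the first stage). Nodes are genotype *paths* (e.g. `MM|Mm|MM`), so
every locus contributes exactly one root-to-leaf path and child counts
sum exactly to parent counts at every node. The rate under a step is the
edge count divided by the parent node count: the paper-style figures
print step rates without stating denominators, and parent-count
normalization is the unique choice that makes rates composable along
paths and bounded by 1; it reproduces the published rate orderings.

Step identifiers (G1, G2, ... for GOH steps; L1, L2, ... for LOH steps)
are assigned over the *complete* genotype tree, not just observed edges,
so the same identifier always denotes the same step regardless of the
dataset: diagrams are traversed in origin order MM, mm, Mm; within a
diagram by stage level, then parent genotype (MM, Mm, mm), then parent
enumeration order, then child genotype (MM, Mm, mm). The identifiers are
therefore deterministic but need not coincide with any hand-drawn
figure's numbering; analyses should address steps by their
parent/child genotypes.

```{r patch-example}
paths <- rbind(
    matrix(rep(c("MM", "Mm", "MM"), 263), ncol = 3, byrow = TRUE),
    matrix(rep(c("MM", "Mm", "Mm"), 10), ncol = 3, byrow = TRUE))
colnames(paths) <- c("D5", "D10", "D14")
loci <- methods::new("StagedLoci", caseId = "demo",
    stages = c("D5", "D10", "D14"),
    loci = cbind(data.frame(chrom = "c", pos = seq_len(273) * 10,
        ref = "C", alt = "T", flank5 = "A", flank3 = "G"),
        as.data.frame(paths)))
pd <- buildPatchDiagram(loci)
lineageRatio(pd$MM, "MM|Mm")
```

The `Inf` sentinel marks a fully one-sided partition (all reversions
restored the origin homozygote); `0` marks the opposite side.
`lohPartitionRatios` follows the surviving germline-heterozygote path of
the Mm-origin diagram and reports the stage-wise MM/mm partition of
first-time LOHs, whose decline across stages reflects diminishing
positive selection for reference homozygotes. `reversalFraction` counts
completed forward-reverse cycles: among loci mutated between two
consecutive stages, the fraction whose next-stage genotype equals the
pre-mutation genotype.

Four-stage loci are classified into serial types (`classifySerialSNV`):
I (B = N), IVa (B &ne; N &ne; P = T with B = T, the
reverse-at-P pattern), IVb (B &ne; N = P &ne; T with B = T,
reverse-at-T), then II (N = T) and III (N &ne; T and B &ne; T). IVa and
IVb are evaluated before II and III because the patterns overlap
(an IVa quadruple also satisfies the literal Type II condition); the
explicit precedence resolves the ambiguity, and quadruples matching no
pattern are reported UNCLASSIFIED rather than forced. Type II ignores
the P stage: the defining pattern constrains only B, N and T, and we
take that silence literally.

mn genotypes are labelled like heterozygotes but tallied separately and
omitted from patch diagrams (they are rare and are reported alongside,
not inside, the main figures). Direct MM-mm jumps between adjacent
stages are labelled OTHER and kept out of the four GOH/LOH classes.

## Reversal-split mutational profiles

Every substitution is pyrimidine-normalized: if the mutated base is a
purine, the substitution and its immediate flanks are replaced by their
reverse complement, so profiles are strand-symmetric by construction
(`normalizeMutation`). Counts land in a 6 &times; 16 matrix (C>A, C>G,
C>T, T>A, T>C, T>G by the 16 ordered flank contexts "X.Y"), with each
cell split into mutations that were reversed in the next stage tier and
mutations that were not (`buildProfile`). Counts are deliberately *not*
normalized for genomic trinucleotide frequencies. The share of C>T
counts at the four N.G contexts (`ncgPeakShare`) summarizes the
CpG-deamination peak pattern; 0.25 is the uniform baseline. This share
is our summary statistic for the qualitative "CpG peak" call, not a
published threshold.

On the double helix, the 16 ordered contexts collapse into 10 duplex
groups (context X.Y pairs with comp(Y).comp(X); C.G, A.T, T.A and G.C
are self-paired). Within a group, each mutation is paired with its
opposing mutation — the substitution converting the product back on the
same triplet duplex (`opposingPairTable`): C>T opposes T>C at the same
context, C>A opposes T>G at the mate context, C>G and T>A oppose
themselves at the mate context. The 96 cells resolve into 44 two-sided
pairs plus 8 self-inverse cells. Pair ratios (max/min, at least 1)
discriminate mutational mechanisms: near-equal opposing rates are the
signature of double-strand-break gene conversion (either chromatid may
carry the break), divergent rates indicate direction-specific point
mutation processes. `tsTvRatio` sums transition over transversion rates
per diagram; ratios are reported to two decimals to match printed
precision, with full precision kept internally.

## CNV serial orders and Q statistics

Fixed windows (50-500 kb, tiled from position 0, partial terminal
windows dropped) get a copy-number status per stage-versus-baseline
comparison. The built-in caller is a deliberately simple library-size
normalized log2-ratio threshold (default 0.35): the published
window-based caller used upstream of this kind of analysis is not
specified by the analysis itself, so the caller is pluggable and
precomputed U/G/L series are accepted as first-class input. Windows with
zero counts in both samples are called U and flagged low-coverage.

The (N, P, T) status triple versus B gives one of 26 serial orders (UUU
is excluded as "no CNV anywhere"), split into class I (exactly two U;
6 orders), class II (at most one U, no disadvantage; 8 orders, including
the reversion orders GUG and LUL), and class III (12 orders: the 10
containing an abrupt G-L double-dose change plus LUG and GUL, whose
T-stage status fails to restore the N-stage status). The lineage
quotients Q = GUG/GUL and LUL/LUG have null expectation 1 in the absence
of lineage effects; each is tested with a two-cell chi-square
goodness-of-fit against equal expectation, without continuity correction
(the two-cell counts are large in practice; a zero denominator gets a
0.5 pseudocount on both terms and is flagged). Recurrent CNVs are
windows altered in any stage comparison in at least a threshold number
of patients (default 6), optionally minus user-supplied exclusion zones.

## Co-localization analyses

`nearestRcnvDistances` measures the gap (in intervening bases) from each
classed SNV to its nearest recurrent-CNV window, 0 inside a window —
edge distance makes "inside = 0" natural, and midpoint distance would
penalize wide windows. Focal-versus-other classes are compared with
two-tailed t tests on per-SNV distances (per-case breakdowns can be
formed by splitting the input). `ageFractionCorrelation` is a plain
Pearson correlation with its two-sided test. `decileDensityCorrelation`
tiles the genome into tandem 2000-bp windows, drops windows with zero
annotation density (missing-data guard), splits the rest into ten
near-even groups by annotation-density percentile — ties broken by a
stable sort on window coordinate so the assignment is reproducible — and
correlates mean breakpoint density with decile index.

## The simulator: what it emulates, and what it does not

`simulateCase` is the generative mirror of the staged-sample analysis.
Germline genotypes are drawn from an MM/Mm/mm mixture; each later stage
first *reverts* each extant non-germline mutation with the stage's
reversal probability and then applies fresh forward mutations. A
reverting loss restores the pre-mutation homozygote with probability
`lineageFidelity` (the lineage effect is injected here, and only here),
a reverting gain restores the origin heterozygote, and a locus that
reverts in a stage does not also acquire a fresh mutation in that same
stage — one net event per locus per stage, which is the minimal
generative process reproducing the observed outcome patterns and makes
the truth log and the tracker agree exactly in the noiseless limit.
Fresh losses at germline heterozygotes go to MM with probability
`mmPreference` (default 0.85, echoing the observed preference for
reference homozygotes, stage-wise partition ratios near 5.7). Gains at
CpG-dimer loci are `contextBias`-fold enriched (default 8) and gain the
deamination product (C>T, or G>A on the opposite strand), producing the
CpG peak pattern in profiles.

Default study conditions (chosen once, as a scaled-down rendition of the
staged-sample study): 12 tetra cases of 20,000 loci; germline 30% Mm and
5% mm; forward rates per transition rGOHM = 0.010, rGOHm = 0.020,
rLOH = 0.047, giving a few hundred forward events per case in the
proportions of the published aggregate counts (losses dominating, then
mm-origin gains relative to their small at-risk pool); reversal
probability 0.9 at the paratumor-like stage and 0.05 at the tumor-like
stage (the observed ~96% early reversal versus ~0-16% late reversal);
lineage fidelity 0.99 (partitions such as 1518/1 imply near-perfect
fidelity). Read evidence uses negative-binomial depth (mean 50, size
10), binomial allele counts with a 0.5% error rate, Gaussian QD (means
25/32, sd 6) and exponential FS (mean 3) — typical annotation
distributions for clean short-read calls, set so that a well-covered
locus passes the filters with probability about 0.99 per stage.
`noise = FALSE` is the depth-to-infinity limit used for exactness tests.

The CNV simulator assigns serial orders from explicit probabilities
(defaults put 4:1 ratios on GUG:GUL and LUL:LUG, i.e. Q = 4) and emits
either true status series or read counts with true |log2 ratio| 0.8 and
multiplicative log-normal noise (sd 0.08), so the threshold caller
recovers the truth for most windows while mis-calls remain possible.
Note that with a high prevalence of genuine gains the library-size
normalization compresses per-window ratios — a real phenomenon of
ratio-based callers that the simulator reproduces.

What the simulator does *not* model: real human sequence context
(the reference fragment is synthetic with controllable CpG density at
loci), linked loci or clonal substructure, amplicon-specific coverage
patterns, mapping artifacts, tumor purity, or segmental-deletion LOH
(all simulated LOH is copy-neutral "interstitial" LOH). Passing tests on
simulated data therefore demonstrate the correctness and statistical
calibration of the analysis chain, not the biological claims themselves
on real data.

## Numerical and design choices

* Coordinates are 1-based inclusive internally (VCF convention);
  interval inputs and outputs use 0-based half-open BED convention at
  the boundary.
* Indels and symbolic alleles are skipped with a counter; SNVs only.
* Undefined ratios carry explicit sentinels (Inf / 0 for one-sided
  partitions, NA plus a `defined` flag for 0/0) rather than silent
  drops.
* Stage-wise deltas (e.g. P vs B) are always direct comparisons, never
  compositions of intermediate deltas.
* Problem sizes in the test-suite and acceptance script (12 cases of
  20,000 loci; 10,000 CNV windows; 5,000-locus symmetry checks) were
  chosen so that binomial sampling error is several-fold smaller than
  the tolerances being checked.
* The cross-sample sign-test style claim for "more reversals at P than
  at T in every case" is exposed as per-case counts; no specific test is
  attached because the original test identity is unstated.

## Known limitations

The heterozygote filter window (0.30-0.70) biases against loci with
allele-specific amplification; the package reports but does not correct
for this. The simple log2-ratio CNV caller has no segmentation, so
isolated noisy windows become isolated status flips; Q statistics are
robust to this (flips affect numerator and denominator symmetrically)
but absolute order frequencies are not. Whether an MM call should carry
an implicit QD floor is left open by the filtering scheme; we impose
none, so low-QD reference-homozygous calls pass if depth, allele
fraction and FS are satisfied.
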