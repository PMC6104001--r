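# frcycle

Forward-reverse mutation cycles in multi-stage cancer genomes.

## What this is for

In staged same-patient designs — white blood cells (B, germline),
nontumor tissue > 2 cm from the tumor (N), paratumor tissue ≤ 2 cm (P),
tumor (T), or sequential time points — single-nucleotide variants can be
traced residue by residue. With M the reference-matching allele and m a
mismatch, transitions between stages are gains of heterozygosity
(GOH-M: MM→Mm, GOH-m: mm→Mm) or losses (LOH-M: Mm→MM, LOH-m: Mm→mm).
Two signals of sequential (rather than parallel) clonal evolution are:

* **forward–reverse cycles** — a large fraction of early forward
  mutations (ΔNB) is reversed at the paratumor stage, and far fewer at
  the tumor stage;
* **lineage effects** — when a heterozygote created by a forward GOH
  later reverts by LOH, the partition of products between MM and mm is
  almost entirely one-sided toward the germline homozygote of origin
  (patch-diagram partitions like 1518/1 or 0/357), and the analogous
  copy-number quotients Q = GUG/GUL and LUL/LUG exceed the no-effect
  expectation Q = 1.

`frcycle` implements the full analysis chain for anyone running or
re-analyzing such designs:

* `classifyGenotype` / `readCase` / `intersectCase` — per-sample
  genotype-class filters (depth > 8; MM: major allele ≥ 95 %, FS ≤ 20;
  Mm/mn: 30–70 %, QD ≥ 4, FS ≤ 20; mm: non-reference allele ≥ 95 %,
  QD ≥ 20, FS ≤ 20) and the every-stage intersection, from per-stage
  VCFs plus a reference FASTA;
* `labelTransition`, `deltaSummary`, `buildPatchDiagram`,
  `lineageRatio`, `lohPartitionRatios`, `classifySerialSNV`,
  `reversalFraction` — stage tracking, patch diagrams with
  deterministic G#/L# step labels and rates (edge count / parent
  count), serial types I–IVb;
* `normalizeMutation`, `buildProfile`, `duplexGroup`,
  `opposingPairTable`, `rateDiagram`, `tsTvRatio`, `ncgPeakShare` —
  reversal-split 6 × 16 trinucleotide profiles, the 10 duplex context
  groups, opposing-pair rate ratios, TS/TV;
* `callWindowStatus`, `enumerateSerialOrders`, `classifyOrder`,
  `orderFrequencies`, `qStatistics`, `recurrentCNVs`,
  `lohCopyStateOverlap` — the 26-order CNV serial taxonomy (classes of
  6/8/12), lineage Q statistics with chi-square tests, recurrent-CNV
  windows (≥ 6 of 12 patients by default);
* `nearestRcnvDistances`, `ageFractionCorrelation`,
  `decileDensityCorrelation` — SNV–CNV distance statistics, age
  correlations, 2000-bp decile density co-localization;
* `simParams`, `simulateCase`, `simulateCnvCase`, `emitStandardFiles` —
  a simulator with per-stage forward rates, reversal probabilities,
  lineage fidelity and CpG context bias that emits VCF/FASTA/TSV plus a
  ground-truth log.

See the vignette (`vignettes/forward-reverse-cycles.Rmd`) for the model,
parameter meanings, and design choices.

## Worked example

```r
library(frcycle)
params <- simParams(nLoci = 20000)            # staged-study defaults
sim  <- simulateCase(params, seed = 11, caseId = "demo")
loci <- intersectCase(sim$case)
loci
#> StagedLoci: demo - 19248 loci callable in all of B,N,P,T
#>   genotypes at B : mm=869 Mm=5731 MM=12648

deltaSummary(loci, "B", "N")
#> DeltaSummary dNB:
#>  NONE GOH_M GOH_m LOH_M LOH_m OTHER
#> 18669   306    14   209    50     0
#>   LOH total: 259 | sigma (changed loci): 579 | mn-involved: 0

reversalFraction(loci, c("B", "N"), c("N", "P"))$fraction
#> 0.896       # 519 of 579 forward DNB mutations reversed at P

pd <- buildPatchDiagram(loci)
lineageRatio(pd$MM, "MM|Mm")
#> $countMM 274   $countmm 1   $ratio 274   # one-sided lineage effect

table(serialSNVTypes(loci))
#>     I    II   III   IVa   IVb
#> 18669    76     5   495     3           # reverse-at-P dominates

cnv <- simulateCnvCase(simParams(nWindows = 10000), seed = 11)
qStatistics(orderFrequencies(callWindowSeries(cnv$data)))
#>   quotient numerator denominator        Q            p
#> 1  GUG/GUL       166          49 3.387755 1.471252e-15
#> 2  LUL/LUG       159          37 4.297297 2.925976e-18
```

Reading the numbers: 19,248 of 20,000 simulated loci pass the calling
filters in all four stages; the ΔNB tier carries 579 forward mutations
of which 89.6 % complete a forward-reverse cycle by P (the generative
reversal probability is 0.9); the revertant MM|Mm node partitions
274 : 1 toward the origin homozygote (fidelity 0.99); serial type IVa
(mutated in ΔNB, reversed at P, stable at T) far exceeds IVb; and both
copy-number lineage quotients exceed 1 with vanishing chi-square p,
recovering the simulated 4 : 1 design.

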