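---
title: "Methods: marker-assisted backcross analysis and simulation"
author: "speedcongenics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-assisted backcross analysis and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedcongenics)
```

## The problem

Creating a congenic mouse line means moving a gene of interest from a
donor strain onto the uniform genetic background of a recipient strain
by repeated backcrossing. Unassisted, about ten backcross generations
are needed before the background is essentially pure recipient. "Speed
congenics" halves that: at every generation, all offspring carrying the
gene are genotyped at a panel of *diagnostic SNPs* — markers homozygous
for different alleles in the two parental strains — and the individuals
with the highest percentage of recipient-strain alleles are chosen as
the next breeders.

This package covers the analysis half of such an experiment (the wet
lab and the read-mapping/variant-calling pipeline sit upstream; the
package consumes their canonical outputs, a joint-genotyped VCF plus a
panel BED and an optional per-SNP read-depth table), and bundles a
backcross simulator that generates the same data with known ancestry
truth, so every analysis step can be validated end to end.

## Data model

* `SnpPanel` (a `GRanges` subclass): the marker map — chromosome
  (1..19, X, Y), 1-based position, marker id, ref/alt alleles. BED
  coordinates are converted at the I/O boundary only.
* `GenotypeCalls` (a `RangedSummarizedExperiment` subclass): dense
  samples x loci calls in `HOM_REF` / `HET` / `HOM_ALT` / `MISSING`,
  relative to the recipient-strain reference genome (the AA / AB / BB /
  failed vocabulary of sample reports).
* `DiagnosticSet`: the diagnostic subset of autosomal + X loci for one
  donor source, with per-filter-step provenance counts.

## The selection statistic

For a sample with genotyped counts $n_{AA}, n_{AB}, n_{BB}$ over a
locus scope,

$$\%\,\text{recipient} \;=\; 100 \cdot
  \frac{2 n_{AA} + n_{AB}}{2\,(n_{AA}+n_{AB}+n_{BB})}.$$

Failed calls are excluded from the denominator; genotyping success
(`pct_genotyped`) is reported separately, and a sample with nothing
genotyped gets a flagged, undefined percentage rather than a number.
Y-chromosome loci never enter the statistic: the Y does not recombine,
so its ancestry is fixed by the breeding design. Hemizygous male calls
(haploid X, or diploid-coded by the upstream caller) contribute two
identical alleles, so one formula serves both sexes without biasing
heterozygosity. Ranking for breeder selection (`rankForBreeding`) sorts
by this percentage, breaking ties by genotyping success and then sample
id so results are stable and auditable.

Tunable thresholds, with defaults: congenic declaration at 99.8%
recipient alleles (`isCongenic`), the conventional stopping point;
low-quality sample flagging below 90% genotyping success
(`flagLowQuality`), far under the 94.5–98.4% a good run achieves; and
read-depth QC flagging samples whose median per-SNP mapped-read count
falls below 10 (`flagLowDepthSamples`), the empirical threshold below
which genotyping success deteriorates. Depth quartiles use linear
interpolation on sorted values (quantile type 7), stated because
conventions differ; loci absent from a depth file count as zero reads —
absence of reads is exactly the signal sought.

## Diagnostic-SNP filtering

`callDiagnosticSnps` starts from the autosomal + X panel and applies,
per donor source (the same strain from different suppliers can differ
genetically):

1. remove loci that failed in more than `maxFailures` donor replicates
   (default 1 — with 2–3 replicates a single failure is tolerated);
2. remove loci where any donor replicate is heterozygous or homozygous
   for the recipient allele.

The order matters: a locus missing in one replicate but homozygous
alternate in the others is kept. The filter presumes the genotypes were
called against the recipient's reference genome; `verifyRecipient`
checks that assumption by confirming recipient-strain samples are
nearly all `HOM_REF` (warning below 99.5%) at the diagnostic loci.
`predictPairwiseDiagnostics` extends the idea to a consensus
strain-by-SNP table: a marker predicts as diagnostic for a pair when
the two strains are opposite homozygotes; markers heterozygous,
segregating or missing in either strain are excluded from that pair —
the conservative reading of "different genotypes".

## The simulator

The simulator is the package's source of ground truth. Design choices:

* **Genomes as ancestry segments.** Each chromosome copy is a list of
  breakpoints partitioning it into DONOR/RECIPIENT segments. Founders
  are ancestry-pure; all downstream structure arises from meiosis.
* **Meiosis: Haldane model.** Crossover counts are
  Poisson(map length in Morgans); positions are uniform on the genetic
  map; the gamete alternates between the two parental haplotypes
  starting from a fair coin. Crossover interference and the obligate
  chiasma are omitted — the simplest model consistent with
  trajectory-level validation; the map is a configuration hook for
  anything finer.
* **Map.** mm10 physical lengths with one genome-wide rate of
  0.56 cM/Mb (~1380 cM over the autosomes), linearly interpolated
  within chromosomes. A user-supplied map can change lengths, rate or
  chromosome set.
* **Sex chromosomes.** X recombines only in female meiosis; a male
  transmits his X intact to daughters and his Y label to sons. The Y is
  a non-recombining paternal label.
* **Panel.** `simulatePanel` emulates the genotyping assay: 1591
  autosomal + 49 X + 29 Y markers placed near-evenly (positions
  jittered around a regular grid, autosomal counts apportioned by
  chromosome length), of which 819 autosomal + X markers are flagged
  truly *divergent* between the strains — the density of a
  BALB/c-type donor crossed into a B6-type recipient, ~3 Mb between
  diagnostic markers. Genotyping maps local ancestry to calls at
  divergent loci and returns `HOM_REF` at shared loci, then applies a
  2.5% per-call failure rate (the assay's typical genotyping success is
  ~97.5%) and an optional error rate (default 0).
* **Gene of interest.** Default at the midpoint of chromosome 11; its
  true location in any given experiment must be configured, since
  linkage drag around it is what caps the attainable percent recipient.
  Carriers are offspring with donor ancestry at this position
  (transmission ~1/2 from a carrier parent).

### The breeding scheme

`breedingScheme()` defaults encode the reference experiment: one donor
male x two recipient females; three F1 males (F1 individuals are
exchangeable, so no selection applies there); then backcross
generations numbered 2–6 with 13, 8, 14, 28 and 6 carrier offspring
genotyped, and 3, 3, 2, 2 top-ranked carriers bred on. Carrier counts
are fixed scheme parameters rather than litter-size draws, keeping an
unmodelled nuisance out of trajectory comparisons; non-carrier
littermates are generated and discarded.

Breeders are selected from carriers of **both sexes**: a selected male
is mated to pure recipient females, a selected female to a pure
recipient male. This follows routine speed-congenics practice — all
carriers of both sexes are genotyped precisely so the best individuals
can breed — and it is also quantitatively necessary: with only 8
carriers at generation 3 (about 4 males), male-only selection is too
weak to produce the observed generation-3 to generation-4 gain, which
both-sex selection reproduces.

### What the simulator does and does not emulate

It reproduces the sampling structure of a real program: ancestry block
lengths under Haldane meiosis, hemizygous X transmission, marker
missingness, selection intensity set by carrier counts. It does not
model read depths tied to genotype quality, genotyping error correlated
with depth, mutation, segregation distortion, litter-size variation or
recombination-rate heterogeneity along chromosomes. Passing validation
therefore shows the *analysis* is correct and the *design* behaves as
population genetics predicts — not that any particular wet-lab run will
match numerically.

## Validation strategy and problem sizes

The test suite validates each layer against something independent of
the implementation:

* the diagnostic filter against a brute-force predicate evaluator on
  hundreds of random matrices (exact agreement);
* quantiles against a sort-based oracle; pairwise predictions against
  per-pair enumeration;
* file formats by exact write/read round trips (VCF and BED);
* meiosis against closed forms: crossover counts average the map
  length in Morgans; unselected backcross means follow $1 - 2^{-g}$
  (checked on the autosomal scope, where the derivation lives — in a
  male-line backcross the X is structurally recipient from
  generation 2, so the autosome+X fraction sits above the closed form);
* the marker estimate against true segment ancestry (mean absolute
  deviation under 2 percentage points at 819 markers, backcross-2
  individuals, where ancestry variance is largest);
* the full program against the reference trajectory, averaging
  generation means over replicate programs (20–24 replicates; a full
  five-generation program simulates in ~1.5 s, so the whole comparison
  stays under a minute);
* selection dominance: over 50 replicate programs per arm, generation-6
  means with top-rank selection decisively exceed random breeder
  choice — the premise of speed congenics.

Degenerate inputs are handled explicitly rather than coerced: empty
marker sets give empty reports (spacing) or errors (ranking over an
empty diagnostic set), undefined percentages are flagged and refuse to
feed the congenic decision, and multiallelic VCF records at panel loci
demote to `MISSING` with a warning tally instead of aborting a whole
run.

## Known limitations

* Linkage drag is modelled around a single configurable locus; there is
  no per-chromosome ancestry painting or congenic-interval report.
* The recipient-equals-reference assumption is checked, not relaxed;
  re-polarising loci where the recipient is `HOM_ALT` is out of scope.
* Physical spacing only (Mb); no genetic-map-aware (cM) spacing report.
* The simulator's single genome-wide recombination rate flattens real
  rate heterogeneity; block-length distributions at fine scales will
  differ from real data.
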