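---
title: "Simulating and detecting hypermutable recognition loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting hypermutable recognition loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Self/non-self recognition systems need receptors polymorphic enough to tell
close relatives apart. In social amoebae, recognition is mediated by a pair
of transmembrane proteins encoded as two adjacent genes transcribed
head-to-head from a shared promoter region, sitting inside a genomic interval
bounded by conserved single-copy marker genes. Comparative genomics of such
loci shows a striking pattern: while the genomes at large remain collinear
and only a few percent diverged, the recognition locus itself is scrambled —
segmental duplications, intralocus gene conversion, inversions, gene losses,
truncated gene fragments, and wholesale swaps of gene complements between
even closely related strains. `hyperlocus` packages the analysis chain used
to characterize such loci, together with a forward simulator that generates
annotated genomes with a known event history so that every detector can be
scored against exact truth.

# The simulator

`simulateRootGenome()` builds an ancestral genome with (i) a background
contig of single-copy genes, (ii) seed copies of an "expanding" family that
transposes genome-wide, and (iii) a hotspot contig laid out as
`[markerA][locus][markerB][markerC]`, where the locus contains the
head-to-head diverging pair, one extra copy of each pair family (the initial
substrate for gene conversion), and filler genes. Base composition defaults
to 23% GC, the AT-rich regime of compact amoebozoan genomes; genes are
stop-free codon sequences with geometrically sized intergenic spacers.

`evolveAlongTree()` evolves the root along a rooted, branch-length-bearing
species tree. Events are drawn from independent Poisson processes with rates
proportional to branch length:

* **substitutions** (Jukes-Cantor, default 0.02/site/unit) act uniformly
  genome-wide. Substitutions that would create an internal stop codon in a
  currently intact gene are resampled, a minimal stand-in for purifying
  selection against nonsense mutations; gene intactness therefore changes
  only through truncation events, which keeps the ground truth crisp.
* **indels** (default 5e-4/site/unit, geometric lengths, mean 5 bp) are
  placed in intergenic sequence only, so reading frames and gene lengths
  stay stable. This is a deliberate simplification: real indels do hit
  coding sequence, but frame-preserving bookkeeping buys exact replayability
  of the event log at no cost to the detectors under test.
* **structural events** target genes, with per-gene rates multiplied by the
  hotspot factor (default 25) when the target lies inside the marker-bounded
  locus: segmental duplication (0.06), inversion of runs of 1–3 adjacent
  genes (0.02), gene loss (0.025), gene truncation (0.03; an internal
  in-frame deletion of 55–200 codons, i.e. strictly more than the 50-residue
  tolerance of the intactness filter, so filter true-positives are
  unambiguous), and transposition of expanding-family copies (1.0 per copy).
  Intralocus gene conversion (0.08 per locus gene) replaces a codon-aligned
  tract of one locus gene with the homologous tract of a same-family,
  same-length donor — the mechanism that produces chimeric recognition
  genes. Conversion tracts are copied verbatim; divergence between donor and
  recipient accrues through the point process, and the tract is recorded in
  the event log so replay is exact.

The hotspot multiplier applies to structural events only. The empirical
signature being emulated is *structural* hypermutability: closely related
genomes stay alignable at the nucleotide level outside rearranged segments,
which would be impossible if point mutation were also 25-fold elevated.

Marker genes are immune to structural events (the analysis presumes findable
flanking anchors; violations are exercised separately as error cases), and
any structural event that would destroy or split the last intact diverging
pair of a genome is resampled, with the resample count reported — every tip
therefore retains at least one intact pair, matching the biology in which at
least one functional receptor pair is required for development.

Two invariants pin the implementation down. First, **replayability**: every
logged event carries the coordinates valid at its application time, and
`replayEvents()` reproduces each tip sequence byte-for-byte from the root.
Second, **per-base ancestry**: `ancestryMap()` replays the log over integer
tags instead of bases, yielding, for every tip position, the root position
(if any) it descends from. This is the ground truth behind "unalignable"
calls.

Rate defaults are not empirically constrained; they were chosen once so that
tip locus spans fall around 11–25 kb — one tenth of the observed 104–250 kb
span range, matching the package's overall ~10x scale-down (300 kb genomes,
six tips) that keeps simulation plus detection within minutes on one CPU.

# Homolog curation

`findHomologs()` aligns every annotated CDS translation locally (BLOSUM62,
affine gaps, shared 4-mer prefilter) against query proteins; this is a
translated search over annotated gene models rather than a six-frame genome
scan, since the simulated genomes are fully annotated. Non-intact genes are
translated through their stops so pseudogene fragments stay findable. The
default score threshold (250) was set from the observed score separation:
true homologs of these gene sizes score above ~1000 even after heavy
truncation, while the best chance alignments between unrelated AT-rich-biased
proteins stay below ~150 — composition bias makes random scores here much
higher than BLOSUM62 intuition suggests, which is why the threshold is not
lower.

`filterByLength()` implements the pseudogene length filter: within each
family the longest member defines the reference length and members strictly
shorter than half of it are removed (a member at exactly half is kept). The
length used is the raw translated protein length per family; measuring
length after alignment trimming would be an alternative reading, but the raw
length is deterministic and testable. `buildFamilyTree()` aligns members
(via the MAFFT executable in its deterministic progressive mode), drops
columns with more than 50% gaps, and applies neighbor-joining to p-distances.
`classifyFamilies()` calls a family static single-copy iff it is exactly
single-copy in every genome and its tree is Robinson–Foulds-identical to the
species tree over shared leaves, and expanding iff any genome holds three or
more copies or the family occupies two or more distinct insertion sites.

# Locus comparison

`extractLocus()` returns the interval strictly between the outermost markers;
`findDivergingPairs()` scans for adjacent, head-to-head family-B/family-C
gene pairs with an intergenic gap of at most 3 kb (the shared-promoter
criterion; intervening genes disqualify a pair and are counted as near
misses). `filterIntactPairs()` rejects a gene that aligns to its family
consensus (majority-rule consensus of the longest 25% of members) with any
single deletion longer than 50 residues, or at under half the reference
length; exactly 50 residues is tolerated.

`anchorAlign()` is a seed-and-extend aligner: shared 12-mers on both strands
are grouped into exact-diagonal segments, segments are clustered into
candidate blocks, and block identity is computed piecewise (direct base
comparison along diagonals, gapped alignment of short inter-segment gaps,
X-drop extension at the ends), with identity defined as matches over
alignment columns, gaps counting as mismatches. Two guards matter in AT-rich
sequence, where random gapped alignments reach 40–50% identity: terminal
cluster units whose identity falls below 0.60 are trimmed (chance seeds glue
themselves onto real blocks otherwise), and every block must exceed the
composition-expected match count by at least 10 standard deviations. The 30%
identity floor is kept as the conventional syntenic-block threshold, but in
this composition regime the significance filter is what separates homology
from chance.

`callUnalignableRegions()` chains blocks collinearly per orientation by
dynamic programming (union of the best forward and best inverted chains, so
one orientation switch is representable), enforces a 1-1 map — a partner
interval may back only one block, so surplus duplicate copies stay uncovered
— and emits uncovered intervals of at least 2 kb as unalignable regions.
`testRegionOrigin()` masks the locus and searches the region against the
rest of the genome: `imported` when a hit covers at least 80% of the region,
`local` when the longest hit is shorter than the genome's median gene length
(the operational reading of "nothing larger than a single gene matches
elsewhere"), `unresolved` otherwise.

**Scoring unalignable calls against truth.** Per-base ancestry makes two
truth sets available: the *novel core* (positions whose tag is absent from
the partner locus — unambiguous) and the *surplus mask* (additionally every
copy of over-represented material; a 1-1 collinear map must leave one copy
of such material unplaced, but *which* copy is the aligner's free choice).
`compareToTruth()` therefore scores recall against novel-core regions
(coverage at least half), precision against the permissive mask, and
boundary error against mask transitions. Interval-to-interval reciprocal
matching was tried first and discarded: equivalent regions fragment and
extend differently when duplicated material abuts novel material, and the
reciprocal criterion punishes correct calls. For headline numbers the
package instead uses `plantSwap()`: an explicit replacement of three locus
genes by six novel ones in one member of a sister pair — the situation
observed between closely related genomes — where the inserted interval is
exact truth. In the shipped benchmarks this yields swap recall 1.0 with mean
boundary error around 100–400 bp.

# Molecular-evolution statistics

`pairwiseIdentity()`, `nucleotideDiversity()` (listwise gap deletion; pi as
mean pairwise differences per comparable site; Watterson's theta as
S/(a1 L)), `tajimasD()` (the standard constants; undefined in-band when
S = 0 or n < 4), and `ng86dnds()` (Nei–Gojobori site counting with all nine
per-position changes counted so that N + S equals three per codon — changes
to stop codons count as nonsynonymous; equal-weight averaging over shortest
substitution pathways, excluding pathways through stop codons when any
avoids them; Jukes–Cantor correction, undefined at p >= 0.75). Both
statistics are verified to 1e-10 against brute-force oracles coded
independently in the test suite. Family-level dN/dS in the pipeline is the
median over pairwise estimates, which resists pseudogene outliers. Under
neutral simulation the estimator averages slightly below 1 (~0.97): the
mutation process cannot create stops while the site counting books
stop-changes as nonsynonymous opportunity; the bias is well inside the
0.9–1.1 sanity band.

# Breakpoint scanning

`segmentAlignment()` segments an alignment by dynamic programming over a
10-column candidate grid (minimum segment 100 columns), with each segment
costed as the negative Jukes–Cantor log-likelihood of its columns under the
segment's own NJ tree, plus a fixed penalty per breakpoint. An NJ
least-squares distance residual was implemented first and discarded after it
proved structurally blind: a chimeric sequence merely shifts its average
position in the distance matrix, which stays near-additive, so the correct
split often *increased* the residual cost. The likelihood cost responds
strongly because the chimera's columns are bimodal between two topologies.
Breakpoints are then refined at single-column resolution by a CUSUM on the
per-column log-likelihood ratio between the flanking segments' trees.

The penalty (default 16 nats) is calibrated by
`scripts/calibrate_penalty.R`: 1.1 times the 99th percentile of the best
single-split improvement on substitution-only simulations across three
divergence regimes, which holds the false-positive rate near zero while
planted between-clade conversion tracts improve the fit by 50+ nats.
`testBreakpointSignificance()` permutes column order within the flanking
window (destroying linkage, preserving site frequencies); the observed
statistic is the best single-split improvement over the same candidate grid
the null optimizes, so observed and null undergo identical selection and the
p-values are uniform on linkage-free data.

Detectability depends on the divergence geometry: recombination between
sequences that are nearly equidistant from everything is close to
information-theoretically invisible at these alignment lengths. The
benchmark scenario is therefore a deep two-clade genus with nearly identical
within-clade sequences (within-clade ~2%, between-clade ~30% expected
substitutions) — the regime in which real chimeric recognition genes are
recognized, matching one clade on one side of the junction and the other
clade beyond it. There, planted 300-column tracts are recovered with both
junctions within one grid step in >80% of replicates and median localization
error of a few columns.

# Pipeline

`runPipeline()` chains the stages (simulate or load, curate homologs,
extract loci, detect and filter pairs, compare locus pairs, statistics,
breakpoint scan, truth comparison) under a single validated configuration
(`defaultRunConfig()`; unknown keys are rejected before any computation) and
returns a `RunReport`; `outDir` additionally writes TSV/BED/JSON outputs.
Runs are deterministic under a fixed seed. The R functions are the
interface; `inst/scripts/hyperlocus.R` wraps `runPipeline()` for shell use.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run, per invocation: 50 oracle
alignments and 50 codon pairs; 2 x 25 two-branch enrichment simulations
(multiplier 1 and 50); one default-scale six-tip simulation for detection
plus a second one contributing planted swaps (six swaps, twelve planted
origin regions); 25 + 25 breakpoint recovery/false-positive replicates and
15 permutation-calibration replicates; 150 coalescent alignments and 80
codon pairs for the neutrality checks. These sizes were chosen so a full
acceptance pass completes in roughly a quarter hour on one CPU while keeping
every binomial estimate meaningfully away from its threshold.

# Known limitations

* The simulator evolves one haploid locus per genome; there is no
  within-species polymorphism, no diploid or sexual recombination, and no
  assembly error. Passing detectors here says nothing about assembly
  artifacts in real data.
* Indels are intergenic and conversion tracts are codon-aligned between
  same-length homologs; real data contain frame-disrupting events the
  intactness filter would catch by the internal-stop route instead of the
  deletion route.
* The expanding family transposes as exact gene copies without its own
  sequence model (no terminal repeats, no fragmenting insertions).
* Syntenic-block identity down to the conventional 30% floor is only
  meaningful together with the significance filter; in 23% GC sequence an
  identity threshold alone cannot distinguish 30–50% "identity" from chance.
* Breakpoint counts on real alignments depend on the penalty scale; the
  default is calibrated for false-positive control, not to reproduce any
  particular published count.
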