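---
title: "Simulating and genotyping barcoded loxPsym shuffle-cassette experiments"
author: "shuffleseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and genotyping barcoded loxPsym shuffle-cassette experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental system

`shuffleseq` models an engineered structural-variant (SV) assay in which a
176-bp "shuffle cassette" is integrated many times into a diploid genome
by a TTAA-specific transposon. Each cassette carries, from the outside in:
two convergent T7 promoters, two single-cell capture sequences (CS2 on the
left of the top strand, CS1 on the right), two PCR primer sites, and two
random 20-nt barcodes flanking a palindromic loxPsym recombination site.
Cre recombinase drives crossovers between pairs of cassettes in the same
cell. Because each crossover re-sorts which barcodes lie *in cis*, every
induced deletion, inversion, translocation or extrachromosomal circle
(ecDNA) is identified by a novel barcode pair that can be read out by
amplicon sequencing in bulk, or by T7 in-situ transcripts alongside a
single-cell transcriptome.

The package implements, as testable code with a mechanistic simulator
behind it, the four computational stages of such an experiment:

1. **Simulation** (`simulateReference()`, `placeInsertions()`,
   `applyCreEvents()`, `computeDerivatives()`, `emitIvtReads()`,
   `emitAmpliconReads()`, `emitT7SingleCellReads()`): a small two-haplotype
   genome, a clonal population of cassette integrations, Cre events, and
   the three read types, with truth tables for every downstream stage.
2. **Insertion mapping** (`placeIvtReads()`, `clusterObservations()`,
   `pairClusters()`, `filterBonafideInsertions()`, `mapInsertions()`):
   reconstructing position, orientation, barcode pair and haplotype of
   every integration from T7 IVT reads.
3. **Bulk SV calling** (`countAmpliconPairs()`, `callRearrangements()`,
   `classifySv()`, `classifyDeletionTopology()`, `validateWithIvt()`).
4. **Single-cell genotyping** (`extractT7Records()`,
   `filterChimericUmis()`, `collapseUmis()`, `buildBcCellMatrix()`,
   `reconstructClonotypes()`, `assignCells()`,
   `callScRearrangements()`).

## The recombination model

A crossover at the loxPsym site joins the chromosomal left part of one
cassette to the right part of the other. The palindromic site supports two
alignment registers, drawn with probability 1/2 each:

* **direct** — product 1 = A-left + B-right, product 2 = B-left + A-right.
  On the same chromosome this excises the intervening segment: the
  outer-part product is the genomic scar, the inner-part product the
  circular ecDNA, always in 1:1 stoichiometry at formation.
* **inverted** — each junction joins two same-name parts with one flipped
  onto the opposite side; on the same chromosome this inverts the
  segment.

Each junction side carries one barcode with its capture-sequence label.
A derivative cassette is PCR-detectable only when its two sides carry
*different* capture sequences (same-CS products are suppressed by
suppressive PCR). Tracking the labels through the crossover shows that
deletion products are detectable exactly for same-orientation pairs,
inversion products exactly for opposite-orientation pairs, and that over
uniformly oriented integrations half of all products are invisible —
which is why the caller can classify "same chromosome + same orientation"
as a deletion and "same chromosome + opposite orientation" as an
inversion from the parental geometry alone.

For deletions between top-CS2 insertions X (left) and Y (right), the scar
carries (bc1 of X, bc2 of Y) and the ecDNA (bc1 of Y, bc2 of X); for
bottom-CS1 pairs the assignment is mirrored. Cis partners are drawn with
probability proportional to `exp(-d / lambda)` (default `lambda` = 100 kb),
the canonical distance dependence of Cre efficiency; the trans
(translocation) rate is a free parameter (default 0.2 events/clone, as the
per-event trans probability is not constrained by the assay).

## Mapping model and coordinate conventions

piggyBac-style integration duplicates the TTAA target site, so the two
flanking T7 transcripts carry TTAA copies that both align to the single
reference motif. With the position rule — plus-strand alignments collapse
to their (0-based exclusive) end, minus-strand alignments to their 0-based
start — the two flanking clusters of one insertion sit **exactly 4 bp
apart**, minus cluster first. An insertion is reported at the 1-based
first base of the TTAA; BED/BEDPE exports are 0-based half-open.

Within a (chromosome, position) group, observations are clustered by
single linkage under a **joint Levenshtein budget**: the sum of the edit
distances of the two barcodes must be at most 6. The budget is summed
rather than per-barcode because sequencing errors are spread over one
contiguous barcode region of a single read; it is configurable
(`levenshtein_budget`). Representative values are modal with
lexicographic tie-breaks, making clustering invariant to input order.
Cluster pairing additionally requires opposite genome strands in (-, +)
order, different cassette strands, and mutually reverse-complementary
barcodes. The support filters follow the published conventions: a flank
is removed iff it has fewer than 6 reads **and** fewer than 3 distinct
aligned lengths (the conjunction is read literally from the removal rule;
an OR reading is available through configuration), barcode pairs seen at
two loci are removed, parental amplicon support must exceed 50 reads and
30 UMIs (applied to replicate-averaged, depth-normalised counts scaled
back to the mean library depth), and multi-pair sites resolve to the
candidate with more distinct aligned lengths on its left flank.

Haplotype assignment compares read bases at overlapped heterozygous
variants; mixed evidence is inconclusive and discarded, cluster alleles
are majorities ignoring `noVariant` members, and one-sided evidence
carries the insertion call. An allele is physically callable only when a
variant lies within the flank read; at the default spacing (150 bp, the
density of a BL6xCAST F1 hybrid) and 120-nt flanks about 80% of
insertions receive a call, so recovery tests assert that every *called*
allele matches truth rather than demanding a call everywhere.

The bundled placer (`placeIvtReads()`) matches 24-nt read anchors exactly
against both haplotypes with `Biostrings::matchPDict()`; it exists so the
mapper can run on self-contained synthetic genomes. Real-genome alignment
(BAM/CIGAR handling) is deliberately out of scope — the mapper consumes
documented observation tables and will accept any upstream aligner that
fills them.

## Single-cell model

Cells belong to one clone (two for doublets, default rate 3%); each Cre
event is carried by one cell of its clone, which loses the two recombined
parental pairs and gains the detectable derivative pairs. Pairs are
captured independently (default 0.7), yield zero-truncated Poisson UMIs
(mean 4), and ambient contamination re-samples reads from the pooled,
abundance-weighted pair population (default 2% of reads) — the simplest
model consistent with interpreting incongruent novel pairs as ambient
RNA. The generator does **not** model chromatin context, ecDNA
replication/segregation dynamics, Cre toxicity or transcriptome reads
(beyond a parametric QC table), so passing tests demonstrate the
correctness of the inference machinery under the stated noise model, not
robustness to every artefact of real droplet data.

Matrix construction follows the published conventions exactly: chimeric
(cell, UMI) combinations below a 0.2 read share are discarded, UMIs
collapse to Hamming-distance-1 connected components, and capture sides
are summed per pair and cell.

Clonotype reconstruction thresholds entries at >= 3 UMIs, removes cells
and pairs under 20 total UMIs, embeds cells by library-size normalisation
(scale 10,000, log-free) and up to 100 principal components, and
partitions a 10-nearest-neighbour graph with Leiden modularity
communities at resolution 1. Any modularity partitioner would do — the
clonotype definitions are threshold-driven afterwards: per community,
pair detection fractions are rank-ordered and cut at the first
rank-to-next ratio above 1.5. The ranking includes undetected pairs, so
in a clean community the boundary ratio is infinite and the cut lands
exactly at the clone's pair set; a candidate with no inflection anywhere
is rejected. Accepted clonotypes need a maximum detection fraction above
0.5 and more than 6 pairs. Doublet-artifact clonotypes are flagged
automatically by a spectral bipartition of the pair co-detection matrix
(flag when cross-block co-detection is under 10% of within-block), a
reproducible stand-in for the manual matrix inspection the protocol
implies. Near-duplicates merge through a Jaccard graph (connect > 0.1;
bulk clonotypes match de novo ones at Jaccard > 0.05), and discovery
iterates: assignable cells are removed and reconstruction repeats until a
round adds nothing.

Cell assignment works on barcode-1 sets at >= 2 UMIs: the clonotype with
the highest precision wins, a cell is assigned iff recall > 0.1 and
precision > 0.75, and a second-best recall above 0.1 discards the cell as
a probable doublet. Single-cell SV calls apply the bulk novel-pair rules
per assigned cell at >= 2 UMIs and keep only congruent calls (both
contributing insertions belong to the assigned clonotype); incongruent
calls are reported as probable ambient contamination.

## Numerical and degenerate-input choices

* All majority votes break ties lexicographically; tables are emitted in
  canonical sort order, so identical configuration and seed give
  byte-identical outputs.
* Every stage takes an explicit seed; the pipeline derives per-stage
  seeds from one master seed.
* Empty inputs produce empty, fully typed tables (headers preserved
  through TSV round-trips).
* Sites are sampled without replacement across the whole population by
  default: on a megabase-scale synthetic genome, cross-clone TTAA
  collisions would otherwise be about three orders of magnitude more
  frequent than on a real mammalian genome.
* Sequencing noise is substitution-only; the Levenshtein clustering
  budget is exercised by substitutions, and indel reads would be dropped
  at anchor extraction exactly as in the published extraction scripts.

## Problem sizes used by the test suite

The packaged tests run the full machinery at desk scale: mapping
recovery uses 100 clones x 50 insertions on a 3.2-Mb four-chromosome
genome at 10 reads per cassette side and an error rate of 0.1% (100%
exact recovery, zero spurious insertions in the checked seeds); ecDNA
stoichiometry uses 1,000 detectable deletions; clonotype recovery uses 20
clones x 2,000 cells at capture 0.7, 2% ambient and 3% doublets (all
clones at Jaccard 1.0, assignment accuracy >= 99%). These sizes were
chosen so each property is measured with comfortable statistical margin
while the whole suite stays quick to run.

## Worked example

```{r example}
library(shuffleseq)

cfg <- shuffleConfig(sim_n_clones = 5L, sim_insertions_per_clone = 8L,
                     sim_cis_rate = 2, sim_trans_rate = 0.3,
                     sim_n_cells = 250L, seed = 77L)
manifest <- runPipeline(cfg, "shuffle_run")
manifest$counts
```

The same stages are exposed individually (see `?mapInsertions`,
`?callRearrangements`, `?reconstructClonotypes`) and through the thin
command-line wrapper in `inst/cli/shuffleseq.R`.

## Known limitations

* The fixed cassette elements other than the anchors are arbitrary
  spacer-grade sequence of the published lengths; analyses depend only on
  the anchors, element order and total length.
* The placer is exact-match and synthetic-genome-only by design.
* Inter-homolog cis events are classified by the same chromosome and
  orientation rules and only flagged via the allele mismatch column,
  mirroring the parsimony argument that such events are rare.
* Detection-bias mechanisms proposed for the ecDNA excess in real data
  (preferential purification, accessibility-biased transcription, ecDNA
  amplification) are intentionally absent: the simulator emits both
  deletion products at equal depth, and the package's stoichiometry
  checks measure the unbiased 1:1 baseline.
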