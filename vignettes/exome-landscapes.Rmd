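---
title: "Exome landscapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome landscapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomescape)
```

## The method

Vertebrate genomes carry long-range regional structure in base
composition: blocks of genes embedded in GC-rich or GC-poor isochores.
`exomescape` summarises that structure at the level of the *exome* — the
set of protein-coding genes — and compares it across species.  The unit of
analysis is a per-gene metric:

* **GC content** of the representative transcript,
  $100\,(G+C)/(A+C+G+T)$, with ambiguous bases excluded from both counts;
* **amino-acid usage** of the encoded protein, summarised as the mole
  percentage of residues encoded by GC-rich codons (**GARP**: Gly, Ala,
  Arg, Pro), by AU-rich codons (**FYMINK**: Phe, Tyr, Met, Ile, Asn, Lys),
  and by the remaining "mixed" codons (the other ten residues);
* **protein divergence** between a pair of species, $1 - \text{identity}$
  from a global alignment of the orthologous proteins.

Orthologs are matched to a reference species by gene symbol
(case-insensitively, with an explicit alias map for nonstandard names) and
ordered by their position on the reference genome, chromosome by
chromosome.  Each per-gene series is then smoothed with a sliding mean
over the gene and its 100 ordered neighbours (50 on each side), stepping
one gene at a time.  The smoothed series is the **landscape**.  Smoothing
at this width suppresses single-gene noise — a bounded outlier of 100
percentage points can move an interior window mean by at most
$100/101 < 1$ point — while preserving regional peaks and valleys that
are typically 10 points or more in amplitude.

Landscapes of many species, restricted to their shared genes, are
compared by Pearson correlation, turned into a Euclidean distance matrix
$d(i,j) = \sqrt{\sum_g (x_{ig} - x_{jg})^2}$, and clustered
agglomeratively (UPGMA by default) into a dendrogram that can be written
as Newick and checked against a reference phylogeny with the unrooted
Robinson–Foulds distance and the cophenetic correlation.

## Identity, divergence, and the discard rule

Protein pairs are aligned globally (Needleman–Wunsch with Gotoh's affine
gap recurrences, BLOSUM62 scores).  Identity is defined as

$$\text{identity} = \frac{\#\text{matching columns}}
  {\text{alignment length} - \#\text{gap columns}}$$

where a *gap column* is any column containing a gap in either row.
Removing gapped columns from the denominator deliberately makes the
statistic robust to incomplete sequences: a protein with a missing
terminal exon still scores its aligned region fairly.  Pairs with
identity below 0.30 are discarded rather than reported, because at that
level the signal is dominated by annotation problems and dubious
orthology.  Divergence is $1-\text{identity}$ for retained pairs.

Two conventions here were genuinely open and are worth recording:

* *Gap columns versus gap characters.*  We count gap-containing columns.
  Counting gap characters instead gives the same value for single-row
  gaps and differs only where both rows gap in overlapping runs, which a
  global pairwise alignment never produces; the column reading also
  matches the motivation of excluding missing sequence.  Both options are
  exposed through the alignment result fields.
* *Gap penalties.*  The affine cost of a gap run of length $L$ is
  $\text{open} + (L-1)\,\text{extend}$ with defaults open = 12,
  extend = 2, conventional values for global protein alignment at
  BLOSUM62 scale.  They are arguments everywhere, never constants.
  Unknown residues (`X`) score zero against everything and never count as
  matches.
* *Traceback ties* prefer the diagonal, then a gap in the second
  sequence, then the first — an arbitrary but fixed order that makes
  every alignment reproducible.

## Gene catalogs

The catalog layer reproduces a standard representative-transcript
workflow: rows without a protein-coding RefSeq accession (`NM_` curated,
`XM_` predicted) are dropped — non-coding `NR_`/`XR_` entries never enter
the gene set — and among a gene's remaining transcripts the longest is
kept, with ties broken by the lexicographically smallest accession.  The
common vertebrate gene set keeps genes present in at least `min_count`
species of a chosen clade group (default: two among fish, amphibians and
non-avian reptiles), which anchors the set in the deepest-branching
lineages rather than in the many mammal and bird genomes.

## Window mechanics and numerical choices

* **Edges.** Windows are truncated at the ends of the ordered set:
  position $k$ averages ranks $\max(1, k-w)$ to $\min(n, k+w)$.  The
  alternative — dropping the first and last $w$ genes — wastes 100 genes
  of signal per chromosome end and is not used.  An option restricts
  windows to single chromosomes; by default they slide across boundaries,
  and at the default width the difference is confined to the ~50 genes on
  either side of each junction.
* **Missing genes** (no ortholog, no sequence, discarded alignment) are
  removed *before* windowing, so a window always averages the nearest
  available neighbours.  Each species' landscape therefore lives on its
  own gene subset; correlations and matrices re-intersect gene sets
  explicitly.
* **Correlations** between landscapes use the smoothed values by
  default; an unsmoothed per-gene mode exists for checking how much of a
  correlation is created by smoothing itself.
* **Tryptophan** is placed in the mixed class.  Its single codon (UGG) is
  neither GC- nor AU-rich, and the grouping of the other nineteen
  residues forces the mixed class to ten members.
* The distance step exposes **both readings** of "correlate, then build a
  distance matrix": Euclidean distance on smoothed values (default) and
  $1-r$.  Linkage defaults to UPGMA with single/complete/Ward
  selectable.  All reported dendrograms state both choices.

## The simulator

Simulated data are the test bed for every claim the package makes, so the
generator is first-class, deterministic code rather than a fixture.  One
`simulation_config()` describes a study:

| parameter | meaning | default |
|---|---|---|
| `n_genes`, `n_chromosomes`, `n_codons` | genome size and gene length | 2000 genes × 300 codons on 5 chromosomes |
| `gc_baseline`, `peaks` | GC target curve: baseline plus Gaussian bumps (center, sd, amplitude in ranks/points), clipped to [25, 75] | 45% + three peaks of 10–15 points |
| `kappa` | coupling of amino-acid sampling to the GC target | 0.6 |
| `tree` | species tree, branch lengths in expected substitutions/site | 4 taxa, 2 clades |
| `gbgc` | per-clade rank intervals with a GC-fixation bias | none |
| `rearrangement_rate` | gene-block moves per branch | 1 |
| `seed` | full determinism | — |

The desk-scale defaults (2000 × 300) keep a complete simulation under a
few seconds while leaving window estimates with ~20 independent windows
per genome; tests use smaller genomes (150–1200 genes) sized so each
check runs in seconds.

**Coding sequences.** Each codon's residue is drawn from the three groups
with $P(\text{GARP}) = 0.25 + \kappa\,(g-50)/100$ for GC target $g$,
$P(\text{FYMINK})$ mirrored, mixed absorbing the remainder (uniform
within groups); the synonymous codon takes a G/C third position with
probability $g/100$.  At $\kappa = 1$ this plants the strongest
GC–GARP coupling the law allows (GARP fraction 0 to 0.5 over the clipped
GC range), the regime in which the landscape correlation checks run.

**Evolution.** Along each branch of length $t$, every site substitutes
with probability $1-e^{-t}$, drawing its new base from the ancestral
exome's overall base frequencies.  That proposal choice makes base
composition stationary in expectation when no bias acts — a property the
suite tests — at the cost of slowly regressing extreme genes toward the
genome mean, which is also the biologically expected behaviour of
composition without reinforcement.  GC-biased gene conversion is modelled
as *additional* directed events at rate $(1-e^{-t})\,B$ inside a branch's
configured rank intervals, each setting the site to G or C.  Modelling
the bias as extra fixations (rather than as a tilt of an otherwise
fixed-rate process) raises both GC content *and* the substitution rate
inside the interval, so divergence landscapes co-locate with GC gains —
the qualitative signature the pipeline is designed to detect.
Substitutions that would create a stop codon are reverted.  gBGC episodes
attach to the whole subtree spanned by their species set, including its
stem branch, so clades share them.

**Rearrangements** move contiguous blocks of 5–50 genes to a random
position; sequences are untouched, only the species' own gene order
changes.  Because landscapes are always drawn on the *reference* order,
rearrangements exercise the catalog and ordering machinery rather than
the smoothing.

**What the simulator does not emulate** — and hence what green tests do
*not* establish about real data: no indels (orthologous proteins stay
length-matched, so the gap machinery is exercised mainly by its oracle
tests), no rate variation among sites or genes, no selection on amino
acids beyond the composition coupling, no gene birth/death or lineage-
specific gene sets (every species has every gene unless filtered), fixed
gene length, and no within-chromosome gene-density structure.  Results on
real genomes additionally depend on annotation quality and ortholog
assignment, which the alias-map input only partially captures.

## Problem sizes and test design

The oracle suite checks the sliding window against brute-force range
means (1000 random series), the affine aligner against exhaustive
enumeration of all global alignments (all pairs to length 3 over a
4-letter alphabet, plus random pairs to length 6) and against an
independent affine-gap implementation, and the simulator's divergence
against a closed-form codon-level expectation.  Recovery tests use fixed
seeds: a planted 10-point GC bump (sd 300 ranks) must be located within
±150 ranks; a 6-taxon tree with nested clade-specific gBGC episodes must
be reconstructed exactly (RF = 0); and divergence must be elevated inside
gBGC intervals.  `scripts/acceptance.R` re-runs all of these from scratch
under a caller-supplied seed.

## Limitations

The dendrogram is a similarity clustering, not a phylogenetic inference:
it has no substitution model, no rate calibration, and its branch lengths
are merge heights of landscape distances.  Landscape correlation between
distant clades can be driven by a few strong shared isochores rather than
genome-wide similarity; the per-gene (unsmoothed) correlation mode is the
control for that.  Finally, the 30% identity discard interacts with the
common-gene-set rule: a gene can be present everywhere yet missing from a
divergence track, so track comparisons should always report their n.
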