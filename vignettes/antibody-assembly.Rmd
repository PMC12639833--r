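---
title: "Database-free antibody sequencing from integrated MS data: methods and design"
author: "AbSeqMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Database-free antibody sequencing from integrated MS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbSeqMS)
```

## The problem

Polyclonal antibody preparations and monoclonal mixtures contain several
immunoglobulins whose light chains (LC) and heavy chains (HC) must be
sequenced residue-by-residue without any germline or proteome database.
AbSeqMS implements a purely mass-spectrometric workflow that integrates
three data layers:

* **bottom-up** de novo peptide reads (8-20 residues, with per-residue
  local confidence and an average local confidence, ALC);
* **middle-down** neutral c/z fragment masses of the hinge-cleaved,
  reduced subunits LC, Fd and Fc/2 (20-30 kDa species that ETD can
  fragment informatively), deconvoluted upstream;
* **intact** proteoform masses of the whole, reduced and subunit samples.

Bottom-up reads supply the letters, middle-down masses arbitrate between
alternative assemblies, and intact masses fix the endpoints and finally
group the subunits back into whole antibodies.

## Isobaric mass blocks and the overlap graph

De novo reads disagree in isobaric ways: N reads as GG, Q as GA, SL as
TV, adjacent residues swap.  Two reads are therefore aligned by
decomposing the maximal suffix/prefix overlap into *mass blocks* - ordered
pairs of equal-mass segments no longer than two residues per side
(`alignMassBlocks()`).  Block equality is symbolic: N and GG share an
elemental composition, so the comparison uses exact residue arithmetic at
1e-6 Da, not an instrument tolerance.  The residue table carries
monoisotopic masses at elemental precision precisely so these identities
hold to float rounding.

A directed edge u -> v is drawn when the maximal decomposable overlap has
at least three blocks and v contributes residues beyond the overlap
(`buildOverlapGraph()`).  Candidate pairs are found by hashing all prefix
masses, so only mass-compatible suffix/prefix pairs are aligned.

Positional confidence is then accumulated across the graph
(`accumulateConfidence()`): residues aligned one-to-one receive the
neighbour's positional score, residues inside longer blocks (where the
position correspondence is ambiguous) receive the neighbour's ALC, and a
residue's accumulated score is `min(1, base + mean(contributions))`.  The
mean-with-cap form keeps the score a probability-like quantity and makes
accumulation order-independent; the raw-sum alternative is unbounded and
usable only for ranking, which is why we normalise and document the
choice here.

## Discretized-mass DP assembly

One subunit is assembled at a time against its deconvoluted monoisotopic
mass and its aggregated fragment mass list.  Fragments are read twice:
as c ions, giving neutral prefix residue masses (PRMs), and as z ions,
giving suffix residue masses (SRMs).  Converting SRMs to PRMs through the
precursor mass would inflate a 0.05 Da fragment error to ~1 Da
(`srmToPrmError()`), so the forward pass uses PRMs and the reverse pass
uses SRMs, and the two directions are merged.

Partial paths live in a DP table indexed by discretized total residue
mass (width 0.1 Da; a mass of 111.2 Da has index 1112, nearest-integer
rounding).  Each index holds a bounded priority queue (capacity 10) of
paths scored

  `s(p) = T + (NA - NU)`

with `T` the number of matching middle-down fragments (50 ppm), `NA` the
path mass divided by the averagine residue mass (111.1254 Da), and `NU`
the number of residues with accumulated confidence below 0.5.  Terminal
candidates are paths within 4 Da of the subunit mass; paths not ending in
a classifier-labelled end read are penalised by 5 score units (the
magnitude is a configuration default; only its existence is prescribed by
the method).  Because the subunit type is unknown, assembly is attempted
three times, once per type (LC, Fd, Fc/2) with that type's start/end
read sets, and the attempt with the most middle-down matches wins.

Note one bookkeeping convention: DP path masses are residue sums, while
intact subunit masses include one water; targets are water-corrected at
the assembly interface.

### Terminus classification

The start/end read sets come from a pluggable classifier
(`classifyTerminus()`).  The default scores read prefixes and suffixes
against shipped consensus motifs of antibody chain termini (e.g. the
DIQMTQSP / EIVLTQSP / QSVLTQPP light-chain starts, the GPSVFLFP Fc/2
start, the hinge-proximal Fd end) in Leu-space with a 0.8 identity floor,
returning OTHER otherwise.  This replaces a learned classifier trained on
repertoire databases: the contract (seven classes, pluggable
implementation) is preserved while keeping the package database-free.
The motif table is a plain-text file that can be swapped for other
species or scaffolds.

### Merging the two directions

Forward candidates are accurate where c ions are dense (the N-terminal
half) and reverse candidates where z ions are dense.  A forward and a
reverse candidate that share a read are spliced at that read.  The cut
point is located by *local mass anchors*: the shared read's realized span
carries exactly the read's mass in both paths (mass-block alignment
conserves segment mass), so its far boundary is the near boundary plus
the read mass.  Positional bookkeeping would drift whenever an isobaric
block changes segment length, and the two halves' absolute prefix masses
differ by their respective errors, so neither is usable; the local anchor
is exact.  Merged sequences must match the subunit mass within 4 Da and
are ranked by left-half PRM matches plus right-half SRM matches.

### Performance design

Three implementation measures keep the search tractable without touching
the model:

* **Dominance.** Two co-indexed paths ending in the same read with
  exactly equal mass have identical extension behaviour and identical
  future score increments, so only the better one is kept.  This removes
  the many re-decompositions of one realized prefix and cannot change the
  optimum.
* **Amortized sweeps.** The three type attempts of all subunits share one
  graph, and a chain's prefix masses match essentially only its own
  subunit's fragments.  The pipeline therefore runs one forward and one
  reverse DP per type with *all* subunit masses as simultaneous targets
  and the pooled PRM/SRM lists as expansion guidance, then rescores the
  collected candidates per subunit with that subunit's own fragment list.
  Candidates are collected deeper (50) than the reported top 10 so that
  per-subunit rescoring, not the pooled surfacing score, decides the
  ranking - this matters when two subunit masses fall within one
  candidate window of each other.
* **Beam margin.** An extension is skipped when, even gaining one
  fragment match per new boundary, it would trail the best accepted score
  at comparable mass (50 Da windows) by more than `beamMargin` (default
  30).  This is a heuristic beam: chimeric paths that have stopped
  matching fragments fall behind linearly and are cut; setting
  `beamMargin = Inf` (the default of `forwardPass()`/`reversePass()`)
  restores the exact bounded-queue DP, which is what the
  oracle-equivalence tests exercise.

## Refinement

`spiderCorrect()` repairs isobaric assembly errors by consensus over the
reads themselves: segments with at least two low-confidence residues are
anchored by exact 4-residue flanks in the mapped reads, the residues each
read places between the flanks are collected as candidate rewrites, and a
rewrite is accepted only when it is strictly isobaric (mass preserved to
1e-6 Da), supported by at least two reads forming a majority, and
improves the segment's mean confidence.  Conflicting equally supported
rewrites leave the segment flagged.  The trigger uses the realized path's
*source-read* local confidence rather than the accumulated score: graph
accumulation deliberately saturates wherever any neighbour overlaps (long
blocks contribute ALC), so it cannot flag isobaric ambiguity.

Ile and Leu share a residue mass, so assembly runs in Leu-space
(`convertIleToLeu()`); afterwards `resolveIleLeu()` maps EThcD reads onto
the sequence and lets their w-ion evidence vote per position, a strict
majority setting Ile, ties and silence defaulting to Leu with a flag.

## Antibody pairing

`pairHeavyChains()` joins Fd and Fc/2 into heavy chains when the junction
satisfies the hinge-protease motif (IdeS cleaves inside ...LLG|G...),
at least one bottom-up read spans the junction, and the combined average
mass (Fd + Fc/2 minus water) is within 4 Da of an observed reduced mass.
`pairAntibodies()` then forms whole antibodies: the expected whole mass
is twice the sum of the observed reduced HC and LC masses minus 16
disulfide bonds, accepted within 100 ppm - a deliberately lenient gate
because partially reformed disulfide bonds shift reduced masses.  All
mass-consistent pairings are reported, including ambiguous ones; intact
mass alone cannot always exclude a false pairing, and the report is
explicit about it.  The average-mode water constant is 18.011 Da
throughout the pairing arithmetic, the convention under which the
pairing-table ppm values reproduce; the sub-mDa difference from the
physical average water mass is irrelevant at these gates.  The
per-disulfide mass is two hydrogens (2.0159 Da average).

## The synthetic-data generator

`simulateDataset()` emulates all three layers for a ground-truth mixture
so the whole pipeline is testable without instrument data.  The default
scenario is the package's reference condition: four antibodies at
3:2:1:1 with pairwise-shared Fc/2 sequences (ten distinct subunits, as a
four-IgG1 mixture produces), chains of realistic length (LC 214, Fd 225,
Fc/2 210 residues; ~23-25 kDa), variable regions randomized behind
conserved terminal motifs, one antibody carrying N-terminal
pyroglutamate on LC and Fd, and all Fc/2 chains without the C-terminal
Lys (the processed molecular forms are what the instruments see).

* **Bottom-up**: 8 digest passes of 8-20-residue windows per species.
  Reads are drawn from the reduced chains (LC, HC) *and* the
  hinge-cleaved subunits (Fd, Fc/2): the assembly needs reads that
  terminate exactly at subunit boundaries and the pairing needs reads
  spanning the hinge junction, and digesting both preparations - as the
  multi-sample bench workflow does - yields both.  Local confidence is
  Beta(9, 1.5) in the read interior and Beta(3, 2) at the two terminal
  residues (poor terminal fragmentation); 2 percent of reads carry one
  injected isobaric error whose site and neighbours get clearly low
  confidence (errors manifest as locally poor fragmentation - this is
  also what makes both expansions and contractions satisfy the
  two-low-residue segment rule during refinement).  Reads are emitted in
  Leu-space; half are EThcD with w-ion evidence at 80 percent of I/L
  positions.  Carbamidomethylation is not applied to simulated reads:
  the assembly target is the non-alkylated subunit mass (the chem module
  still parses the modification in real exports).
* **Middle-down**: fragmentation sites retained at 60 percent marginal
  coverage, c sites biased to the N-terminal half and z sites to the
  C-terminal half (where ETD fragments of 25 kDa subunits are actually
  observed), 20 ppm Gaussian mass noise, 5 percent decoy masses, split
  across four emulated targeted runs with per-run precursor error.
* **Intact**: subunit masses monoisotopic at 10 ppm, reduced and whole
  masses average-mode at 10 and 30 ppm.

What the generator does **not** emulate: isotope envelopes (intact
centroid synthesis places one monoisotopic peak per charge, which is why
no averagine apex correction is implemented in the deconvolution),
ionization-efficiency differences beyond a scalar abundance, chimeric
spectra, glycoforms, and real CDR length variation.  Passing the
round-trip tests therefore demonstrates the correctness of the assembly
logic under realistic mass arithmetic and error structure, not
instrument-level performance.

## Intact deconvolution

`deconvoluteIntact()` follows the feature-based scheme: a 0.1 min RT
sliding window merges neighbouring centroided spectra (peaks within 0.01
Th summed), each merged spectrum is deconvoluted by greedy
highest-intensity-first charge assignment (a mass needs at least two
supporting charges), and masses agreeing within 20 ppm across at least 3
consecutive merged scans with a run of at least 3 consecutive charges
become proteoforms with per-charge (m/z, RT) features.  A full Bayesian
charge-smoothing deconvolution is deliberately not reproduced; the
consecutive-charge support rule is deterministic and sufficient at
antibody scale.  `buildInclusionList()` picks, greedily by intensity, up
to four features per proteoform that overlap no previously selected
feature in *both* m/z and RT (the conjunction is a design choice; the
alternative disjunction rule would discard more targets than the
instrument requires).

## Parameter reference

| parameter | default | unit | role |
|---|---|---|---|
| ALC filter | > 0.7 | - | read quality gate |
| low-confidence threshold | 0.5 | - | defines unconfident residues (filter runs, NU, refinement) |
| max low-confidence run | 4 | residues | read filter |
| min mass blocks per edge | 3 | blocks | overlap graph |
| DP width | 0.1 | Da | mass discretization |
| queue capacity | 10 | paths | bounded DP queue |
| terminal tolerance | 4 | Da | candidate and merge mass gate |
| middle-down tolerance | 50 | ppm | fragment matching |
| end penalty | 5 | score | unlabelled path ends |
| beam margin | 30 | score | pipeline pruning (Inf = exact) |
| inclusion entries | 4 | per mass | targeted precursor list |
| whole-mass tolerance | 100 | ppm | antibody grouping |
| disulfide bonds | 16 | per antibody | whole-mass arithmetic |

## Problem sizes used by the test-suite

The round-trip suite runs the default four-antibody scenario over 20
seeds (about 2200 reads and ten ~23-25 kDa subunits per seed); DP
oracle equivalence uses 200 random graphs of at most 12 reads with queue
capacity 64, the regime in which the bounded queue provably equals
exhaustive enumeration; refinement monotonicity uses 20 planted-error
chains.  These sizes were chosen so each property is measured at
meaningful scale while the whole suite remains routine to run.

## Known limitations

* Two subunits whose masses differ by less than the 4 Da window are
  separated only by their fragment matches; deeper candidate collection
  handles the simulated case, but co-eluting near-isobaric subunits with
  poor fragmentation would remain ambiguous (they are in practice, too).
* The default terminus classifier is motif-based; strongly divergent
  scaffolds (camelid VHH, engineered termini) need a replacement motif
  table or classifier.
* Fab-level intact analysis and disulfide connectivity mapping are out
  of scope.
* Abundance reporting follows intensity, which is not sample
  stoichiometry.

## A worked example

```{r example, eval = FALSE}
library(AbSeqMS)
ds <- simulateDataset(simScenario(seed = 1))
res <- runPipeline(ds, truth = ds$truth)
res$metrics$identity            # length-weighted residue identity
res$metrics$pairingsRecovered   # of res$metrics$pairingsTrue
res$groups                      # antibody-group table with ppm deltas
```
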