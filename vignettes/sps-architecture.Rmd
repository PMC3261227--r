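---
title: "Detecting and comparing Su(H) paired-site regulatory architecture"
author: "spsarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing Su(H) paired-site regulatory architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsarch)
```

## The biology being modelled

Genes of the Enhancer of split complex (E(spl)-C) are Notch-pathway
repressors of proneural identity. Most of them share a compact upstream
regulatory signature: an **inverted pair of Suppressor of Hairless (Su(H))
binding sites** — consensus `YGTGRGAA` — canonically separated by 17 bp,
often with a **proneural A box** (`RCAGSTG`) close by. The pair plus A box
is the *SPS+A* element; a pair without an associated A box is a bare *SPS*.
Two further details carry signal: the spacer length (15 bp and 7 bp
variants occur and are conserved), and the degenerate first position of the
Su(H) consensus (the "Y" position), which is canonically `T` in the
gene-upstream site and `C` in the gene-downstream site. Post-transcriptional
regulation acts through three short 3' UTR elements bound by miRNAs — the
Brd box (`AGCTTTA`), GY box (`GTCTTCC`) and K box (`TGTGAT`) — whose
*ordered organization* along the UTR, rather than exact positions, is the
conserved feature between species.

`spsarch` implements this census as a reusable, fully testable pipeline:
degenerate motif scanning of non-coding DNA on both strands, inverted-pair
construction and SPS/SPS+A classification, gene-relative positioning,
3' UTR box profiling with cross-species organization comparison, and flank
alignment for conservation reports. A synthetic-contig generator plants
whole architectures with ground truth so that recall, false-positive
behaviour and every coordinate convention are checked by construction,
without any sequence downloads.

## Coordinate conventions

All coordinates are **1-based inclusive** on the plus strand of the contig,
the convention of GFF3 and of the Bioconductor ranges infrastructure this
package builds on. Three derived definitions follow from it and are used
everywhere:

* **Spacer**: bases strictly between the two 8-mer Su(H) intervals
  (`right_start - left_end - 1`), so "separated by 17 bp" means 17
  intervening bases.
* **Upstream distance**: bases strictly between the module edge nearest the
  start codon and the first base of the start codon, exclusive of both. A
  module ending at 4447 with a plus-strand start codon at 5001 is 553 bp
  upstream.
* **A-box distance**: bases strictly between the A box and the pair span
  (0 when they touch or overlap).

UTR box offsets are the one deliberate exception: they are reported as the
number of bases *preceding* the box within the gene-oriented UTR window
(a 0-based offset), because "distance from the UTR start" is how these
profiles are read and compared.

## Scanning model and its parameters

Patterns are degenerate IUPAC words; a compiled pattern accepts exactly the
Cartesian expansion of its codes, case-insensitively, and non-ACGT
characters in the contig (assembly `N`s) never match. Both strands are
scanned exhaustively; overlapping and nested matches are all reported, and
deduplication is deliberately deferred to the pair builder, since no filter
at the hit level is part of the architecture definition. Matching is
delegated to `Biostrings::matchPattern()` with a fixed subject; an
independent per-offset enumeration oracle in the test suite guarantees the
semantics just stated.

The tunable parameters, their defaults, and why:

| parameter | default | rationale |
|---|---|---|
| spacer window | 0–30 bp | captures the known 7, 15 and 17 bp architectures with head-room |
| canonical spacer | 17 bp | the defining SPS geometry |
| A-box `max_dist` | 500 bp | real modules count A boxes 232 bp and 405 bp away; 500 gives margin while staying local |
| flank width | 200 bp | the standard window extracted around a module for cross-species alignment |
| UTR window | 1000 bp 3' of the stop codon | the genomic fallback when no transcript defines the UTR |
| background GC | 0.40 | fly-like intergenic composition for the generator |

Three design points were genuinely open and were decided as follows:

* **Inversion without orientation filtering.** Any opposite-strand,
  non-overlapping pair within the spacer window qualifies as inverted;
  convergent vs divergent is recorded but not filtered, because the
  head-to-head/tail-to-tail distinction is not part of the published
  architecture definition.
* **Greedy pair deduplication.** When one site could join several pairs,
  the pair whose spacer is closest to 17 bp wins (ties go to the smaller
  spacer, then the leftmost pair). One module per locus is the reported
  reality; this rule makes the choice deterministic and testable against a
  brute-force oracle.
* **A boxes on both strands.** `RCAGSTG` is not its own reverse complement,
  so strandedness changes counts. Both strands are scanned by default (the
  conservative superset for an enhancer element, whose function is not
  strand-dependent); UTR boxes, by contrast, are mRNA-level elements and
  are scanned **sense-strand only**.

"Non-coding" means **non-CDS**: introns and intergenic DNA are both
searched. A mask defined relative to transcripts would lose modules lying
downstream of two genes, a configuration that demonstrably exists.

Module-to-gene assignment lists every gene the module is upstream of
(nearest first), so a module between two divergently transcribed genes
reports both candidates rather than forcing a choice. Y positions are only
typed once a gene context fixes which site is gene-upstream.

## UTR organization comparison

Conservation of UTR regulation is judged on the ordered string of box
*types*; offsets are ignored. Matched boxes form the longest common
subsequence of the two type strings, and the class is `identical`
(equal, non-empty), `identical-empty` (no boxes in either species — a real,
distinct state), `none` (empty LCS with at least one non-empty profile) or
`partial`. Windows truncated by contig ends or short ESTs are flagged
through to the comparison instead of being interpreted: absence of a box in
a truncated window is weak evidence and the output says so.

## Alignment and percent identity

Flank conservation uses optimal global alignment with affine gaps
(match +1, mismatch −1, gap open 5, gap extend 1; a run of *L* gaps costs
`open + ext * L`), computed by `Biostrings::pairwiseAlignment()` and checked
against an independent dynamic-programming oracle at small lengths. A
segment-based aligner would give slightly different identity figures on
real data — published values may shift by a few percent under aligner
choice — so a deterministic, standard aligner with a stated scoring scheme
is used instead, and **two** identities are always reported: over all
alignment columns (gaps count against identity) and over gap-free columns
only. The two bracket the plausible published definitions. Conserved
blocks are maximal runs of identical columns of length ≥ k (default 10),
reported in first-sequence coordinates.

## What the generator emulates — and what it does not

`generate_contig()` draws an i.i.d. background at a configurable GC
fraction and plants, verbatim: start/stop codons for each gene,
whole modules (two inverted Su(H) sites with requested spacer and Y
characters, A boxes at requested gaps) and UTR box strings. In
clean-background mode, any accidental unplanted match of the five motifs is
removed by re-drawing only the background bases it uses, so recall is 1.0
and the false-positive count is 0 *by construction* — which is exactly what
makes the mode suitable for unit tests. With cleaning off, background hit
counts follow the closed form
`(L - m + 1) * sum of word probabilities (both strands)`, and the test
suite verifies the empirical rate against it.

`generate_ortholog_pair()` derives a second contig under per-base
substitution (and optionally geometric-length indels), with planted
elements protected or exposed. With no indels the expected flank identity
is `100 * (1 - d)`.

The generator deliberately does **not** emulate: compositional
heterogeneity or repeats, substitution-rate variation across sites,
phylogenies with more than two taxa, or transcript structure beyond a
single-interval CDS. Passing tests therefore demonstrate the correctness of
the *detection and comparison machinery*, not the false-positive rate to be
expected on real, repeat-rich genomic DNA — on real contigs the background
model underestimates motif clustering.

`degrade_site()` mutates planted sites for sensitivity studies. One edge
was resolved deliberately: a substitution that changes the sequence but
leaves the site matching its degenerate consensus (flipping the Y position
between `T` and `C`) is *accepted* and the truth record updated, because
the Y flip is a biologically meaningful state to simulate; deletions must
break the consensus, and byte-identical no-op edits are rejected.

## The census fixture

`census_specs()` encodes an 11-gene complex in two synthetic species:
7 SPS+A modules and 4 bare SPS pairs, one 15 bp spacer, upstream distances
of 4970/553/469/338 bp (species a) and 1419/353/761/275 bp (species b) for
the four distance-documented genes, a distal A box (232 bp / 405 bp), four
genes with a `C` in the upstream Y position, and UTR box strings whose
comparison yields 5 identical organizations, 1 identical-empty, 3 partial
and 2 with nothing in common. Only these architectural facts are specified
by the study design; the gene layout (9 kb spacing, 900 bp single-interval
CDS on a 100 kb contig), the concrete box strings realizing each
conservation class, and the sides on which A boxes sit are this package's
own construction, chosen once for feasibility of packing. The module that
in real data lies downstream of two genes is represented as a second, more
distal module upstream of the same gene, since the generator places modules
gene-relatively. The counts are forced by construction; recovering them
end-to-end is a plumbing check, not a biological result.

## Numerical choices and degenerate inputs

* Ties in the greedy pair dedup: smaller spacer, then leftmost pair.
* Hits tables sort by start, then end, then strand (`+` before `-`); a
  position matching on both strands yields two hits.
* Empty results are valid values everywhere (empty hit table, empty UTR
  profile, zero-row assignment when no genes exist); empty *inputs* (an
  empty FASTA) are errors.
* UTR windows shorter than a motif return empty profiles rather than
  failing; windows truncated at contig ends carry a flag.
* Lowercase (soft-masked) sequence matches normally; `exclude_softmasked`
  drops hits overlapping masked bases.
* The clean-background rejection loop caps at 100 sweeps and fails loudly
  if an unplanted match ever lies entirely inside planted footprints
  (never observed with the shipped specs).

## Problem sizes in the shipped tests

The test suite checks scanner/oracle equivalence on twenty 5–10 kb
contigs, pair-builder/oracle equivalence on instances up to 50 hits,
aligner optimality on all length combinations up to 8 bp, recall on 50
clean two-gene specs, background rates on 200 ten-kb contigs, and flank
identity on 100 ortholog pairs at 10% divergence — sizes chosen so the
whole suite completes in about a minute while keeping the standard errors
of the stochastic checks well below the tested tolerances (3 standard
errors in every case).

## Known limitations

* Modules are detected from exact degenerate-consensus matches; there is no
  position-weight-matrix scoring, so near-consensus sites (like a
  documented single-base-deleted Su(H) site) appear only through their
  *absence*, which is the intended semantics of a consensus census.
* The A-box association radius is a hard threshold; the SPS+A vs SPS split
  of a real census can shift under a different `max_dist`, which is why the
  parameter is exposed and the analysis scripts report distances alongside
  classes.
* Percent identity depends on the aligner and scoring scheme; both identity
  definitions are emitted to make that dependence visible.
* The ortholog mutation model is neutral and uniform; it is a calibration
  device, not an evolutionary simulation.
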