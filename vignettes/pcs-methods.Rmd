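---
title: "Methods: comparative annotation of phytochelatin synthases"
author: "PCSkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative annotation of phytochelatin synthases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PCSkit)
```

## The biological problem

Phytochelatin synthases (PCS, EC 2.3.2.15) are papain-like cysteine
peptidases that build the metal-chelating peptides
(gamma-Glu-Cys)~n~-Gly from glutathione.  Their N-terminal catalytic
domain carries a strictly conserved Cys/His/Asp triad (Cys56, His162 and
Asp180 in the *Arabidopsis thaliana* AtPCS1 numbering that anchors the
field's coordinates).  Across cyanobacteria and microalgae, PCS and
PCS-like proteins fall into two groups that are *not* the old
prokaryote/eukaryote divide: the discriminating feature is the residue
four positions upstream of the catalytic cysteine.  Asn there defines the
"N" isoforms (group 1, short, cysteine-poor, usually lacking a C-terminal
extension — the "half PCS" architecture), while Glu or Asp define the
"E"/"D" isoforms (group 2, plant-like, with the four conserved cysteines
arranged as CC and CXXXC between the catalytic Cys and His, and a
Cys-rich C-terminal tail).  The same residue controls a regulatory
property: with Glu/Asp at Cys-4 and Ser/Thr at Cys-7 the upstream
threonine sits in a `[ST]-X2-[DE]` context and is a casein kinase 2
target; with Asn the context is lost.

PCSkit re-implements that comparative analysis as a tested pipeline:
triad annotation, isoform and CK2 calls, ProtParam-style physicochemical
profiles, JTT-distance neighbor-joining trees with bootstrap, ungapped
motif discovery by expectation maximization, and the group statistics —
plus a synthetic-data generator that provides ground truth for all of it.

## Triad annotation

`detectTriad()` offers two paths.

* **Reference alignment** — the query is globally aligned
  (Needleman–Wunsch, affine gaps, BLOSUM62, gap open 11 / extension 1) to
  an annotated reference and the reference triad is mapped through the
  alignment; the mapping is accepted only if the mapped residues are
  exactly C, H and D and exactly 17 residues lie strictly between His and
  Asp.  This path presumes homology with the reference.  The packaged
  reference is a **synthetic** scaffold
  (`inst/extdata/synthetic_pcs_reference.fasta`) built by the package's
  own generator with its triad at 56/162/180; it is a stand-in
  constructed so that the package is self-contained, not a natural
  sequence, and users with real annotated proteins should supply them via
  `readReferenceSet()`.
* **Constrained scan** — all (C, H, D) position triples with
  `chBounds` (default 90–160) intervening residues between Cys and His
  and exactly 17 between His and Asp are enumerated and scored for
  context plausibility: +2 for N/E/D at Cys-4, +1 for S/T/N at Cys-7, +1
  for Y/F at Cys-1.  The highest-scoring candidate wins; ties go to the
  smallest Cys position.  The default spacing bounds bracket the 94–155
  range observed across annotated PCS proteins.

"Distance" here always means the count of residues strictly *between*
the two catalytic residues, the convention under which the AtPCS1
coordinates 56/162/180 give the familiar values 105 and 17 and the
His–Asp spacing is universally 17.

## Classification and regulatory context

`classifyIsoform()` reads the residue at Cys-4: N maps to subtype N /
group 1, E and D map to subtypes E and D / group 2, anything else leaves
the sequence `unclassified` with no group (it stays in all outputs — the
data do not justify guessing, e.g. for Gln at that position).
`checkCk2Context()` is deliberately the bare published rule: S **or** T
at Cys-7 (Ser is accepted alongside Thr) and D or E at Cys-4.
`findConservedCys()` scans only the open Cys–His interval for CC and
C-X(3)-C, reports all (possibly overlapping) hits, and counts distinct
participating cysteines capped at 4 to mirror the four-conserved-cysteine
bookkeeping; the catalytic Cys itself is not counted.
`columnInformation()` provides sequence-logo information content,
`log2(20) - H`, per column of a gap-free block.

## Physicochemical profile

All Table-style quantities are computed from packaged constant tables:
Expasy average residue masses (molecular weight, kDa), the Bjellqvist pKa
set (isoelectric point; the net-charge function is strictly decreasing in
pH, so bisection to 1e-4 pH finds the unique root), the charged-residue
percentages `100*(D+E)/L` and `100*(R+K)/L`, the Guruprasad dipeptide
instability index `(10/L) * sum DIWV(x_i, x_{i+1})` with the "stable"
flag at the conventional threshold of 40, and Ikai's aliphatic index
`X(Ala) + 2.9 X(Val) + 3.9 (X(Ile)+X(Leu))` in mole percent.  `X`
residues count toward length and percentages but contribute nothing to
mass, charge or dipeptide sums (with a warning).  Comparisons against
printed reference values use half-even rounding to two decimals.

## Phylogenetic grouping

Pairwise distances are maximum-likelihood divergences under the JTT
empirical substitution model: `jttMlDistance()` maximizes
`sum log(pi_a P_ab(t))` with `P(t) = exp(Qt)`, `Q` built from the
published JTT exchangeabilities and equilibrium frequencies (packaged as
static data) and scaled to one expected substitution per site per unit
`t`.  Optimization is bounded scalar search on [0, 10] to 1e-6; the cap
flags saturated pairs.  Gap and `X` columns are removed pairwise rather
than list-wise, because the C-terminal domain is highly variable and
complete deletion would discard most of the signal.  Trees come from
classical neighbor joining (`ape::nj`), which is exact on additive
matrices; negative branch lengths are clamped to zero.  Bootstrap
supports resample alignment columns, rebuild the NJ tree per replicate
and count bipartitions of the full-data tree.  The default multiple
alignment is reference-anchored stacking of pairwise alignments
(insertions relative to the reference are dropped) — adequate for the
conserved catalytic domain, and replaceable by any user-supplied MSA.
A full ML topology search is out of scope; NJ on ML distances is the
documented substitute and is sufficient for the two-group split that the
analysis turns on.

## Motif discovery

`discoverMotifs()` elicits ungapped motifs sequentially.  The model is
ZOOPS (zero or one occurrence per sequence; OOPS by flag): with prior
`gamma` a sequence carries one site at a uniform offset.  The motif is a
width-by-20 letter-probability matrix with pseudocount 0.01 per cell; the
background is the 0-order composition of the input.  EM maximizes the
observed-data log likelihood plus the Dirichlet prior term, so the
tracked objective is non-decreasing (asserted in tests).  Model selection
is a BIC-penalized log-likelihood ratio, `LLR - (19w+1)/2 * log(N)` —
a deliberate, documented substitute for MEME's E-value.  The search runs
a coarse width grid (step 2) with subsequence-seeded starts filtered by
short pilot runs, then refines the winner by register-shift polishing
(EM restarted from the shifted matrix) and a one-column-at-a-time width
hill-climb; without the refinement, EM can converge to a register shifted
by a few columns.  Discovered sites are masked before the next motif.

Discovery stops when the best remaining motif drops below
`icThreshold` bits of information per column.  The default of 2.0 comes
from a null calibration: across 20 datasets of 30 uniform-random 80-mers,
the best spurious motif reached 1.33–1.68 bits/column, while a faithfully
recovered exact 12-mer sits near 4.2; the threshold separates the two
regimes with margin on both sides.  `scanMotif()` scores log-odds per
window, with a threshold calibrated from the *exact* null score
distribution of the motif (discrete convolution over columns) at a
configurable per-window p-value (default 1e-4).

## Statistics

`compareGroups()` reproduces the published testing protocol literally:
Shapiro–Wilk normality per group and Levene's test (centered on the
mean) as assumption checks at `alphaAssume = 0.05`, then a two-sided
pooled-variance Student's t-test.  Assumption violations are *flagged*,
never silently switched to another test (Welch is available by explicit
flag); constant groups make Shapiro undefined and are reported as
not-ok.  No multiple-testing correction is applied, matching the original
protocol.

## The synthetic-data generator

`generatePcsSequence()` assembles scaffolds with the PCS architecture:
an N-terminal region (default 48 residues, putting the catalytic Cys at
position 56), Thr at Cys-7 when requested (and guaranteed-not-S/T
otherwise), the subtype letter at Cys-4 followed by Gln (N) or Pro (E/D)
at Cys-3 and Tyr/Phe at Cys-1 as in natural form strings, a Cys–His
segment with optional planted CC and CXXXC, exactly 17 residues between
His and Asp, and a tail with a configurable Cys fraction.  Defaults
encode the two architectures: N scaffolds get a 50-residue tail at 1%
Cys and no conserved pairs; E/D scaffolds get a 250-residue tail at 6%
Cys with both pairs — the short/cysteine-poor versus long/cysteine-rich
contrast reported for the two groups.  The background is uniform over
the 20 residues so no motif signal exists unless planted; real PCS
composition statistics are not published, so uniformity is a stand-in,
not an inferred property.  Reserved letters are excluded from regions
where they could create competing triads, and every scaffold is
re-drawn until the constrained scanner recovers exactly the planted
triad, making the ground truth unambiguous.  Dataset generation draws
each scaffold's Cys–His spacing uniformly from 94–155.  One integer
seed drives derived sub-seeds for every record, so whole datasets are
byte-reproducible.

`evolvePair()` simulates ancestor/descendant pairs at a chosen JTT
divergence for testing the distance estimator, and `mutateSequence()`
produces homologous variants with protected positions for testing the
alignment-guided triad path (on uniform-random scaffolds unrelated to
the reference that path cannot work — it presumes homology — so its
tests use mutated derivatives of an annotated scaffold).

What passing tests on these data do and do not show: the generator
reproduces the *architecture* of PCS proteins (positions, spacings,
composition contrasts), not their evolutionary correlation structure,
indel patterns, or real amino-acid composition.  Perfect recovery rates
on synthetic data therefore validate the machinery and its conventions,
not performance on diverged natural sequences.

## Problem sizes and determinism

The shipped test-suite and acceptance-script experiments use 201
scaffolds for recovery properties, 10^4 sites for divergence estimation,
50 random trees (5–12 taxa) for NJ exactness, 30 sequences for the
planted-motif experiment, 8 taxa with 100 bootstrap replicates for the
two-cluster analysis and 2000 simulations for the type-I error check —
sizes chosen so the whole suite runs in about a minute on one CPU while
every check retains clear statistical margins.  All stochastic steps take
explicit integer seeds; identical seeds give byte-identical outputs
(manifest checksums are compared in the tests).

## Known limitations

* The alignment-guided triad path needs a homologous reference; the
  packaged reference is synthetic, so for real data users should supply
  an annotated natural PCS (e.g. AtPCS1) via `readReferenceSet()`.
* Reference-anchored stacking discards insertions relative to the
  reference; deeply diverged C-terminal regions are better served by an
  external MSA.
* NJ on pairwise ML distances replaces a full ML topology search.
* The classifier uses fixed sequence offsets (-4, -7) from the catalytic
  Cys, not alignment columns; an indel inside that 7-mer window would
  defeat it (none are observed in the published form strings).
* Motif numbering is search-order dependent and not comparable across
  datasets or to other tools' numbering.
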