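---
title: "Screening sponge metagenomes for swf-type mono-modular PKS/FAS genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening sponge metagenomes for swf-type mono-modular PKS/FAS genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swfscreen)
```

## The problem

Marine sponges host dense, mostly uncultivable microbial communities, and
several sponge polyketides are believed to be made by these symbionts.
PCR screens of sponge metagenomic DNA with degenerate ketosynthase (KS)
primers are dominated by one ubiquitous PKS family, so rarer clusters are
found by shifting the target: degenerate primers against conserved
*acyltransferase* (AT) motifs recover a wider spectrum of type I PKS
fragments.  Applied to sponge metagenomes, this strategy exposes a family
of mono-modular type I PKS/FAS genes ("swf": an operon of a single-module
KS-AT-DH-ER-KR-ACP synthase, a reductase/sulphotransferase gene and a
radical SAM gene) that standard KS screens miss, because the family's KS
signature motifs deviate from the canonical ones.

`swfscreen` re-implements that discovery pipeline as testable components:

1. reverse translation of conserved protein motifs into minimally
   degenerate primers;
2. in-silico PCR on contigs with IUPAC-aware mismatch counting;
3. signature-motif family classification of translated amplicons;
4. neighbour-joining phylogenetics with bootstrap support, outgroup
   rooting and support-cutoff condensation;
5. proteoform mass spectrometry: isotope patterns and multiply charged
   ESI m/z predictions for the acyl carrier protein (ACP) domain in its
   apo and holo (phosphopantetheinylated) forms.

A seeded synthetic-metagenome generator supplies ground-truth inputs for
every stage, so the whole pipeline is exercised without any external
sequence data.

## Primer design

A protein motif is reverse-translated position by position: each
uppercase residue contributes the position-wise union of its standard
codons written as IUPAC ambiguity letters (`Q` → `CAR`, `W` → `TGG`), and
each lowercase residue is read as a low-confidence position and
contributes fully degenerate `NNN`.  Degeneracy is the product of the
per-position expansion counts and is invariant under reverse
complementation; a reverse primer is the IUPAC-aware reverse complement
of the motif's coding-strand pattern.

Two design points deserve emphasis:

* For amino acids whose codon set factors over the three positions
  (17 of the 20), the pattern covers *exactly* the codon set.  Ser, Leu
  and Arg have split codon boxes, so a single oligo necessarily
  over-covers (Ser → `WSN`, 16 sequences for 6 codons).  This is inherent
  to single-tube degenerate priming, not an approximation we chose; the
  test suite checks exact coverage for product-closed residues and
  superset coverage for the split boxes.
* Codon-usage weighting and inosine bases are not modelled: no
  organism-specific codon statistics are assumed anywhere in the
  package, and uniform synonymous codon choice keeps the synthetic data
  assumption-free.

The two built-in pairs are the broad AT screen (`AT1F`/`AT3R2`, from
`FPGQGsQW` and `QGEIAAA`; the lowercase `s` is fully degenerate) and the
swf-specific pair (`SWF_ATF`/`SWF_ATR`, from `FSGQGTQW` and the swf
signature `QCALVEL`).

## In-silico PCR

Annealing uses subset semantics on IUPAC expansions: a template letter
matches a pattern letter iff its expansion is contained in the pattern
letter's (a concrete base matches iff the pattern covers it; an `N` in
the template counts as a mismatch unless the pattern position is at
least as ambiguous).  A site qualifies if its total mismatch count is
within budget *and* the primer's 3'-terminal clamp is mismatch-free,
mimicking the polymerase's intolerance of 3' mismatches.

Defaults: `maxMismatch = 2`, `clampLen = 3`, product window 50–2000 bp.
Wet-lab annealing stringency is not knowable from a screen's published
description, so these are stated engineering defaults, chosen once so
that both in-scope product classes (about 290 bp for the AT pair, about
220 bp for the swf pair) pass with a wide margin; they are echoed in
every report header.  All forward x reverse pairings in the length
window are reported — a screen favours sensitivity, and multiple clones
per product are the norm — and amplicons are measured 5' end of the
forward site to 5' end of the reverse site inclusive, so a forward motif
and a reverse motif planted 66 codons apart yield `21 + 65*3 + 3 = 219`
bp.  Results are invariant under reverse-complementing the input
contig.

## Family classification

The discriminating motif observations for the swf family:

| motif | canonical | swf state |
|---|---|---|
| KS active site `DPQQR` | intact in cis-AT PKS | second Q replaced by I or V (animal FAS-like) |
| KS condensation `HGTGT` | intact | `HATGT` |
| AT substrate `IAFH` | — | present (malonyl-CoA loading) |
| AT active site `GHS-x-GE` | bulkier fourth residue | unusual Ser recorded verbatim |
| AT signature `QCALVEL` | absent | unique to swf (first/last residue may vary) |
| radical SAM `C-x(3)-C-x(2)-C` | — | cysteine triad of radical SAM enzymes |

`classifyFamily()` applies a fixed rule order: the unique `QCALVEL`
signature (exact, or varied only at its edges) dominates; then both swf
KS variants; then the canonical KS pair without the signature
(cis-AT-like); then the cysteine triad with no KS/AT evidence
(radical-SAM); else unclassified.  The rule order resolves conflicting
evidence in favour of the unique signature, and classification is a pure
function of the evidence map.  The fourth residue of `GHS-x-GE` is
recorded rather than classified, because the set of alternatives in
non-swf sequences is open-ended.  Domain-architecture reporting beyond
the KS/AT anchors (DH/ER/KR/ACP) is out of scope: those domains carry no
usable motif signal at this level of analysis.

Percent identity (the quantity behind identity-range screening claims)
is computed from a Needleman–Wunsch global alignment under identity
scoring (match +1, mismatch 0, gap −1) with the *total number of
alignment columns* as denominator — the stricter, more reproducible
convention; the BLAST-style ungapped-column denominator is available by
argument, and the convention used is part of the return value.  The
optimisation is delegated to `Biostrings::pairwiseAlignment`; the test
suite validates it against an independently written dynamic program that
is itself validated against literal enumeration of all alignments at
tiny lengths.

## Phylogeny

The distance stage is deliberately assumption-minimal: uncorrected
p-distances with pairwise deletion (a Poisson correction is available by
flag), neighbour joining via `ape::nj`, bootstrap bipartition support by
column resampling via `ape::boot.phylo` under an explicit seed.  Taxa
are sorted lexicographically before clustering so ties in the NJ
criterion resolve deterministically; negative NJ branch lengths are
clamped to zero with the total deficit kept as an attribute for audit.
Outgroup rooting places the root at the midpoint of the outgroup's
pendant edge, which preserves all leaf-to-leaf path lengths.
Condensation collapses every internal edge with support *strictly
below* the cutoff into a polytomy (the boundary rule "retain at support
>= cutoff" is stated explicitly so tests are unambiguous); collapsed
edge lengths are discarded, as in a condensed topology display.

Reproducing any published tree topology is out of scope — those input
sequence sets live in external databases — so the tests assert method
properties instead: exact recovery of additive matrices (checked against
a path-length oracle over random trees of up to 8 taxa), the three-taxon
closed form, seeded determinism of supports, and parameter recovery on
alignments simulated down a known tree.

## Proteoform mass spectrometry

Formulas are element-count maps over C/H/N/O/P/S from a pinned
CIAAW/NIST isotope table (version echoed in every report; a published
calculation made with different table versions can differ at the
10^-3 amu level, and pinning makes any such discrepancy attributable).
The isotope pattern of a formula is computed by exact per-element
convolution (binary powering of each element's single-atom
distribution), aggregated into unit-mass (nucleon-count) bins whose
mass is the abundance-weighted mean of their isotopologues.  Peaks
below `pruneThreshold` (default 1e-10, un-normalized) are dropped after
each convolution step, so retained probability stays within a small
multiple of the threshold of 1.  "Most intense peak" selection operates
on these unit-mass bins — matching how resolved isotopic peaks of a
~10 kDa protein are read off a spectrum — and m/z uses proton charge
carriers, `(m + z * 1.007276) / z`.  The ppm sign convention is
`1e6 * (calculated − measured) / calculated`.

The phosphopantetheinylation arithmetic encodes a small puzzle of the
apo/holo mass shift.  The canonical even-electron bookkeeping says the
ACP serine gains phosphopantetheine (dihydrogenophosphate form, nominal
358) minus water: `C11H21N2O6PS`, nominal +340.  The experimentally
established shift, however, is +339, i.e. the odd-electron fragment
`C11H20N2O6PS` — which by the nitrogen rule is a radical.  The
consistent reading is that the holo protein's terminal thiol is
oxidised to a disulfide dimer (2 x monomer − H2, provided as
`disulfideDimer()`), and homolytic S–S cleavage during electrospray
leaves a sulphur radical on each monomer.  Both adduct variants are
first-class (`ppantAdduct(apo, "radical" | "even_electron")`), and the
radical variant reproduces the holo composition exactly.

Raw spectrum processing (mzML parsing, deconvolution) and intensity
modelling of charge-state envelopes are out of scope; an observed peak
list can be matched against the predicted charge ladder by nearest
peak with ppm errors.

## The synthetic metagenome

The generator emulates exactly the structure the screen assumes, with a
single top-level seed driving every random choice:

* **Proteins** (650 aa, uniform background over the 20 amino acids,
  residue 1 fixed to Met): the swf layout plants `DPQIR` at 180 and
  `HATGT` at 320 (inside the first ~420 aa, the KS domain), `IAFH` at
  470, `GHSSGE` at 500, `FSGQGTQW` at 525 and `QCALVEL` at 591–597 —
  66 codons downstream of the forward motif, giving the 219 bp product.
  The cis-AT decoy plants the canonical bundle (`FPGQGSQW` at 100,
  `DPQQR`, `HGTGT`, `IAFH`, `GHSAGE`, `QGEIAAA` at 190; 90 codons →
  291 bp product) inside the broad-AT amplicon window so that the
  translated amplicon carries its classification evidence; a radical-SAM
  decoy plants only the cysteine triad.  Background stretches that
  would create an accidental hit of any diagnostic or primer motif are
  redrawn, so the truth manifest is the only source of motif evidence —
  without this guarantee a ~650 aa random background would produce
  spurious triad hits in roughly one protein in twelve.
* **Contigs**: uniform synonymous back-translation, in-frame TAA stop,
  300 bp random flanks at GC 0.5, genes on either strand.  Primer-site
  codons are adjusted to realise *exactly* the requested number of
  substitutions against the named primer (outside the 3' clamp, so a
  site with k <= budget substitutions stays detectable), and the
  manifest records gene coordinates in the annotation-table convention
  (1-based inclusive, start > end on the reverse strand, stop codon
  inside the span), site coordinates, mismatch counts and expected
  amplicon lengths.  Every manifest is verified against the emitted
  sequence by an independent re-scan before it is returned.
* **Alignments**: i.i.d. sites evolved down a known tree under a
  uniform-exchange 20-state model (redraw uniformly with probability
  `1 − exp(−20 t / 19)` per branch), so expected p-distance is an
  increasing function of path length and saturates at 0.95.  The
  bundled recovery tree is three cherries around a central node
  (internal edges 0.08, pendant 0.15 substitutions/site).

What passing tests on these data do *not* show: real metagenomes have
non-uniform residue composition, codon bias, sequencing error, chimeras
and fragmented genes; motif-bearing false relatives can sit closer to
the family boundary than uniform-background decoys do.  The generator
is a correctness instrument, not a realism instrument.

## Problem sizes and numerical choices

The shipped tests and workflows use desk-scale sizes chosen as the
package's own defaults: twelve single-gene contigs (about 2.5 kb each)
for the end-to-end screen, one hundred generator replicates for the
classification crossover check, one hundred simulated alignments of
2000 columns on six taxa for topology recovery, one hundred bootstrap
replicates for support values, and isotope patterns pruned at 1e-10.
Coordinates are held 1-based inclusive internally (the native R and
Bioconductor convention) with the table convention (start > end =
reverse strand) produced at I/O boundaries; this departs from a
0-based half-open internal design one might choose in other languages,
and was picked so that every index in the code reads in one convention.
ORF calling requires an ATG start and an in-frame stop by default
(alternative starts GTG/TTG are a parameter): annotation-table
arithmetic is start-codon-agnostic, so the conservative default has no
effect on the coordinate checks.

## Known limitations

* Primer thermodynamics (melting temperature, secondary structure,
  multiplex bias) are not modelled; mismatch count plus 3' clamp is the
  whole annealing model.
* The published primer oligo sequences are not recoverable from motif
  descriptions alone; primers here are motif-faithful minimal-degeneracy
  reverse translations, which may differ from the bench oligos in
  terminal truncations or mixed-base subsets.
* Identity percentages depend on the alignment scoring and denominator
  convention; both are reported alongside the numbers.
* The mass module predicts compositions and patterns, not intensities;
  which charge state dominates an ESI spectrum is an observation about
  the instrument and solution conditions, not a prediction made here.
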