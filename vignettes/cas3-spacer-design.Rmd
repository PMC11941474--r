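---
title: "Designing spacers and cloning constructs for compact type I-C CRISPR-Cas3 editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing spacers and cloning constructs for compact type I-C CRISPR-Cas3 editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas3design)
```

## The editing system and the design problem

Compact type I-C CRISPR-Cas3 systems (four genes: *cas3*, *cas5*, *cas8*,
*cas7*) are attractive for genome engineering in high-GC bacteria such as
streptomycetes. The CASCADE complex recognises a T-rich 5'-TTC-3' protospacer
adjacent motif (PAM) immediately 5' of a 34-nt protospacer, and Cas3 then
degrades DNA processively. Two properties drive the computational design
problem this package solves:

* **PAM density.** In a ~72% GC chromosome, the T-rich TTC motif is roughly
  an order of magnitude rarer than the Cas9 5'-NGG-3' motif, which both
  constrains where spacers can sit and reduces the pool of potential
  self-targeting sites. `pam_census()` quantifies this for any genome and
  motif.
* **Seed-dominated recognition.** Target recognition tolerates mismatches
  poorly in the PAM-proximal seed (the first 8 nt of the protospacer).
  A genomic locus is a plausible off-target if it carries the PAM plus a
  perfect seed match, even when the distal protospacer diverges. Off-target
  evaluation therefore runs two searches: the exact full-length 34-mer
  (PAM-independent) and the exact PAM+seed concatenation (an 11-mer for the
  default system).

A spacer is called *specific* when both searches find only the on-target
site. Because the on-target site is itself an occurrence "in the genome",
both counts include it: perfect specificity reads (1, 1), never (0, 0).
`filter_spec()`'s defaults retain exactly these candidates.

## Scanning and counting conventions

Several conventions are genuinely open; the package fixes them as follows
and states them here because any census comparison depends on them:

* Both strands are scanned independently, and overlapping motif occurrences
  are all counted. A palindromic site therefore counts once per strand.
* Mean PAM spacing is genome length (sum of record lengths, not doubled per
  strand) divided by the total two-strand count.
* Motif matching is exact IUPAC-class membership. An ambiguity letter in the
  *motif* (the N of NGG) matches any of A/C/G/T; an ambiguity letter in the
  *genome* matches nothing — an N cannot be claimed as a PAM. Internally
  scans run on a masked copy of each record in which non-ACGT letters are
  replaced by a sentinel that no pattern letter matches.
* No mismatches are ever allowed in the PAM or in the PAM+seed query.
* Coordinates are 0-based half-open internally and in BED output; report
  TSVs add 1-based inclusive twin columns; the command line speaks
  `record:start-end` 1-based inclusive, converted losslessly
  (`parse_region()` / `format_region()`).
* Candidates are not deduplicated across strands: two PAMs yielding the
  same protospacer sequence are distinct candidates with distinct cloning
  consequences.

## Off-target search

`mismatch_scan()` is an exhaustive Hamming search: every window on both
strands of every record within `max_mm` substitutions is reported, with its
mismatch count and a flag for whether a valid PAM flanks it in the correct
geometry. Indel (bulge) off-targets are out of scope. The default radius is
`max_mm = 3` with `require_pam = FALSE` — a conservative screening choice,
since the biologically decisive screens are the two exact searches above;
both parameters are exposed. Matching is delegated to Biostrings; windows
hanging off a record end are discarded, and a genome ambiguity letter counts
as a mismatch. The search universe defaults to every record of the input
FASTA (chromosome plus any plasmids), because self-targeting anywhere in the
host matters.

`rank_spacers()` orders survivors by (seed+PAM count, full-length count,
position, coordinate, strand). The position criterion is exposed as a
preference (`"edge"`, `"middle"`, `"none"`) rather than fixed: editing
outcomes can depend on where the spacer sits relative to the repair
templates, and no single rule is established. Ties break by coordinate and
then strand (`+` before `-`), so the ordering is total and permuting the
input never changes the output.

## Cloning design

Spacer cloning follows a two-PCR Gibson strategy dictated by the plasmid's
architecture: the spacer slot sits between two CRISPR repeats (the second
repeat sequence-modified to prevent recombination between them), and direct
oligo cloning between near-identical repeats is unreliable. The kit
(`cloning_kit()`) records the repeats, two fixed primer annealing sites up-
and downstream of the slot, the platform enzymes (NdeI, HindIII, BstBI,
NcoI, SnaBI), and optionally the full circular backbone.
`design_spacer_primers()` emits:

* two fixed primers (`fixed_fwd`, `fixed_rev`), and
* two spacer-carrying primers whose 3' ends anneal to repeat 1 and repeat 2
  and whose 5' overhangs carry the 34-nt spacer.

PCR A runs from the upstream fixed primer through repeat 1 and gains the
spacer from the overhang; PCR B starts at the spacer, reads through
repeat 2 and the origin region, and ends at the downstream fixed site. The
destination digest (BstBI + NdeI) removes the slot *and* the origin of
replication, so only correctly assembled plasmids replicate. The spacer
strand carried by each primer is fixed by the requirement that assembly
reconstructs repeat1–spacer–repeat2 in the transcribed orientation; this is
enforced by the round-trip property below, not by convention.

`digest_circular()` abstracts digestion as blunt cuts at recognition-site
start offsets — sticky-end chemistry is irrelevant to an overlap-based
assembly check. `simulate_gibson()` joins fragments at unique exact terminal
overlaps of at least `min_overlap` nt (default 20, a standard Gibson
homology length), tries both orientations of each fragment, errors
distinctly on missing or ambiguous overlaps, and reports the circle in a
canonical form (lexicographically minimal rotation) so assemblies can be
compared independent of start position. The package's central correctness
property is the round trip: digest, design primers, assemble — the result
must equal direct string surgery placing the spacer between the repeats.
The suite verifies this for 1000 seeded random spacers.

The shipped kit (`toy_kit()`, `inst/extdata/toy_kit.json`) is a 344-bp
synthetic stand-in with the real geometry; actual plasmid sequences live in
plasmid repositories (e.g. Addgene) rather than in this package, so users
supply their own through `read_kit()` without touching code.

## Repair templates and cargo

`design_repair_template()` takes the deletion interval and extracts two
homology arms of `arm_len` bp (default 1000, the standard flank length for
this editing platform) immediately flanking it. An optional cargo — for
example the 51-bp PhiC31 *attB* attachment site used to substitute a
deleted gene cluster with an integration site — is placed between the arms
in the orientation given; no automatic orientation choice is made because
attachment sites are directional. The fused template is screened for every
kit enzyme recognition site on both strands (the arms are cloned via the
plasmid's MCS, so an internal site is a real cloning hazard; the tool
reports occurrences and never edits them away). The predicted edited locus
satisfies exact length conservation (original − deletion + cargo), and
`predict_edited_locus()` windows the junction to produce a mapping
reference for sequencing-based verification of the edit.

## The synthetic-genome generator

`generate_genome()` draws i.i.d. bases with P(G) = P(C) = gc/2 under a
fixed seed; the default gc = 0.72 emulates a streptomycete chromosome's
composition. `plant_sites()` overwrites chosen offsets with a given
sequence (or its reverse complement), creating exact ground truth for
on-/off-target counting. This order-0 model deliberately omits codon
structure, repeat families, and the homology landscape of real genomes: it
is sufficient to verify counting, extraction and design logic exactly, but
passing these tests says nothing about biological off-target risk in a real
chromosome, where near-repeats make seed matches far more common than the
i.i.d. model predicts. Published-census agreement on the real
*S. coelicolor* chromosome is checked by a separate integration test that
requires a locally available copy of the RefSeq NC_003888 FASTA (see
`tests/testthat/test-acceptance.R`).

## Problem sizes and verification scales

The checks shipped with the package run at desk scale, chosen to exercise
every code path exactly while remaining quick: sliding-window and Hamming
oracle comparisons on 200 random genomes of 0.5–10 kb at GC 0.30/0.50/0.72;
planted-site recovery on 100-kb genomes with 0–5 extra copies; the PAM
density ratio on a 1-Mb synthetic genome (NGG/TTC expected near
(g²)/(t²·g) ≈ 18 at g = 0.36, t = 0.14, asserted within [8, 30]); 1000
cloning round trips; 100 random repair-template designs. The acceptance
script (`scripts/acceptance.R`) recomputes headline quantities at the same
scales from a caller-supplied seed.

## Known limitations

* No cleavage-efficiency or thermodynamic scoring (CFD/MIT-style models,
  RNA secondary structure, primer melting temperature) — candidates are
  ranked purely by specificity counts and position.
* Hamming-only mismatch search; no bulge off-targets.
* Linear-record matching: motif and off-target scans do not wrap the origin
  of circular records (slicing and extraction do support wrap-around).
* The toy kit verifies geometry, not the actual plasmid sequence.
* Biological outcomes — editing efficiencies, random-sized deletions,
  recombination beyond the designed junction — are not predictable from
  sequence and are out of scope.
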