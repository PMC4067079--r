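---
title: "Annotating Helentrons and HINEs: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating Helentrons and HINEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helentronscan)
```

## The elements and the recognition problem

Helitrons are DNA transposons that move by rolling-circle transposition.
The canonical animal Helitron has well-defined termini (5' `TC`, 3'
`CTRR`), a 16–20 nt subterminal palindrome ending about 11 bp from the
3' end, inserts between an A and a T, and creates no target-site
duplication (TSD).  Helentrons are a distinct variant whose
Rep/Helicase protein additionally carries a C-terminal
apurinic/apyrimidinic endonuclease, and whose element structure is
different: short (12–15 bp) *palindromic* subterminal inverted repeats
(subTIRs) 2–4 bp from the 5' terminus and 38–60 bp from the 3'
terminus, plus a 5–10 bp palindrome (stem-loop) 8–35 bp from the 3'
end.  Their non-autonomous deletion derivatives — HINEs, which include
the Drosophila DINE-1 elements — keep the terminal structure but lose
the coding capacity.  Helentrons and HINEs insert into T-rich targets,
preferentially within a TT dinucleotide, carry a variable (2–5 bp) run
of T at each terminus, and also create no TSD.  A proto-Helentron is
the intermediate form: Helentron-type Rep protein, Helitron-type
element structure (5' `TT`, 3' `CTAG`).

This package turns those descriptions into an operational recognition
pipeline: a hairpin/inverted-repeat engine, window-based structural
annotation, family and subfamily classification, paralogous empty-site
validation, target-site analysis, and Rep motif diagnostics — together
with a synthetic-genome generator that plants elements with full ground
truth, so each stage can be validated at desk scale.

## The hairpin engine

`find_palindromes()` reports *maximal* hairpins `(offset, arm, loop)`:
a hit is maximal when the stem can be extended neither outward
(`offset-1, arm+1`) nor inward into the loop (`arm+1, loop-2`) without
violating the arm/loop/mismatch constraints.  All hairpins on one
anti-diagonal share their base pairing, which gives a linear-time scan;
the test suite checks the output against a brute-force enumeration of
every `(offset, arm, loop)` triple.  `N` pairs with nothing, so
assembly gaps cannot seed stems.  A dispersed inverted-repeat pair is
the same object with the loop re-interpreted as a gap, and
`find_inverted_repeat_pairs()` is deliberately implemented that way.

One subtlety matters downstream: under a mismatch budget *k*, a clean
planted stem can be absorbed into a longer, chance-extended stem on the
same diagonal and effectively disappear.  Candidate generation for
genome scans therefore unions the trimmed scans over every budget
`0..k`; the budget-0 pass always retains the clean stem.

## Structure profiles and the genome scan

A `structure_profile()` holds the positional windows as inclusive hard
ranges (the source descriptions say "approximately"; every window can
be widened by `slack`, default 3 bp).  Two calibrations of the
HINE/Helentron profile are shipped:

* `hine_mo_profile("consensus")` — for curated consensus sequences:
  no stem mismatches, subTIR pair identity ≥ 0.90, 3' palindrome
  required.  This is the default.
* `hine_mo_profile("genomic")` — for divergent genomic copies: up to
  2 arm mismatches, pair identity ≥ 0.80, a summed mismatch budget of
  4 for the subTIR pair, and the requirement that a call's subTIR
  recurs in at least two calls genome-wide.  The calibration comes from
  a binomial calculation, not from tuning: at ≤ 5% per-base divergence
  a 12–15 bp subTIR carries ≈ 0.6 expected substitutions, so demanding
  perfection at both ends would lose ≈ 1 − 0.88² ≈ 22% of copies,
  while two tolerated mismatches per stem retain ≈ 98% of them.

`scan_genome()` proceeds: hairpin candidates in the subTIR windows →
pairing within the element length bounds (12× weighted subTIR pair
identity, mismatch budget) → 3' palindrome and joint positional
windows → boundary placement at the terminal TT signal → scoring →
chimera suppression → greedy non-overlapping selection → re-annotation
of each accepted interval with `annotate_element()`.  Both strands are
scanned; minus-strand calls are reported on the forward assembly with
`strand = "-"`.

Scoring design (all decided before the acceptance experiments were
run):

* arm contributions are capped at the profile's design maximum, so a
  chance-extended stem cannot outrank the designed architecture;
* feature-to-window centrality enters as a small penalty and an
  isolated-TT check at both boundaries as a small bonus — these
  disambiguate a genuine call from its near-equal "mirror" read on the
  opposite strand, which palindromic subTIRs make possible;
* copies of one family recur at a consistent length at distinct loci,
  so calls sharing a subTIR (≥ 0.85) *and* a similar span (±10%) at
  disjoint positions receive a support bonus; chimeric pairings of the
  5' subTIR of one copy with the 3' subTIR of its neighbour produce
  mutually overlapping variants and receive none.  A residual chimera
  is dropped when an equal-quality call shares one boundary but is
  ≥ 100 bp shorter.

Boundary convention: the terminal T runs belong to the element (they
are part of the element, though copies vary in their number), and the
host's TT target contributes exactly one T on each side, which the scan
subtracts.  `canonicalize_boundaries()` converts between this inclusive
convention and the exclusive one; a "split" policy is refused because
the attribution is genuinely ambiguous.

## Classification

Families: two elements belong to one family when their subTIRs share at
least an 11 bp identical stretch.  This is operationalised as the
longest common substring over both orientations, because families share
11 of 12–15 bp in practice and subTIRs are palindromic in some families
only.  The ≥ 11 bp relation is not transitive, so the partition is its
single-linkage closure — the weakest reading consistent with the rule,
and the choice is surfaced in the output.  Family numbers are assigned
by decreasing family size (ties by lexicographically smallest subTIR),
which makes the partition invariant under input reordering; the
numbering itself is an artifact convention, since published family
numbers are dataset-historical.

Subfamilies: members share ≥ 80% identity over the last 60 bp of the 3'
end (which covers the 3' subTIR and stem-loop), single-linkage within
each family.  Identity is computed from a global alignment (match +1,
mismatch −1, gap open −2, gap extend −1) with gap columns counting
against identity; whether the published 80% was gap-inclusive is not
recoverable, so both modes exist behind `gap_inclusive` (inclusive, the
conservative reading, is the default).  Letters A, B, … by decreasing
subfamily size, continuing AA, AB, … past 26.

Deletion-derivative linking aligns the candidate's terminal windows
(default 200 bp) locally against the autonomous element; both ends must
reach 84% identity — the low end of the published HINE/Helentron
identity range — over an anchor of at least 50 aligned columns.  The
anchor keeps a spurious short high-identity core from linking; identity
is measured over the aligned span because a short derivative's terminal
window can straddle the deletion junction.

Names follow the published convention: `Helentron-<sp>-<fam><sub>` for
autonomous elements, `HINE-<sp>-<fam><sub>.<variant>` for their
partners, `proto-Helentron-<sp>` for intermediates.

## Rep diagnostics

`locate_rep_motif2()` matches the rolling-circle initiator block
`(V/I)ExQxRG(S/L)(P/L)HxH` as a 12-position pattern.  The residue
between the conserved G and the P/L is the primary diagnostic: S calls
Helentron, L calls Helitron; by construction of the pattern every match
yields one of the two.  The secondary three-residue diagnostic
(F/Y, w/l/y/k, R) is positionally ambiguous in the source material, so
it is disabled unless the user supplies an offset, and it never
overrides the primary call.  Frameshift/stop "correction" is not
automated: when no single ORF carries the motif, translations of
adjacent same-strand ORF pairs are tested and a hit is *flagged* as a
putative corrected ORF rather than silently repaired — automatic
correction would invent sequence.

## Empty sites and target sites

Element boundaries are validated the way the field does it: a chimeric
query of 50 bp upstream + 50 bp downstream is searched against the
genome; a hit with ≥ 90% identity over ≥ 90% of the query at another
locus is a paralogous empty (pre-insertion) site.  The implementation
is seed-and-extend (exact 8-mers — by the pigeonhole bound any
qualifying hit of a 100-bp query contains an exact 9-mer — clustered
and re-aligned locally); the test suite compares its hit set against a
full Waterman–Eggert dynamic-programming enumeration over the entire
genome.  Identity counts gap columns as errors; coverage is the aligned
query span over the query length.

`analyze_target_site()` reports the contiguous T runs immediately
inside the element boundaries, whether the reconstructed pre-insertion
site carries a TT spanning the junction, the Helitron-style A|T
junction, and the TSD scan (identical flanking k-mers, k = 2–20).  A
TSD candidate found by the naive flank scan is validated against the
empty site whenever one is available: the candidate is accepted only if
deleting one copy reconstructs the pre-insertion locus *better* than
the plain flank concatenation does.  This matters because short
flanking repeats arise by chance (a 2-mer coincidence alone has
probability 1/16 per site); repeats that pre-date the insertion are
thereby rejected, which is exactly how absence of target-site
modification is established from empty sites.  Without an empty site
the naive candidate is reported with `tsd_validated = FALSE`.  One
arithmetic consequence worth knowing: a genuine k-bp TSD caps the
chimeric-query identity at the empty site to 100/(100+k), so
validating long TSDs requires relaxing the empty-site identity
threshold by the expected TSD length (the rolling-circle defaults of
0.90/0.90 assume a TSD-free insertion).

## The synthetic genome: what it emulates, and what it does not

`make_element()` assembles 5' pad + palindromic subTIR + body
(optional microsatellite, optional embedded Rep ORF containing a
`VELQARGSPHIH` motif instantiation) + subTIR copy + spacer + 3'
stem-loop + 3' pad, honouring the printed windows.
`plant_insertions()` inserts copies at TT targets (AA on the forward
strand for minus-strand copies; A|T junctions for Helitron kinds),
appends 2–5 terminal Ts per end, optionally duplicates the
pre-insertion locus to create a paralogous empty site, and mutates each
copy at a rate drawn uniformly from `[0, divergence]` — an
insertions-accumulate-over-time model with a default ceiling of 5%,
matching the > 95% copy/partner identities seen in recently active
families.  Every copy consumes its own derived RNG stream, so adding
copies never perturbs earlier ones, and the recorded truth (feature
coordinates, T runs) is re-measured on the emitted sequence.

Three deliberate idealisations keep the ground truth *decidable*, and
define what a green test does and does not establish:

* terminal pads avoid T, and the 3' spacer/pad are drawn from {A, C}
  (which can host neither T runs nor hairpins), so the planted features
  are the unique in-window optima and boundary placement has a
  well-defined answer;
* insertion targets are *isolated* TT dinucleotides (neighbouring bases
  non-T), so the host contributes exactly one T per side and the
  planted T runs are exactly recoverable;
* sites whose pre-existing flanking repeats would mimic a TSD are
  rejected (about 2% of candidate sites), so "no TSD" is true by
  construction and testable.

Real elements offer none of these guarantees: the boundary T count is
genuinely ambiguous against a T-rich host (the tool reports both runs
and never asserts symmetry), decoy hairpins occur, and empty-site
validation — not structure alone — is what settles boundaries.  A green
recovery test therefore establishes that the machinery is correct on
unambiguous architectures, not that real-genome curation is automatic.
Nesting of elements and indel divergence are off by default (indels at
0.1× the substitution rate behind a flag); tandem-array cluster
structure and gene-fragment capture are not simulated.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally everywhere; GFF3 (1-based
  inclusive) conversion happens only at serialization.
* `is_self_palindromic()` is strictly even-length; odd-length
  "palindromes" are loop-1 hairpins.
* Alignment scoring is match +1, mismatch −1, gap open −2, gap extend
  −1 throughout (a gap of length *k* costs 2 + *k*).
* Feature ties break by longer arm, fewer mismatches, smaller offset;
  the subTIR pair in re-annotation is chosen jointly (cross-end
  agreement outranks individual stem length).
* Sequences shorter than the minimum element length (default 150 bp)
  are `unclassified` with reason "too short"; element length bounds
  (150 bp – 20 kb) are package defaults, as no published bounds exist.
* Whether the two subTIRs of one element must be near-identical copies
  of one another is unstated in the literature; the default requires
  ≥ 0.90 identity on consensus sequences (0.80 for genomic copies) and
  the threshold is exposed.

## Known limitations

* With palindromic subTIRs, a minus-strand element admits a shifted
  "mirror" interpretation on the plus strand whose architectural score
  is nearly equal; centrality, target-isolation and support terms
  resolve almost all of these, but occasional strand flips remain
  (about 1–2% of copies in simulation).
* The divergence-tolerant genomic preset trades precision for recall;
  on random sequence it emits candidate calls that only copy-number
  support and downstream empty-site validation can remove, which
  mirrors how the original analyses also relied on copy alignment and
  manual curation.  The strict consensus preset keeps the false-call
  rate at or below about one per megabase.
* Family numbering is stable and size-ranked but not comparable to
  published dataset-historical numbers.
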