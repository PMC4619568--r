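---
title: "Methods: profiling anti-hapten scFv repertoires with panrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling anti-hapten scFv repertoires with panrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrep)
```

## Scope and model

`panrep` analyses repertoires of sheep scFv variable domains sampled before
and after phage-display panning against hapten antigens. The analysis rests
on three classical models of antibody structure:

1. **Kabat numbering** gives homologous positions the same code across
   antibodies, with insertion letters (e.g. `95A`) absorbing loop-length
   variation at designated anchors, so that per-position statistics are
   comparable across clones of different CDR lengths.
2. **Canonical structures**: apart from CDR H3, the hypervariable loops
   adopt a small set of main-chain conformations predicted by loop length
   plus a few key residues. We implement strict SDR template matching over
   Chothia-style loop windows.
3. **Conservative substitution**: residues within a biophysical group are
   treated as interchangeable when judging whether selection has preserved a
   site.

## Kabat numbering by profile alignment

Each chain is globally aligned (Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10 / extend 1) against an
embedded reference profile: a synthetic consensus-like VH (116 residues,
including the standard 82A–82C positions) or Vλ (109 residues), shipped as
plain-text, user-replaceable data files mapping each reference residue to its
Kabat code. Matched residues inherit the reference code. The gap penalties
are conventional protein-alignment values; they only influence pathological
inputs, since variable domains differ from the reference mostly by loop
length.

Length variation is then renumbered deterministically per variable-loop
window (heavy 31–35, 50–65, 95–102 with anchors 35, 52, 100; lambda 24–34,
89–97 with anchors 27, 95): a window holding `k` residues gets its base codes
up to the anchor, then insertion letters `A, B, …` at the anchor, then the
remaining base codes; when `k` is short of the window, codes are deleted
walking backwards from the anchor (so a six-residue H3 reads
95-96-97-98-101-102). This makes numbering a pure function of the window
occupancy — identical inputs always produce identical codes, and insertions
are effectively placed leftmost at the anchor. Insertions attached to
framework positions are only legal at the scheme's framework anchors (heavy
82, lambda 106), where they extend the letter run (82C → 82D); anywhere else
numbering aborts with an error naming the offending position. An alignment
score below `score_floor` (default 50; an unrelated protein scores near or
below zero against either profile, a true domain several hundred) rejects
the input as not a variable domain. `validate_numbering()` re-checks strict
code ordering, anchor-only insertions and exact reconstruction of the input
from the numbered residues.

The numbering is validated in two independent ways: a reconstruction
property (the numbered residues re-concatenate to the input for every chain
of the synthetic corpus) and an oracle test, in which sequences edited
inside a single loop are numbered by exact framework-flank matching plus
direct enumeration of the Kabat insertion/deletion rules, with no alignment
involved, and the codes must agree exactly for edits up to six inserted
residues.

## Regions and CDR lengths

Kabat boundaries are hard-coded but exposed (`kabat_region_boundaries()`)
for audit: heavy CDR1 31–35, CDR2 50–65, CDR3 95–102; lambda CDR1 24–34,
CDR2 50–56, CDR3 89–97. Insertion-lettered codes belong to the region of
their base number (35B is CDR1). This boundary table is the one under which
the invariant lengths the analysis expects (H1 = 5, H2 = 16, L2 = 7 for
unindelled chains) all hold, which is the internal consistency check. A CDR
length is the count of residues actually present — absent codes never count.

## Canonical classification

Templates are declarative YAML records (chain, loop, class, window, length,
key residues with allowed sets), so the rule base is auditable and
replaceable; `load_templates()` validates uniqueness and per-loop window
agreement. The canonical loop windows are Chothia-style and deliberately
distinct from the Kabat CDR boundaries: H1 spans Kabat 26–35, so its class 1
is a 10-residue loop even though Kabat CDR H1 has 5 residues, and H2 spans
50–58 (class 1 = 9 residues) inside the 16-residue Kabat CDR H2. This is the
only reading under which the invariant Kabat lengths and the stated class
lengths coexist.

Assignment is strict: measure the loop length over the window; no template
of that length ⇒ `X` (no canonical class of that length is known);
otherwise the unique fully-matching template's class, with one violated key
residue disqualifying a template; all candidates violated ⇒ `unmatched`,
reported separately from `X` by default because the two are different
epistemic states (unknown loop length vs. known length, failed keys). The
`collapse_unmatched` flag folds `unmatched` into `X` for outputs that
conflate the two. Two fully-matched length-compatible templates raise an
"ambiguous template set" error rather than picking silently.

Design choice: published strict-SDR compilations do not fix every
class/length pair this analysis needs, and no key-residue sets are printed
in the sources the templates emulate. The built-in set therefore anchors the
stated pairs (H1 class 1 → 10, H2 class 1 → 9, L1 class 6 → 14, L2 class 1 →
7) and assigns the remaining classes to adjacent lengths by cross-referencing
observed post-selection loop lengths with their class labels (L3 class 4 → 9,
class 5 → 11, with length 10 deliberately left template-free so it classifies
as `X`; L1 classes 2/3/5 → 11/12/13). Key-residue sets are curated,
synthetic-but-plausible data marked configurable — replacing the YAML file
changes the rule base without touching code.

## Variability, consensus, and conserved sites

Per-position variability is frequency-based, `100 × (1 − modal
count/coverage)`, not entropy-based, because the thresholds it is compared
against ("<10 %", ">50 %") are modal-frequency statements. The five bins are
`[0,10) [10,25) [25,50) [50,75) [75,100]`: the bin count and the 10 %/50 %
edges are fixed by the analysis design; the intermediate edges 25 and 75 are
a documented, configurable choice. Positions covered by fewer than
`coverage_floor = 5` chains are flagged insufficient rather than binned,
since percentages from fewer observations are noise. Consensus is the modal
residue with an alphabetical tie-break (deterministic, documented).

A position is *conserved* in a clone set when (i) every chain in the set
carries a residue there — a site cannot be "unchanged" where it does not
exist, so positions lost to shorter loops are never conserved — and (ii)
each residue equals the pre-selection consensus residue or shares its
seven-group biophysical class. The seven groups (aliphatic AVLI, aromatic
FWY, polar-neutral STNQ, acidic DE, basic KRH, sulfur CM, conformational GP)
are shipped as data: the grouping cardinality is fixed by the analysis
design, the membership is a standard biophysical partition of that
cardinality and fully configurable. An alternative reading of "conserved
relative to the original pre-selection residues" — similarity to *any*
residue observed pre-selection rather than to the consensus — is available
as `mode = "any"`; the consensus reading is the default because it is the
stricter and better-determined rule. `conservation_report()` always emits
self-consistent tables: every total equals the sum of the per-region
position lists it prints (reports of this design have been published with
internally inconsistent arithmetic; this implementation refuses to
reproduce that).

This rule set implies two tested invariants: the conserved set is
antitone in the test set (adding a clone can only remove positions), and a
zero-variability position whose shared residue equals the reference
consensus is always conserved.

## Selection statistics

Frequency tables (CDR lengths, canonical combinations) store exact counts
and unrounded percentages, sorted by descending count with ties broken by
category; rendering to TSV formats percentages with one decimal place, and
comparisons always use unrounded values. `dedupe = TRUE` collapses identical
amino-acid sequences first — the convention for post-selection panels where
one binder is isolated repeatedly. The chi-square goodness-of-fit test uses
a uniform null over the *observed* categories (k = categories with count >
0), matching the question "is class representation equal within this
library"; zero-count classes are not invented, and no multiple-testing
correction is applied across libraries. Enrichment tables report the
fold-change of category percentages (post/pre) with categories absent
pre-selection flagged `novel` and their fold-change undefined rather than
infinite.

## The synthetic repertoire generator

No sequence data of this design is publicly deposited, so the generator is a
first-class, tested module rather than a fixture. It emulates, per library:

- a **canonical-combination mixture** per chain (defaults mirror the
  dominant published pre-selection combinations, e.g. lambda `6-1-X` near
  50 %); printed frequency columns that list only the most prevalent
  categories do not sum to 100, so mixture values are treated as weights and
  normalized;
- **CDR-H3 Kabat lengths** drawn from their own distribution, and the L3
  length of `X` combinations from a separate distribution over
  non-template lengths (default mass on length 10). Lengths of the five
  canonical loops are induced by the class labels — generating them from an
  independent length distribution would contradict the mixture;
- **per-site substitution** at region rates (FW 0.01, CDR 0.15 per site),
  uniform over the 19 alternatives, except that canonical key residues
  mutate only within their allowed sets, so planted class labels survive
  mutation and mixture-recovery tests can be exact per clone;
- **selection**: founders sampled from the pre-selection pool with weight
  `2^(−substitutions)` (scaffold-faithful bias), paired heavy+lambda,
  replicated per copy number without further mutation, and **planted
  conserved positions** overwritten in every founder with the
  pre-selection consensus residue (mode `identical`) or a random member of
  its biophysical group (mode `group`, which exercises the
  similarity branch of the conservation rule).

Pre-selection heavy and lambda chains are generated unpaired (their counts
differ per library in the emulated design); post-selection clones are
paired scFv constructs joined by the `EGKSSGASGESKVDD` linker. Everything is
a pure function of the config seed, down to emitted FASTA bytes.

What the generator does **not** emulate: nucleotide-level V(D)J
recombination and junctional diversity, gene-conversion tracts, phage
amplification/expressibility bias, affinity maturation dynamics, and real
sheep germline segment usage (scaffolds are synthetic consensus-like
sequences, not database germlines — users can substitute real ones via the
reference-profile and template files). Passing recovery tests therefore
demonstrates that the pipeline measures what the generator planted under a
realistic statistical shape; it does not certify behaviour on real
repertoires with, e.g., allelic variation or sequencing error.

## Numerical and degenerate-input conventions

- Alignment: BLOSUM62, gap open 10 / extend 1, score floor 50; all
  configurable.
- Tie-breaks: leftmost best window for fuzzy linker location (threshold
  80 % identity over the 15-residue window, tolerating somatic/PCR
  variation without spurious splits); alphabetical modal residue; leftmost
  insertion placement at anchors.
- Degenerate inputs: empty clone sets, empty regions, zero-size post panels
  and empty report tables warn or error explicitly rather than emitting
  silent zeros; numbering failures in a pipeline run are tallied and the
  run aborts above a 20 % failure rate.
- `X` residues in sequences are accepted by the data model, scored by
  BLOSUM62's X column during alignment, and are "ungroupable" (`NA`) under
  the biophysical scheme, so they never support a conservation call.

## Problem sizes

The shipped test suite validates on a 25+20-chain library with an 8+7
planted conserved-position design, mixture/length recovery at n = 500 per
chain (3 % absolute tolerance), and one full three-library emulation
(588 pre-selection chains, 23 founders); these sizes were chosen to give
exact planted-truth recovery and comfortable binomial margins while keeping
the suite fast on a single CPU.
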