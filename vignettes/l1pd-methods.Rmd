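---
title: "Detecting full-length LINE-1 elements by seed-and-pattern-match"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting full-length LINE-1 elements by seed-and-pattern-match}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(L1PD)
```

## The problem and the model

Long Interspersed Element-1 (LINE-1, L1) is the only active autonomous
retrotransposon in the human genome. A full-length element is roughly 6 kb
and consists of a 5'UTR, two open reading frames (ORF1 and ORF2) separated
by a short inter-ORF spacer, and a 3'UTR. Only full-length, intact copies
are plausible retrotransposition sources, so this package targets them
exclusively; the vast majority of genomic L1 copies are 5'-truncated and
are deliberately *not* called.

Classical annotation tools rely on seed-and-extend alignment, whose
extension heuristics behave poorly on highly repetitive, diverged element
families. L1PD instead uses *seed-and-pattern-match*:

1. **Probes.** A fixed set of k-mers (k ∈ {50, 75, 100}) is drawn from
   highly conserved columns of a multiple sequence alignment of known
   intact L1 ORF sequences. Each probe carries its offset from the start of
   the ORF1 region, so the probe set doubles as a template of the expected
   element layout.
2. **Seeding.** Every probe is mapped against the target genome under a
   maximum Levenshtein distance *e*, on both strands.
3. **Pattern matching.** A locus is called an L1 when at least *m* probes
   hit in probe order, and each consecutive pair of matched probes is
   spaced within *t* bp of the gap implied by their offsets:
   |(pos_j − pos_i) − (offset_j − offset_i)| ≤ t.
4. **Boundary extrapolation.** Start/end coordinates of a call are
   extrapolated from the anchoring (most 5') matched probe using the
   *modes* of the component lengths observed in the annotation metadata,
   then written as GFF3.

The three knobs *e* (edit distance), *t* (distance threshold) and *m*
(minimum probes per pattern) trade precision against recall. The shipped
human defaults — 15/625/18 for 50-mers, 30/625/17 for 75-mers, 30/600/9 for
100-mers (`default_params()`) — are the combinations that maximised F1 in
large parameter sweeps over the human reference genome. Other species need
their own sweeps (`sweep_params()`); suitable values vary considerably
between genomes.

## Probe generation

`generate_probes()` reproduces the probe pipeline from pre-aligned per-ORF
FASTA input (the package does not run an MSA program; any aligner's output
works, and the simulator emits true alignments directly):

* **Consensus.** For each alignment column, the most frequent non-gap base
  is the consensus base; the column *qualifies* when that base's frequency
  over all rows (gaps count in the denominator) reaches the identity
  threshold (default 0.95). All-gap columns are dropped from the consensus
  coordinate space. Applying the identity filter before k-mer extraction
  keeps the pre-candidate count manageable at large k.
* **Candidates.** Every window of k consecutive qualifying positions is a
  candidate, at stride 1 — the later non-overlap step handles packing, and
  stride 1 keeps the hit-count ordering meaningful.
* **Refinement.** Candidates are mapped genome-wide at a small edit
  distance `e_map` (default 2) and filtered in four steps: (1) discard
  candidates with no hit inside the source ORF of at least one annotated
  element; (2) discard candidates lacking a hit inside the corresponding
  ORF interval of *every* annotated element ("universal" probes); (3) sort
  survivors by total genome-wide hit count ascending — fewer hits mean
  fewer false-positive seeds — with offset as the deterministic tie-break;
  (4) greedily accept non-overlapping candidates in that order.
  "Maps to an ORF" is interpreted genomically: the hit window must fall
  inside the annotated ORF interval (padded by `e_map`) of the element on
  the element's strand. An empty survivor set raises an explicit
  "no universal probes" error suggesting a lower identity or smaller k;
  automatic search over k is out of scope.
* **Assembly.** ORF1 probes keep their offsets; ORF2 offsets are shifted by
  the modal ORF1-start→ORF2-start distance so that the merged set lives on
  one ORF1-anchored axis. The merge re-validates non-overlap. The original
  pipeline performed this combination step manually; the modal shift is
  this package's own definition of that step.

## The matcher

The built-in mapper (`find_matches()`, `map_probeset()`) replaces the
external short-read aligner of the original pipeline. It computes, for
every text position, the best semi-global edit distance of the probe
against any window ending there — a Myers bit-vector scan for k ≤ 64 and a
plain dynamic-programming column scan for longer probes. Co-optimal
overlapping alignments at a single diverged locus are collapsed to one hit
per locus: qualifying end positions within `e` of each other form a
cluster reporting its minimum distance, ties resolved by leftmost
alignment start, then leftmost end. Without this rule a diverged locus
yields a smear of near-duplicate hits that corrupts probe counting. `N`
never matches a probe base, so assembly gaps cannot seed spurious hits.

Minus-strand hits are found by scanning the reverse complement of each
chromosome and mapping positions back to forward coordinates. This choice
(rather than scanning the reverse-complemented probe against the forward
text) matters: the collapse rule is directional, and only the
reverse-complement scan makes detection *exactly* mirror-symmetric —
`detect_l1()` on a genome and on its reverse complement produce
coordinate-mirrored identical call sets, a property the test suite asserts.

Correctness of the matcher is defined by equivalence with a brute-force
oracle (an `adist()` sweep over every window) on seeded random instances,
not by the scanning technique.

## Chaining and calling

The distance predicate applies between **consecutive matched probes**, not
between every probe and the pattern anchor: an insertion early in an
element shifts all downstream hits by the same amount, and consecutive
gaps absorb that drift while anchor-relative gaps would accumulate it.
Anchor-relative measurement is still available via
`detection_params(gap_mode = "anchor")` for comparison.

`chain_hits()` selects, per chromosome and strand, the best remaining chain
under the priority (most probes, smallest summed gap deviation, leftmost,
lexicographic), consumes its hits, and repeats until no chain of ≥ m hits
remains. The implementation is a dynamic program, but the *contract* is
agreement with an exhaustive chain-enumeration oracle on small instances,
which the tests check on hundreds of seeded cases. Probes may be skipped
within a chain, so a deleted or diverged probe site does not break an
otherwise consistent pattern.

Patterns whose projected intervals overlap a better pattern's interval by
more than half of the shorter are suppressed (`dedupe_patterns()`;
retention priority: more probes, smaller gap error, leftmost) — very
permissive settings can otherwise match one locus twice.

Boundaries are extrapolated from the anchor probe hit: on the plus strand
`start = h − offset − mode(5'UTR length)` and
`end = start + mode(total length) − 1`, mirrored on the minus strand and
clamped to the chromosome. Component-length modes come from the metadata
(`length_modes()`), with ties broken toward the smaller value for
determinism, and the total-length mode computed independently rather than
as the sum of component modes.

## Coordinates, formats and numerical conventions

Internally every coordinate is 0-based half-open; conversion to 1-based
inclusive happens in exactly one place, at the GFF3/CSV/SAM boundary, to
prevent off-by-one drift. GFF3 output fills seven of the nine columns:
source `L1PD`, type `mobile_genetic_element`, start/end, strand, and
attribute `Name=LINE1` (GFF3 tag=value syntax forbids padding around `=`).
The metadata CSV schema (`chrom, l1_start, l1_end, strand` plus 1-based
element-relative start/end for 5'UTR, ORF1, ORF2 and 3'UTR) is this
package's documented emulation of per-element L1 database downloads — the
exact upstream column layout is not public, so sample files ship under
`inst/extdata/` (synthetic, produced by the simulator). Rows with any empty
required field are skipped and counted, not fatal. SAM import takes every
reported alignment (including secondary), reads `NM` as the edit distance
(missing `NM` → 0 with a warning), and derives the reference span from the
CIGAR.

Precision/recall matching (`match_calls()`) is greedy one-to-one in
ascending call order: a call matches an unmatched truth element when their
overlap reaches `min_overlap` (default 0.5) of the truth length and strands
agree. This criterion is the package's own definition — the published
experiments do not state their matching rule — and both the fraction and
strand enforcement are exposed (`--overlap`, `--ignore-strand`). Undefined
ratios (zero denominators) are reported as 0 so sweeps stay total at
extreme parameters.

## The simulator and what passing tests mean

`simulate_l1_genome()` builds the fixtures every other module is tested
against: one random ancestral element with human-like component lengths
(900 / 1017 / 63 / 3825 / 206 bp ≈ 6 kb), `n_intact = 30` diverged copies
planted non-overlapping on both strands of a 400 kb i.i.d. background
(GC 0.42), per-copy substitution rate 1% and indel rate 2×10⁻⁴ with
geometric (mean 2) lengths, plus 5 negatives truncated at the 5' end by a
uniform 60–90% of their length — enough to remove the 5'UTR and at least
part of ORF1, mirroring the dominant truncation mode of real L1 biology.
Substitution positions are sampled without replacement together with indel
positions, and a deletion is clipped before the next sampled mutation so
the recorded history stays exactly recoverable from the emitted alignment;
`mutation_audit()` recomputes the counts from the alignment and the tests
require them to equal the log. Truncated copies appear in the genome and
the truth GFF3 (flagged) but not in the intact-element CSV used as
detection truth.

Detection on these fixtures uses e = 5, t = 50 and
m = ⌈0.6 × n_probes⌉, scaled from the published defaults to the fixture's
divergence: at 1% substitution a 50-mer carries ~0.5 expected edits
(e = 5 leaves ample slack), total indel drift across 6 kb is ~6 bp
(t = 50 likewise), and the published m defaults span 53–77% of their probe
sets, with 60% placing truncated copies — which retain well under 60% of
the probe offsets — safely below the pattern threshold. Smaller test
fixtures (12 copies) lower the consensus identity to 0.90 because a
12-row alignment cannot reach 0.95 with a single discordant row.

What the simulator does *not* emulate: subfamily phylogenies (all copies
are independent draws from one ancestor), target-site duplications,
poly-A tails, nested insertions, and non-uniform background composition.
Passing the recovery tests therefore demonstrates the machinery —
probe design, approximate matching, chaining, extrapolation — under
controlled divergence, not performance on a real reference genome, which
requires genuine genome and annotation downloads and is out of scope here.

## Reproducibility and problem sizes

Every stochastic step runs under an explicit seed (`withr::with_seed`), and
two runs with equal seeds produce byte-identical outputs, asserted
file-by-file in the tests. The validation suite uses problem sizes chosen
to keep a full run in minutes on one CPU: oracle equivalence on 100 mapper
instances (genomes ≤ 20 kb, e ≤ 5) and 200 chaining instances (≤ 12 hits),
and recovery on ten seeded 400 kb fixtures of 30 intact + 5 truncated
copies each.

## Known limitations

* Probe generation requires pre-aligned ORF input and enough alignment
  rows for the identity threshold to be meaningful (with n rows the
  per-column bar is effectively ⌈identity·n⌉ agreeing rows).
* Whether a candidate "maps to every element" is judged inside annotated
  ORF intervals; elements missing from the metadata can therefore veto
  nothing, and mis-annotated intervals bias refinement.
* The chain selector is optimal per round but rounds are greedy: a
  globally different partition of hits into patterns is conceivable at
  pathological densities.
* Calls carry only probe count and gap error as quality signals — no
  subfamily classification, no truncated-element calling, no mapping
  qualities.
* At very large e or t, distinct patterns can project onto one locus;
  duplicate suppression bounds, but does not eliminate, the effect of
  over-permissive parameters.
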