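---
title: "Topology-aware ER retention motif and LPT triad scanning"
author: "fitmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware ER retention motif and LPT triad scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitmscan)
```

# Scope and model

`fitmscan` analyses the primary structure of polytopic ER membrane
proteins of the FITM family and their LPT (lipid
phosphatase/phosphotransferase, PAP2-superfamily) relatives. Everything
rests on two observations about these proteins:

* their *residency* in the ER is encoded by short cytoplasmic retrieval
  signals — C-terminal lysine-based motifs and di-arginine motifs — whose
  counts, mapped onto the membrane topology, predict localization;
* their *catalytic anatomy* is encoded by the conserved luminal blocks C1,
  C2 and C3 that house the LPT triad (H-1, H-2 and a third acidic
  residue), with FITM-specific deviations: no C1, a `[K]xNØØN` motif in
  luminal loop 1/2, glutamate instead of aspartate as the third triad
  residue, and a disulphide-capable cysteine pair in the long luminal
  loop 3/4.

The package scans for all of these motif classes, assembles and
classifies the triad, predicts ER residency, and aggregates statistics
over protein families. All coordinates in reports are 1-based inclusive
spans, matching the residue-numbering style used for point mutants
(H178, E243, E354).

# Motif scanning conventions

## Di-arginine motifs

A di-arginine motif is a pair of arginines at separation 1 (`RR`), 2
(`RxR`) or 3 (`RxxR`); the wildcard position may hold any residue,
including another arginine. How overlapping arginine clusters should be
counted is genuinely underdetermined — `RRRR` contains six qualifying
pairs — so both conventions are implemented:

* **greedy** (default): scan left to right, pair each unconsumed R with
  its nearest downstream R at distance ≤ 3, consume both. Each arginine
  contributes to at most one motif, so a cluster is not inflated into
  many motifs (`RRRR` counts 2).
* **all_pairs**: report every qualifying pair (`RRRR` counts 6).

Greedy is the per-protein default because a retrieval signal is a local
feature: consuming both arginines reflects one COP-I binding epitope per
cluster. The all-pairs mode matches the high-throughput family counting
style, and the report records which convention produced each number.

## C-terminal retrieval signals

Only the last five residues of the chain are examined, against (in
priority order) `KKxx`, `KxKxx`, `RKxx`, `RxKxx`, `KxRxx`, `HxHxx`,
`KxHxx`, anchored at the stop: e.g. `KKxx` requires lysines at positions
−4 and −3. At most one motif is reported (the family statistics need
only presence/absence, and the canonical di-lysine signal outranks its
variants). Sequences shorter than a pattern skip that pattern. The ER
residency classifier treats all seven classes as equivalent
"C-terminal di-lysine" evidence, because family counts group them
together.

## Catalytic-site motifs

* **C1** `K-x6-RP` (9 residues) — present in LPTs, absent from FITMs.
* **C2** `[ST]-m-H` with middle class `m ∈ {G, S, D, T, L}` — canonical
  `SGH`; the middle residue is S in FITM1, D in SAR/algal sequences, and
  T/L occur in active phosphatases of other subfamilies. The hit's
  histidine is the candidate H-1.
* **C3** `H-x-x-x-t` with third class `t ∈ {D, E, Q, H}` — D in canonical
  LPTs, typically E in FITMs, occasionally Q or H. The histidine is the
  candidate H-2, the fifth residue the third triad residue.
* **KxN** `x-x-N-Ø-Ø-N` with Ø = {F, I, L, V}; the first residue is
  predominantly, but not necessarily, K (recorded as `has_K`).
* **Cysteine pair**: any region holding ≥ 2 cysteines yields one hit
  spanning the first and last, intended for luminal loop 3/4.

All residue classes are YAML-configurable. When a topology is available
these scanners are restricted to luminal loops by default
(`luminal_restrict`), because the LPT catalytic centre always faces the
lumen; without topology the whole sequence is scanned.

## Ambiguity codes

X/U/B/Z are tolerated on input but never satisfy a motif position:
literal positions compare exactly and class positions are explicit sets
of standard residues. Only the pure wildcard `x` matches them. This is
deliberately conservative — an ambiguous residue is never promoted into a
motif call.

# Topology

## Representation

A topology is a per-residue string over `i` (cytoplasmic), `M`
(membrane), `o` (luminal). TMDs are maximal `M` runs; the two loops
flanking a TMD must lie on opposite sides. Loops are labelled `N-term`,
`1/2`, …, `C-term`, where `k/(k+1)` is the segment between TMD k and
TMD k+1; loops and TMDs partition the sequence, and zero-length loops
(adjacent TMDs, only constructible programmatically) are reported with
an empty span. Motif hits are assigned to the loop containing their
entire span; a hit straddling a TMD boundary gets no side and is
excluded from side-filtered counts — topology-aware motif counting
should not credit a motif that is partly buried in the membrane.

## Supplied annotations

Consensus-predictor output is accepted in two dialects: a minimal
`id<TAB>statestring` table, and TOPCONS-style blocks in which framing
lines are skipped, ids come from `Sequence name:`/`>` lines, and lines
consisting solely of state characters are concatenated. Uppercase
`I`/`O` (reentrant states in some outputs) are normalised to `i`/`o`. A
supplied topology always overrides prediction, so externally computed
consensus topologies reproduce their motif counts exactly. State-line
detection requires at least one lowercase side state, so an amino-acid
line consisting only of I/M/O residues is not misread; a protein whose
topology line is all-`M` is rejected anyway (no loop states).

## Prediction

When no annotation is supplied, a deterministic single-sequence
predictor stands in for consensus methods (which cannot be embedded):

* sliding-window Kyte–Doolittle hydropathy, window 19, candidate
  threshold 1.6 (mean per window);
* candidate runs merged across gaps ≤ 3 residues; runs shorter than 15
  discarded; surviving runs normalised into the 17–25-residue range.
  A candidate segment long enough to hold two helices (> 25 and ≥ 36
  residues) is split at its least-hydrophobic interior position — two
  planted TMDs around a loop of ~10 residues otherwise fuse into one
  above-threshold run — and each piece is shaved back, from its less
  hydrophobic end, to a typical 21-residue helix;
* orientation by the positive-inside rule: of the two alternating side
  assignments, the one placing more K/R within 15 residues of a TMD end
  in cytoplasmic loops wins (whole-loop counting is a config option);
  ties put the N-terminus in the cytoplasm, which is also the call for a
  0-TMD chain.

Window, threshold, minimum TMD length, merge gap and flank window are
exposed in the YAML config. The predictor is intentionally simple: it is
deterministic, auditable, and recovers planted hydrophobic helices
exactly, but it does not model signal peptides, reentrant helices or
marginal amphipathic TMDs, and no attempt is made to reproduce a
particular consensus predictor's TMD count for any specific real
protein (FITM1's predicted extra N-terminal TMD being a known example of
predictor-dependent output).

# Triad assembly and classification

`find_triad()` pairs a C2 hit with a C3 hit. With a topology, C2 must
lie in a luminal loop and C3 in a *later* luminal loop, mirroring the
LPT arrangement (C2 closes loop 3/4, C3 sits in loop 5/6); without
topology, any pair with C3 downstream of C2 is eligible. Among eligible
pairs the one maximising the extended C3 context score wins, ties
breaking to the smallest H-2 position — conservation context, not mere
adjacency, is what identifies the genuine triad among spurious
pattern matches. (The context criterion supersedes a simple
smallest-separation rule by design; with a single C2 and C3 both give
the same answer.) If either motif is missing, or no eligible pair
exists, the assignment is `incomplete`, with any single motifs still
reported for inspection.

The extended FITM C3 context is the 14-position consensus
`TAØYF-H-TØØ-E-KØØG` spanning H-2 −5…+8. The context score counts
matched positions (Ø matches F/I/L/V; all other positions exact);
out-of-range positions near chain ends simply do not score. The flags
`f_minus1` and `k_plus5` record the two highly conserved positions
singled out as substrate-specificity markers.

Classification applies rules in order:

| condition | class |
|---|---|
| C2 or C3 missing / unpaired | `incomplete` |
| H-2 substituted | `likely_inactive` |
| H-1 substituted | `likely_inactive` (`FITM_variant` in lenient mode) |
| third residue D | `LPT_canonical` |
| third residue E | `FITM_typical` |
| third residue Q or H | `FITM_variant` |
| otherwise | `likely_inactive` |

H-2 substitution is decisive because it is essential for all activity in
mutagenised LPTs and is always substituted (N or S) in the LPR/PRG
pseudo-enzymes. H-1 substitution is classified `likely_inactive` by
default — an H-1→A mutant of a yeast FITM lost function — even though
bacterial-enzyme data show substrate-dependent effects of H-1 variation;
the lenient mode records that uncertainty by downgrading only this rule
to `FITM_variant`. The function is total over all residue triples plus
missing states.

# ER residency classification

Per protein: a C-terminal signal ⇒ `ER`; otherwise ≥ 2 di-arginines ⇒
`ER`, exactly 1 ⇒ `unsure`, 0 ⇒ `not_ER`. The count used is the
cytoplasmic one when a topology is present (only cytoplasmic motifs are
functional) and the whole-sequence total otherwise (the high-throughput
convention, which knowingly includes luminal motifs — typically one or
more in loop 3/4). The report records which mode produced each call.
The rule is monotone: adding di-arginine motifs never moves a call away
from `ER`.

Families are summarised by member count, mean and SD of the di-arginine
count (over whichever count field the run provides), and the counts of
members with a C-terminal signal and with a KxN motif. Group comparison
reports the mean difference and calls a group "more ER-like" only when
it has both the higher mean and at least as high a C-terminal-signal
fraction; anything else is `mixed`. No inferential statistics are
attached — the family contrasts of interest are large
(e.g. means 3.7 vs 1.6, signal fractions 4/40 vs 0/52 in the yeast
FITM paralogue families) and the package stays descriptive.

# The synthetic generator: what it emulates, what it does not

`synthetic_spec()` describes a stated world: a polytopic protein built
loop–TMD–loop–…, by default 6 TMDs of 21 residues, cytoplasmic
N-terminus, loop lengths (25, 15, 12, 60, 12, 15, 30) echoing the FITM
anatomy with its long luminal loop 3/4. Motifs are planted over the
background at loop-relative offsets and recorded, with exact spans, as
ground truth; a single integer seed makes generation deterministic, and
family members derive per-member RNG substreams by index so member *i*
is reproducible regardless of family size.

Two deliberate design choices:

* **The background alphabet is {A, G, N, P, W, Y}.** A background that
  merely avoided R/K/H/C would still forge catalytic-site hits around
  planted motifs: S or T two residues before a planted C3 histidine
  completes a C2 match, D/E/Q four residues after a planted C2 histidine
  completes a C3 match, and N plus F/I/L/V can assemble KxN hits. Since
  the generator's contract is *exact* ground truth (100% precision and
  recall for the scanners), the default background also excludes S, T,
  D, E, Q, F, I, L, V and M (membrane-like hydropathy). The alphabet is
  overridable; with a realistic composition only recall of planted
  motifs should be asserted.
* **TMDs are drawn from {L, I, V, F}**, making planted helices
  unambiguous to the hydropathy predictor; with loops ≥ 10 residues the
  predictor recovers the planted TMD count exactly and centres within
  ±2 residues.

Family divergence substitutes loop residues (never TMDs, never planted
motif spans unless `mutate_motifs`) with background residues at a
per-site probability, default 0.05 — paralogue-family depth of variation
without disturbing the planted signals. The generator does not emulate
evolution (no trees, no indels), realistic amino-acid composition,
disorder or secondary structure; a green recovery test establishes
scanner correctness, not performance on natural sequences.

# Numerical and degenerate-input choices

* FASTA input: sequences uppercased; one terminal `*` stripped; internal
  `*`, digits or other non-residue characters rejected with their
  position; duplicate ids rejected by name; empty files rejected.
* Empty sequences never error in scanners (empty hit tables); an empty
  profile list yields a header-only TSV.
* `aggregate_family()` on a single member reports SD 0 (not NA), so
  one-member groups compare cleanly.
* The comparison fraction ratio is `Inf` when only the denominator group
  lacks C-terminal signals and `NA` when both do.
* Yeast-specific regression coordinates (H-1 at 178, third residue E at
  243 ⇒ H-2 at 239) are exercised on synthetic stand-in sequences
  constructed to carry those coordinates, since no accession is bundled
  with the package; tests label them as synthetic.

# Known limitations

* The topology predictor is a hydropathy heuristic, not a consensus
  machine-learning predictor; on natural sequences its TMD calls should
  be treated as a fallback, and externally supplied topologies are
  always preferred.
* Di-arginine counting near TMDs applies no distance penalty, although
  motifs very close to a TMD are reported to be less active; hits fully
  inside a loop count equally wherever they sit. The loop assignment in
  the JSON report retains enough information to post-filter.
* Orthologue/paralogue set construction (database mining, homology
  search, tree building) is out of scope; users supply family FASTA
  files and group tables.
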