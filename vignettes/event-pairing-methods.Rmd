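---
title: "Event-pairing analysis of developmental sequences: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-pairing analysis of developmental sequences: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsimovr)
```

This vignette documents the models implemented by `parsimovr`, the
conventions and tie-breaks it fixes where the underlying methods leave
choices open, and what its validation machinery does and does not
establish.

## The data model

An **event catalogue** is an ordered list of labelled events, each
`morphological`, `hatching` (at most one) or `molt`. The row order is
part of the model: it fixes the canonical orientation of every event
pair, and therefore the meaning of every character state. Two analyses
are comparable only if they use the same catalogue in the same order.

A **developmental sequence** is an ordered list of simultaneity blocks
(ranks) over the catalogue. A rank is a set of events indistinguishable
in timing at the study's chronological resolution — simultaneity is an
observational statement, not a biological one. Events absent from a
taxon and events simply not observed are both recorded as `missing`:
the encoding gives them unknown states in every pair, which is the only
representation the character model offers. The distinction
(true absence of a mandibular palp versus an unscored structure) is
deliberately not modelled; if it matters for a question, it must be
handled upstream.

## Event-pair characters

For catalogue order *i* before *j*, the character for {*i*, *j*} is the
timing of *j* relative to *i*: `0` = *j* earlier, `1` = simultaneous,
`2` = *j* later, unknown if either event is missing. The direction of
the 0/2 convention is arbitrary; it is fixed here once and documented so
that linearized codes are comparable across runs. The linearized code
lists the characters in lexicographic catalogue order and round-trips
losslessly (`linearize_code()` / `delinearize_code()`).

A pair table derived from a genuine ranked sequence is transitively
consistent. `check_consistency()` enumerates violating event triples;
note that a contradiction can also run through a cycle of four or more
events whose chords are unknown, which no triple detects —
`derive_sequence()` therefore performs its own cycle detection on the
precedence graph.

### Deriving sequences from (ancestral) pair tables

Ancestral reconstructions are made per character, so an ancestral pair
table need not be consistent. `derive_sequence()`:

* merges events tied by state `1` (union–find), then layers the merged
  groups by **longest path** over the known precedence relation. This is
  the weakest deterministic extension: every known entry of the input is
  honoured, unknown entries resolve reproducibly, and an event sits as
  early as its constraints allow. Round-tripping a complete encoding
  recovers the original ranks exactly.
* treats events with no known pair as missing.
* on inconsistency, fails by default, carrying the violating triples.
  With `repair = TRUE`, each strongly connected component of the
  precedence graph collapses into a single simultaneity rank and the
  result is flagged `repaired` — ambiguity is reported as simultaneity
  rather than resolved by guessing. Pipeline functions
  (`reconstruct_ancestors()`, `summarize_tree()`) use the repair mode
  and surface the flag.

## Parsimony reconstruction

Characters are treated as **unordered** by default (any state change
costs 1): a single heterochronic displacement can carry a pair directly
from `0` to `2` with no meaningful intermediate dwell at simultaneity,
so additive coding is not obviously right, and unordered is the common
default for event-pair data. The additive 0–1–2 alternative is exposed
as `treatment = "ordered"` so the choice is explorable rather than
baked in.

The implementation is a unit-cost dynamic program (subtree and
rest-of-tree cost tables), equivalent to Fitch parsimony for the
unordered case. It yields per character: the minimum change count, the
exact per-node set of states attained by at least one most-parsimonious
reconstruction, and deterministic ACCTRAN/DELTRAN resolutions computed
from the conditional-cost tables in preorder: DELTRAN keeps the parent's
state whenever that is cost-neutral (delaying changes toward the tips);
ACCTRAN takes a cost-neutral immediate change when one exists
(accelerating changes toward the root, allowing later reversal). Both
attain the per-character minimum by construction, which the test suite
verifies against an exhaustive-labeling oracle.

Fixed conventions, all deterministic:

* **Root.** The tree is used as supplied, rooted, with no outgroup.
  Root-state ties are broken toward the lowest state index and the
  affected characters flagged (`root_ambiguous`). Changes on the two
  root-adjacent branches are only identifiable up to this convention —
  an unrooted character set cannot distribute changes between them.
* **Remaining ties** break toward the parent's resolved state, then the
  lowest state index.
* **Missing data.** Unknown leaf states are compatible with every state
  and never generate changes; characters unknown at *every* leaf stay
  unknown at every node rather than being imputed. Branch change lists
  exclude unknown-involving transitions and count them separately as
  indeterminate.

## Parsimov movement inference

A change on pair {*i*, *j*} is explained by exactly two directed
movements (one of each underlying event, in opposite senses). Per
branch, `minimal_move_sets()` enumerates **all** minimum-cardinality
sets of movements accounting for every change, excluding sets that move
one event in both directions. The search is an exact branch-and-bound
over the two explanations of each uncovered change; at the scale this
method is used (six taxa, at most 2 × 27 candidate movements per
branch) exactness is mandatory and cheap, and the suite checks the
enumeration against brute-force subset search.

The consensus report contains the movements present in **every**
minimal set (necessary movements, with the partner events they were
scored against as reference events) and **joint groups**:
interchangeable alternatives such that every minimal set contains
exactly one member. Members of a joint group carry their own
directions — the two explanations of a single pair-change necessarily
move in opposite senses, while groups arising from a shared suite of
changes may share one. The cross-optimization consensus keeps movements
inferred under both ACCTRAN and DELTRAN and retains
optimization-specific movements in side channels rather than discarding
them, since DELTRAN-only signal (e.g. embryonic-phase shifts) can be
biologically informative.

Changes with an unknown endpoint are excluded from the explananda and
reported as indeterminate; inventing movements for them would require
assumptions the characters cannot support.

## Life phases

Phase definitions operate on any sequence containing the hatching
event:

* **embryonic** — morphological events strictly before hatching;
* **larval** — morphological events from hatching up to and including
  the **metamorphosis molt**, the earliest molt followed by no
  morphological event;
* **pre-metamorphosis molts** — molts strictly between hatching and the
  metamorphosis molt;
* **stages** — inter-molt intervals in that span containing at least one
  morphological event (so stages ≤ molts + 1, with equality exactly when
  no interval is empty).

Ties are resolved by convention, logged here because published
sequences never exhibit them: events simultaneous with hatching or with
the metamorphosis molt count as larval, and an event tied with a molt
belongs to the stage that molt closes. Ancestral sequences whose events
cannot be placed relative to hatching contribute to an `unplaced` count
instead of inflating phase counts.

The bundled *Penilia avirostris* fixture resolves four events (G, M, N,
D) whose stage of first appearance is ambiguous in the source
observations; the placements are recorded in the fixture's `note`
column and chosen to agree with the published per-phase counts for
Cladocera (6 embryonic, 13 larval, 1 pre-metamorphosis molt, 2 stages).

## The simulator and what validation shows

`simulate_on_tree()` evolves a root sequence from root to tips by
applying per-branch **shifts** (an event moves a given number of rank
positions, merging into an existing block or travelling as its own
block; boundary-clamped moves are flagged), optional **rank merges**
(modelling low chronological resolution) and **event losses**. Shifts
act on rank positions, never on pair codes, so simulated data are
always transitively consistent — matching the premise that observed
sequences are genuine orders. Every applied operation is logged, and a
fixed seed replays byte-identically.

The packaged regression scenario uses the six-taxon fixture topology, a
9-rank root sequence drawn once from a frozen seed (nine ranks mirrors
the resolution of the empirical sequences), and one explicit planted
shift of displacement 3 per branch, no merges, no losses. The shifts
were designed once, with two constraints: no shift may clamp at a
boundary, and the shifts on the two root-adjacent branches must be
identifiable under the root tie-break — a planted movement there is
only recoverable on its true branch if at least one crossed partner
lies on the favourable side of the canonical pair orientation (for a
late shift, a partner earlier in catalogue order; for an early shift, a
later one). Under that scenario every planted movement is recovered in
at least one minimal set on its true branch under both optimizations;
necessity in the consensus is additionally achieved here but is not
guaranteed in general, because a single pair-change always admits two
explanations.

Validation scales, chosen to keep the full suite fast while leaving the
oracles exhaustive: 1000 random three-state characters on trees of 3–6
leaves against brute-force labeling enumeration; 200 random movement
toys (≤ 10 candidates) against brute-force subset search; 1000 random
sequence encode/derive round trips; and the seeded scenario above.

What passing these tests does **not** show: that real sequences satisfy
the model. The simulator plants discrete rank displacements with
complete resolution; empirical data add correlated timing noise,
pervasive soft simultaneity, and taxon-specific event loss, and the
method's output there is a parsimony statement, not an estimate with
error bars. The ancestral reconstructions also depend on the supplied
topology, which is taken as given.

## Known limitations

* Ranks only: no fractional or clock-time sequences.
* Rooted-tree parsimony without an outgroup leaves root-adjacent change
  placement conventional (flagged, not resolved).
* Joint-group detection is exact for the partition structures that
  occur at this scale but greedy in member selection; movements in some
  but not all minimal sets that do not form an exact group appear only
  in the verbose enumeration.
* Absence and non-observation of an event are conflated as missing
  data.
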