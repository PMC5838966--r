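---
title: "Simulating phosphorylation networks with a two-regime Petri net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phosphorylation networks with a two-regime Petri net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphopetri)
```

## The model

`phosphopetri` simulates signaling through a kinase–phosphatase network as a
discrete Petri net specialized to phosphorylation:

* **Places** are proteins; the integer token count of a place is the amount
  of phosphate carried by that protein (its *phosphorylation status*).
* **Transitions** are directed enzyme → substrate reactions of two types.
  Firing a *phosphorylation* adds one token to the substrate; firing a
  *de-phosphorylation* removes one, clamped at zero.  Firing never changes
  the enzyme's own tokens — an enzyme catalyzes without consuming its own
  phosphate.
* **Enabling** depends only on the input place and its *activation regime*.
  Most kinases and phosphatases are activated by phosphorylation: their
  transitions are enabled when the enzyme holds strictly more than the
  enabling threshold $\tau$ tokens.  A minority are activated *without*
  phosphorylation (i.e. inhibited by it): their transitions are enabled when
  the enzyme holds strictly fewer than $\tau$ tokens.  A count exactly equal
  to $\tau$ enables nothing under either regime.

A simulation runs in **blocks**.  Each block shuffles the full transition
list afresh, traverses it once (re-applying any perturbation before every
transition check), and then applies a degradation step that removes a
fraction $\gamma$ of the tokens in every place:

$$ n \leftarrow \lfloor (1-\gamma)\, n \rfloor . $$

The floor keeps counts integral and guarantees strict decay of every
positive count in the absence of firing.  The initial marking assigns every
place an independent uniform integer in $[0, 2\tau]$.  Because both the
initial marking and the shuffle order are random, a state's
*phosphorylation status* is the mean of the final-block markings over
several independently seeded iterations (`simulate_state()`).

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` ($\tau$) | 35 | tokens | enabling cutoff for both regimes |
| `blocks` | 100 | blocks | simulation length; counts saturate well before the end at the default $\gamma$ |
| `degradation_rate` ($\gamma$) | 0.10 | fraction/block | bulk turnover applied after each block |
| `iterations` | 10 | runs | independently seeded simulations averaged into a status |
| `init_max` | $2\tau$ | tokens | upper bound of the uniform initial marking |
| `seed` | 1 | — | master seed; all sub-streams derive from it via `mix_seed()` |

The default $\tau = 35$ is the most robust value under the pairwise
rank-correlation scan described below; `init_max` and the stimulus clamp
level both scale as $2\tau$ so that the dynamic range tracks the threshold.

## States and perturbations

Three states are compared:

* **Reference** — no perturbation.
* **Atrophic** — a persistent stimulus.  Myostatin, the muscle-growth
  inhibitor that induces the atrophic state, carries no place of its own in
  a phosphorylation network, so the stimulus is modeled by clamping its
  *direct targets* to high activity ($2\tau$ tokens) before every
  transition check.
* **Gene-inhibited** — the atrophic stimulus plus a knock-down of one gene.

Inhibition uses a deliberately double-barreled semantics: the place's tokens
are forced to zero **and** every transition whose input place is inhibited
is suppressed.  The token clamp alone would be wrong for enzymes activated
without phosphorylation, for which zero tokens means *maximally active*; the
suppression rule silences those too.  This is a design choice on a point the
enabling rules leave genuinely open, and it is what makes "zero activity"
mean the same thing under both regimes.

When an inhibited candidate is itself one of the stimulus's direct targets,
the knock-down overrides the stimulus: the candidate is dropped from the
clamp set for its own inhibited-state runs.  Perturbations are re-applied
before each transition check and once after the last one, so a firing onto a
clamped or inhibited place can never leak into the recorded marking; an
inhibited place therefore reads exactly zero throughout its trajectory.

## Fixed-point bands: what the dynamics can and cannot do

The degradation floor gives the per-block map of a place fed by $d$
constantly firing enzymes, $n \mapsto \lfloor(1-\gamma)(n+d)\rfloor$, a whole
*interval* of fixed points — $[9d-10,\; 9d]$ at $\gamma = 0.1$ — entered at
its lower end from below and its upper end from above.  Three consequences
matter for anyone designing networks or interpreting results:

1. A place fed through a single edge can never rise from zero
   ($\lfloor 0.9 \cdot 1 \rfloor = 0$); sustained signal propagation needs
   fan-in of at least 2.
2. A place crosses $\tau = 35$ upward from *any* start only when its whole
   band clears the threshold, which requires fan-in of at least 6.
3. Gaining or losing a single input edge shifts the band by 9 but does not
   move a place already inside its band; switching an enzyme between states
   therefore requires changing its active fan-in by at least 2, or toggling
   it between fed and unfed.

Within a band, where a trajectory settles depends on the initial marking, so
saturated token counts retain initial-condition memory even after 100
blocks.  That is why statuses are iteration means and why the screening
logic compares *directions* of change, never magnitudes.

## Screening for therapeutic targets

Marker proteins with a validated direction of phosphorylation change in the
diseased state (hyper- or hypo-phosphorylated) form a panel
(`marker_panel()`).  A marker is **recovered** by a knock-down when its
reference→atrophic and atrophic→inhibited directions of change are both
non-tied and opposite; exact ties count as no direction, because a tie is
evidence of nothing (a configurable `epsilon` widens the tie band, default
0).  The screenable candidates are the kinases and phosphatases with a
directed path to at least one marker (`candidate_enzymes()`; an undirected
reading is available, since "linked to" admits either).  Each candidate is
screened in three independently seeded replicate inhibited-state
simulations, and selected only if **every** replicate recovers at least 4 of
the 5 markers — so replicate triples like (5, 5, 3) or (4, 5, 3) fail while
(4, 4, 5) passes.  Replicate seeds are derived from the master seed and the
candidate's id, so candidate order cannot change any verdict.

## Choosing the enabling threshold

`scan_thresholds()` scores each candidate $\tau$ (default grid 1, 5, 10, …,
50) by how reproducibly independently seeded simulations rank the places by
final-block token count: the average pairwise Spearman correlation over the
10 iterations (45 pairs), computed separately in the reference and atrophic
states and then averaged.  How to combine the two states is not dictated by
the procedure itself; averaging is this package's choice, and per-state
scores are always reported alongside.  Ties break toward the smaller
threshold (the cheaper dynamics).  A marking with zero variance has no
defined rank correlation; such pairs are dropped from the mean and an
all-undefined score disqualifies the threshold.

## Evaluation statistics

Predicted target sets are evaluated two ways:

* **Hypergeometric overlap** (`overlap_test()`): the exact upper-tail
  probability of drawing at least $k$ gold-standard genes among $n$
  predictions from a population of $N$ containing $K$, summed directly from
  the probability mass (the populations are far too small for a normal
  approximation).  The worked example — population 331, 3 gold-standard
  genes, 37 predictions, overlap 2 — gives $p = 0.034$.
* **Shortest-path proximity** (`proximity_table()`,
  `top_k_by_proximity()`): the static baseline ranks candidates by mean
  breadth-first path length to the panel (undirected by default, the usual
  proximity convention; directed mode available).  Markers unreachable from
  a gene are excluded from its mean rather than treated as infinite, keeping
  the statistic finite but flagged; a gene reaching no marker is undefined
  and never selected.  The top-$k$ cut always carries the complete tie class
  at the cutoff length, so the returned set may exceed $k$ — a fixed-size
  nearest set is not well defined across a tie.

## The synthetic generator

`generate_network()` emulates the *structure* such a screen runs on: a few
hundred down to a few dozen proteins split into kinases, phosphatases and
substrate-only proteins; phosphorylation edges out of kinases and
de-phosphorylation edges out of phosphatases; a small fraction of enzymes
(default 5%, roughly the 25-in-526 share seen in curated annotation)
activated without phosphorylation; a stimulus with direct targets; and a
marker panel reachable from the stimulus.  Edge endpoints are drawn
uniformly at random — no degree heterogeneity — which keeps generation
simple and deterministic under a seed.

With `plant_relay = TRUE` the generator wires a recoverable ground truth
governed by the fixed-point arithmetic above: 6 stimulus-target kinases fan
into one relay phosphatase (band 44–54 when clamped, so the relay is ON in
the atrophic state from any start, and decays to OFF in the reference
state); a pool of 4 constitutively active kinases (activated without
phosphorylation, zero in-degree, idling near zero tokens) holds every marker
in the 26–36 band; and the relay de-phosphorylates each marker directly,
pulling it to ≤ 27 under the stimulus.  Every stimulus→marker path runs
through the relay — asserted at generation time by deleting it and checking
reachability — so inhibiting the relay restores every marker, and the
end-to-end screen selects it.

Consequence (3) above imposes a real constraint here: an enzyme downstream
of a single relay receives at most one relay-dependent edge and therefore
can never itself be switched between states, so a single cut-vertex relay
can only move its *direct* substrates, in the single direction of its own
catalytic sign.  A planted panel with mixed expected directions would
require either two relays (no longer a unique knock-down target) or
multi-edge relay wiring that the deduplication invariant forbids.  The
planted panel is therefore uniformly "down" (relay = phosphatase), with the
directions derived from the wiring rather than asserted.

What passing on these networks does **not** show: real phosphorylation
networks are scale-free-ish, far larger, incompletely mapped, and their
marker directions come from noisy measurements; the generator has uniform
degrees, exact annotations and wiring-derived directions.  Synthetic
recovery demonstrates that the pipeline's logic is sound, not that the
biology of any particular network is captured.

## Problem sizes and numerical choices

The shipped test suite runs the full pipeline at the scale the package is
designed to be verified at on a single CPU: networks of 35–50 nodes and
50–200 transitions, 100 blocks, 10 iterations, 3 replicates, 5 generator
seeds for the planted-relay screen, and the canonical eleven-threshold scan
run twice for reproducibility — a few minutes end to end.  Other choices
worth knowing:

* All randomness flows from one master seed through `mix_seed()`, a
  multiplicative hash over stream labels; results are bit-reproducible and
  independent of evaluation order, and adding iterations, replicates or
  candidates never perturbs existing streams.
* Degradation uses `floor()`; the rounding direction is part of the model
  (it guarantees decay to zero absent firing).
* Conflicting interaction annotations (the same enzyme–substrate pair
  recorded with both types) are resolved by curated evidence when provided,
  otherwise both rows are dropped — conservative removal, with counts
  reported.
* Enzymes with both default and override activation evidence are classified
  as activated without phosphorylation: the rule is an override of the
  cascade default, so the special evidence wins.
* Protein identifiers are opaque strings; no identifier-namespace
  validation is attempted.

## Known limitations

Token dynamics are unit-gain and unweighted: no reaction stoichiometry,
kinetics or dwell times, and no distinction between phospho-sites.  The
fixed-point bands mean saturated levels carry initial-condition memory, so
individual token counts should never be over-interpreted — only direction
statistics over iteration means are meaningful.  The selection rule is
binary and can miss genuine targets whose replicate counts fluctuate around
the cutoff; magnitude-aware scoring is deliberately out of scope.
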