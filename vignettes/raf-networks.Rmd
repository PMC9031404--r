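---
title: "RAF networks: methods, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RAF networks: methods, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafnet)
```

## The model

A catalytic reaction system Q = (X, R, C, F) couples a set of entity types X,
reactions R over X, a catalysis relation C between types and reactions, and a
foodset F of types assumed present from the start. A non-empty reaction
subset R′ is a RAF when (1) every reaction in R′ has at least one catalyst
among F ∪ products(R′) (reflexive autocatalysis), and (2) every reactant of
every reaction in R′ is reachable from F using only reactions of R′
(F-generation). The two criteria are deliberately independent in this
package: the closure used for F-generation ignores catalyst availability
entirely, because criterion (2) concerns reactants only, and catalysis is
judged by criterion (1) alone. For a subset that is F-generated the two views
coincide anyway — closure(F, R′) = F ∪ products(R′) — but keeping the checks
separate lets `is_raf()` return a precise certificate (`uncatalyzed` versus
`ungenerated`) when a subset fails.

Reactants and products are multisets: chemistry allows `a + a -> b`.
Multiplicity is preserved through serialization and nowhere else, because
both criteria are statements about the *availability of types*, not about
stoichiometric amounts. There are no rate constants, concentrations, or
kinetics anywhere in the model; it is purely structural.

## Algorithms and their certification

`max_raf()` runs the standard interleaved-pruning reduction: compute the
foodset closure W of the current reaction set, delete every reaction with a
reactant outside W or with no catalyst inside W, and repeat until a fixed
point. Each pass is linear in the reaction/type incidence (closure is
computed with unmet-reactant counters, not repeated scanning), at most |R|
passes occur, and the surviving set is the unique maximal RAF — empty when no
RAF exists, which is an ordinary result rather than an error. Because the
computation is set-valued, the answer cannot depend on reaction iteration
order; the test suite still verifies this behaviourally by relabelling
reactions (which permutes every internal ordering) and comparing results.

The exponential counterpart, `all_sub_rafs()`, scans all 2^|R| − 1 non-empty
subsets with the definitional check and is the package's oracle: on
generated systems with |R| ≤ 12 the suite asserts that the reduction's
answer equals the union of all brute-force RAFs, and additionally checks the
poset laws (union closure, unique maximal element). A second, deliberately
naive implementation of the definition lives in the test helpers, sharing no
code with either exported path, so the certification does not rest on a
single implementation. The exhaustive size cap defaults to 14 reactions
(2^14 subsets) and is configurable; above it `irr_rafs()` falls back to
seeded random shrinkage walks (remove a random reaction, recompute the
maxRAF of the remainder, repeat until no removal leaves a RAF), which can
miss irrRAFs but never returns a reducible set.

## The cognitive instantiation

A `mind()` holds mental representations partitioned into a foodset —
innate items, individually learned items, and socially transmitted items —
and a foodset-derived set produced by `redescribe()`, the cognitive
reaction: existing representations (reactants), triggered by another
representation or stimulus (catalyst), are recoded into a new one (product).
Three rules are enforced structurally rather than checked after the fact:

* **Partition** — foodset and derived sets are disjoint and jointly
  exhaustive at every point; `add_foodset_item()` refuses social and derived
  provenance, which can only arise through `transmit()` and `redescribe()`.
* **Generational rule** — a transmitted item always lands in the receiver's
  foodset, whatever its provenance was for the sender, while the origin-mind
  tag is inherited; creativity is thus attributed to the mind it arose in,
  across any number of retransmissions.
* **Groundedness** — every derived item records exactly one producing
  reaction whose reactants predate it, so `provenance_chain()` always
  terminates in foodset items. Catalysts appear in the chain as annotated
  edges but are not recursed into: a derivation is grounded in what it was
  *made from*, with triggers recorded alongside.

External stimuli that act as catalysts (a therapist's question, laughter)
are normalised into transmitted foodset items of the receiving mind before
they catalyse anything, so that every catalysis edge connects two typed
nodes of the same system.

### Impact weights

The sources for this model describe the influence of a belief cluster only
ordinally (a RAF's "impact" growing or shrinking), so the update rule is a
package design choice and documented as non-normative: each tracked RAF
carries a positive weight, multiplied by 1 + α per supporting event and by
1 − β per inhibition, with α = β = 0.5 by default. Multiplicative updates
keep weights positive for any event sequence and make the guaranteed claims
— inhibition strictly decreases, support strictly increases, order of
ordinal comparisons — independent of α and β. Only ordinal comparisons are
contractual; the absolute numbers are not interpretable. RAF labels are the
sorted reaction ids joined by `+`, so when the network grows and
`refresh_rafs()` recomputes the irreducible RAFs, an unchanged reaction set
keeps its weight and history, new irrRAFs start at weight 1, and vanished
ones are dropped. Inhibition deliberately stays out of RAF detection:
detection with hard inhibition is a much harder computational problem, and
the phenomenon being modelled is a weakening of influence, not a structural
veto.

### The scripted dyad and its two readings

`build_clive_thera()` scripts a client–therapist session: belief formation
under a catalyzing incident, social transmission of the client's
self-description to the therapist, praise transmitted back and acting as an
inhibitor, a humour reframe and a prompting question transmitted as future
catalysts, the client's joke as a reinterpretation of a bad memory, and a
new adaptive belief catalyzed by the therapist's laughter. The event
vocabulary is `add`, `transmit`, `react`, `inhibit`, `reweight`; `add` is
included because the session itself creates new direct experiences (the
client hears himself deliver the joke) that none of the other kinds can
encode. Replay from the initial snapshot is exact and idempotent.

One step of the narrative is genuinely ambiguous: the final reaction's
reactant — the joke — can be read either as the *same* representation as the
reinterpretation it grew from (one derived item feeding the next reaction),
or as a *new direct experience* (the heard utterance) entering the foodset.
The source material is internally inconsistent at this point (its set-update
notation adds the joke to the derived set while the surrounding prose makes
the new belief the product), and we do not silently resolve it: the
constructor exposes both readings. Under the foodset reading (the default)
the final client network has three irreducible RAFs — belief, joke, new
belief — whose union is the maxRAF, matching the described final structure;
under the one-item reading the joke-RAF and the new-belief reaction chain
together, giving two irrRAFs. A related note concerns the therapist's
mirror copies of transmitted items: from the RAF point of view they may be
counted inside or outside the client's maxRAF, so `cmd_example()` exposes
`include_therapist_mirrors` as a boolean.

## Generators and study conditions

`binary_polymer_system()` implements the ligation-only variant of the binary
polymer chemistry: types are all binary strings of length 1..n, food is all
strings of length ≤ t (default t = 2), and reactions are all ordered
ligations a + b → ab within the length bound. Cleavage is the same reaction
read backwards and is not represented separately; this is the minimal
variant commonly used for RAF phase-transition work, chosen here once and
not varied. Catalysis is the classic independent Bernoulli(p) per
(type, reaction) pair. Replicate sub-seeds are derived from the master seed
by a counter-based affine map, so replicate k is reproducible in isolation
without replaying the stream.

The phase experiment's default grid
(0, 0.001, 0.002, 0.004, 0.008, 0.016, 0.05, 1) is log-spaced through the
transition region for the default n = 6, t = 2 chemistry (126 types, 516
reactions), where the RAF-found fraction moves from 0 to 1 between roughly
p = 0.001 and p = 0.02; the endpoints are included because they are exact
(p = 0 has no catalysis, p = 1 catalyses everything reachable). The testing
and acceptance runs use 25 replicates per grid point, 100 oracle-certified
systems with |R| ≤ 12, and 200 random minds with up to ~14 items — sizes at
which the exhaustive oracle is still exact, chosen as the package's own
desk-scale defaults.

`random_mind()` builds property-test fodder: a valid mind with the requested
derived fraction, every derivation grounded by construction, and random
extra catalysis. It samples foodset provenance over innate and individual
learning only, because a standalone generator cannot certify the
source-item-exists invariant that social provenance requires. What these
generators emulate is the *structure* of cognitive networks — provenance
partitions, grounded derivations, sparse catalysis — not their content:
there is no semantics, no association strength, no spreading activation, and
no dynamics of attention or memory. Passing tests therefore certify the
bookkeeping and the RAF mathematics, not any claim about real minds or
clinical practice; "stable attractor" language is represented only by the
impact weight, with no dynamical-systems simulation behind it.

## Serialization and numerical conventions

The JSON document (with `format_version: 1`) is the normative form; the
line-oriented text dialect is sugar for hand-written examples. Both are
inventions of this package — the underlying theory fixes no file format.
Output is canonical (every collection sorted by id), so write–parse–write is
byte-identical and system equality can be tested on serialized form.
Unknown ids are always an error, never an implicit declaration; a `strict`
flag additionally requires explicit type declarations. Degenerate inputs are
well-defined by the mathematics and treated as such: an empty reaction set,
an empty foodset (closure is then empty), and systems without catalysis
(maxRAF empty) are all valid. All returned collections are sorted by
reaction id; the only randomness in the algorithm layer is the sampled
irrRAF mode, which requires an explicit seed.

## Limitations

* RAF detection here is exact but structural: no kinetics, no molecule
  counts, no evolution of RAFs under selection.
* Exhaustive enumeration is exponential by nature; beyond the cap, irrRAF
  sampling is sound but incomplete.
* The impact-weight scale is arbitrary; only directions of change are
  meaningful.
* The dyad model covers one scripted interaction pattern; it makes no claim
  of clinical validity and models no trust, motivation, or alliance
  variables.
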