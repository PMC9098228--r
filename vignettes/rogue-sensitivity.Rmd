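---
title: "Rogue-taxon sensitivity of parsimony ancestral states: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rogue-taxon sensitivity of parsimony ancestral states: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roguestate)
```

## What the package computes

`roguestate` asks how robust a parsimony ancestral-state reconstruction is to
two things that are usually frozen before the analysis starts: the placement
of phylogenetically unstable taxa, and the delimitation of the character
itself.  Instead of reconstructing on one tree, it enumerates a topology
space — every combination of the candidate placements of the rogue taxa on
each backbone hypothesis — reconstructs on all of them, and reports the
complete grid of ancestral calls.

The shipped vocabulary is the angiosperm carpel-fusion problem: four rogues
(*Ceratophyllum*, *Nuphar*, *Euptelea*, Tofieldiaceae), three mesangiosperm
backbones, two codings of syncarpy, and two focal nodes (the *Ceratophyllum*
stem node and the mesangiosperm crown node).  The machinery underneath —
tree surgery, the parsimony engine, the sweep — is generic.

## The parsimony model

The engine is unit-cost parsimony on a rooted tree, implemented as the
generalized (Sankoff) recursion rather than Fitch set operations:

* downpass: `cost(v, s) = sum over children c of min_t( cost(c, t) + [s != t] )`,
* a leaf costs 0 at each state in its observed set and (a sentinel)
  infinity elsewhere; an uncertain leaf (missing `?`, inapplicable `-`, or
  polymorphic `{01}`) costs 0 at both states,
* tree length `L` is the minimum root cost; an uppass then yields, for every
  node and state, the minimal total length conditional on fixing that node,
  and the node's **MPR set** collects the states whose conditional length
  equals `L`.

The Sankoff form was chosen because it handles hard polytomies, polymorphic
leaves and (future) multistate characters with no special-casing; classic
Fitch is retained only as an independent cross-check in the test-suite,
where on fully resolved trees the count of set-intersection failures must
equal the Sankoff length.

**MPR semantics.** A state belongs to a node's set iff it is realized at
that node in at least one globally minimal labeling (the union over MPRs).
This is the operational meaning of an "equivocal" ancestral call: both
states are exactly equally parsimonious.  On polytomous trees this union can
differ from Fitch uppass sets, which is why the definition is pinned down
here and enforced against an exhaustive-enumeration oracle
(`brute_force_mpr`, capped at 16 internal nodes) on randomized instances
with polytomies, missing data and polymorphism.

**Numerical choices.** All costs are integers; infinity is a sentinel larger
than any achievable length (`n_tips + n_nodes + 1`), so no clamping or
floating point is ever needed.  Ambiguity is always reported as a set; no
tie-breaking is applied anywhere.  Degenerate inputs are defined, not
errors: a monomorphic column has length 0 with every set a singleton; an
all-missing column has length 0 with every set `{absent, present}`; a
single-leaf tree has length 0.  Branch lengths, when present on input, are
carried through I/O but ignored by every computation — the analysis is
purely topological.

## The character and its two codings

Raw observations are *fusion records*: per taxon, whether any between-carpel
fusion is present (`yes`/`no`/`unknown`/`inapplicable`/`polymorphic`) and of
which developmental type (`congenital`/`postgenital`/`both`/`none`/
`unknown`).  `inapplicable` is reserved for monomerous (one-carpel)
gynoecia, where fusion between carpels has no referent; it maps to missing
for reconstruction but stays distinct in the records so reports can separate
`?` from `-`.  Validation enforces coherence in both directions (`no`
implies type `none`; a determinate type implies `yes`), which is exactly
what makes the coding comparison monotone: the taxa scored fused under
`congenital_only` are always a subset of those under `any_fusion`.  This
inclusion is tested by exhaustive enumeration of all coherent record values.

Two codings turn records into the analysis character.  `any_fusion` scores
fused whenever any fusion is recorded; `congenital_only` restricts the fused
state to congenital fusion (syncarpy in the narrow sense) and rescores
purely postgenital fusion as free-carpellate, with indeterminate types
becoming uncertain.  Per-taxon overrides are applied after the mode mapping
and win over it; the two *Ceratophyllum* interpretations are overrides to
`uncertain` (monomerous, character inapplicable) and `present`
(pseudomonomerous, congenitally fused).  A measurement convention defining
"fused" (e.g. carpels united for more than 5% of their length) can be
attached as metadata; it documents provenance and never alters computation,
since applying it needs specimen measurements the package never sees.

## The topology space

`enumerate_recipes()` is the Cartesian product, ordered backbone-major and
then by *Ceratophyllum*, *Nuphar*, *Euptelea*, Alismatales, matching the
layout of the rendered grid.  `realize_recipe()` is deterministic and built
entirely from prune/graft surgery:

1. the four rogues are pruned from the user's scaffold tree (degree-2 nodes
   suppressed, so lengths stay comparable);
2. the mesangiosperm crown of the rogue-free tree is replaced by the
   backbone template, whose placeholder leaves (`EUDICOTS`, `MONOCOTS`,
   `MAGNOLIIDS`, `CHLORANTHACEAE`) are filled with the scaffold's own
   within-clade subtrees — everything not under test is retained as in the
   scaffold;
3. *Nuphar*, *Euptelea* and Tofieldiaceae are regrafted per the recipe, and
   *Ceratophyllum* last, so its stem node is the final graft-created node.
   Graft order cannot affect the topology (the placements are in disjoint
   regions except for *Ceratophyllum*'s, which is applied last); this is
   asserted by a test that regrafts in a different order.

Design choices that were genuinely open:

* **Backbone defaults.**  The three templates must realize the three rooted
  resolutions of {eudicots, monocots, magnoliids}; the published diagrams of
  the JM/1KP/DE hypotheses are graphical, so the exact position of
  Chloranthaceae within each is a reading, not a datum.  The defaults place
  Chloranthaceae sister to magnoliids in all three backbones and ship as
  editable Newick files — anyone preferring a different reading edits one
  line rather than the code.
* **"Sister to all other mesangiosperms"** is realized by grafting onto the
  mesangiosperm crown edge; the crown node is then redefined to include
  *Ceratophyllum* (for that placement the stem and crown nodes coincide).
* **Clade addressing** is by an explicit taxon-to-clade map rather than by
  node labels, because user scaffolds rarely carry internal labels; the map
  doubles as the definition of "mesangiosperms" when locating the crown.
* The scaffold is accepted as a single tree (not a sample); if the source
  analysis used a preferred tree, that is what should be supplied.

All 96 realized trees are checked pairwise non-isomorphic via a canonical
form (sorted recursive parenthesization), which is order-insensitive while
the writer itself preserves child order verbatim for stable diffs.

## The two strategies

Strategy 1 scores *Ceratophyllum* `uncertain` and reads the MPR call
(`P`/`A`/`U`) at its stem node for each recipe and coding.  The uncertain
scoring is implemented as an override rather than leaf deletion so the stem
node keeps its identity for reporting.  The two are equivalent: an
uncertain leaf contributes cost 0 at either state, so deleting it changes no
length and no other node's set; the stem node itself sits on the
parent-sister edge of the pruned tree, and its MPR set equals the union of
those two endpoints' sets.  Both facts are property-tested.

Strategy 2 reads the mesangiosperm crown node under both *Ceratophyllum*
scorings (`uncertain` and `present`), giving per-backbone tallies of
{fused, free, equivocal} over each set of 32 trees — 3 backbones x 2 codings
x 2 scorings = 12 tallies.

An `A` (free-carpellate) call is fully representable at both focal nodes;
nothing hard-codes the published observation that only `P` and `U` occurred
at the stem node in the full data set.  Counting is always over the 96
recipe-level calls (each rendered grid cell holds three backbone results).

## The synthetic generator and the exemplar

`simulate_tree()` builds rooted binary trees by recursive random joins, with
named clades generated monophyletic; `simulate_character()` either walks the
tree with a symmetric per-edge flip probability (returning the true internal
states and the realized number of changes) or draws leaf states i.i.d. at
per-clade frequencies.  A symmetric single-rate flip model is deliberate:
the analysis is parsimony-based, so the generator only needs clade-structured
variation, not a calibrated evolutionary model.  Every draw is a pure
function of an explicit seed (`withr::with_seed`); there is no global random
state.  Defaults — 64 leaves, flip rate 0.05, no missing data — are chosen so
that a character typically accrues a handful of changes on the tree, the
regime where parsimony is a sensible estimator and where the calibration
claim is meaningful: over 500 replicates the true root state must lie in the
root MPR set at least 95% of the time, and the parsimony length may never
exceed the realized number of changes (it is a minimum).  The observed
recovery in this configuration is around 98%.

The packaged exemplar is a 38-taxon scaffold with real genus names covering
every clade the topology space addresses, plus a human-editable CSV of
fusion records that exercises every record code path (congenital-only,
postgenital-only, both, none, unknown, inapplicable; *Ceratophyllum* is
`?`).  The records follow clade-level fusion-type annotations from the
systematic literature where those are well known (e.g. Nymphaeaceae
congenitally syncarpous, Cabombaceae and most Ranunculales free-carpellate,
Chloranthaceae monomerous and therefore inapplicable) and are otherwise
editable placeholders.  **What the exemplar does and does not show:** it
proves the pipeline end-to-end — 96 realizable, pairwise distinct trees,
total and deterministic call grids, coding-sensitivity detection — but its
tallies are properties of 38 taxa, not of the published 792-species matrix.
Reproducing the published tallies requires that matrix and its scaffold
tree, which are not redistributable here; given files of the documented
shape (NEXUS/CSV matrix, Newick scaffold, clade-map CSV), the same sweep
functions reproduce them directly, and the test-suite contains the
corresponding checks.

## Problem sizes and runtime

The test-suite and the acceptance script run at desk scale by choice: oracle
agreement on 500 random trees of 4–10 leaves (the exhaustive oracle is
exponential, capped at 16 internal nodes); sweeps on the 38-taxon exemplar
(96 topologies x 2 codings x 2 scorings in a few seconds); calibration at 64
leaves x 500 replicates.  The sweep itself is O(recipes x tree size) integer
dynamic programming, so a 792-taxon matrix over 96 topologies remains a
minutes-scale computation on one core.

## Known limitations

* Parsimony only: no likelihood or Bayesian reconstruction, no asymmetric
  step matrices, no ordered/multistate characters (the engine's Sankoff form
  would extend, but the surface is binary).
* The topology space varies exactly the four stated rogues; alternative
  Chloranthaceae positions are a template edit, not an enumerated axis.
* Tree surgery does not apportion branch lengths (the analysis ignores
  them); trees written after surgery carry only the lengths that survived
  intact.
* The Alismatales placements assume the scaffold's rogue-free Alismatales
  splits into Araceae versus the rest, as in the source tree's shape;
  other within-clade arrangements would need a template of their own.
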