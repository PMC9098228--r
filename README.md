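# roguestate

Sensitivity analysis for parsimony ancestral-state reconstruction when the
phylogeny itself is uncertain.

## The problem

Ancestral-state reconstruction normally takes the tree as given.  But some of
the most interesting characters sit right next to *rogue taxa* — lineages
whose phylogenetic position swings between analyses.  The motivating case is
the evolution of carpel fusion (syncarpy) in flowering plants.
*Ceratophyllum*, an ancient aquatic genus, is one of the five lineages of
mesangiosperms, yet it attaches variously as sister to Chloranthaceae, to
eudicots, to monocots, or to all other mesangiosperms; its gynoecium can be
read as a single carpel (the fusion character is then inapplicable) or as two
congenitally fused carpels (pseudomonomery, i.e. fused).  Three further taxa
near the relevant nodes are also unstable: *Nuphar* within Nymphaeales,
*Euptelea* at the root of Ranunculales, and Tofieldiaceae at the root of
Alismatales.  And the character itself can be delimited two ways: "any carpel
fusion" versus "congenital fusion only" (syncarpy in the narrow sense, with
postgenitally fused gynoecia rescored as free-carpellate).

`roguestate` makes this whole analysis reproducible as a pipeline:

1. **Parsimony engine** — unit-cost (Fitch-equivalent) parsimony on rooted,
   possibly polytomous trees via the Sankoff recursion, returning the minimum
   number of changes *L* and, at every node *v*, the MPR state set
   `S(v) = { s : L(v = s) = L }` — the set of states realized in at least one
   most parsimonious reconstruction.  `|S(v)| = 2` is an equivocal ("U")
   call.  Integer arithmetic, hard polytomies, uncertain/polymorphic/missing
   leaves at cost 0 for either state.  An exhaustive-enumeration oracle
   (`brute_force_mpr`) double-checks the dynamic programme.
2. **Topology space** — `enumerate_recipes()` crosses 3 backbone hypotheses
   (JM, 1KP, DE: the three rooted resolutions of eudicots / monocots /
   magnoliids) with 4 placements of *Ceratophyllum* and 2 each for *Nuphar*,
   *Euptelea* and the Alismatales root: 3 × 4 × 2 × 2 × 2 = 96 trees.
   `realize_recipe()` builds each tree by pruning the rogues from a scaffold,
   rearranging the mesangiosperm crown per an editable Newick backbone
   template, and regrafting the rogues.
3. **Sweeps** — `run_strategy1()` scores *Ceratophyllum* as unknown and reads
   the MPR call at its stem node on all 96 trees under both codings;
   `run_strategy2()` reads the mesangiosperm crown node with *Ceratophyllum*
   scored unknown and again scored fused.  `render_table1()` and
   `render_fig13()` lay the calls out as a placement-by-placement grid and as
   per-backbone tallies; `autoplot()` draws them.
4. **Synthetic data** — `simulate_tree()` / `simulate_character()` generate
   clade-structured binary characters (per-edge flip model or per-clade
   frequencies, tunable missing fraction) with the true history retained, so
   the engine's calibration is testable; `build_exemplar()` loads a packaged
   38-taxon exemplar with real genus names and literature-based fusion
   records.

## Worked example

```r
library(roguestate)

# a three-taxon reconstruction
tr  <- read_newick("((Magnolia,Helianthus),Amborella);")
col <- tibble::tibble(taxon = c("Magnolia", "Helianthus", "Amborella"),
                      state = c("absent", "present", "absent"))
mpr_sets(tr, col)
#> <mpr> tree length: 1
#>   internal node calls: A = 2  P = 0  U = 0

# the full sweep on the packaged exemplar
ex <- build_exemplar()
g1 <- run_strategy1(ex$records, ex$templates, ex$scaffold, ex$clade_map)
glance(g1)
#> # A tibble: 2 x 7
#>   ceratophyllum_scoring coding              n   n_P   n_A   n_U n_sensitive
#> 1 unknown               any_fusion         96     0    64    32           8
#> 2 unknown               congenital_only    96     0    72    24           8
```

One change suffices on the small tree and both internal nodes are
unambiguously free-carpellate.  On the exemplar sweep, each row summarises 96
stem-node calls under one coding: under any-fusion coding 32 of the 96
topologies leave the ancestral state of the *Ceratophyllum* lineage equivocal
and 64 call it free-carpellate; 8 topologies change their call when syncarpy
is restricted to congenital fusion.  `render_table1(g1)` prints the
placement-by-placement grid with the coding-sensitive cells flagged:

```r
render_table1(g1)[1:3, 1:4]
#>   ceratophyllum         nuphar               backbone `sister_other_ranunculales & araceae_first`
#> 1 sister_chloranthaceae sister_nymphaeoideae JM       A/A
#> 2 sister_chloranthaceae sister_nymphaeoideae 1KP      A/A
#> 3 sister_chloranthaceae sister_nymphaeoideae DE       *U/A*
```

These exemplar numbers characterise the packaged 38-taxon fixture, not the
published 792-species matrix; to sweep a full data set, pass your own matrix
(`read_fusion_records()`), scaffold tree and clade map to the same functions.

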