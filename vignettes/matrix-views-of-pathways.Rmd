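---
title: "Matrix views of pathway relation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix views of pathway relation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmat)
```

## The data model

A pathway reduced to binary relations is a set of statements
`SOURCE relation-type TARGET` over a fixed taxonomy of eight relation
types: five directed (`controls-state-change-of`,
`controls-phosphorylation-of`, `controls-transport-of`,
`controls-expression-of`, `catalysis-precedes`) and three undirected
(`in-complex-with`, `interacts-with`, `neighbor-of`). This reduction is
lossy — multi-input reactions, stoichiometry and chronology are gone — but
it is what makes pathway-scale overviews tractable, and it is the form in
which public pathway databases export their curation.

`pathmat` stores a parsed pathway as a `pathway_network`: a sorted protein
list plus a map from ordered protein pair `(p, q)` to the relation set
`R_pq`. Two representation choices matter downstream:

* **Orientation is part of the element.** A relation element is a
  `(type, orientation)` pair with orientation `out`, `in`, or `none`,
  expressed relative to the first protein of the pair. The dissimilarity
  measure compares how `P_i` and `P_j` each relate to a third protein
  `P_k`; if direction were discarded, a kinase and its substrate would
  look identical with respect to each other's partners, conflating
  controller and controlled. Reciprocity is maintained internally
  (`(t, out)` under `(p, q)` iff `(t, in)` under `(q, p)`), so `R_ik` and
  `R_jk` are always directly comparable.
* **Relation sets are sets.** Duplicate input lines collapse; undirected
  relations listed in either or both endpoint orders normalise to a single
  element. Database exports are inconsistent on this point, so the parser
  accepts both conventions.

Protein identity is the exact name string; identifier normalisation is a
curation task out of scope here. Nested complexes arrive through a
separate two-column TSV (`complex_id TAB member_ref`), since full pathway
exchange formats (BioPAX/OWL) are out of scope; a member reference that
names another complex creates nesting, and membership is validated to be
acyclic before use.

## The dissimilarity measure

For proteins `P_i`, `P_j` in a pathway with proteins `P_1..P_n`:

$$\mathrm{Dis}(P_i, P_j) = \sum_{k=1}^{n}\bigl(|U_{ijk}| - w\,|C_{ijk}|\bigr)$$

with `C_ijk = R_ik ∩ R_jk`, `U_ijk` the symmetric difference, and
`|U_ijk| = |R_ik| + |R_jk| − 2|C_ijk|`. Substituting gives the equivalent
form `Σ_k(|R_ik| + |R_jk| − (2+w)|C_ijk|)`, which is what the matrix
routine computes; the test suite asserts the two formulations agree
everywhere.

Decisions embedded in the implementation:

* **The sum runs over all `n` proteins, including `k = i` and `k = j`.**
  Self relation sets are empty, so these two terms each contribute
  `|R_ij|` to the uncommon part, and the diagonal is forced to
  `−w·Σ_k|R_ik|`. Skipping the pair itself would be defensible, but the
  summation bounds are taken literally and the consequence documented.
* **`w` is a non-negative integer, default 1.** `w = 0` compares proteins
  purely by uncommon relations; large `w` rewards shared partners, and the
  measure then goes negative exactly when
  `Σ_k|U_ijk| < w·Σ_k|C_ijk|` — negative values are meaningful ("more
  alike than different"), not an error. Integer `w` keeps all
  dissimilarities integral, which makes tie-breaking exact.
* **Complexity.** The full matrix is computed as one sparse cross-product:
  writing `M` for the binary incidence of proteins over
  (third protein, relation element) pairs, `Σ_k|C_ijk|` is the inner
  product of rows `i` and `j`, so
  `Dis = T ⊕ T − (2+w)·MMᵀ` with `T` the per-protein element totals.
  This is exact (integer arithmetic throughout) and makes 150-protein,
  ~7,500-relation pathways a sub-second computation where the naive
  triple loop takes minutes.

## Ordering

Two orderings are provided. `order_by_name` sorts case-insensitively with
a case-sensitive tiebreak, which clusters protein families that share name
stems. `order_by_similarity` is a greedy nearest-neighbour chain: start at
a protein, repeatedly append the unplaced protein with minimum
dissimilarity to the *most recently placed* protein.

"Append by similarity" is ambiguous between chaining from the last-placed
protein and attaching to the growing set; the chain variant is implemented
as the simplest reading of adding successive proteins one at a time, and
only this variant is offered. The original formulation seeds the chain
with a random protein; for reproducibility the default start is the
lexicographically first protein, with an explicit start protein or a
seeded random start available. Ties in the argmin break
lexicographically, so the ordering is a pure function of
(network, `w`, start).

## Grouping by structural equivalence

A single-pass leader algorithm over proteins in lexicographic order: each
protein joins the first leader whose relation profile matches, else founds
a new group. One pass suffices because profile identity is an equivalence
relation; the scan order only determines *which* member becomes leader.

The profile comparison excludes the candidate pair itself: `p` matches
leader `q` iff `R_pk = R_qk` for every `k ∉ {p, q}`. Whether the mutual
entry should also have to match is genuinely open; the exclusion rule is
this package's choice, made so that two proteins related to each other
(say, mutual neighbours) but otherwise identical can still group — the
mutual entry can never match symmetrically except when empty. Collapsing
replaces each group by a node labelled `LEADER (+k)`, inherits the
leaders' relations between groups, and stashes within-group relations as
self-cell metadata rather than as self-pairs (which the network model
forbids). Group size is exposed for label-darkness rendering.

## The Venn summary

`summarize_relations` counts, per relation type, the unordered protein
pairs carrying that type (a type present in both directions counts once —
frequency is over pairs, not relation instances, a convention this package
fixes since either reading is defensible), plus pairwise co-occurrence
counts. The layout assigns each type a circle of area exactly equal to its
count (radius `sqrt(count/π)`, analytic, never fitted) and then minimises

$$\mathrm{stress} = \sum_{s<t}\bigl(\mathrm{target}(s,t) - \mathrm{lens}(s,t)\bigr)^2$$

over circle centers, where the target overlap is the co-occurrence count
on the same area scale and `lens` is the closed-form two-circle
intersection area. Only pairwise overlaps enter the objective; triple
overlaps are unconstrained, matching the two-way semantics of the summary
and keeping the gradient closed-form (the derivative of the lens area with
respect to center distance is minus the chord length). Optimisation is
gradient descent with backtracking line search from a seeded circular
arrangement; defaults `max_iter = 1000`, `tol = 1e-9` on stress
improvement. The recorded stress trace is non-increasing by construction
(backtracking never accepts a worse configuration). Exact-area Euler
diagrams are impossible in general; attainable two-circle targets
(disjoint, containment, partial overlap) converge to well under 5%
relative area error, which the tests assert.

## Complex hierarchies

Complex "size" is the number of *distinct* proteins in the transitive
closure, not the direct member count — shared subunits deduplicate. The
listing sorts by size descending (name tiebreak), then applies a bounded
stable repair pass moving any complex that precedes one of its ancestors
to just after its last ancestor, so a nested complex always appears below
every parent even when it is larger than unrelated complexes; a
topological fallback guards the (never observed) case of the pass not
settling. Arc data connect listing positions along direct membership
edges reachable from a selected complex, with thickness proportional to
the sub-complex protein count and saturation `s₀·decay^(level−1)`
(defaults `s₀ = 1`, `decay = 0.6` — rendering constants, configurable, not
data). The matrix overlay counts, per cell, the selected complexes whose
closure contains both the row and the column protein; counting covering
complexes (rather than maximum nesting depth) is the documented choice.

## Rendering and the lens

Matrix cells carry one 45° circular sector per visible relation element:
directed types appear in the (row = source, column = target) cell only;
undirected types mirror into both cells. Each type owns a fixed angular
slot in every cell, so orientation works as a secondary identification
channel alongside color; dividing the circle among only the types present
in a cell would destroy that constancy. Colors follow the taxonomy
defaults (red `controls-state-change-of`, blue `neighbor-of`, cyan
`in-complex-with`, yellow `controls-transport-of`; the other four from a
colorblind-safe palette), identical in matrix cells and Venn circles.

The lens is bifocal (piecewise-linear): cell widths inside the focus range
scale by the magnification, all outside widths scale by the single factor
that conserves total extent exactly. A continuous fisheye would look
smoother but has no exact arithmetic contract; the bifocal transform is
testable to machine precision (conservation to 1e−9 and strict
monotonicity are asserted on 1000 random configurations). Magnifications
large enough to drive outside widths non-positive clamp the outside cells
to 0.1% of the extent with a warning. All output is static SVG 1.1 built
as text and parsed back with `xml2` in the tests; animation, hover and
brushing are interaction concerns deliberately out of scope — the command
layer selects focus, complexes and grouping *before* rendering.

## The fixture generator

`fixture_spec()` defaults describe the study conditions the package is
exercised under: 150 proteins and 0.8 expected relations per unordered
pair (≈7,500 typed relations — the scale of a large curated pathway),
two planted structurally identical groups (sizes 8 and 5), a single
community, and complex nesting distance 3. Relations are sampled per pair
and type as independent Bernoulli draws with probability
`density × type_weight` (uniform type weights by default), random
direction for directed types. Planted group members receive one shared
external profile (3–6 background targets, identical types and directions)
and no other relations, so their structural equivalence is exact;
multi-community specs never draw cross-community relations, so the
relation graph splits into at least that many components. Everything is
deterministic given the seed, which written fixtures record in a comment
header.

What the generator does *not* emulate: scale-free degree distributions,
correlated relation types (real `in-complex-with` edges cluster into
cliques), near-miss structural equivalence, or curation noise. Passing
tests therefore demonstrate algorithmic correctness on networks with the
right size, sparsity and planted structure — not robustness to the full
messiness of real exports. Pathway-specific published figures (particular
nucleoporin or ubiquitin groups, particular component splits) depend on
specific database exports and are deliberately not asserted; users can
run their own Pathway Commons SIF through `cmd_render`/`cmd_stats`.

Test and acceptance problem sizes (8–24 proteins for oracle
cross-checks, 18–40 for grouping recovery over 100 seeds, 60–150 for
pathway-scale statistics) were chosen to exercise every code path while
keeping the whole suite comfortably under a minute.

## Known limitations

* The dissimilarity includes the `k = i, j` terms (see above); relative
  rankings are unaffected but absolute values differ by `2|R_ij|` from a
  pair-excluding variant.
* Greedy chaining is a heuristic; it is not an optimal seriation and can
  lock in early mistakes. It is, however, exactly reproducible.
* The Venn layout optimises pairwise overlaps only and can settle in
  local minima for 4+ mutually overlapping types; the reported stress
  makes the residual visible.
* Grouping is exact-identity only; relaxed multi-level grouping with a
  dendrogram is future work.
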