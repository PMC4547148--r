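# pathmat

Adjacency-matrix views of binary protein relations in biological pathways.

Pathway databases export curated reaction networks as binary relations
between proteins (the simple interaction format, SIF): statements such as
`RAF1 controls-phosphorylation-of MEK1`, drawn from a fixed taxonomy of
eight relation types — five directed (`controls-state-change-of`,
`controls-phosphorylation-of`, `controls-transport-of`,
`controls-expression-of`, `catalysis-precedes`) and three undirected
(`in-complex-with`, `interacts-with`, `neighbor-of`). Node-link drawings of
these networks degrade into hairballs at a few hundred proteins. `pathmat`
instead renders the pathway as an adjacency matrix whose cells carry
colored 45° circular sectors (one fixed angular slot and color per relation
type), and supplies the analysis machinery that makes a matrix view useful:

* **Set-based dissimilarity.** With `R_ij` the set of relations between
  proteins `P_i` and `P_j`, the dissimilarity of `P_i` and `P_j` is

  ```
  Dis(P_i, P_j) = Σ_k ( |U_ijk| − w·|C_ijk| )
  ```

  where `C_ijk = R_ik ∩ R_jk` are the relations the two proteins share with
  respect to a third protein `P_k`, `U_ijk` is the symmetric difference
  (`|U_ijk| = |R_ik| + |R_jk| − 2|C_ijk|`), and the integer weight `w ≥ 0`
  sets the reward for shared relations (`w = 0` counts only uncommon
  relations; large `w` makes heavily co-related pairs strongly negative,
  i.e. very similar).
* **Seriation.** A greedy nearest-neighbour chain orders the matrix so
  that similar proteins are adjacent, exposing modules and disconnected
  sub-pathways; lexicographic name ordering is also provided.
* **Structural-equivalence grouping.** A single-pass leader algorithm
  collapses proteins with identical relation profiles into one labelled
  group node (`LEADER (+k)`), shrinking dense pathways dramatically.
* **Venn summary.** Relation-type frequencies and co-occurrence over
  protein pairs, laid out as area-proportional circles by stress-minimising
  gradient descent (a Wilkinson-style approximation).
* **Complex hierarchies.** Nested protein complexes (a DAG — complexes
  share members and parents) with size-ordered listings, arc-diagram
  geometry, and a membership overlay that darkens matrix cells covered by
  many complexes.
* **Static SVG rendering** of all three views, with an optional bifocal
  lens that magnifies a focal band while exactly conserving total extent.
* **Synthetic fixtures.** A seeded generator plants structurally identical
  groups, relation-disjoint communities and nested complexes at
  pathway-database scale, so everything is testable without downloads.

## Worked example

```r
library(pathmat)

lines <- c("RAF1\tcontrols-phosphorylation-of\tMEK1",
           "MEK1\tcontrols-phosphorylation-of\tERK1",
           "MEK1\tcontrols-phosphorylation-of\tERK2",
           "ERK1\tneighbor-of\tERK2",
           "RAF1\tin-complex-with\tMEK1")
p <- tempfile(); writeLines(lines, p)
net <- read_sif(p)

dissimilarity_matrix(net, w = 1L)
#>      ERK1 ERK2 MEK1 RAF1
#> ERK1   -2    1    6    4
#> ERK2    1   -2    6    4
#> MEK1    6    6   -4    6
#> RAF1    4    4    6   -2

order_by_similarity(net, w = 1L)$sequence
#> [1] "ERK1" "ERK2" "RAF1" "MEK1"

g <- group_by_similarity(net)
g$collapsed$proteins
#> [1] "ERK1 (+1)" "MEK1"      "RAF1"
```

The negative diagonal is forced by the definition (a protein shares all of
its relations with itself, so the diagonal is `−w·Σ_k|R_ik|`). ERK1 and
ERK2 are structurally equivalent — both are phosphorylated by MEK1, and
their mutual `neighbor-of` link is excluded from the profile comparison —
so grouping collapses them into the node `ERK1 (+1)`. Rendering follows the
same pattern:

```r
cmd_render(p, "out/", order = "similarity", w = 1L)   # matrix.svg, venn.svg, ...
```

or from a shell via the installed `exec/pathmat` script:

```sh
pathmat render --input pathway.sif --out-dir out --order similarity --w 1
pathmat stats  --input pathway.sif
```

Users with their own Pathway Commons SIF export can point `cmd_render` /
`pathmat render` at it directly; only the eight relation types above are
accepted.

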