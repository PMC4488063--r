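# topocomp

Topological comparison of large sets of phylogenetic trees.

Modern phylogenetic studies routinely produce many competing topologies —
optimal and near-optimal trees, trees from different data partitions,
alignment methods, cost schemes or optimality criteria — often with
hundreds or thousands of terminals. `topocomp` gives systematists one
toolkit to compare them:

- **Topological distances.** Every tree is reduced to its set of
  *elements* — unrooted splits (bipartitions) or rooted clades, chosen by
  the user. For two trees with element sets `E1`, `E2` the **local
  distance** is

      d(T1, T2) = 1 − |E1 ∩ E2| / |E1 ∪ E2|

  and the **global distance** normalizes by the element universe of the
  whole run (the union over all `n` trees being compared):

      D(T1, T2) = 1 − |E1 ∩ E2| / |∪_{i∈n} E_i|

  Both range over [0, 1]; the fewer the shared splits or clades, the
  larger the distance. `D ≥ d` always, and `D` is comparable across pairs
  of the same run.

- **Sensitivity analysis.** Which clades survive across analytical
  conditions? `score_sensitivity()` scores each reference-tree element as
  present/absent per condition (strict rule by default, majority rule
  optional) and `render_sensitivity_svg()` draws one filled/open grid
  ("navajo rug") per element, named `node_<id>.svg` after the reference
  tree's preorder node numbers for easy manual figure editing.

- **Rogue (wildcard) taxon detection.** The **matching split distance**
  (MSD) is the minimum-cost perfect matching between two trees' split
  sets, where pairing two splits costs the fewest terminals that must
  switch sides to make them equal (unmatched splits pair with dummies at
  cost `min(|A|,|B|)`). Because MSD reacts to the displacement of even a
  single terminal, `rank_rogues()` can rank every terminal by the average
  MSD of the tree set after pruning it: terminals whose removal drops the
  average MSD the most are the unstable wildcards destroying consensus
  resolution.

- **Synapomorphy diagnosis.** `classify_transformations()` optimizes a
  character matrix (simplified NEXUS) on a tree with an internal
  unordered-parsimony engine, compares the ACCTRAN and DELTRAN extreme
  resolutions, and categorizes every inferred state change as ambiguous
  or unambiguous, the unambiguous ones further as *unique &
  non-homoplastic*, *unique & homoplastic* or *non-unique & homoplastic*,
  with CSV tables and annotated tree SVGs.

Trees are plain [ape](https://cran.r-project.org/package=ape) `phylo`
objects; readers are included for Newick files, a TNT-style parenthetical
dialect (whitespace separators, numeric taxon indices), and simplified
NEXUS character matrices. A seeded generator (`random_tree()`,
`spr_perturb()`, `plant_wildcard()`, `random_matrix()`) produces synthetic
tree sets and matrices for testing and benchmarking.

## Worked example

Five trees — a 12-taxon base topology and four light SPR perturbations of
it — plus a planted wildcard:

```r
library(topocomp)

base  <- random_tree(12, seed = 7)
trees <- c(list(base),
           lapply(1:4, function(i) spr_perturb(base, moves = 1, seed = 100 + i)))

res <- pairwise_matrices(trees, mode = "splits")
res
#> Topological distances (splits mode): 5 trees, 12 taxa, universe of 16 elements
#>   mean local d:  0.4152
#>   mean global D: 0.5938

round(res$local, 3)
#>        tree#0 tree#1 tree#2 tree#3 tree#4
#> tree#0  0.000  0.200  0.364  0.200  0.615
#> tree#1  0.200  0.000  0.200  0.364  0.615
#> tree#2  0.364  0.200  0.000  0.364  0.615
#> tree#3  0.200  0.364  0.364  0.000  0.615
#> tree#4  0.615  0.615  0.615  0.615  0.000
```

Tree 0 shares 8 of its 9 nontrivial splits with tree 1 (union of 10, so
`d = 1 − 8/10 = 0.2`); tree 4's single perturbation happened to move a
deep subtree, so it disagrees more with everything. Now graft a wildcard
terminal onto a different random branch of each tree and ask which
terminal explains the disagreement:

```r
wild <- plant_wildcard(trees, "WILDCARD", seed = 11)
rank_rogues(wild)
#> Leave-one-out rogue ranking (baseline average MSD = 11.7)
#>    rank terminal avg_msd_after_pruning baseline_avg_msd
#> 1     1 WILDCARD                   7.2             11.7
#> 2     2       t9                   8.2             11.7
#> 3     3      t11                   9.4             11.7
#> ...
```

Pruning `WILDCARD` lowers the average matching split distance from 11.7
to 7.2 — more than pruning any real terminal — so it is correctly flagged
as the top rogue candidate. Finally, a parsimony diagnosis of a character
matrix evolved on the base tree:

```r
cm   <- random_matrix(NULL, 10, c("0", "1"), seed = 13,
                      tree = base, change_prob = 0.1)
recs <- classify_transformations(base, cm)
head(as.data.frame(recs), 4)
#>   character child_node child_label from to   ambiguity              category
#> 1         0         NA         t11    0  1 unambiguous nonunique-homoplastic
#> 2         0         NA          t5    0  1 unambiguous nonunique-homoplastic
#> 3         0          9        <NA>    0  1 unambiguous nonunique-homoplastic
#> 4         1          5        <NA>    1  0 unambiguous unique-nonhomoplastic
attr(recs, "total_length")
#> [1] 15
```

Character 1 changes once on the branch above internal node 5 — a clean,
unique, non-homoplastic synapomorphy of that clade — while character 0
needs three parallel gains of state 1. `write_diagnosis()` writes the
table as CSV (with the total tree length of 15 in the footer) and an SVG
of the tree with one color-coded glyph per record.

## Command-line usage

A thin front end over the same functions ships at
`inst/cli/topocomp.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/topocomp.R", package = "topocomp"))')
Rscript $CLI simulate --config run.cfg --init   # write a template config
Rscript $CLI dist  --config run.cfg             # local/global CSV matrices
Rscript $CLI sens  --config run.cfg --grid 2x3  # navajo-rug SVGs + CSV
Rscript $CLI rogue --config run.cfg             # leave-one-out ranking CSV
Rscript $CLI diag  --config run.cfg             # diagnosis CSV + SVG
```

The configuration grammar (sectioned `key = value`; `[run]`, `[trees]`,
`[conditions]`, `[simulate]`) is documented in `?parse_config`, and
unknown keys are rejected rather than ignored.

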