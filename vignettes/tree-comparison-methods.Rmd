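---
title: "Methods: element-based tree comparison, rogue detection, and synapomorphy diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: element-based tree comparison, rogue detection, and synapomorphy diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topocomp)
```

This vignette is the package's own account of the methods it implements:
the models and conventions, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Elements: splits and clades

Every comparison in `topocomp` reduces a tree to a set of *elements*.

In **splits mode** an element is a nontrivial bipartition of the taxon
set: the partition induced by deleting one internal edge of the unrooted
form of the tree. Bipartitions separating a single leaf are present in
every tree on the same taxa and are excluded; so is the duplicate
bipartition defined by the two root-adjacent edges of a rooted binary
tree. A fully resolved unrooted tree on *n* leaves therefore has *n* − 3
elements, and the split set is invariant under rerooting.

In **clades mode** an element is the leaf set descending from one
internal node of a *rooted* tree, excluding the root (whose clade is the
full taxon set) and the leaves. A rooted binary tree on *n* leaves has
*n* − 2 such clades. Clade sets change under rerooting, which is why
clades mode demands rooted input — supply an outgroup via
`reroot_outgroup()` when trees arrive unrooted. Rooting is judged by the
basal dichotomy convention of `ape`.

Internally each element is a fixed-width bitmask over a shared
`taxon_index` whose order is the sorted order of the labels, so it is
identical across runs and machines. Splits are canonicalized to the side
*not* containing the first indexed taxon; a split and its complement
therefore hash identically. The only contract is exact element equality
— masks are fingerprinted and compared as sets.

Multifurcations are accepted everywhere. Consensus trees — the dominant
real-world input for sensitivity analysis — are multifurcating, and all
the definitions above are stated for general trees; the *n* − 3 / *n* − 2
counts are simply upper bounds reached by binary trees. Branch lengths
and internal labels are parsed and discarded: every computation here is
purely topological.

### Distances

For element sets $E_1, E_2$ and a run of $n$ trees:

$$d(T_1,T_2) = 1 - \frac{|E_1 \cap E_2|}{|E_1 \cup E_2|}, \qquad
  D(T_1,T_2) = 1 - \frac{|E_1 \cap E_2|}{|\bigcup_{i \in n} E_i|}.$$

*d* is a Jaccard distance on element sets: 0 for identical sets, 1 for
disjoint ones. *D* replaces the pairwise union by the pooled element
universe of the whole run, making values comparable across pairs at the
cost of a nonzero self-distance; $D \ge d$ always, with equality when the
run holds exactly the two trees. When several input files are given they
are pooled into one universe — the run, not the file, is the unit of
comparison.

Two degenerate conventions are fixed by the package:

* If both element sets are empty (two star trees), $d$ is defined as 0:
  the trees are topologically indistinguishable, and the formula's 0/0 is
  resolved in favor of identity.
* Trees with unequal leaf sets are an error by default; silent pruning
  hides data errors. An explicit `prune_to_common = TRUE` restricts all
  trees to the leaf intersection (suppressing the degree-2 nodes that
  pruning leaves behind) before extraction.

Distance matrices are written as CSV with 6 decimal places and tree
identifiers `<filename>#<k>` (k = 0-based position within the file), so
artifacts are diff-stable and multi-tree files remain addressable.

## Sensitivity analysis

Conditions (one per assumption set: a cost scheme, an alignment, a search
strategy...) each contribute one or more trees. Every element of a
user-chosen reference tree is scored present or absent per condition.
The default is the **strict rule** — present only if the element occurs
in *every* tree of the condition — mirroring strict consensus, which is
the framing under which losing a clade to a single aberrant tree is
informative. The rule is deliberately conservative; `rule = "majority"`
with a threshold relaxes it. A consequence of the strict rule, asserted
in the tests, is monotonicity: removing trees from a condition can only
turn absences into presences.

Elements are labeled by the preorder number of the reference-tree node
that defines them (root first, children in input order, leaves skipped),
and each element gets one SVG named `node_<id>.svg`: a rows × columns
grid of cells in row-major condition order, filled when present, open
when absent. Grid shape, colors, cell size and margins are parameters
with fixed defaults (row-major `1 × k` grid, `#1f3b73` on white, 24 px
cells, 6 px margins); the grid must multiply exactly to the number of
conditions because the arrangement of a parameter grid is meaning the
user supplies, not something the package can infer.

## Matching split distance and rogue detection

The element distances above are deliberately coarse: one displaced
terminal destroys every split on its path to its new position. That
sensitivity is a *feature* for rogue detection. The **matching split
distance** between two trees on one leaf set is the minimum-total-cost
perfect matching between their split sets, where

* pairing splits $A|B$ and $C|D$ costs
  $\min(|A \triangle C|, |A \triangle D|)$ — the fewest terminals that
  must switch sides to make the bipartitions equal (computed as
  $\min(m, n-m)$ with $m = |A \triangle C|$, since $D$ is the complement
  of $C$);
* when the split sets have unequal sizes, the smaller is padded with
  dummy splits costing $\min(|A|,|B|)$ against a real split $A|B$ and 0
  against another dummy.

The assignment problem is solved exactly by an $O(k^3)$ Hungarian
algorithm with row/column potentials, written in the package because no
exact linear-assignment solver is available among its dependencies; the
test suite anchors it to a brute-force permutation minimum on every
instance small enough to enumerate, and asserts the pseudometric
properties (identity on equal split sets, symmetry, triangle inequality)
on seeded random triples.

`rank_rogues()` applies the leave-one-out scheme: for each terminal,
prune it from every tree (suppressing degree-2 nodes), recompute the
average MSD over all unordered pairs, and sort ascending. The terminals
whose removal yields the lowest average MSD are the candidate wildcards.
The report always includes the no-pruning baseline so the improvement
each removal buys is visible, and ties are broken lexicographically by
label so reports are deterministic. Self-pairs are excluded from the
average; duplicated input trees are kept — if the user supplied them,
they are part of the comparison. Ranking by lowest absolute average or
by largest drop from baseline coincide, since the baseline is one
constant per run.

## Parsimony diagnosis

Characters are unordered (Fitch-style) with unit cost; ordered or
step-matrix characters are out of scope. The engine is a dynamic program
over the unit substitution cost — for each node $v$ and state $s$, the
minimal cost of the subtree of $v$ with $v = s$ — which handles
multifurcations directly and gives the parsimony length at the root.
Each character's alphabet is the set of states *observed in its column*;
missing data (`?`, and `-` by default, with `gap_as_state = TRUE` to
treat gaps as a real fifth state) expands to that full observed
alphabet, so an unscored leaf can never add a change on its own terminal
branch.

"All possible optimization schemes" is operationalized as agreement
between the two classical extreme resolutions:

* **ACCTRAN** resolves each tie toward a state *different* from the
  parent, placing changes as close to the root as possible (early gains,
  later reversals);
* **DELTRAN** resolves ties toward the parent state, delaying changes
  tipward (parallel gains).

Both are produced by conditional arg-min preorder assignment over the
dynamic program, so each is provably most-parsimonious — their change
counts always equal the parsimony length, which the tests verify against
an exhaustive enumeration of all internal-node labelings on small trees.
Remaining ties go to the alphabetically smallest state, and leaves with
ambiguous observations prefer the parent's state under both variants
(the missing-data rule takes precedence over acceleration). Full
enumeration of the entire most-parsimonious-reconstruction set is kept
to the test oracle: its size is exponential in the worst case, and the
ACCTRAN/DELTRAN-agreement criterion is the standard practical surrogate.
Agreement with TNT's internal ambiguity bookkeeping is plausible but not
claimed.

A change on a branch is **unambiguous** when ACCTRAN and DELTRAN place
the same from→to change there, otherwise **ambiguous** (category
`not-applicable`). For unambiguous changes, two orthogonal properties
drive the three-way categorization:

* **homoplasy** is per-character: the character needs more steps than its
  minimum conceivable length (observed states − 1);
* **uniqueness** is per-state-origin: the to-state is gained on exactly
  one branch (in both resolutions).

This is precisely what makes the middle category non-empty: a state with
a single origin inside a character that wastes steps elsewhere is
*unique & homoplastic*. A non-unique, non-homoplastic change is logically
impossible — with observed-states − 1 changes every non-ancestral state
is gained exactly once — and the implementation asserts it never occurs.

Diagnosis CSVs identify the child end of each change branch by the same
preorder internal-node numbering used for sensitivity plots; leaf
children are identified by their tip label in a separate column, since a
leaves-skipped numbering cannot address them. The CSV footer carries the
summed tree length; the companion SVG draws the tree with node numbers
and one glyph per record, color-coded by category (black = unique &
non-homoplastic, orange = unique & homoplastic, open = non-unique &
homoplastic, gray = ambiguous).

## Input dialects

* **Newick**: quoted labels follow the standard convention (single
  quotes, doubled internal quotes); branch lengths and internal labels
  are accepted and discarded; degree-2 nodes are suppressed at parse
  time; duplicate or empty leaf labels and unbalanced parentheses are
  errors with character positions. The writer quotes any label containing
  whitespace or Newick punctuation, so write∘parse preserves split sets
  exactly (asserted on 200 random trees).
* **TNT parenthetical dialect**: whitespace-separated sibling groups,
  terminals as literal names or 0-based numeric indices resolved against
  a taxon order, trees separated by `*` or `;`, with an optional leading
  `tread` keyword and quoted comment. The dialect is fixed and documented
  here; unknown tokens are parse errors, never silently skipped.
* **Simplified NEXUS**: exactly one `DATA` (or `CHARACTERS`) block with
  `DIMENSIONS` and a `MATRIX` of single-character symbols. Declared
  `NTAX`/`NCHAR` are verified against the parsed content. Symbols are
  normalized to upper case. Interleaved simple matrices are accepted;
  the full NEXUS standard (TREES/ASSUMPTIONS blocks, polymorphism
  braces) is not.

## Synthetic data: what it emulates and what it does not

The generator exists so every workflow is testable end-to-end from a
single integer seed, with no external files.

* `random_tree(n, seed)` draws a binary rooted topology over `t1..tn` by
  recursive random splitting (`ape::rtree` without branch lengths). The
  topology distribution is not Yule- or coalescent-calibrated, and no
  model of branching times is implied — irrelevant here, because every
  method in the package is purely topological.
* `spr_perturb(tree, moves, seed)` applies subtree-prune-regraft moves
  (detach a non-root subtree, reattach onto a uniformly chosen branch of
  the remainder), the standard knob for a controlled amount of
  topological disagreement. One move displaces one subtree; light
  perturbation (1–2 moves) emulates near-optimal tree sets.
* `plant_wildcard(trees, label, seed)` grafts one new terminal onto an
  independently chosen random branch of each tree — the ground-truth
  construction for rogue detection: when the base trees agree, the
  planted terminal is the *only* source of disagreement and pruning it
  restores identical topologies (average MSD exactly 0).
* `random_matrix(...)` draws i.i.d. uniform states, or evolves
  characters along a tree from a uniform root state with a fixed
  per-branch change probability (default 0.15), recording the simulated
  change branches so single-gain characters can be checked against the
  reconstruction.

Sub-streams are derived from the master seed by index, so generating
more trees never shifts the earlier ones. What passing these tests shows
is that the algorithms are correct on trees whose disagreement structure
is known by construction. What they do *not* show: robustness to the
systematic signal structure of real data (correlated characters, clocklike
or highly unbalanced trees, taxon sampling artifacts), nor anything about
branch lengths, which the package ignores by design.

## Problem sizes and numerical notes

The shipped checks run at the following scales, chosen as the smallest
sizes at which each property is non-trivial while keeping the whole
suite fast on a laptop: distance-oracle equivalence on 100 pairs of
16-taxon trees; assignment-solver exactness on 50 pairs with ≤ 6 splits
per tree plus 100 random triples for the pseudometric; wildcard recovery
on 10 replicates of 5 × 21-taxon trees; parsimony-oracle equivalence on
200 cases of ≤ 8 leaves × ≤ 3 states; category exhaustion over 1000
random characters; and one desk-scale feasibility run of all pairwise
distances among 100 random 1000-leaf trees (about half a minute).

All distances are ratios of small integer counts, so floating-point
comparisons in the package's own invariant checks use a `1e-12` slack
only where two independently computed ratios are compared. Transfer
costs and MSD values are exact integers. The Hungarian solver operates
on integer cost matrices embedded in doubles, far below the precision
where ties could be misresolved.

## Known limitations

* Clades mode follows `ape`'s basal-dichotomy convention for rootedness;
  a consensus tree with a root polytomy must be rerooted on an outgroup
  before clade extraction.
* Rerooting requires the outgroup to be displayable as one side of an
  edge; paraphyletic "outgroups" are rejected rather than approximated.
* The MSD dummy-split convention (`min(|A|,|B|)` against a real split)
  is fixed by this package; other matching-distance implementations may
  pad differently, so absolute MSD values are comparable only within one
  convention. Rankings, which is what rogue detection consumes, are
  robust to this choice in the tested constructions.
* Diagnosis reports the two extreme resolutions only; branches where
  other most-parsimonious reconstructions disagree but ACCTRAN and
  DELTRAN coincide are reported as unambiguous. This is the standard
  practical criterion, but it is a surrogate for full MPR enumeration.
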