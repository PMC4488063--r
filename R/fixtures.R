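# Seeded synthetic data: random topologies, SPR-perturbed tree sets,
# planted wildcards and character matrices, so every workflow can be
# exercised end-to-end without external data.

# Independent sub-streams from one master seed: stream i never shifts when
# streams before it draw a different number of variates.
sub_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(i) * 7919L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded random binary rooted tree
#'
#' Draws a random binary rooted topology over terminals `t1..tn` by
#' recursive random splitting (no branch lengths; every method in this
#' package is purely topological, so the branching-time model is
#' immaterial). Identical seeds reproduce identical trees byte-for-byte.
#'
#' @param n_taxa Number of terminals (at least 3).
#' @param seed Integer seed.
#' @return A binary rooted `phylo` object without edge lengths.
#' @export
random_tree <- function(n_taxa, seed) {
  if (n_taxa < 3L) stop("need at least 3 taxa", call. = FALSE)
  with_seed(seed, ape::rtree(n_taxa, br = NULL))
}

#' Perturb a tree by random SPR moves
#'
#' Applies `moves` random subtree-prune-regraft rearrangements: a non-root
#' subtree is detached (suppressing the degree-2 node left behind) and
#' reattached onto a uniformly chosen branch of the remainder. `moves = 0`
#' returns the topology unchanged. Used to generate tree sets with a
#' controlled amount of topological disagreement.
#'
#' @param tree A `phylo` object with at least 4 leaves.
#' @param moves Nonnegative number of SPR moves.
#' @param seed Integer seed.
#' @return A `phylo` object on the same leaf set.
#' @export
spr_perturb <- function(tree, moves, seed) {
  stopifnot(inherits(tree, "phylo"), moves >= 0L)
  if (moves == 0L) return(tree)
  with_seed(seed, {
    for (i in seq_len(moves)) tree <- spr_once(tree)
    tree
  })
}

spr_once <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  repeat {
    e <- sample.int(nrow(tree$edge), 1L)
    v <- tree$edge[e, 2L]
    subtips <- if (v <= n) tree$tip.label[v] else
      ape::extract.clade(tree, v)$tip.label
    if (length(subtips) > n - 3L) next  # remainder must stay a tree
    rest <- ape::drop.tip(tree, subtips)
    te <- sample.int(nrow(rest$edge), 1L)
    tchild <- rest$edge[te, 2L]
    out <- if (length(subtips) == 1L) {
      phytools::bind.tip(rest, subtips, edge.length = 1,
                         where = tchild, position = 0.5)
    } else {
      sub <- ape::extract.clade(tree, v)
      sub$root.edge <- 1
      ape::bind.tree(rest, sub, where = tchild, position = 0.5)
    }
    out$edge.length <- NULL
    return(as_clean_phylo(out))
  }
}

#' Plant a wildcard terminal into a set of trees
#'
#' Grafts one new terminal onto an independently chosen random branch of
#' each tree — the ground-truth construction for wildcard detection: the
#' planted terminal is the only source of disagreement when the base
#' trees agree, so pruning it restores identical topologies.
#'
#' @param trees List of `phylo` objects, none already containing `label`.
#' @param label Name of the new terminal.
#' @param seed Integer seed; tree `i` uses sub-stream `i`, so earlier
#'   trees are unaffected by how many follow.
#' @return List of `phylo` objects, each with one extra leaf.
#' @export
plant_wildcard <- function(trees, label, seed) {
  stopifnot(length(trees) >= 1L, is.character(label), nzchar(label))
  clash <- vapply(trees, function(t) label %in% t$tip.label, logical(1))
  if (any(clash))
    stop("label '", label, "' already present in tree(s) ",
         paste(which(clash), collapse = ", "), call. = FALSE)
  lapply(seq_along(trees), function(i) {
    with_seed(sub_seed(seed, i), {
      tr <- trees[[i]]
      tr$edge.length <- rep(1, nrow(tr$edge))
      e <- sample.int(nrow(tr$edge), 1L)
      out <- phytools::bind.tip(tr, label, edge.length = 1,
                                where = tr$edge[e, 2L], position = 0.5)
      out$edge.length <- NULL
      as_clean_phylo(out)
    })
  })
}

#' Generate a seeded character matrix
#'
#' Without a tree, each cell is an independent uniform draw from the
#' alphabet. With a tree, characters evolve along the topology from a
#' uniform root state with a fixed per-branch change probability (a new
#' state is drawn uniformly among the other symbols), so true
#' synapomorphies exist; the simulated change branches are recorded in
#' the `"true_changes"` attribute (`char`, `child` as ape node id,
#' `from`, `to`).
#'
#' @param taxa Character vector of terminal labels (ignored when `tree`
#'   is given: the tree's tip labels are used).
#' @param n_characters Number of characters (at least 1).
#' @param alphabet Character vector of state symbols.
#' @param seed Integer seed.
#' @param tree Optional `phylo` to evolve the characters on.
#' @param change_prob Per-branch change probability when evolving on a
#'   tree.
#' @return A `character_matrix`.
#' @export
random_matrix <- function(taxa, n_characters, alphabet, seed,
                          tree = NULL, change_prob = 0.15) {
  stopifnot(n_characters >= 1L)
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0L) stop("empty alphabet", call. = FALSE)
  if (is.null(tree)) {
    raw <- with_seed(seed, matrix(sample(alphabet,
                                         length(taxa) * n_characters,
                                         replace = TRUE),
                                  nrow = length(taxa)))
    rownames(raw) <- as.character(taxa)
    return(new_character_matrix(raw))
  }
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- root_node(tree)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]
  raw <- matrix(NA_character_, n_tip, n_characters,
                dimnames = list(tree$tip.label, NULL))
  changes <- list()
  for (j in seq_len(n_characters)) {
    with_seed(sub_seed(seed, j), {
      st <- character(n_nodes)
      st[root] <- sample(alphabet, 1L)
      for (i in seq_len(nrow(pre))) {
        par <- pre[i, 1L]; child <- pre[i, 2L]
        if (length(alphabet) > 1L &&
            stats::runif(1) < change_prob) {
          st[child] <- sample(setdiff(alphabet, st[par]), 1L)
          changes[[length(changes) + 1L]] <-
            data.frame(char = j, child = child, from = st[par],
                       to = st[child], stringsAsFactors = FALSE)
        } else st[child] <- st[par]
      }
      raw[, j] <- st[seq_len(n_tip)]
    })
  }
  out <- new_character_matrix(raw)
  attr(out, "true_changes") <- if (length(changes))
    do.call(rbind, changes) else
    data.frame(char = integer(0), child = integer(0),
               from = character(0), to = character(0))
  out
}
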