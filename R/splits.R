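#' Build the shared taxon universe for a tree comparison
#'
#' All trees in a comparison must address the same ordered taxon universe.
#' By default every tree must carry the identical leaf-label set; any
#' mismatch is an error that lists the offending labels, because silent
#' pruning hides data errors. With `prune_to_common = TRUE` the index is
#' built over the intersection of all leaf sets instead, and trees should
#' then be restricted with [conform_tree()].
#'
#' @param trees A list of `phylo` objects.
#' @param prune_to_common Build the index over the intersection of leaf
#'   sets rather than requiring identical sets.
#' @return A `taxon_index` object: list with `labels` (sorted, unique) and
#'   `n`. Label order is the deterministic sorted (C-locale) order.
#' @export
build_taxon_index <- function(trees, prune_to_common = FALSE) {
  stopifnot(length(trees) >= 1L)
  sets <- lapply(trees, function(t) t$tip.label)
  common <- Reduce(intersect, sets)
  union_all <- Reduce(union, sets)
  if (!prune_to_common && length(common) < length(union_all)) {
    diff <- sort(setdiff(union_all, common))
    stop("trees do not share one leaf-label set; labels absent from ",
         "some tree: ", paste(diff, collapse = ", "),
         " (use prune_to_common to restrict to the intersection)",
         call. = FALSE)
  }
  if (length(common) < 3L)
    stop("fewer than 3 shared taxa", call. = FALSE)
  taxon_index(common)
}

#' @rdname build_taxon_index
#' @param labels Character vector of terminal labels.
#' @export
taxon_index <- function(labels) {
  labels <- sort(unique(as.character(labels)), method = "radix")
  structure(list(labels = labels, n = length(labels)),
            class = "taxon_index")
}

#' @export
print.taxon_index <- function(x, ...) {
  cat("Taxon index over", x$n, "terminals\n")
  invisible(x)
}

#' Restrict a tree to the taxa of an index
#'
#' Drops leaves outside the index and suppresses the resulting degree-2
#' nodes. The tree must contain every indexed taxon.
#'
#' @param tree A `phylo` object.
#' @param taxa A `taxon_index`.
#' @return A `phylo` object on exactly the indexed leaves.
#' @export
conform_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), inherits(taxa, "taxon_index"))
  missing <- setdiff(taxa$labels, tree$tip.label)
  if (length(missing))
    stop("tree lacks indexed taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(tree$tip.label, taxa$labels)
  if (length(extra) == 0L) return(tree)
  as_clean_phylo(ape::drop.tip(tree, extra))
}

# logical tip-membership masks (rows = nodes in ape numbering, columns =
# taxon-index positions), built in one postorder sweep
node_tip_masks <- function(tree, taxa) {
  n_tip <- length(tree$tip.label)
  pos <- match(tree$tip.label, taxa$labels)
  if (anyNA(pos))
    stop("tree leaves do not match the taxon index", call. = FALSE)
  if (n_tip != taxa$n)
    stop("tree has ", n_tip, " leaves but the index has ", taxa$n,
         call. = FALSE)
  n_nodes <- n_tip + tree$Nnode
  masks <- matrix(FALSE, n_nodes, taxa$n)
  masks[cbind(seq_len(n_tip), pos)] <- TRUE
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge)))
    masks[edge[i, 1L], ] <- masks[edge[i, 1L], ] | masks[edge[i, 2L], ]
  masks
}

# hex fingerprint of a logical mask; equality of keys == equality of sets
mask_key <- function(mask) {
  pad <- (-length(mask)) %% 8L
  paste(as.character(packBits(c(mask, rep(FALSE, pad)), type = "raw")),
        collapse = "")
}

#' Preorder numbering of internal nodes
#'
#' Numbers the internal nodes of a tree 1, 2, ... in a deterministic
#' preorder traversal from the root, skipping leaves. These numbers label
#' sensitivity-plot files and diagnosis records, so users can map outputs
#' back to nodes of the reference tree.
#'
#' @param tree A `phylo` object.
#' @return Integer vector over ape node ids; `NA` for leaves.
#' @export
preorder_numbers <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  ch <- children_list(tree)
  out <- rep(NA_integer_, n_nodes)
  counter <- 0L
  stack <- root_node(tree)
  while (length(stack)) {
    v <- stack[1L]
    stack <- stack[-1L]
    if (v > n_tip) {
      counter <- counter + 1L
      out[v] <- counter
      stack <- c(ch[[v]], stack)
    }
  }
  out
}

#' Extract the nontrivial splits (bipartitions) of a tree
#'
#' One split per internal edge of the unrooted form of the tree. Splits
#' separating a single leaf are trivial and excluded; the two root-adjacent
#' edges of a rooted binary tree define the same bipartition and are
#' deduplicated. Each split is stored in canonical orientation: the side
#' not containing the first indexed taxon. For a fully resolved unrooted
#' tree on n leaves the set has n - 3 elements; the split set is invariant
#' under rerooting.
#'
#' @param tree A `phylo` object whose leaves exactly match `taxa`.
#' @param taxa A `taxon_index`.
#' @return An `element_set` with `mode = "splits"`: `keys` (canonical
#'   fingerprints), `masks` (logical element x taxon matrix, canonical
#'   side), and `node_ids` (preorder internal-node number that produced
#'   each element).
#' @export
extract_splits <- function(tree, taxa) {
  masks <- node_tip_masks(tree, taxa)
  n_tip <- length(tree$tip.label)
  pre <- preorder_numbers(tree)
  root <- root_node(tree)
  internal <- setdiff(seq_len(n_tip + tree$Nnode)[-seq_len(n_tip)], root)
  keep <- list(); ids <- integer(0); keys <- character(0)
  for (v in internal) {
    m <- masks[v, ]
    sz <- sum(m)
    if (min(sz, taxa$n - sz) < 2L) next
    if (m[1L]) m <- !m  # canonical side excludes taxon index 0
    k <- mask_key(m)
    if (k %in% keys) next  # root-adjacent duplicate bipartition
    keys <- c(keys, k)
    ids <- c(ids, pre[v])
    keep[[length(keep) + 1L]] <- m
  }
  element_set("splits", taxa, keys, keep, ids)
}

#' Extract the clades of a rooted tree
#'
#' One element per internal node other than the root: the set of terminals
#' descending from that node. Leaf "clades" and the root clade are shared
#' by every tree on the same taxa and are excluded so they do not deflate
#' distances uniformly. Unlike splits, the clade set changes under
#' rerooting.
#'
#' @inheritParams extract_splits
#' @return An `element_set` with `mode = "clades"`.
#' @export
extract_clades <- function(tree, taxa) {
  if (!ape::is.rooted(tree))
    stop("clades mode needs a rooted tree: configure an outgroup ",
         "(reroot_outgroup) or supply pre-rooted input", call. = FALSE)
  masks <- node_tip_masks(tree, taxa)
  n_tip <- length(tree$tip.label)
  pre <- preorder_numbers(tree)
  root <- root_node(tree)
  internal <- setdiff(seq_len(n_tip + tree$Nnode)[-seq_len(n_tip)], root)
  keep <- lapply(internal, function(v) masks[v, ])
  keys <- vapply(keep, mask_key, character(1))
  element_set("clades", taxa, keys, keep, pre[internal])
}

element_set <- function(mode, taxa, keys, masks, node_ids) {
  m <- if (length(masks)) do.call(rbind, masks) else
    matrix(FALSE, 0L, taxa$n)
  structure(list(mode = mode, taxa = taxa, keys = keys, masks = m,
                 node_ids = node_ids),
            class = "element_set")
}

#' @export
print.element_set <- function(x, ...) {
  cat("Element set (", x$mode, "): ", length(x$keys), " elements over ",
      x$taxa$n, " taxa\n", sep = "")
  invisible(x)
}

#' Human-readable labels of an element set
#'
#' @param x An `element_set`.
#' @return Character vector; each element rendered as the sorted labels of
#'   its canonical side (splits) or its leaf set (clades).
#' @export
element_labels <- function(x) {
  stopifnot(inherits(x, "element_set"))
  apply(x$masks, 1L, function(m)
    paste(x$taxa$labels[m], collapse = "|"))
}
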