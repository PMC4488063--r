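# Independent oracles used across the suite. These deliberately avoid the
# package's bitmask/postorder code paths: splits are recovered by deleting
# one edge at a time and flood-filling the remaining graph, distances are
# computed on literal label-set strings, the matching split distance is
# minimized by enumerating all permutations, and the parsimony length is
# minimized by enumerating all internal-node state assignments.

# canonical string form of the bipartition induced by deleting one edge:
# the side not containing the alphabetically first label
oracle_split_labelsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  n_nodes <- n_tip + tree$Nnode
  out <- character(0)
  first <- min(tree$tip.label)
  for (e in seq_len(nrow(edges))) {
    adj <- edges[-e, , drop = FALSE]
    # flood fill from the child endpoint over the remaining edges
    seen <- rep(FALSE, n_nodes)
    queue <- edges[e, 2L]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- c(adj[adj[, 1L] == v, 2L], adj[adj[, 2L] == v, 1L])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    side <- sort(tree$tip.label[seen[seq_len(n_tip)]])
    if (first %in% side)
      side <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  sort(unique(out))
}

oracle_local_d <- function(t1, t2) {
  s1 <- oracle_split_labelsets(t1)
  s2 <- oracle_split_labelsets(t2)
  u <- length(union(s1, s2))
  if (u == 0L) return(0)
  1 - length(intersect(s1, s2)) / u
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

# splits as logical-side lists over sorted labels, plus n; dummy = NULL
oracle_msd <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  sides <- function(tree) {
    sets <- oracle_split_labelsets(tree)
    lapply(sets, function(s) labs %in% strsplit(s, "|", fixed = TRUE)[[1L]])
  }
  s1 <- sides(t1); s2 <- sides(t2)
  k <- max(length(s1), length(s2))
  if (k == 0L) return(0)
  pad <- function(s) c(s, rep(list(NULL), k - length(s)))
  s1 <- pad(s1); s2 <- pad(s2)
  pair_cost <- function(a, b) {
    if (is.null(a) && is.null(b)) return(0)
    if (is.null(a)) return(min(sum(b), n - sum(b)))
    if (is.null(b)) return(min(sum(a), n - sum(a)))
    m <- sum(xor(a, b))
    min(m, n - m)
  }
  best <- Inf
  for (p in all_permutations(k)) {
    tot <- sum(vapply(seq_len(k), function(i)
      pair_cost(s1[[i]], s2[[p[i]]]), numeric(1)))
    best <- min(best, tot)
  }
  best
}

# exhaustive minimum over all single-state assignments to internal nodes;
# cells: list per tip (ape order) of allowed state-index vectors
oracle_fitch <- function(tree, cells, s) {
  n_tip <- length(tree$tip.label)
  m <- tree$Nnode
  internal <- n_tip + seq_len(m)
  edges <- tree$edge
  best <- Inf
  grid <- rep(list(seq_len(s)), m)
  combos <- expand.grid(grid)
  for (r in seq_len(nrow(combos))) {
    assign <- integer(n_tip + m)
    assign[internal] <- as.integer(combos[r, ])
    cost <- 0
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; child <- edges[e, 2L]
      if (child <= n_tip) {
        if (!(assign[par] %in% cells[[child]])) cost <- cost + 1
      } else if (assign[par] != assign[child]) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# exhaustive set of most-parsimonious full assignments (small cases only);
# returns a list of integer state vectors over all nodes, leaves resolved
oracle_mp_assignments <- function(tree, cells, s) {
  n_tip <- length(tree$tip.label)
  m <- tree$Nnode
  edges <- tree$edge
  best <- oracle_fitch(tree, cells, s)
  grids <- c(cells, rep(list(seq_len(s)), m))
  combos <- expand.grid(grids)
  keep <- list()
  for (r in seq_len(nrow(combos))) {
    assign <- as.integer(combos[r, ])
    cost <- sum(assign[edges[, 1L]] != assign[edges[, 2L]])
    if (cost == best) keep[[length(keep) + 1L]] <- assign
  }
  keep
}

# small deterministic matrix builder for diagnosis tests
char_mat <- function(taxa, ...) {
  cols <- list(...)
  raw <- do.call(cbind, lapply(cols, function(x) as.character(x)))
  rownames(raw) <- taxa
  new_character_matrix(raw)
}
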