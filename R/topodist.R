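#' Local topological distance between two trees
#'
#' The local distance between two trees is one minus the proportion of
#' elements (splits or clades) shared between them, relative to the union
#' of their element sets:
#' \deqn{d(T_1, T_2) = 1 - |E_1 \cap E_2| / |E_1 \cup E_2|.}
#' Values range from 0 (identical element sets) to 1 (no shared elements);
#' the fewer the shared clades or splits, the greater the distance. When
#' both sets are empty (e.g., two star trees) the trees are topologically
#' indistinguishable and the distance is defined as 0.
#'
#' @param e1,e2 `element_set` objects on the same taxon index and mode.
#' @return A proportion in \[0, 1\].
#' @export
local_distance <- function(e1, e2) {
  check_comparable(e1, e2)
  u <- length(union(e1$keys, e2$keys))
  if (u == 0L) return(0)
  1 - length(intersect(e1$keys, e2$keys)) / u
}

#' Global topological distance between two trees
#'
#' Like [local_distance()], but the shared-element count is normalized by
#' the element universe of the whole run — the union of the element sets
#' of every tree in the configured comparison:
#' \deqn{D(T_1, T_2) = 1 - |E_1 \cap E_2| / |\bigcup_i E_i|.}
#' D is comparable across pairs of the same run and never smaller than the
#' local distance of the pair. Note that D of a tree with itself need not
#' be 0. When the run holds exactly the two trees, D equals d.
#'
#' @inheritParams local_distance
#' @param universe Character vector of element keys pooled over every tree
#'   of the run (see [element_universe()]).
#' @return A proportion in \[0, 1\].
#' @export
global_distance <- function(e1, e2, universe) {
  check_comparable(e1, e2)
  shared <- intersect(e1$keys, e2$keys)
  if (length(universe) == 0L) {
    stopifnot(length(shared) == 0L)
    return(0)
  }
  if (!all(c(e1$keys, e2$keys) %in% universe))
    stop("element sets are not contained in the supplied universe",
         call. = FALSE)
  1 - length(shared) / length(universe)
}

#' Pooled element universe of a run
#'
#' @param sets List of `element_set` objects from every tree of the run.
#' @return Character vector of the distinct element keys.
#' @export
element_universe <- function(sets) {
  unique(unlist(lapply(sets, function(s) s$keys), use.names = FALSE))
}

check_comparable <- function(e1, e2) {
  stopifnot(inherits(e1, "element_set"), inherits(e2, "element_set"))
  if (!identical(e1$mode, e2$mode))
    stop("element sets have different modes (", e1$mode, " vs ",
         e2$mode, ")", call. = FALSE)
  if (!identical(e1$taxa$labels, e2$taxa$labels))
    stop("element sets are indexed on different taxon universes",
         call. = FALSE)
  invisible(TRUE)
}

#' Pairwise local and global distance matrices
#'
#' Extracts the element set of every tree and computes the local and
#' global distances for all unordered pairs. The global matrix uses the
#' run-wide element universe, so adding trees to a run can only increase
#' global distances.
#'
#' @param trees List of `phylo` objects on one leaf-label set (or
#'   restrictable to one with `prune_to_common`).
#' @param mode `"splits"` (unrooted comparison) or `"clades"` (rooted;
#'   trees must be rooted, e.g. via [reroot_outgroup()]).
#' @param tree_ids Optional identifiers; defaults to `tree#<k>` with `k`
#'   the 0-based input position.
#' @param prune_to_common Restrict trees to their common leaves instead of
#'   requiring identical leaf sets.
#' @return An object of class `topo_distances`: list with `local` and
#'   `global` (symmetric matrices), `pairs` (long-form data frame with
#'   columns `tree_i`, `tree_j`, `d`, `D`), `mode`, `taxa` and
#'   `universe_size`.
#' @export
pairwise_matrices <- function(trees, mode = c("splits", "clades"),
                              tree_ids = NULL, prune_to_common = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(trees) >= 2L)
  if (is.null(tree_ids))
    tree_ids <- paste0("tree#", seq_along(trees) - 1L)
  stopifnot(length(tree_ids) == length(trees), !anyDuplicated(tree_ids))
  taxa <- build_taxon_index(trees, prune_to_common = prune_to_common)
  if (prune_to_common)
    trees <- lapply(trees, conform_tree, taxa = taxa)
  extract <- if (mode == "splits") extract_splits else extract_clades
  sets <- lapply(trees, extract, taxa = taxa)
  universe <- element_universe(sets)
  k <- length(trees)
  local <- matrix(0, k, k, dimnames = list(tree_ids, tree_ids))
  global <- matrix(0, k, k, dimnames = list(tree_ids, tree_ids))
  for (i in seq_len(k)) for (j in i:k) {
    d <- local_distance(sets[[i]], sets[[j]])
    D <- global_distance(sets[[i]], sets[[j]], universe)
    local[i, j] <- local[j, i] <- d
    global[i, j] <- global[j, i] <- D
  }
  idx <- which(upper.tri(local), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  pairs <- data.frame(tree_i = tree_ids[idx[, 1L]],
                      tree_j = tree_ids[idx[, 2L]],
                      d = local[idx], D = global[idx],
                      stringsAsFactors = FALSE)
  structure(list(local = local, global = global, pairs = pairs,
                 mode = mode, taxa = taxa,
                 universe_size = length(universe)),
            class = "topo_distances")
}

#' @export
print.topo_distances <- function(x, ...) {
  k <- nrow(x$local)
  cat("Topological distances (", x$mode, " mode): ", k, " trees, ",
      x$taxa$n, " taxa, universe of ", x$universe_size, " elements\n",
      sep = "")
  cat("  mean local d:  ", format(mean(x$pairs$d), digits = 4), "\n",
      "  mean global D: ", format(mean(x$pairs$D), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write distance matrices as CSV artifacts
#'
#' Writes `local.csv` and `global.csv` (square matrices with identifier
#' header row/column, 6 decimal places) and `pairs.csv` (long form:
#' `tree_i, tree_j, d, D`).
#'
#' @param x A `topo_distances` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of the paths written, invisibly.
#' @export
write_distance_csv <- function(x, dir) {
  stopifnot(inherits(x, "topo_distances"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("local.csv", "global.csv", "pairs.csv"))
  write_square_csv(x$local, paths[1L])
  write_square_csv(x$global, paths[2L])
  pairs <- x$pairs
  pairs$d <- formatC(pairs$d, digits = 6, format = "f")
  pairs$D <- formatC(pairs$D, digits = 6, format = "f")
  utils::write.csv(pairs, paths[3L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

write_square_csv <- function(m, path) {
  out <- formatC(m, digits = 6, format = "f")
  utils::write.csv(data.frame(id = rownames(m), out,
                              check.names = FALSE,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}
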