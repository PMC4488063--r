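#' Transfer cost between two splits
#'
#' The minimum number of terminals that must switch sides to turn one
#' bipartition into the other: for splits A|B and C|D on the same taxon
#' set this is `min(|A xor C|, |A xor D|)`, where `xor` is the symmetric
#' difference. Because D is the complement of C, the second term equals
#' `n - |A xor C|`.
#'
#' @param s1,s2 Logical membership vectors of one side of each split
#'   (positions follow one shared `taxon_index`; either side may be
#'   given — the cost is orientation-free).
#' @return A nonnegative integer.
#' @export
split_transfer_cost <- function(s1, s2) {
  stopifnot(is.logical(s1), is.logical(s2))
  if (length(s1) != length(s2))
    stop("splits are drawn from different taxon universes", call. = FALSE)
  m <- sum(xor(s1, s2))
  min(m, length(s1) - m)
}

# exact minimum-cost perfect matching (Hungarian / Jonker-Volgenant
# potentials, O(k^3)); cost is a square numeric matrix
solve_assignment <- function(cost) {
  k <- nrow(cost)
  stopifnot(k == ncol(cost))
  if (k == 0L) return(list(assignment = integer(0), cost = 0))
  INF <- .Machine$double.xmax / 4
  u <- numeric(k + 1L)          # row potentials, index r+1 (row 0 virtual)
  v <- numeric(k + 1L)          # column potentials, index c+1 (col 0 virtual)
  p <- integer(k + 1L)          # p[c+1]: row matched to column c (0 = none)
  way <- integer(k + 1L)
  for (r in seq_len(k)) {
    p[1L] <- r
    j0 <- 0L
    minv <- rep(INF, k + 1L)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      r0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(k)) {
        if (used[j + 1L]) next
        cur <- cost[r0, j] - u[r0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:k) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(k)
  for (j in seq_len(k)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(k), assignment)]))
}

# pairwise transfer costs between two canonical split mask matrices
# (rows = splits); via |A xor C| = |A| + |C| - 2 |A & C|
split_cost_matrix <- function(m1, m2, n) {
  if (nrow(m1) == 0L || nrow(m2) == 0L)
    return(matrix(0, nrow(m1), nrow(m2)))
  inter <- tcrossprod(m1 * 1, m2 * 1)
  xo <- outer(rowSums(m1), rowSums(m2), "+") - 2 * inter
  pmin(xo, n - xo)
}

#' Matching split distance between two trees
#'
#' The minimum-total-cost perfect matching between the nontrivial split
#' sets of two trees, where pairing two splits costs the fewest terminals
#' that must change sides to make them identical
#' ([split_transfer_cost()]). When the trees have unequal numbers of
#' splits, the smaller set is padded with dummy splits: pairing a real
#' split A|B with a dummy costs `min(|A|, |B|)` and two dummies cost 0.
#' The result is a pseudometric on trees over one leaf set: zero exactly
#' on identical split sets, symmetric, and obeying the triangle
#' inequality. It is sensitive to the displacement of even a single
#' terminal, which is what makes it useful for wildcard detection.
#'
#' @param t1,t2 `phylo` objects on the same leaf-label set.
#' @return A nonnegative integer.
#' @export
matching_split_distance <- function(t1, t2) {
  taxa <- build_taxon_index(list(t1, t2))
  e1 <- extract_splits(t1, taxa)
  e2 <- extract_splits(t2, taxa)
  msd_from_sets(e1, e2, taxa$n)
}

msd_from_sets <- function(e1, e2, n) {
  k1 <- nrow(e1$masks); k2 <- nrow(e2$masks)
  k <- max(k1, k2)
  if (k == 0L) return(0)
  cost <- matrix(0, k, k)
  cost[seq_len(k1), seq_len(k2)] <- split_cost_matrix(e1$masks, e2$masks, n)
  dummy_cost <- function(m) pmin(rowSums(m), n - rowSums(m))
  if (k2 < k)  # columns k2+1..k are dummies facing rows (real splits of e1)
    cost[seq_len(k1), (k2 + 1L):k] <- dummy_cost(e1$masks)
  if (k1 < k)  # rows k1+1..k are dummies facing columns (splits of e2)
    cost[(k1 + 1L):k, seq_len(k2)] <-
      matrix(dummy_cost(e2$masks), k - k1, k2, byrow = TRUE)
  solve_assignment(cost)$cost
}

#' Average matching split distance over a tree set
#'
#' Arithmetic mean of [matching_split_distance()] over all unordered pairs
#' of distinct positions (self-pairs excluded; duplicated trees in the
#' input are kept and compared).
#'
#' @param trees List of at least two `phylo` objects on one leaf set.
#' @return A nonnegative number.
#' @export
average_msd <- function(trees) {
  stopifnot(length(trees) >= 2L)
  taxa <- build_taxon_index(trees)
  sets <- lapply(trees, extract_splits, taxa = taxa)
  k <- length(trees)
  tot <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    tot <- tot + msd_from_sets(sets[[i]], sets[[j]], taxa$n)
  tot / (k * (k - 1L) / 2L)
}

#' Rank terminals by their effect on average matching split distance
#'
#' Leave-one-out wildcard (rogue) detection: each terminal is pruned from
#' every tree in turn (suppressing the resulting degree-2 nodes) and the
#' average matching split distance of the pruned set is recomputed.
#' Terminals whose removal yields the lowest average MSD are the ones
#' whose unstable placement drives the disagreement between the trees —
#' the candidate wildcards — and are listed first.
#'
#' @param trees List of at least two `phylo` objects sharing at least four
#'   terminals (pruning must leave at least three leaves).
#' @return A `rogue_report`: data frame with columns `rank`, `terminal`,
#'   `avg_msd_after_pruning` and `baseline_avg_msd` (the no-pruning
#'   average), sorted ascending by `avg_msd_after_pruning` with ties
#'   broken by terminal label.
#' @export
rank_rogues <- function(trees) {
  stopifnot(length(trees) >= 2L)
  taxa <- build_taxon_index(trees)
  if (taxa$n < 4L)
    stop("need at least 4 shared terminals to prune one and keep a tree",
         call. = FALSE)
  baseline <- average_msd(trees)
  scores <- vapply(taxa$labels, function(lab) {
    pruned <- lapply(trees, function(t) as_clean_phylo(ape::drop.tip(t, lab)))
    average_msd(pruned)
  }, numeric(1))
  ord <- order(scores, names(scores), method = "radix")
  out <- data.frame(rank = seq_along(ord),
                    terminal = names(scores)[ord],
                    avg_msd_after_pruning = unname(scores[ord]),
                    baseline_avg_msd = baseline,
                    stringsAsFactors = FALSE)
  class(out) <- c("rogue_report", "data.frame")
  out
}

#' @export
print.rogue_report <- function(x, ...) {
  cat("Leave-one-out rogue ranking (baseline average MSD = ",
      format(x$baseline_avg_msd[1L], digits = 5), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more terminals\n")
  invisible(x)
}

#' Write a rogue report as CSV
#'
#' @param report A `rogue_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rogue_csv <- function(report, path) {
  stopifnot(inherits(report, "rogue_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
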