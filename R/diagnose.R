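#' Parsimony length of one character on a tree
#'
#' Minimum number of state changes over all assignments of single states
#' to the internal nodes (unordered states, unit cost — Fitch counting,
#' generalized to multifurcations by dynamic programming over the unit
#' substitution cost). Missing data participates as the full observed
#' alphabet of its character and can never add a change on its own.
#'
#' @param tree A rooted `phylo` object.
#' @param cm A `character_matrix` whose taxa cover the tree's leaves.
#' @param char Character index, 1-based.
#' @return A nonnegative integer.
#' @export
fitch_length <- function(tree, cm, char) {
  cells <- char_cells(tree, cm, char)
  s <- length(cm$alphabet[[char]])
  if (s <= 1L) return(0L)
  down <- sankoff_down(tree, cells, s)
  as.integer(min(down[root_node(tree), ]))
}

# per-tip allowed state-index sets, in ape tip order
char_cells <- function(tree, cm, char) {
  stopifnot(inherits(cm, "character_matrix"),
            char >= 1L, char <= cm$n_char)
  missing <- setdiff(tree$tip.label, cm$taxa)
  if (length(missing))
    stop("leaf absent from the character matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  alpha <- cm$alphabet[[char]]
  lapply(cm$cells[[char]][tree$tip.label],
         function(st) match(st, alpha))
}

# down[v, t]: minimal cost of the subtree rooted at v given state t at v
sankoff_down <- function(tree, cells, s) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  INF <- n_nodes + 1  # any cost above the worst possible tree length
  down <- matrix(0, n_nodes, s)
  for (i in seq_len(n_tip)) {
    row <- rep(INF, s)
    row[cells[[i]]] <- 0
    down[i, ] <- row
  }
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    child <- down[edge[i, 2L], ]
    down[edge[i, 1L], ] <- down[edge[i, 1L], ] +
      pmin(child, min(child) + 1)
  }
  down
}

#' Most-parsimonious ancestral reconstruction (ACCTRAN or DELTRAN)
#'
#' Resolves one character to a single most-parsimonious assignment of
#' states to every node. Ties in the optimization are broken by the two
#' classical extreme rules: `ACCTRAN` (accelerated transformation) places
#' changes as close to the root as possible, favoring early gains with
#' later reversals; `DELTRAN` (delayed transformation) places them as
#' close to the tips as possible, favoring parallel gains. Both always
#' realize exactly [fitch_length()] changes. Leaves with ambiguous or
#' missing observations resolve to the parent's state whenever compatible
#' under both rules, so missing data never manufactures a terminal change.
#' Remaining ties go to the alphabetically smallest state, making the
#' reconstruction deterministic.
#'
#' @inheritParams fitch_length
#' @param variant `"ACCTRAN"` or `"DELTRAN"`.
#' @return A `parsimony_reconstruction`: list with `states` (state symbol
#'   per node, ape node order; `NA` if the character has no observed
#'   states), `changes` (data frame `parent`, `child`, `from`, `to` in ape
#'   node ids and state symbols), `length`, `variant` and `char`.
#' @export
reconstruct <- function(tree, cm, char,
                        variant = c("ACCTRAN", "DELTRAN")) {
  variant <- match.arg(variant)
  cells <- char_cells(tree, cm, char)
  alpha <- cm$alphabet[[char]]
  s <- length(alpha)
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  empty <- data.frame(parent = integer(0), child = integer(0),
                      from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  if (s == 0L)
    return(new_reconstruction(rep(NA_character_, n_nodes), empty, 0L,
                              variant, char))
  down <- sankoff_down(tree, cells, s)
  root <- root_node(tree)
  state <- integer(n_nodes)
  state[root] <- which.min(down[root, ])  # smallest optimal state
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1L]; child <- pre[i, 2L]
    ps <- state[par]
    tot <- down[child, ] + as.numeric(seq_len(s) != ps)
    opt <- which(tot == min(tot))
    state[child] <-
      if (ps %in% opt && (child <= n_tip || variant == "DELTRAN")) ps
      else if (variant == "ACCTRAN" && length(setdiff(opt, ps)))
        min(setdiff(opt, ps))
      else if (ps %in% opt) ps
      else min(opt)
  }
  changed <- which(state[edge[, 1L]] != state[edge[, 2L]])
  changes <- data.frame(parent = edge[changed, 1L],
                        child = edge[changed, 2L],
                        from = alpha[state[edge[changed, 1L]]],
                        to = alpha[state[edge[changed, 2L]]],
                        stringsAsFactors = FALSE)
  changes <- changes[order(changes$child), , drop = FALSE]
  rownames(changes) <- NULL
  new_reconstruction(alpha[state], changes, length(changed), variant, char)
}

new_reconstruction <- function(states, changes, len, variant, char) {
  structure(list(states = states, changes = changes,
                 length = as.integer(len), variant = variant,
                 char = char),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat(x$variant, " reconstruction of character ", x$char, ": ",
      x$length, " change(s)\n", sep = "")
  if (nrow(x$changes)) print.data.frame(x$changes)
  invisible(x)
}

#' Compile and categorize character-state transformations on a tree
#'
#' For every character and every branch on which any most-parsimonious
#' reconstruction places a state change, emits one transformation record.
#' A change is *unambiguous* when the ACCTRAN and DELTRAN resolutions
#' agree on the branch (same from- and to-state), otherwise *ambiguous*
#' (ambiguous records carry category `not-applicable`). An unambiguous
#' change of a character is *homoplastic* when the character needs more
#' steps on the tree than its minimum conceivable length (observed states
#' minus one); its to-state is *unique* when that state is gained on
#' exactly one branch of the reconstruction. This yields the three-way
#' classification of unambiguous synapomorphies:
#' `unique-nonhomoplastic`, `unique-homoplastic` (single origin within an
#' otherwise homoplastic character), and `nonunique-homoplastic`
#' (parallel origins). A non-unique, non-homoplastic change is logically
#' impossible and is asserted never to occur.
#'
#' @param tree A rooted `phylo` object.
#' @param cm A `character_matrix` covering the tree's leaves.
#' @return A `diagnosis` data frame with one row per record: `character`
#'   (0-based index, matching the output file convention), `child_node`
#'   (preorder internal-node number of the branch's child, `NA` for
#'   leaves), `child_label` (tip label, `NA` for internal children),
#'   `from`, `to`, `ambiguity` (`unambiguous`/`ambiguous`) and
#'   `category`. The attribute `total_length` holds the summed parsimony
#'   length over all characters.
#' @export
classify_transformations <- function(tree, cm) {
  stopifnot(inherits(tree, "phylo"), inherits(cm, "character_matrix"))
  if (!ape::is.rooted(tree))
    stop("diagnosis needs a rooted tree", call. = FALSE)
  n_tip <- length(tree$tip.label)
  pre <- preorder_numbers(tree)
  rows <- list()
  total_len <- 0L
  for (j in seq_len(cm$n_char)) {
    alpha <- cm$alphabet[[j]]
    if (length(alpha) <= 1L) next
    acc <- reconstruct(tree, cm, j, "ACCTRAN")
    del <- reconstruct(tree, cm, j, "DELTRAN")
    total_len <- total_len + acc$length
    if (acc$length == 0L) next
    homoplastic <- acc$length > length(alpha) - 1L
    key <- function(ch) paste(ch$child, ch$from, ch$to)
    ka <- key(acc$changes); kd <- key(del$changes)
    gains_a <- table(acc$changes$to); gains_d <- table(del$changes$to)
    both <- rbind(acc$changes, del$changes)
    both$k <- c(ka, kd)
    both <- both[!duplicated(both$k), , drop = FALSE]
    both <- both[order(both$child, both$to), , drop = FALSE]
    for (i in seq_len(nrow(both))) {
      unamb <- both$k[i] %in% ka && both$k[i] %in% kd
      if (unamb) {
        uniq <- gains_a[[both$to[i]]] == 1L && gains_d[[both$to[i]]] == 1L
        if (!homoplastic && !uniq)
          stop("internal error: non-unique non-homoplastic change",
               call. = FALSE)
        category <- if (!homoplastic) "unique-nonhomoplastic"
                    else if (uniq) "unique-homoplastic"
                    else "nonunique-homoplastic"
      } else category <- "not-applicable"
      child <- both$child[i]
      rows[[length(rows) + 1L]] <- data.frame(
        character = j - 1L,
        child_node = pre[child],
        child_label = if (child <= n_tip) tree$tip.label[child]
                      else NA_character_,
        from = both$from[i], to = both$to[i],
        ambiguity = if (unamb) "unambiguous" else "ambiguous",
        category = category,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = integer(0), child_node = integer(0),
               child_label = character(0), from = character(0),
               to = character(0), ambiguity = character(0),
               category = character(0), stringsAsFactors = FALSE)
  attr(out, "total_length") <- total_len
  class(out) <- c("diagnosis", "data.frame")
  out
}

#' Write a diagnosis as CSV and annotated tree SVG
#'
#' The CSV holds one row per transformation record plus a footer comment
#' line with the total tree length; the SVG draws the tree with node
#' numbers matching the CSV and one glyph per record on the branch where
#' the change occurs, color-coded by category.
#'
#' @param records A `diagnosis` object from [classify_transformations()].
#' @param tree The rooted `phylo` the records were computed on.
#' @param csv,svg Output paths (either may be `NULL` to skip).
#' @param colors Named fill colors per category.
#' @return Character vector of paths written, invisibly.
#' @export
write_diagnosis <- function(records, tree, csv = NULL, svg = NULL,
                            colors = diagnosis_colors()) {
  stopifnot(inherits(records, "diagnosis"))
  written <- character(0)
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(records), csv, row.names = FALSE,
                     quote = FALSE, na = "")
    cat("# total_tree_length,", attr(records, "total_length"), "\n",
        sep = "", file = csv, append = TRUE)
    written <- c(written, csv)
  }
  if (!is.null(svg)) {
    render_diagnosis_svg(records, tree, svg, colors)
    written <- c(written, svg)
  }
  invisible(written)
}

#' Default category colors for diagnosis plots
#' @return Named character vector of fill colors.
#' @export
diagnosis_colors <- function() {
  c("unique-nonhomoplastic" = "#000000",
    "unique-homoplastic" = "#d95f02",
    "nonunique-homoplastic" = "#ffffff",
    "not-applicable" = "#999999")
}
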