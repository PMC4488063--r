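#' Parse a Newick tree description
#'
#' Parses a single parenthetical (Newick) tree description into an
#' [ape::phylo] object. Branch lengths, internal node labels and support
#' values are accepted on input but discarded: every computation in this
#' package is purely topological. Degree-2 internal nodes are suppressed on
#' construction (a basal dichotomy of a rooted tree is kept).
#'
#' Labels may be unquoted or single-quoted following Newick conventions
#' (internal quotes doubled). Unquoted underscores are kept verbatim, not
#' translated to spaces.
#'
#' @param text A character scalar holding one semicolon-terminated Newick
#'   tree description.
#' @return A `phylo` object with unique tip labels and no edge lengths.
#' @examples
#' tr <- parse_newick("((A:1,B:2)90:0.1,C);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (nchar(text) == 0L)
    stop("empty tree description", call. = FALSE)
  check_parentheses(text)
  if (!grepl(";\\s*$", text))
    stop("tree description not terminated by ';' (position ",
         nchar(text), ")", call. = FALSE)
  # shield quoted labels behind placeholders; ape does not unquote them
  q <- gregexpr("'([^']|'')*'", text)[[1L]]
  quoted <- character(0)
  if (q[1L] != -1L) {
    quoted <- regmatches(text, list(q))[[1L]]
    for (i in seq_along(quoted))
      text <- sub(quoted[i], sprintf("QUOTEDLBL%dX", i), text,
                  fixed = TRUE)
    quoted <- gsub("''", "'", substr(quoted, 2L, nchar(quoted) - 1L))
  }
  tr <- tryCatch(ape::read.tree(text = text, keep.multi = FALSE),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick description", call. = FALSE)
  if (length(quoted)) {
    for (i in seq_along(tr$tip.label)) {
      m <- regmatches(tr$tip.label[i],
                      regexpr("^QUOTEDLBL([0-9]+)X$", tr$tip.label[i]))
      if (length(m))
        tr$tip.label[i] <-
          quoted[as.integer(sub("^QUOTEDLBL([0-9]+)X$", "\\1", m))]
    }
  }
  as_clean_phylo(tr)
}

#' Read one or more Newick trees from a file
#'
#' Each semicolon-terminated description in the file yields one tree; trees
#' are identified downstream as `<filename>#<k>` with `k` the 0-based
#' position within the file.
#'
#' @param path Path to a Newick file.
#' @return A list of `phylo` objects.
#' @export
read_newick_trees <- function(path) {
  if (!file.exists(path))
    stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # split on semicolons so each description is validated individually
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) == 0L)
    stop("no tree descriptions in ", path, call. = FALSE)
  lapply(parts, function(p) parse_newick(paste0(trimws(p), ";")))
}

# Balanced-parenthesis pre-check with a 1-based character position in the
# error message; quoted labels are skipped so "'a)b'" does not miscount.
check_parentheses <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") { in_quote <- !in_quote; next }
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, call. = FALSE)
    }
  }
  if (in_quote) stop("unterminated quoted label", call. = FALSE)
  if (depth > 0L)
    stop("unbalanced '(': ", depth, " unclosed at end of input",
         call. = FALSE)
  invisible(TRUE)
}

# Strip lengths/labels, suppress degree-2 nodes, enforce unique tip labels.
as_clean_phylo <- function(tr) {
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr <- ape::collapse.singles(tr)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tr$tip.label)))
    stop("empty leaf label", call. = FALSE)
  tr
}

#' Parse trees in the TNT parenthetical dialect
#'
#' The dialect accepted here: parenthetical tree descriptions in which
#' sibling groups are separated by whitespace (not commas); terminals are
#' either non-negative integer indices resolved against `taxon_order`
#' (0-based, the order of a companion data matrix) or literal names; several
#' trees may appear in one text, separated by `*` or `;`. An optional
#' leading `tread` keyword (with an optional quoted comment) is skipped.
#' Any other token is a parse error, never silently dropped.
#'
#' @param text Character scalar with one or more tree descriptions.
#' @param taxon_order Character vector of terminal names used to resolve
#'   numeric indices; may be `NULL` when all terminals are literal names.
#' @return A list of `phylo` objects.
#' @examples
#' parse_tnt_trees("(0 (1 2));", taxon_order = c("A", "B", "C"))
#' @export
parse_tnt_trees <- function(text, taxon_order = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  # optional header: "tread" keyword plus optional 'comment'
  txt <- sub("^tread\\s*('([^']|'')*')?\\s*", "", txt, ignore.case = TRUE)
  if (!nzchar(txt)) stop("no tree descriptions", call. = FALSE)
  toks <- tnt_tokenize(txt)
  trees <- list()
  current <- character(0)
  flush <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    tnt_build_tree(cur, taxon_order)
  }
  for (tk in toks) {
    if (tk %in% c("*", ";")) {
      tr <- flush(current)
      if (!is.null(tr)) trees[[length(trees) + 1L]] <- tr
      current <- character(0)
    } else {
      current <- c(current, tk)
    }
  }
  tr <- flush(current)
  if (!is.null(tr)) trees[[length(trees) + 1L]] <- tr
  if (length(trees) == 0L) stop("no tree descriptions", call. = FALSE)
  trees
}

tnt_tokenize <- function(txt) {
  pat <- "\\(|\\)|\\*|;|'([^']|'')*'|[^()'*;[:space:]]+"
  m <- gregexpr(pat, txt)[[1L]]
  toks <- regmatches(txt, list(m))[[1L]]
  # every non-space character must belong to some token
  covered <- sum(attr(m, "match.length"))
  plain <- gsub("[[:space:]]", "", txt)
  if (covered < nchar(plain))
    stop("unrecognized characters in TNT tree text", call. = FALSE)
  toks
}

tnt_build_tree <- function(toks, taxon_order) {
  pos <- 0L
  n_tok <- length(toks)
  peek <- function() if (pos < n_tok) toks[pos + 1L] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos] }
  resolve <- function(tk) {
    if (grepl("^[0-9]+$", tk)) {
      idx <- as.integer(tk)  # 0-based
      if (is.null(taxon_order))
        stop("numeric terminal '", tk,
             "' but no taxon order supplied", call. = FALSE)
      if (idx >= length(taxon_order))
        stop("terminal index ", idx, " out of range (",
             length(taxon_order), " taxa)", call. = FALSE)
      taxon_order[idx + 1L]
    } else if (startsWith(tk, "'")) {
      gsub("''", "'", substr(tk, 2L, nchar(tk) - 1L))
    } else tk
  }
  parse_group <- function() {
    stopifnot(identical(advance(), "("))
    parts <- character(0)
    repeat {
      nxt <- peek()
      if (is.na(nxt)) stop("unterminated '(' in TNT tree", call. = FALSE)
      if (nxt == ")") { advance(); break }
      if (nxt == "(") parts <- c(parts, parse_group())
      else parts <- c(parts, newick_quote(resolve(advance())))
    }
    if (length(parts) == 0L) stop("empty group '()'", call. = FALSE)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  if (!identical(peek(), "("))
    stop("TNT tree must start with '(', got '", peek(), "'", call. = FALSE)
  nwk <- parse_group()
  if (pos != n_tok)
    stop("trailing tokens after tree: '", toks[pos + 1L], "'", call. = FALSE)
  parse_newick(paste0(nwk, ";"))
}

#' Write a tree as a Newick string
#'
#' Emits a semicolon-terminated, topology-only Newick description. Labels
#' containing whitespace, quotes, or Newick punctuation are single-quoted
#' with internal quotes doubled, so the output always re-parses to the same
#' split set.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- children_list(tree)
  root <- root_node(tree)
  render <- function(v) {
    if (v <= n_tip) return(newick_quote(tree$tip.label[v]))
    paste0("(", paste(vapply(children[[v]], render, character(1)),
                      collapse = ","), ")")
  }
  out <- paste0(render(root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

newick_quote <- function(label) {
  if (grepl("[][(){}:;,'[:space:]]", label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

# adjacency helpers shared across modules ----------------------------------

children_list <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
}

#' Reroot a tree on an outgroup
#'
#' Returns a rooted tree whose root separates the outgroup from the
#' remaining terminals. Rerooting never changes the unrooted split set.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of terminal labels; must be a proper
#'   nonempty subset of the tree's leaves and displayable as one side of an
#'   edge of the unrooted tree.
#' @return A rooted `phylo` object.
#' @export
reroot_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  outgroup <- as.character(outgroup)
  if (length(outgroup) == 0L)
    stop("empty outgroup", call. = FALSE)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup label(s) absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(outgroup) >= length(tree$tip.label))
    stop("outgroup must be a proper subset of the leaves", call. = FALSE)
  ok <- ape::is.monophyletic(tree, outgroup, reroot = TRUE)
  if (!ok)
    stop("outgroup is not displayable as one side of an edge ",
         "(not monophyletic in the unrooted tree)", call. = FALSE)
  out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  as_clean_phylo(out)
}
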