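#' Score element stability across analytical conditions
#'
#' Sensitivity analysis asks which groups survive changes in analytical
#' assumptions (alignment method, transformation costs, search strategy,
#' optimality criterion...). Each assumption set — a *condition* —
#' contributes one or more trees; every reference element (split or clade
#' of the reference tree) is scored present or absent in every condition.
#' Under the default strict rule an element is present in a condition only
#' when it occurs in *every* tree of that condition, mirroring strict
#' consensus; `rule = "majority"` relaxes this to a proportion threshold.
#'
#' @param reference A `phylo` object defining the elements to score; its
#'   internal nodes name the rows (and the plot files) via
#'   [preorder_numbers()].
#' @param conditions Named list; each entry is a list of `phylo` objects
#'   (a single tree such as a consensus is fine).
#' @param mode `"splits"` or `"clades"` (clades requires rooted trees).
#' @param rule `"strict"` (present in all trees of the condition) or
#'   `"majority"`.
#' @param majority Proportion threshold used when `rule = "majority"`;
#'   presence means occurrence in more than this fraction of the
#'   condition's trees.
#' @param prune_to_common Restrict all trees to the common leaf set.
#' @return A `sensitivity_matrix`: list with `presence` (logical elements
#'   x conditions matrix; rows named `node_<id>`), `element_ids`,
#'   `condition_ids`, `element_desc` (readable element labels) and `mode`.
#' @export
score_sensitivity <- function(reference, conditions,
                              mode = c("splits", "clades"),
                              rule = c("strict", "majority"),
                              majority = 0.5,
                              prune_to_common = FALSE) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  stopifnot(inherits(reference, "phylo"), length(conditions) >= 1L)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be named", call. = FALSE)
  sizes <- vapply(conditions, length, integer(1))
  if (any(sizes == 0L))
    stop("empty condition(s): ",
         paste(names(conditions)[sizes == 0L], collapse = ", "),
         call. = FALSE)
  all_trees <- c(list(reference), unlist(conditions, recursive = FALSE))
  taxa <- build_taxon_index(all_trees, prune_to_common = prune_to_common)
  if (prune_to_common) {
    reference <- conform_tree(reference, taxa)
    conditions <- lapply(conditions, function(ts)
      lapply(ts, conform_tree, taxa = taxa))
  }
  extract <- if (mode == "splits") extract_splits else extract_clades
  ref_set <- extract(reference, taxa)
  if (length(ref_set$keys) == 0L)
    stop("reference tree has no ", mode, " to score", call. = FALSE)
  presence <- matrix(FALSE, length(ref_set$keys), length(conditions),
                     dimnames = list(paste0("node_", ref_set$node_ids),
                                     names(conditions)))
  for (ci in seq_along(conditions)) {
    hit <- vapply(conditions[[ci]], function(t)
      ref_set$keys %in% extract(t, taxa)$keys,
      logical(length(ref_set$keys)))
    hit <- matrix(hit, nrow = length(ref_set$keys))
    frac <- rowMeans(hit)
    presence[, ci] <- if (rule == "strict") frac == 1 else frac > majority
  }
  structure(list(presence = presence,
                 element_ids = ref_set$node_ids,
                 condition_ids = names(conditions),
                 element_desc = element_labels(ref_set),
                 mode = mode),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("Sensitivity matrix (", x$mode, "): ", nrow(x$presence),
      " reference elements x ", ncol(x$presence), " conditions\n",
      sep = "")
  cat("Overall presence: ",
      format(mean(x$presence), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Render per-element sensitivity plots (SVG)
#'
#' One SVG per reference element, named `node_<id>.svg` after the
#' element's preorder node number in the reference tree so plots can be
#' matched to nodes when editing figures. Each plot is a rows x cols grid
#' of cells in row-major condition order — filled when the element is
#' present under that condition, open when absent (the classic "navajo
#' rug").
#'
#' @param x A `sensitivity_matrix`.
#' @param out_dir Output directory, created if needed.
#' @param grid Integer `c(rows, cols)`; must multiply to the number of
#'   conditions. Default: one row.
#' @param fill_present,fill_absent Cell fill colors.
#' @param cell Cell side length in pixels.
#' @param margin Outer margin in pixels.
#' @return Character vector of the SVG paths written.
#' @export
render_sensitivity_svg <- function(x, out_dir, grid = NULL,
                                   fill_present = "#1f3b73",
                                   fill_absent = "#ffffff",
                                   cell = 24, margin = 6) {
  stopifnot(inherits(x, "sensitivity_matrix"))
  k <- ncol(x$presence)
  if (is.null(grid)) grid <- c(1L, k)
  grid <- as.integer(grid)
  if (length(grid) != 2L || prod(grid) != k)
    stop("grid (", paste(grid, collapse = "x"),
         ") does not multiply to the number of conditions (", k, ")",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  width <- 2 * margin + grid[2L] * cell
  height <- 2 * margin + grid[1L] * cell
  paths <- character(nrow(x$presence))
  for (e in seq_len(nrow(x$presence))) {
    parts <- svg_open(width, height)
    for (ci in seq_len(k)) {
      row <- (ci - 1L) %/% grid[2L]
      col <- (ci - 1L) %% grid[2L]
      fill <- if (x$presence[e, ci]) fill_present else fill_absent
      parts <- c(parts, svg_rect(margin + col * cell,
                                 margin + row * cell,
                                 cell, cell, fill))
    }
    parts <- c(parts, "</svg>")
    paths[e] <- file.path(out_dir,
                          paste0(rownames(x$presence)[e], ".svg"))
    writeLines(parts, paths[e])
  }
  paths
}

#' Write the presence matrix as CSV
#'
#' Rows are reference elements (`node_<id>`, with a readable description
#' of the element), columns are conditions; cells are 1/0 for
#' present/absent.
#'
#' @param x A `sensitivity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(x, path) {
  stopifnot(inherits(x, "sensitivity_matrix"))
  out <- data.frame(element = rownames(x$presence),
                    description = x$element_desc,
                    x$presence * 1L, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
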