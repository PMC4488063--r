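# Minimal SVG emission helpers. SVG is plain XML text; the few element
# kinds needed (rect, line, circle, text) are emitted directly so the
# artifacts are diff-stable and trivially re-parseable.

svg_open <- function(width, height) {
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', width,
         '" height="', height, '" viewBox="0 0 ', width, ' ', height,
         '">')
}

svg_rect <- function(x, y, w, h, fill, stroke = "#000000",
                     stroke_width = 1) {
  paste0('<rect x="', x, '" y="', y, '" width="', w, '" height="', h,
         '" fill="', fill, '" stroke="', stroke, '" stroke-width="',
         stroke_width, '"/>')
}

svg_line <- function(x1, y1, x2, y2, stroke = "#000000", width = 1.5) {
  paste0('<line x1="', x1, '" y1="', y1, '" x2="', x2, '" y2="', y2,
         '" stroke="', stroke, '" stroke-width="', width, '"/>')
}

svg_circle <- function(cx, cy, r, fill, stroke = "#000000") {
  paste0('<circle cx="', cx, '" cy="', cy, '" r="', r, '" fill="', fill,
         '" stroke="', stroke, '"/>')
}

svg_text <- function(x, y, text, size = 11, anchor = "start",
                     fill = "#000000") {
  paste0('<text x="', x, '" y="', y, '" font-size="', size,
         '" font-family="sans-serif" text-anchor="', anchor,
         '" fill="', fill, '">', xml_escape(text), '</text>')
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# rectangular cladogram layout: x = node depth from the root, y = tip rank
# (preorder tip order) for leaves, mean of children for internal nodes
layout_tree <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  ch <- children_list(tree)
  root <- root_node(tree)
  x <- numeric(n_nodes); y <- numeric(n_nodes)
  tip_rank <- 0
  assign_xy <- function(v, depth) {
    x[v] <<- depth
    if (v <= n_tip) {
      tip_rank <<- tip_rank + 1
      y[v] <<- tip_rank
    } else {
      for (c in ch[[v]]) assign_xy(c, depth + 1)
      y[v] <<- mean(y[ch[[v]]])
    }
  }
  assign_xy(root, 0)
  list(x = x, y = y, root = root, children = ch, n_tip = n_tip)
}

render_diagnosis_svg <- function(records, tree, path, colors) {
  lay <- layout_tree(tree)
  pre <- preorder_numbers(tree)
  xs <- 70; ys <- 24; pad <- 40
  label_w <- 8 * max(nchar(tree$tip.label)) + 20
  width <- pad * 2 + xs * max(lay$x) + label_w
  height <- pad * 2 + ys * lay$n_tip
  px <- pad + xs * lay$x
  py <- pad + ys * (lay$y - 0.5)
  parts <- svg_open(width, height)
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1L]; child <- edge[i, 2L]
    parts <- c(parts,
               svg_line(px[par], py[child], px[child], py[child]),
               svg_line(px[par], py[par], px[par], py[child]))
  }
  for (v in seq_len(lay$n_tip))
    parts <- c(parts, svg_text(px[v] + 5, py[v] + 4, tree$tip.label[v]))
  for (v in which(!is.na(pre)))
    parts <- c(parts, svg_text(px[v] + 3, py[v] - 3,
                               paste0("n", pre[v]), size = 9,
                               fill = "#555555"))
  if (nrow(records)) {
    child_of <- function(i) {
      r <- records[i, ]
      if (!is.na(r$child_label)) match(r$child_label, tree$tip.label)
      else which(pre == r$child_node)
    }
    childs <- vapply(seq_len(nrow(records)), child_of, integer(1))
    for (v in unique(childs)) {
      idx <- which(childs == v)
      par <- edge[edge[, 2L] == v, 1L]
      fr <- seq_along(idx) / (length(idx) + 1)
      gx <- px[par] + fr * (px[v] - px[par])
      for (k in seq_along(idx)) {
        r <- records[idx[k], ]
        parts <- c(parts,
                   svg_circle(gx[k], py[v], 5,
                              fill = unname(colors[r$category])),
                   svg_text(gx[k], py[v] - 7,
                            paste0(r$character, ":", r$from, ">", r$to),
                            size = 8, anchor = "middle"))
      }
    }
  }
  parts <- c(parts, "</svg>")
  writeLines(parts, path)
  invisible(path)
}
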