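#' @method print ensemble_tree
#' @export
print.ensemble_tree <- function(x, ...) {
  n_cells <- length(x$nodes[["C"]]$cells)
  leaves <- leaf_clusters(x)
  cat("Multi-resolution ensemble cluster tree\n")
  cat(sprintf("  %d cells, %d nodes, %d leaf clusters\n",
              n_cells, length(x$nodes), length(unique(leaves))))
  .print_subtree(x, "C", indent = "")
  invisible(x)
}

.print_subtree <- function(x, label, indent) {
  n <- x$nodes[[label]]
  tag <- if (n$is_leftover) " (leftover)" else ""
  cat(sprintf("%s%s: %d cells, R = %.2f%s\n", indent, label,
              length(n$cells), n$robustness, tag))
  for (ch in n$children) .print_subtree(x, ch, paste0(indent, "  "))
}

#' Summarize a fitted ensemble cluster tree
#'
#' @param object An [ensemble_tree()] fit.
#' @param ... Unused.
#' @return The `meta` table (label, size, robustness, parent, is_leftover),
#'   invisibly printed.
#' @method summary ensemble_tree
#' @export
summary.ensemble_tree <- function(object, ...) {
  meta <- object$tables$meta
  n_mark <- vapply(object$nodes, function(n) {
    if (is.null(n$markers)) NA_integer_ else nrow(n$markers)
  }, 0L)
  meta$n_markers <- unname(n_mark[meta$label])
  meta
}

#' Plot the cluster tree
#'
#' Draws the tree with node sizes and robustness values as edge labels;
#' leftover nodes are filled black, robust nodes grey.
#'
#' @param x An [ensemble_tree()] fit.
#' @param ... Passed to [graphics::plot()].
#' @method plot ensemble_tree
#' @export
plot.ensemble_tree <- function(x, ...) {
  nodes <- x$nodes
  depth <- vapply(nodes, `[[`, 0L, "depth")
  # leaf x-positions in label order, internal nodes centred over children
  pos <- numeric(0)
  next_x <- 0
  assign_x <- function(label) {
    n <- nodes[[label]]
    if (length(n$children) == 0) {
      next_x <<- next_x + 1
      pos[label] <<- next_x
    } else {
      for (ch in n$children) assign_x(ch)
      pos[label] <<- mean(pos[n$children])
    }
  }
  assign_x("C")
  ymax <- max(depth)
  graphics::plot(NA, xlim = c(0.5, next_x + 0.5), ylim = c(ymax + 0.5, -0.5),
                 axes = FALSE, xlab = "", ylab = "depth", ...)
  graphics::axis(2, at = 0:ymax)
  for (n in nodes) {
    if (!is.na(n$parent)) {
      p <- nodes[[n$parent]]
      graphics::segments(pos[p$label], p$depth, pos[n$label], n$depth,
                         col = "grey50")
      graphics::text((pos[p$label] + pos[n$label]) / 2,
                     (p$depth + n$depth) / 2,
                     sprintf("%.2f", n$robustness), cex = 0.7, col = "grey30")
    }
  }
  for (n in nodes) {
    graphics::points(pos[n$label], n$depth, pch = 21, cex = 2.2,
                     bg = if (n$is_leftover) "black" else "grey80")
    graphics::text(pos[n$label], n$depth - 0.22, n$label, cex = 0.8)
  }
  invisible(x)
}
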