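# Independent brute-force oracles and fixture builders used across tests.

# Wrap a named list of label vectors (all named by the same pool) as a
# partition set, bypassing the clusterers.
make_partition_set <- function(pool, partitions) {
  partitions <- lapply(partitions, function(p) {
    stopifnot(length(p) == length(pool))
    stats::setNames(as.character(p), pool)
  })
  structure(list(pool = pool, partitions = partitions,
                 M = length(partitions)),
            class = "partition_set")
}

# Brute-force minimal shared proportion between two explicit cell sets:
# counts co-membership cell by cell and takes the min of the two confidences.
oracle_similarity <- function(cells_x, cells_y) {
  shared <- 0
  for (cx in cells_x) if (cx %in% cells_y) shared <- shared + 1
  if (shared == 0) return(0)
  min(shared / length(cells_x), shared / length(cells_y))
}

# All cross-method base-cluster pairs with their oracle similarity.
oracle_edges <- function(ps) {
  clusters <- list()
  for (m in names(ps$partitions)) {
    labs <- ps$partitions[[m]]
    for (l in unique(labs)) {
      clusters[[length(clusters) + 1]] <-
        list(method = m, label = l, cells = names(labs)[labs == l])
    }
  }
  rows <- list()
  for (i in seq_along(clusters)) {
    for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- clusters[[i]]; b <- clusters[[j]]
      if (a$method == b$method) next
      s <- oracle_similarity(a$cells, b$cells)
      if (s > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          method_x = a$method, label_x = a$label,
          method_y = b$method, label_y = b$label, s = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(method_x = character(0), label_x = character(0),
               method_y = character(0), label_y = character(0),
               s = numeric(0))
}

# Connected components over edges with s > s_lim by depth-first search.
# Returns a list of sorted vertex-id ("method\rlabel") character vectors.
oracle_components <- function(ps, s_lim) {
  vid <- function(m, l) paste(m, l, sep = "\r")
  verts <- character(0)
  for (m in names(ps$partitions)) {
    verts <- c(verts, vid(m, unique(ps$partitions[[m]])))
  }
  edges <- oracle_edges(ps)
  edges <- edges[edges$s > s_lim, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(verts)), verts)
  for (r in seq_len(nrow(edges))) {
    a <- vid(edges$method_x[r], edges$label_x[r])
    b <- vid(edges$method_y[r], edges$label_y[r])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (v in verts) {
    if (v %in% seen) next
    stack <- v
    comp <- character(0)
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      stack <- c(stack, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Pair-counting adjusted Rand index over all cell pairs (quadratic loop).
oracle_ari <- function(a, b) {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  n <- length(common)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Random partition set: n cells, n_methods methods, each partition drawn by
# labelling cells uniformly over 1..n_clusters (clusters may be empty).
random_partition_set <- function(n, n_methods, n_clusters) {
  pool <- sprintf("c%03d", seq_len(n))
  parts <- lapply(seq_len(n_methods), function(m) {
    sample(as.character(seq_len(n_clusters)), n, replace = TRUE)
  })
  names(parts) <- paste0("m", seq_len(n_methods))
  make_partition_set(pool, parts)
}

# A hand-built tree whose topology mirrors a three-recursion analysis:
# root C -> C.1, C.2, C.3, C.L; C.L -> C.L.1, C.L.L;
# C.L.L -> C.L.L.1, C.L.L.2, C.L.L.L. Leaves: 7 labels, one of them
# (C.L.L.L) a leftover.
make_tree_fixture <- function() {
  cells <- sprintf("c%03d", 1:200)
  node <- function(label, cells, robustness, parent, children, is_leftover,
                   depth, threshold) {
    list(label = label, cells = cells, robustness = robustness,
         parent = parent, children = children, is_leftover = is_leftover,
         markers = NULL, methods = character(0), depth = depth,
         threshold = threshold)
  }
  nodes <- list(
    C = node("C", cells, 0, NA_character_,
             c("C.1", "C.2", "C.3", "C.L"), FALSE, 0L, 0),
    C.1 = node("C.1", cells[1:60], 0.9, "C", character(0), FALSE, 1L, 0.25),
    C.2 = node("C.2", cells[61:100], 0.8, "C", character(0), FALSE, 1L, 0.25),
    C.3 = node("C.3", cells[101:120], 0.5, "C", character(0), FALSE, 1L, 0.25),
    C.L = node("C.L", cells[121:200], 0, "C",
               c("C.L.1", "C.L.L"), TRUE, 1L, 0.25),
    C.L.1 = node("C.L.1", cells[121:140], 0.43, "C.L", character(0),
                 FALSE, 2L, 0.25),
    C.L.L = node("C.L.L", cells[141:200], 0, "C.L",
                 c("C.L.L.1", "C.L.L.2", "C.L.L.L"), TRUE, 2L, 0.25),
    C.L.L.1 = node("C.L.L.1", cells[141:160], 0.6, "C.L.L", character(0),
                   FALSE, 3L, 0.25),
    C.L.L.2 = node("C.L.L.2", cells[161:175], 0.3, "C.L.L", character(0),
                   FALSE, 3L, 0.25),
    C.L.L.L = node("C.L.L.L", cells[176:200], 0, "C.L.L", character(0),
                   TRUE, 3L, 0.25))
  fit <- structure(list(nodes = nodes, tables = NULL,
                        log = NULL, config = tree_config(), call = NULL),
                   class = "ensemble_tree")
  fit$tables <- scEnsembleTree:::.result_tables(fit)
  fit
}

# Structural invariants every fitted tree must satisfy: children partition
# their parent's cells exactly, and effective thresholds never decrease from
# root to leaf.
expect_tree_invariants <- function(fit) {
  for (n in fit$nodes) {
    if (length(n$children) > 0) {
      child_cells <- unlist(lapply(n$children,
                                   function(ch) fit$nodes[[ch]]$cells))
      expect_setequal(child_cells, n$cells)
      expect_equal(length(child_cells), length(n$cells))
    }
    if (!is.na(n$parent)) {
      expect_gte(n$threshold, fit$nodes[[n$parent]]$threshold)
    }
  }
  invisible(fit)
}
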