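#' Pairwise similarity between base clusters
#'
#' For every cross-method pair of base clusters x and y sharing at least one
#' cell, the similarity is the minimal proportion of cells shared:
#' \deqn{S_{x,y} = \min(N_{x \cap y} / N_x, \; N_{x \cap y} / N_y)}
#' where \eqn{N_{x \cap y}} is the number of cells in both clusters. This is
#' equivalently the smaller of the two association-rule confidences
#' conf(x -> y) and conf(y -> x). Identical clusters score 1; disjoint
#' clusters produce no edge. Clusters of the same method are never compared
#' (they are disjoint by construction).
#'
#' @param ps A `partition_set` from [run_ensemble()].
#' @return A data frame of edges with columns `method_x`, `label_x`,
#'   `method_y`, `label_y`, `n_x`, `n_y`, `n_shared`, `s`.
#' @export
pairwise_similarities <- function(ps) {
  stopifnot(inherits(ps, "partition_set"), length(ps$partitions) >= 2)
  methods_ <- names(ps$partitions)
  rows <- list()
  for (a in seq_along(methods_)) {
    for (b in seq_along(methods_)) {
      if (b <= a) next
      la <- ps$partitions[[a]]
      lb <- ps$partitions[[b]][names(la)]
      ct <- table(la, lb)
      nz <- which(ct > 0, arr.ind = TRUE)
      if (nrow(nz) == 0) next
      n_a <- rowSums(ct)
      n_b <- colSums(ct)
      shared <- ct[nz]
      rows[[length(rows) + 1]] <- data.frame(
        method_x = methods_[a],
        label_x = rownames(ct)[nz[, 1]],
        method_y = methods_[b],
        label_y = colnames(ct)[nz[, 2]],
        n_x = as.integer(n_a[nz[, 1]]),
        n_y = as.integer(n_b[nz[, 2]]),
        n_shared = as.integer(shared),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method_x = character(0), label_x = character(0),
               method_y = character(0), label_y = character(0),
               n_x = integer(0), n_y = integer(0), n_shared = integer(0))
  edges$s <- pmin(edges$n_shared / edges$n_x, edges$n_shared / edges$n_y)
  rownames(edges) <- NULL
  edges
}

.vertex_id <- function(method, label) paste(method, label, sep = "\r")

#' Build the strong-similarity graph over base clusters
#'
#' Keeps exactly the edges whose similarity strictly exceeds `s_lim`;
#' vertices (base clusters) with no strong edge are retained as isolated
#' vertices.
#'
#' @param edges Edge data frame from [pairwise_similarities()].
#' @param s_lim Similarity threshold in (0, 1); the default 0.5 demands that
#'   two clusters share the majority of their cells.
#' @param vertices Optional data frame with columns `method`, `label` giving
#'   the full vertex set (so isolated base clusters are represented); by
#'   default only vertices incident to some edge are known.
#' @return An [igraph::graph] whose vertices carry `method` and `label`
#'   attributes and whose edges carry `s` and `n_shared`.
#' @export
build_cluster_graph <- function(edges, s_lim = 0.5, vertices = NULL) {
  stopifnot(s_lim > 0, s_lim < 1)
  if (is.null(vertices)) {
    vertices <- unique(rbind(
      data.frame(method = edges$method_x, label = edges$label_x,
                 stringsAsFactors = FALSE),
      data.frame(method = edges$method_y, label = edges$label_y,
                 stringsAsFactors = FALSE)))
  }
  vertices <- unique(vertices[, c("method", "label")])
  vdf <- data.frame(name = .vertex_id(vertices$method, vertices$label),
                    method = vertices$method, label = vertices$label,
                    stringsAsFactors = FALSE)
  keep <- edges$s > s_lim
  edf <- data.frame(from = .vertex_id(edges$method_x[keep], edges$label_x[keep]),
                    to = .vertex_id(edges$method_y[keep], edges$label_y[keep]),
                    s = edges$s[keep], n_shared = edges$n_shared[keep],
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Extract components and their robustness from the strong-similarity graph
#'
#' Each connected component z of the filtered graph yields a candidate
#' robust cluster: its cells are the intersection of the cell sets of all
#' member base clusters, and its robustness is the weighted density of the
#' component,
#' \deqn{R_z = \frac{\sum_{x,y} S_{x,y}}{M(M-1)/2},}
#' the sum of its strong-edge similarities over the edge sum of a complete
#' agreement among all `M` methods. Robustness is 1 exactly when every
#' method predicts the identical cluster; a singleton vertex has robustness
#' 0. A component that contains two clusters of the same method has an empty
#' intersection and is discarded downstream.
#'
#' @param graph Graph from [build_cluster_graph()].
#' @param ps The `partition_set` the graph was derived from.
#' @param M Number of methods (defaults to `ps$M`).
#' @return A list of components, each a list with `vertices` (data frame
#'   `method`,`label`,`n`), `core_cells`, `n_strong_edges`, `robustness`.
#' @export
cluster_components <- function(graph, ps, M = ps$M) {
  stopifnot(inherits(ps, "partition_set"), M >= 2)
  denom <- M * (M - 1) / 2
  memb <- igraph::components(graph)$membership
  v_method <- igraph::vertex_attr(graph, "method")
  v_label <- igraph::vertex_attr(graph, "label")
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  e_s <- igraph::edge_attr(graph, "s")
  out <- list()
  for (comp_id in sort(unique(memb))) {
    vs <- which(memb == comp_id)
    cells <- NULL
    vrows <- data.frame(method = v_method[vs], label = v_label[vs],
                        n = NA_integer_, stringsAsFactors = FALSE)
    for (j in seq_along(vs)) {
      labs <- ps$partitions[[vrows$method[j]]]
      vcells <- names(labs)[labs == vrows$label[j]]
      vrows$n[j] <- length(vcells)
      cells <- if (j == 1) vcells else intersect(cells, vcells)
    }
    in_comp <- if (length(e_s)) {
      ends[, 1] %in% vs & ends[, 2] %in% vs
    } else logical(0)
    out[[length(out) + 1]] <- list(
      vertices = vrows,
      core_cells = cells,
      n_strong_edges = sum(in_comp),
      robustness = sum(e_s[in_comp]) / denom)
  }
  out
}

#' Minimum expected robustness of a majority agreement
#'
#' The robustness a cluster would have if `m` of the `M` methods agreed on
#' it at exactly the similarity threshold:
#' \deqn{R_{lim} = \frac{S_{lim} \cdot m(m-1)/2}{M(M-1)/2}.}
#' By default `m` is the strict majority `floor(M/2) + 1`, so with `M = 4`
#' methods and `s_lim = 0.5` the threshold is 0.25.
#'
#' @param s_lim Similarity threshold.
#' @param m Number of agreeing methods, `2 <= m <= M`; default the strict
#'   majority of `M`.
#' @param M Total number of methods.
#' @return The robustness threshold, a number in (0, 1].
#' @export
robustness_threshold <- function(s_lim, m = NULL, M) {
  stopifnot(s_lim > 0, s_lim <= 1, M >= 2)
  if (is.null(m)) m <- floor(M / 2) + 1
  if (m < 2 || m > M) stop("`m` must satisfy 2 <= m <= M")
  s_lim * (m * (m - 1) / 2) / (M * (M - 1) / 2)
}

#' One consensus step: robust clusters and the leftover
#'
#' Computes pairwise similarities, filters weak edges, extracts components,
#' and accepts every component whose robustness strictly exceeds
#' `r_threshold` and whose core intersection is non-empty. The cells of an
#' accepted component are the intersection of all its member base clusters.
#' All remaining cells form the leftover cluster, whose robustness is
#' exactly 0. In the rare event that two accepted cores overlap, the
#' overlapping cells go to the component with higher robustness (ties:
#' larger core, then lexicographically smallest member), so the output
#' always partitions the pool.
#'
#' @param ps A `partition_set`.
#' @param s_lim Similarity threshold (default 0.5).
#' @param r_threshold Robustness threshold; default
#'   `robustness_threshold(s_lim, M = ps$M)`.
#' @param M Number of methods (defaults to `ps$M`).
#' @return An object of class `consensus_outcome`: list with `robust` (list
#'   of clusters, each with `cells`, `robustness`, `methods`, `vertices`),
#'   `leftover` (`cells`, `robustness = 0`), `M`, `components`, `edges`.
#' @export
consensus_step <- function(ps, s_lim = 0.5, r_threshold = NULL, M = ps$M) {
  stopifnot(inherits(ps, "partition_set"))
  if (is.null(r_threshold)) r_threshold <- robustness_threshold(s_lim, M = M)
  edges <- pairwise_similarities(ps)
  vertices <- unique(do.call(rbind, lapply(names(ps$partitions), function(m) {
    data.frame(method = m, label = unique(ps$partitions[[m]]),
               stringsAsFactors = FALSE)
  })))
  graph <- build_cluster_graph(edges, s_lim, vertices = vertices)
  comps <- cluster_components(graph, ps, M)

  accepted <- Filter(function(z) {
    z$robustness > r_threshold && length(z$core_cells) > 0
  }, comps)

  # deterministic overlap resolution: higher robustness first, then larger
  # core, then lexicographically smallest (method, label) member
  if (length(accepted) > 1) {
    key <- vapply(accepted, function(z) {
      min(paste(z$vertices$method, z$vertices$label))
    }, "")
    ord <- order(-vapply(accepted, `[[`, 0, "robustness"),
                 -vapply(accepted, function(z) length(z$core_cells), 0L),
                 key)
    accepted <- accepted[ord]
  }
  taken <- character(0)
  robust <- list()
  for (z in accepted) {
    cells <- setdiff(z$core_cells, taken)
    if (length(cells) == 0) next
    taken <- c(taken, cells)
    robust[[length(robust) + 1]] <- list(
      cells = cells,
      robustness = z$robustness,
      methods = sort(unique(z$vertices$method)),
      vertices = z$vertices)
  }
  leftover <- list(cells = setdiff(ps$pool, taken), robustness = 0)
  structure(list(robust = robust, leftover = leftover, M = M,
                 r_threshold = r_threshold, components = comps,
                 edges = edges, pool = ps$pool),
            class = "consensus_outcome")
}
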