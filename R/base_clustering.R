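#' Define a base clusterer
#'
#' A base clusterer is one member of the ensemble roster. It declares which
#' normalization it consumes (`"lognorm"` or `"log2cpm"`) and a `fit`
#' function mapping a normalized genes x cells matrix and an integer seed to
#' one cluster label per cell. Labels are opaque: the consensus layer only
#' uses the partition they induce.
#'
#' @param name Short unique method name.
#' @param transform `"lognorm"` or `"log2cpm"`.
#' @param fit `function(norm, seed)` returning a label vector of length
#'   `ncol(norm)` with no missing values.
#' @return An object of class `base_clusterer`.
#' @seealso [builtin_roster()], [run_ensemble()]
#' @export
new_clusterer <- function(name, transform = c("lognorm", "log2cpm"), fit) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.function(fit))
  transform <- match.arg(transform)
  structure(list(name = name, transform = transform, fit = fit),
            class = "base_clusterer")
}

#' The built-in clusterer roster
#'
#' Four base clusterers covering distinct methodological families commonly
#' used in scRNA-seq:
#' \describe{
#'   \item{`knn_louvain`}{kNN-graph community detection with modularity
#'     optimization on a PCA embedding of log-normalized expression.}
#'   \item{`snn_louvain`}{Community detection on a shared-nearest-neighbour
#'     graph with Jaccard edge weights.}
#'   \item{`density_scan`}{Density-based clustering (a DBSCAN-style core/
#'     reachability scan) on a PCA embedding of log2-CPM expression;
#'     unreachable cells are attached to the nearest core point.}
#'   \item{`hier_silhouette`}{Ward hierarchical clustering of the embedding
#'     with the number of clusters chosen by maximal average silhouette
#'     width over k = 2..8.}
#' }
#'
#' @return A list of four [new_clusterer()] objects.
#' @export
builtin_roster <- function() {
  list(
    new_clusterer("knn_louvain", "lognorm", .fit_knn_louvain),
    new_clusterer("snn_louvain", "lognorm", .fit_snn_louvain),
    new_clusterer("density_scan", "log2cpm", .fit_density_scan),
    new_clusterer("hier_silhouette", "lognorm", .fit_hier_silhouette)
  )
}

# ---- shared embedding machinery ------------------------------------------

# PCA scores (cells x rank) of a normalized genes x cells matrix. run_ensemble
# caches the embedding in attr(norm, "embedding") so the roster shares it.
.pca_embed <- function(norm, rank = 50) {
  emb <- attr(norm, "embedding")
  if (!is.null(emb)) return(emb)
  x <- t(norm)
  x <- sweep(x, 2, colMeans(x))
  rank <- max(1, min(rank, nrow(x) - 1, ncol(x)))
  sv <- svd(x, nu = rank, nv = 0)
  emb <- sv$u * rep(sv$d[seq_len(rank)], each = nrow(x))
  rownames(emb) <- colnames(norm)
  emb
}

.default_k_neighbors <- function(n) max(2L, min(15L, floor(n / 5)))

# n x k matrix of nearest-neighbour indices (self excluded), plus the
# distance matrix, from a cells x dims embedding.
.knn_index <- function(emb, k) {
  d <- as.matrix(stats::dist(emb))
  n <- nrow(d)
  k <- min(k, n - 1)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    idx[i, ] <- order(d[i, -i])[seq_len(k)]
    idx[i, ] <- seq_len(n)[-i][idx[i, ]]
  }
  list(idx = idx, dist = d, k = k)
}

.louvain_labels <- function(g, seed) {
  with_seed(seed, {
    comm <- igraph::cluster_louvain(g)
    igraph::membership(comm)
  })
}

# ---- the four built-in fits ----------------------------------------------

.fit_knn_louvain <- function(norm, seed) {
  emb <- .pca_embed(norm)
  nn <- .knn_index(emb, .default_k_neighbors(nrow(emb)))
  n <- nrow(emb)
  from <- rep(seq_len(n), each = nn$k)
  to <- as.vector(t(nn$idx))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  as.character(.louvain_labels(g, seed))
}

.fit_snn_louvain <- function(norm, seed) {
  emb <- .pca_embed(norm)
  n <- nrow(emb)
  k <- .default_k_neighbors(n)
  nn <- .knn_index(emb, k)
  # neighbourhoods include the cell itself, as in SNN graph construction
  memb <- Matrix::sparseMatrix(
    i = c(seq_len(n), rep(seq_len(n), nn$k)),
    j = c(seq_len(n), as.vector(nn$idx)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  s <- shared@x[keep]
  jac <- s / (2 * (k + 1) - s)
  strong <- jac >= 1 / 15
  if (!any(strong)) return(rep("1", n))
  g <- igraph::graph_from_edgelist(cbind(i[strong], j[strong]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- jac[strong]
  as.character(.louvain_labels(g, seed))
}

# DBSCAN-style scan: core points have >= min_pts neighbours within eps
# (eps = median distance to the min_pts-th neighbour); clusters are connected
# components of core points within eps; border/noise cells join the cluster
# of their nearest core point.
.fit_density_scan <- function(norm, seed) {
  emb <- .pca_embed(norm)
  emb <- emb[, seq_len(min(10, ncol(emb))), drop = FALSE]
  n <- nrow(emb)
  min_pts <- max(3L, min(10L, floor(n / 20)))
  d <- as.matrix(stats::dist(emb))
  kth <- apply(d, 1, function(r) sort(r[-1])[min_pts])
  eps <- stats::median(kth)
  n_within <- rowSums(d <= eps) - 1L
  core <- which(n_within >= min_pts)
  if (length(core) == 0) return(rep("1", n))
  adj <- d[core, core, drop = FALSE] <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  labels <- integer(n)
  labels[core] <- comp
  rest <- setdiff(seq_len(n), core)
  if (length(rest)) {
    nearest_core <- core[apply(d[rest, core, drop = FALSE], 1, which.min)]
    labels[rest] <- labels[nearest_core]
  }
  as.character(labels)
}

.fit_hier_silhouette <- function(norm, seed) {
  emb <- .pca_embed(norm)
  n <- nrow(emb)
  d <- stats::dist(emb)
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:min(8, n - 1)
  best_k <- ks[1]
  best_sil <- -Inf
  for (k in ks) {
    cl <- stats::cutree(hc, k = k)
    sil <- mean(cluster::silhouette(cl, d)[, 3])
    if (sil > best_sil) {
      best_sil <- sil
      best_k <- k
    }
  }
  as.character(stats::cutree(hc, k = best_k))
}

# ---- ensemble runner ------------------------------------------------------

#' Run the clustering ensemble on a pool of cells
#'
#' Restricts the counts to the selected highly variable genes, computes each
#' normalization once (sharing one PCA embedding per transform across the
#' roster), and runs every clusterer with a deterministic per-method seed
#' derived from `seed`. Clusterers that raise an error are dropped with a
#' warning; at least two must succeed.
#'
#' @param counts_pool A genes x cells count matrix for the pool.
#' @param hvg Character vector of gene ids to cluster on (see
#'   [select_hvg()]); ids absent from `counts_pool` are ignored.
#' @param roster List of [new_clusterer()] objects (default
#'   [builtin_roster()]).
#' @param seed Integer seed for the run.
#' @return An object of class `partition_set`: a list with `pool` (cell
#'   ids), `partitions` (named list of label vectors over the pool) and `M`
#'   (the number of partitions actually produced).
#' @export
run_ensemble <- function(counts_pool, hvg, roster = builtin_roster(),
                         seed = 1) {
  .validate_counts(counts_pool)
  stopifnot(length(roster) >= 2)
  hvg <- intersect(hvg, rownames(counts_pool))
  if (length(hvg) == 0) stop("no selected genes present in the pool")
  sub <- counts_pool[hvg, , drop = FALSE]
  pool <- colnames(counts_pool)

  transforms <- unique(vapply(roster, `[[`, "", "transform"))
  norms <- list()
  for (tr in transforms) {
    norm <- suppressWarnings(
      if (tr == "log2cpm") to_log2_cpm(sub) else log_normalize(sub))
    attr(norm, "embedding") <- .pca_embed(norm)
    norms[[tr]] <- norm
  }

  partitions <- list()
  for (cl in roster) {
    seed_cl <- (as.numeric(seed) + .stable_hash(cl$name)) %% .Machine$integer.max
    labels <- tryCatch(
      cl$fit(norms[[cl$transform]], as.integer(seed_cl)),
      error = function(e) {
        warning("clusterer '", cl$name, "' failed and was omitted: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(labels)) next
    if (length(labels) != length(pool) || anyNA(labels)) {
      warning("clusterer '", cl$name,
              "' returned an invalid partition and was omitted")
      next
    }
    labels <- as.character(labels)
    names(labels) <- pool
    partitions[[cl$name]] <- labels
  }
  if (length(partitions) < 2) {
    stop(structure(class = c("ensemble_error", "error", "condition"),
                   list(message = "fewer than 2 base partitions completed",
                        call = sys.call())))
  }
  structure(list(pool = pool, partitions = partitions,
                 M = length(partitions)),
            class = "partition_set")
}

#' Import externally computed base partitions
#'
#' Reads one CSV per method (columns `cell_id,label`) and wraps each as a
#' fixed base clusterer, so that base clusterings computed by external tools
#' can be fed to the consensus layer through the same roster interface.
#'
#' @param paths Named character vector of CSV paths; names become method
#'   names (unnamed paths use the file name without extension).
#' @return A list of [new_clusterer()] objects.
#' @export
import_partitions <- function(paths) {
  nms <- names(paths)
  if (is.null(nms)) nms <- rep("", length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    df <- utils::read.csv(paths[[i]], stringsAsFactors = FALSE)
    if (!all(c("cell_id", "label") %in% names(df))) {
      stop("partition file must have columns cell_id,label: ", paths[[i]])
    }
    labels <- stats::setNames(as.character(df$label), df$cell_id)
    nm <- if (nzchar(nms[i])) nms[i] else
      sub("\\.[^.]*$", "", basename(paths[[i]]))
    out[[i]] <- local({
      labs <- labels
      new_clusterer(nm, "lognorm", function(norm, seed) {
        cells <- colnames(norm)
        if (!all(cells %in% names(labs))) {
          stop("imported partition does not cover the pool")
        }
        unname(labs[cells])
      })
    })
  }
  out
}
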