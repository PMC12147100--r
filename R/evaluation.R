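# Align two labellings on their common cells; errors if the overlap is empty.
.align_labellings <- function(a, b) {
  stopifnot(!is.null(names(a)), !is.null(names(b)),
            !anyDuplicated(names(a)), !anyDuplicated(names(b)))
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("labellings share no cells")
  list(a = as.character(a[common]), b = as.character(b[common]))
}

#' Normalized mutual information between two labellings
#'
#' Mutual information of the two partitions normalized, by default, by the
#' larger of the two entropies. The labellings are named vectors (cell id ->
#' label) and are intersected on their common cells first, so a
#' leftover-excluded prediction can be compared directly against a full
#' ground truth. When both partitions consist of a single cluster both
#' entropies are 0 and the value is undefined (`NA`).
#'
#' @param a,b Named label vectors.
#' @param variant Normalization: `"max"` (default), `"min"`, `"sqrt"` or
#'   `"sum"` (twice the MI over the entropy sum).
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
nmi <- function(a, b, variant = c("max", "min", "sqrt", "sum")) {
  variant <- match.arg(variant)
  al <- .align_labellings(a, b)
  ct <- table(al$a, al$b)
  n <- sum(ct)
  pi <- rowSums(ct) / n
  pj <- colSums(ct) / n
  ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  p <- ct / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pi, pj)[nz]))
  denom <- switch(variant,
                  max = max(ha, hb),
                  min = min(ha, hb),
                  sqrt = sqrt(ha * hb),
                  sum = (ha + hb) / 2)
  if (denom == 0) return(NA_real_)
  min(1, max(0, mi / denom))
}

#' Adjusted Rand index between two labellings
#'
#' The pair-counting Rand index corrected for chance agreement; 1 if and
#' only if the two partitions are identical (up to label names), around 0
#' for independent partitions, and possibly negative for systematic
#' disagreement. Labellings are intersected on their common cells.
#'
#' @param a,b Named label vectors.
#' @return A number `<= 1`.
#' @export
ari <- function(a, b) {
  al <- .align_labellings(a, b)
  ct <- table(al$a, al$b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  expected <- sum_i * sum_j / tot
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Mean silhouette width of a labelling in expression space
#'
#' Average over cells of `(b - a) / max(a, b)` where `a` is the mean
#' Euclidean distance to the cell's own cluster and `b` the smallest mean
#' distance to another cluster, computed on the normalized expression matrix
#' (cells in columns). Cells in singleton clusters score 0. Undefined
#' (`NA`) when the labelling has a single cluster.
#'
#' @param norm Normalized genes x cells matrix (typically restricted to
#'   highly variable genes).
#' @param labels Named label vector over (a subset of) the columns of
#'   `norm`.
#' @return Mean silhouette width in `[-1, 1]`, or `NA`.
#' @export
silhouette_score <- function(norm, labels) {
  cells <- intersect(names(labels), colnames(norm))
  if (length(cells) == 0) stop("labels share no cells with `norm`")
  labels <- labels[cells]
  if (length(unique(labels)) < 2) return(NA_real_)
  d <- stats::dist(t(norm[, cells, drop = FALSE]))
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Neighborhood purity of a labelling
#'
#' For each cell, the fraction of its `k_neighbors` nearest neighbours
#' (Euclidean distance in the same expression space as
#' [silhouette_score()]) that share its label, averaged over cells.
#'
#' @param norm Normalized genes x cells matrix.
#' @param labels Named label vector over (a subset of) the columns of
#'   `norm`.
#' @param k_neighbors Neighbourhood size (default 50, capped at `n - 1`).
#' @return A number in `[0, 1]`.
#' @export
neighborhood_purity <- function(norm, labels, k_neighbors = 50) {
  cells <- intersect(names(labels), colnames(norm))
  if (length(cells) < 2) stop("need at least 2 labelled cells")
  labels <- as.character(labels[cells])
  d <- as.matrix(stats::dist(t(norm[, cells, drop = FALSE])))
  n <- length(cells)
  k <- min(k_neighbors, n - 1)
  purity <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    mean(labels[nb] == labels[i])
  }, 0)
  mean(purity)
}
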