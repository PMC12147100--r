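#' Detect marker genes of a cell set
#'
#' A marker gene is a gene expressed much more strongly in one set of cells
#' than in the rest of the pool. The fold change is computed on the
#' de-logged normalized expression: per gene,
#' `log2_fc = log2((mean_in + pseudocount) / (mean_out + pseudocount))`,
#' where the means are taken over the inverse of the log transform of
#' `norm`. Genes whose `log2_fc` strictly exceeds `min_log2fc` are tested
#' with a two-sided Wilcoxon rank-sum test (normal approximation with tie
#' and continuity corrections) and Bonferroni-adjusted over all genes in the
#' matrix; those with adjusted p below `alpha` are returned, sorted by
#' descending fold change. The default `min_log2fc = 4` demands 16-fold
#' enrichment.
#'
#' @param norm A normalized genes x cells matrix ([log_normalize()] or
#'   [to_log2_cpm()]).
#' @param in_cells,out_cells Disjoint, non-empty character vectors of cell
#'   ids (columns of `norm`).
#' @param min_log2fc Minimum log2 fold change (strict).
#' @param pseudocount Added to both means before the ratio.
#' @param alpha Significance level on Bonferroni-adjusted p-values; set
#'   `test = FALSE` for fold-change-only behaviour.
#' @param test Whether to apply the rank-sum significance filter.
#' @return A data frame with columns `gene`, `log2_fc`, `p_value`,
#'   `p_adjusted`, sorted by descending `log2_fc`.
#' @export
find_markers <- function(norm, in_cells, out_cells, min_log2fc = 4,
                         pseudocount = 1, alpha = 0.05, test = TRUE) {
  stopifnot(is.matrix(norm))
  if (length(in_cells) == 0 || length(out_cells) == 0) {
    stop("`in_cells` and `out_cells` must be non-empty")
  }
  if (length(intersect(in_cells, out_cells)) > 0) {
    stop("`in_cells` and `out_cells` must be disjoint")
  }
  if (!all(c(in_cells, out_cells) %in% colnames(norm))) {
    stop("cell ids absent from `norm`")
  }
  expr <- .inv_transform(norm)
  mean_in <- rowMeans(expr[, in_cells, drop = FALSE])
  mean_out <- rowMeans(expr[, out_cells, drop = FALSE])
  fc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
  cand <- which(fc > min_log2fc)
  n_tested <- nrow(norm)
  res <- data.frame(gene = rownames(norm)[cand],
                    log2_fc = unname(fc[cand]),
                    p_value = rep(NA_real_, length(cand)),
                    p_adjusted = rep(NA_real_, length(cand)),
                    stringsAsFactors = FALSE)
  if (test && nrow(res) > 0) {
    p <- vapply(cand, function(g) {
      .wilcox_p(norm[g, in_cells], norm[g, out_cells])
    }, 0)
    res$p_value <- p
    res$p_adjusted <- pmin(1, p * n_tested)
    res <- res[res$p_adjusted < alpha, , drop = FALSE]
  }
  res <- res[order(-res$log2_fc, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Two-sided Wilcoxon rank-sum p-value, normal approximation with tie and
# continuity corrections (matches wilcox.test(exact = FALSE)).
.wilcox_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- (nx * ny / 12) *
    ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- z - sign(z) * 0.5 # continuity correction
  2 * stats::pnorm(-abs(z) / sqrt(sigma2))
}

#' Is a cluster well-characterized?
#'
#' A cluster is well-characterized when at least `min_markers` marker genes
#' are detected in it (default 10).
#'
#' @param markers Marker data frame from [find_markers()].
#' @param min_markers Required number of markers.
#' @return `TRUE` or `FALSE`.
#' @export
is_well_characterized <- function(markers, min_markers = 10) {
  nrow(markers) >= min_markers
}

#' Characterization filter on a consensus outcome
#'
#' Decides whether a consensus split is biologically meaningful. In a first
#' pass, marker genes are detected for every robust cluster against the rest
#' of the pool; robust clusters that are not well-characterized are merged
#' into the leftover. In a second pass, markers are recomputed for the
#' enlarged leftover (each robust cluster's reference -- the rest of the
#' pool -- is unchanged by the merge, so its markers carry over). If at
#' least one robust cluster survives, the split is returned, with the
#' leftover included regardless of its own marker count; otherwise no split
#' is made, which guards against over-clustering: robust but biologically
#' indistinct clusters are filtered out.
#'
#' @param norm Normalized genes x cells matrix over the pool (all genes, not
#'   only the highly variable ones).
#' @param outcome A `consensus_outcome` from [consensus_step()] on the same
#'   pool.
#' @param min_log2fc,min_markers,alpha,pseudocount,test Passed to
#'   [find_markers()] / [is_well_characterized()].
#' @return A list of clusters (each with `cells`, `robustness`, `markers`,
#'   `methods`, `is_leftover`), or `NULL` for "no split".
#' @export
characterize_split <- function(norm, outcome, min_log2fc = 4,
                               min_markers = 10, alpha = 0.05,
                               pseudocount = 1, test = TRUE) {
  stopifnot(inherits(outcome, "consensus_outcome"))
  pool <- outcome$pool
  if (length(outcome$robust) == 0) return(NULL)

  kept <- list()
  leftover_cells <- outcome$leftover$cells
  for (z in outcome$robust) {
    rest <- setdiff(pool, z$cells)
    if (length(rest) == 0) { # cluster equals the pool: not a split
      leftover_cells <- union(leftover_cells, z$cells)
      next
    }
    mk <- find_markers(norm, z$cells, rest, min_log2fc = min_log2fc,
                       pseudocount = pseudocount, alpha = alpha, test = test)
    if (is_well_characterized(mk, min_markers)) {
      z$markers <- mk
      kept[[length(kept) + 1]] <- z
    } else {
      leftover_cells <- union(leftover_cells, z$cells)
    }
  }
  if (length(kept) == 0) return(NULL)

  out <- lapply(kept, function(z) {
    list(cells = z$cells, robustness = z$robustness, markers = z$markers,
         methods = z$methods, is_leftover = FALSE)
  })
  if (length(leftover_cells) > 0) {
    rest <- setdiff(pool, leftover_cells)
    lk <- find_markers(norm, leftover_cells, rest, min_log2fc = min_log2fc,
                       pseudocount = pseudocount, alpha = alpha, test = test)
    out[[length(out) + 1]] <- list(cells = leftover_cells, robustness = 0,
                                   markers = lk, methods = character(0),
                                   is_leftover = TRUE)
  }
  out
}
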