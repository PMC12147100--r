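#' Normalization transforms for count matrices
#'
#' `log_normalize()` scales each cell to `scale` total counts and applies
#' `log(1 + x)`; this is the standard log-normalization used as input for
#' most of the built-in base clusterers and for marker detection.
#' `to_log2_cpm()` computes `log2(1 + CPM)` (counts per million per cell),
#' the transform consumed by the density-based clusterer. On UMI count data
#' with no gene-length information, CPM and TPM coincide.
#'
#' Cells with zero total counts produce an all-zero column and a warning.
#'
#' @param counts A genes x cells count matrix with dimnames (see
#'   [read_counts()]).
#' @param scale Per-cell scale factor for `log_normalize` (default `1e4`).
#' @return A dense genes x cells numeric matrix with an attribute
#'   `transform` set to `"lognorm"` or `"log2cpm"`.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  .validate_counts(counts)
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  .scale_transform(counts, scale, log_base = exp(1), tag = "lognorm")
}

#' @rdname log_normalize
#' @export
to_log2_cpm <- function(counts) {
  .validate_counts(counts)
  .scale_transform(counts, 1e6, log_base = 2, tag = "log2cpm")
}

.scale_transform <- function(counts, scale, log_base, tag) {
  m <- as.matrix(counts)
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts produce all-zero columns")
    totals[zero] <- 1 # columns are all zero anyway
  }
  out <- log1p(sweep(m, 2, scale / totals, `*`)) / log(log_base)
  attr(out, "transform") <- tag
  out
}

# Invert a normalized matrix back to the (scaled) expression scale.
.inv_transform <- function(norm) {
  tag <- attr(norm, "transform")
  if (identical(tag, "log2cpm")) 2^norm - 1 else expm1(norm)
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized expression,
#' standardized against a mean-variance trend fitted by local polynomial
#' (loess) smoothing, and returns the top `k` gene ids. When the data span
#' fewer than 20 distinct mean bins the trend cannot be fit reliably and the
#' ranking falls back to the raw variance of log-normalized expression.
#' Selection is deterministic; ties are broken by gene id so the result is
#' stable under gene reordering.
#'
#' @param counts A genes x cells count matrix.
#' @param k Number of genes to select; if `k >= nrow(counts)` all genes are
#'   returned, in variance order.
#' @return A character vector of `min(k, n_genes)` gene ids, most variable
#'   first.
#' @export
select_hvg <- function(counts, k) {
  .validate_counts(counts)
  stopifnot(length(k) == 1, k >= 1)
  norm <- suppressWarnings(log_normalize(counts))
  if (ncol(norm) < 2) stop("no variable genes")
  mu <- rowMeans(norm)
  v <- rowSums((norm - mu)^2) / (ncol(norm) - 1)
  if (all(v == 0)) stop("no variable genes")
  score <- .standardized_variance(mu, v)
  ord <- order(-score, rownames(counts))
  rownames(counts)[ord][seq_len(min(k, nrow(counts)))]
}

# Variance standardized against a loess mean-variance trend on log10 scale,
# fitted over genes with positive mean and variance. Genes with zero
# variance score 0; if fewer than 20 distinct mean bins exist, raw variance
# is used unchanged.
.standardized_variance <- function(mu, v) {
  fit_idx <- which(mu > 0 & v > 0)
  n_bins <- length(unique(signif(mu[fit_idx], 3)))
  if (n_bins < 20) return(v)
  lx <- log10(mu[fit_idx])
  ly <- log10(v[fit_idx])
  trend <- tryCatch(
    stats::loess(ly ~ lx, span = 0.3, degree = 2,
                 family = "symmetric")$fitted,
    error = function(e) NULL)
  if (is.null(trend)) return(v)
  score <- numeric(length(mu))
  score[fit_idx] <- v[fit_idx] / 10^trend
  score
}
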