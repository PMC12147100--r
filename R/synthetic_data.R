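#' Cluster size schemes for synthetic datasets
#'
#' `balanced_sizes()` splits `N` cells evenly over `k` clusters, spreading
#' the remainder over the first `N %% k` clusters, so the sizes always sum
#' to `N`. `imbalanced_sizes()` emulates rare populations with a geometric
#' size scheme: cluster `i` receives the normalized geometric weight
#' `2^(-i) / (1 - 2^(-k))` of the `N` cells, floored. Flooring can leave a
#' few cells short of `N`; they are deliberately not redistributed, so
#' `imbalanced_sizes(10000, 5)` is exactly `c(5161, 2580, 1290, 645, 322)`
#' (summing to 9998).
#'
#' @param N Total number of cells.
#' @param k Number of clusters.
#' @return Integer vector of `k` cluster sizes (descending for the
#'   imbalanced scheme).
#' @export
balanced_sizes <- function(N, k) {
  stopifnot(N >= 1, k >= 1)
  sizes <- rep(N %/% k, k)
  rem <- N %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  as.integer(sizes)
}

#' @rdname balanced_sizes
#' @export
imbalanced_sizes <- function(N, k) {
  stopifnot(N >= 1, k >= 1)
  i <- seq_len(k)
  as.integer(floor(N * 2^(-i) / (1 - 2^(-k))))
}

#' Perturb a gene-mean profile with differentially expressed genes
#'
#' Selects `ceiling(de_fraction * length(mu))` genes uniformly at random and
#' multiplies their means by `2^(s * f)` where `f ~ Normal(fc_log2_mean,
#' fc_log2_sd)` and the sign `s` is random, leaving all other genes
#' untouched. Uses the current RNG state; seed outside (e.g. via
#' [with_seed()]) for reproducibility.
#'
#' @param mu Strictly positive named vector of gene means.
#' @param de_fraction Fraction of genes to perturb, in (0, 1).
#' @param fc_log2_mean,fc_log2_sd Mean and sd of the per-gene log2 fold
#'   factor.
#' @return A list with `profile` (the perturbed means) and `de_genes` (ids
#'   of the perturbed genes).
#' @export
perturb_profile <- function(mu, de_fraction, fc_log2_mean = 6,
                            fc_log2_sd = 0.5) {
  stopifnot(all(mu > 0), de_fraction > 0, de_fraction < 1)
  n_de <- ceiling(de_fraction * length(mu))
  idx <- sample(length(mu), n_de)
  f <- stats::rnorm(n_de, fc_log2_mean, fc_log2_sd)
  s <- sample(c(-1, 1), n_de, replace = TRUE)
  mu[idx] <- mu[idx] * 2^(s * f)
  list(profile = mu, de_genes = names(mu)[idx])
}

#' Simulate a ground-truth-labelled scRNA-seq count dataset
#'
#' Generates a genes x cells matrix of negative-binomial (gamma-Poisson)
#' counts around cluster-specific expression profiles, with log-normal
#' per-cell library sizes -- the dispersed count model underlying scRNA-seq
#' data. A base profile of log-normal gene means is perturbed once per
#' cluster ([perturb_profile()]), along one of two designs:
#' \describe{
#'   \item{unrelated (`related = FALSE`)}{every cluster profile is an
#'     independent perturbation of the base profile, so clusters differ from
#'     each other roughly equally;}
#'   \item{related (`related = TRUE`)}{cluster `i + 1` is a perturbation of
#'     cluster `i`, giving a chain of increasingly divergent transcriptomes
#'     (as with developmentally related cell types).}
#' }
#' Cluster sizes follow [balanced_sizes()] or [imbalanced_sizes()]; with the
#' imbalanced scheme the realized cell count can fall a few cells short of
#' `n_cells`. With `n_clusters = 1` no genes are perturbed.
#'
#' @param n_cells Target number of cells `N`.
#' @param n_clusters Number of clusters `k`.
#' @param balanced Balanced (`TRUE`) or geometric-imbalanced cluster sizes.
#' @param related Chain-perturbed (`TRUE`) or independently perturbed
#'   cluster transcriptomes.
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes perturbed per cluster.
#' @param fc_log2_mean,fc_log2_sd Log2 fold-factor distribution of
#'   perturbed genes.
#' @param dispersion Negative-binomial dispersion: `var = mu + dispersion *
#'   mu^2`.
#' @param libsize_log_sd Log-sd of per-cell library sizes.
#' @param mean_library Mean library size (total counts per cell).
#' @param seed Integer seed; the dataset is byte-identical for a fixed seed.
#' @return An object of class `synth_dataset`: list with `counts` (integer
#'   matrix, genes x cells), `labels` (named cell -> cluster id), `profiles`
#'   (per-cluster mean vectors), `de_genes` (per-cluster perturbed gene
#'   sets), `sizes`, and the generating parameters in `params`.
#' @export
simulate_cells <- function(n_cells, n_clusters, balanced = TRUE,
                           related = FALSE, n_genes = 2000,
                           de_fraction = 0.1, fc_log2_mean = 6,
                           fc_log2_sd = 0.5, dispersion = 0.15,
                           libsize_log_sd = 0.25, mean_library = 5000,
                           seed = 1) {
  stopifnot(n_cells >= 1, n_clusters >= 1, n_genes >= 2,
            dispersion > 0, libsize_log_sd > 0, mean_library > 0,
            de_fraction * n_genes >= 1)
  with_seed(seed, {
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    base <- stats::setNames(exp(stats::rnorm(n_genes, 0, 1.5)), gene_ids)

    profiles <- vector("list", n_clusters)
    de_genes <- vector("list", n_clusters)
    if (n_clusters == 1) {
      profiles[[1]] <- base
      de_genes[[1]] <- character(0)
    } else {
      parent <- base
      for (i in seq_len(n_clusters)) {
        src <- if (related) parent else base
        pert <- perturb_profile(src, de_fraction, fc_log2_mean, fc_log2_sd)
        profiles[[i]] <- pert$profile
        de_genes[[i]] <- pert$de_genes
        if (related) parent <- pert$profile
      }
    }
    names(profiles) <- names(de_genes) <- paste0("p", seq_len(n_clusters))

    sizes <- if (balanced) balanced_sizes(n_cells, n_clusters) else
      imbalanced_sizes(n_cells, n_clusters)
    total <- sum(sizes)
    cell_ids <- sprintf("cell%05d", seq_len(total))
    labels <- stats::setNames(rep(names(profiles), sizes), cell_ids)

    lib <- stats::rlnorm(total, log(mean_library) - libsize_log_sd^2 / 2,
                         libsize_log_sd)
    counts <- matrix(0L, n_genes, total, dimnames = list(gene_ids, cell_ids))
    offset <- 0
    for (i in seq_len(n_clusters)) {
      if (sizes[i] == 0) next
      p <- profiles[[i]] / sum(profiles[[i]])
      cols <- offset + seq_len(sizes[i])
      mu <- outer(p, lib[cols]) # genes x cells expected counts
      draws <- stats::rnbinom(length(mu), mu = as.vector(mu),
                              size = 1 / dispersion)
      counts[, cols] <- as.integer(draws)
      offset <- offset + sizes[i]
    }
    structure(list(counts = counts, labels = labels, profiles = profiles,
                   de_genes = de_genes, sizes = sizes,
                   params = list(n_cells = n_cells, n_clusters = n_clusters,
                                 balanced = balanced, related = related,
                                 n_genes = n_genes,
                                 de_fraction = de_fraction,
                                 fc_log2_mean = fc_log2_mean,
                                 fc_log2_sd = fc_log2_sd,
                                 dispersion = dispersion,
                                 libsize_log_sd = libsize_log_sd,
                                 mean_library = mean_library, seed = seed)),
              class = "synth_dataset")
  })
}

#' @method print synth_dataset
#' @export
print.synth_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic scRNA-seq dataset: %d genes x %d cells, %d cluster(s)\n",
    nrow(x$counts), ncol(x$counts), p$n_clusters))
  cat(sprintf("  sizes: %s (%s, %s)\n", paste(x$sizes, collapse = ", "),
              if (p$balanced) "balanced" else "imbalanced",
              if (p$related) "related" else "unrelated"))
  invisible(x)
}
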