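#' Configuration of a recursive ensemble clustering run
#'
#' @param k_hvg Number of highly variable genes selected per pool
#'   (default 1000).
#' @param s_lim Similarity threshold for strong edges (default 0.5: two base
#'   clusters must share the majority of their cells).
#' @param min_cells Pools smaller than this are never clustered
#'   (default 100).
#' @param min_log2fc Marker fold-change threshold (default 4, i.e. 16-fold).
#' @param min_markers Markers required for a cluster to count as
#'   well-characterized (default 10).
#' @param alpha Significance level for the Bonferroni-adjusted marker test.
#' @param test Whether markers additionally require rank-sum significance.
#' @param roster List of base clusterers (default [builtin_roster()]).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param include_leftover_in_recursion Whether leftover clusters are
#'   recursed like robust clusters (default `TRUE`).
#' @param max_depth Safety cap on recursion depth.
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(k_hvg = 1000, s_lim = 0.5, min_cells = 100,
                        min_log2fc = 4, min_markers = 10, alpha = 0.05,
                        test = TRUE, roster = builtin_roster(), seed = 1,
                        include_leftover_in_recursion = TRUE,
                        max_depth = 20) {
  stopifnot(k_hvg >= 1, s_lim > 0, s_lim < 1, min_cells >= 2,
            min_log2fc > 0, min_markers >= 1, alpha > 0, alpha <= 1,
            length(roster) >= 2, max_depth >= 1)
  structure(list(k_hvg = as.integer(k_hvg), s_lim = s_lim,
                 min_cells = as.integer(min_cells), min_log2fc = min_log2fc,
                 min_markers = as.integer(min_markers), alpha = alpha,
                 test = isTRUE(test), roster = roster,
                 seed = as.integer(seed),
                 include_leftover_in_recursion =
                   isTRUE(include_leftover_in_recursion),
                 max_depth = as.integer(max_depth)),
            class = "tree_config")
}

#' Fit a multi-resolution ensemble cluster tree
#'
#' Recursively clusters a single-cell count matrix with an ensemble of base
#' clustering methods. Each recursion on a pool of cells (starting from the
#' root pool `"C"` of all cells) selects highly variable genes, runs every
#' base clusterer, extracts robust clusters as connected components of the
#' strong-similarity graph between base clusters, scores each by its
#' robustness (weighted subgraph density in `[0, 1]`), filters the split
#' through the marker-gene characterization rule, and recurses into every
#' accepted child. A child is accepted only if its robustness strictly
#' exceeds `max(R_lim, R_parent)`, so the agreement between methods must
#' increase with depth; cells on which the methods do not agree form a
#' leftover cluster (robustness 0) that is itself recursed.
#'
#' Robust children of a node `P` are labelled `P.1, P.2, ...` by descending
#' size and its leftover child `P.L`, so e.g. `C.L.1` is the first robust
#' cluster found inside the root's leftover.
#'
#' @param counts A genes x cells count matrix of non-negative integers with
#'   unique dimnames (see [read_counts()]).
#' @param config A [tree_config()].
#' @param ... Named `tree_config()` fields overriding `config`.
#' @return An object of class `ensemble_tree` with elements:
#'   \describe{
#'     \item{`nodes`}{named list of cluster nodes (label, cells, robustness,
#'       parent, children, is_leftover, markers, methods, depth,
#'       threshold).}
#'     \item{`tables`}{the four result tables `meta`, `samples`, `features`,
#'       `methods` (see [write_result_tables()]).}
#'     \item{`log`}{one structured row per attempted recursion.}
#'     \item{`config`, `call`}{the configuration and matched call.}
#'   }
#' @seealso [leaf_clusters()], [summary.ensemble_tree()],
#'   [plot.ensemble_tree()]
#' @examples
#' \donttest{
#' sim <- simulate_cells(n_cells = 400, n_clusters = 2, n_genes = 300,
#'                       seed = 7)
#' fit <- ensemble_tree(sim$counts, min_cells = 50, k_hvg = 200, seed = 7)
#' print(fit)
#' table(leaf_clusters(fit), sim$labels)
#' }
#' @export
ensemble_tree <- function(counts, config = tree_config(), ...) {
  cl <- match.call()
  dots <- list(...)
  if (length(dots)) {
    cfg <- unclass(config)
    stopifnot(all(names(dots) %in% names(cfg)))
    cfg[names(dots)] <- dots
    config <- do.call(tree_config, cfg)
  }
  .validate_counts(counts)

  nodes <- list()
  log_rows <- list()
  root <- list(label = "C", cells = colnames(counts), robustness = 0,
               parent = NA_character_, children = character(0),
               is_leftover = FALSE, markers = NULL,
               methods = character(0), depth = 0L, threshold = 0)
  nodes[["C"]] <- root

  queue <- "C"
  while (length(queue) > 0) {
    label <- queue[[1]]
    queue <- queue[-1]
    node <- nodes[[label]]
    step <- .recursion_step(counts, node, config)
    log_rows[[length(log_rows) + 1]] <- step$log
    if (is.null(step$children)) next
    child_labels <- character(0)
    for (ch in step$children) {
      nodes[[ch$label]] <- ch
      child_labels <- c(child_labels, ch$label)
      recurse <- length(ch$cells) >= config$min_cells &&
        ch$depth < config$max_depth &&
        (!ch$is_leftover || config$include_leftover_in_recursion)
      if (recurse) queue <- c(queue, ch$label)
    }
    nodes[[label]]$children <- child_labels
  }

  fit <- structure(
    list(nodes = nodes, tables = NULL,
         log = do.call(rbind, log_rows), config = config, call = cl),
    class = "ensemble_tree")
  fit$tables <- .result_tables(fit)
  fit
}

# One clustering recursion on the pool of `node`. Returns list(children, log);
# children is NULL when the pool is not split.
.recursion_step <- function(counts, node, config) {
  pool <- node$cells
  mk_log <- function(decision, M = NA_integer_, n_comp = NA_integer_,
                     n_robust = NA_integer_, n_char = NA_integer_,
                     threshold = NA_real_) {
    data.frame(label = node$label, n_cells = length(pool), M = M,
               n_components = n_comp, n_robust = n_robust,
               n_characterized = n_char, threshold = threshold,
               decision = decision, stringsAsFactors = FALSE)
  }
  if (length(pool) < config$min_cells) {
    return(list(children = NULL, log = mk_log("pool_below_min_cells")))
  }
  sub <- counts[, pool, drop = FALSE]
  hvg <- tryCatch(select_hvg(sub, config$k_hvg), error = function(e) NULL)
  if (is.null(hvg)) {
    return(list(children = NULL, log = mk_log("no_variable_genes")))
  }
  pool_seed <- (as.numeric(config$seed) + .stable_hash(node$label)) %%
    .Machine$integer.max
  ps <- tryCatch(
    run_ensemble(sub, hvg, config$roster, as.integer(pool_seed)),
    ensemble_error = function(e) NULL)
  if (is.null(ps)) {
    return(list(children = NULL, log = mk_log("ensemble_failed")))
  }
  r_lim <- robustness_threshold(config$s_lim, M = ps$M)
  eff <- max(r_lim, node$robustness)
  outcome <- consensus_step(ps, config$s_lim, eff, ps$M)
  norm <- suppressWarnings(log_normalize(sub))
  split <- characterize_split(norm, outcome,
                              min_log2fc = config$min_log2fc,
                              min_markers = config$min_markers,
                              alpha = config$alpha, test = config$test)
  n_char <- if (is.null(split)) 0L else sum(!vapply(split, `[[`, TRUE,
                                                    "is_leftover"))
  logrow <- mk_log(if (is.null(split)) "no_split" else "split",
                   M = ps$M, n_comp = length(outcome$components),
                   n_robust = length(outcome$robust), n_char = n_char,
                   threshold = eff)
  if (is.null(split)) return(list(children = NULL, log = logrow))

  children <- assign_labels(node$label, split)
  children <- lapply(children, function(ch) {
    ch$depth <- node$depth + 1L
    ch$parent <- node$label
    ch$children <- character(0)
    ch$threshold <- eff
    ch
  })
  list(children = children, log = logrow)
}

#' Label the children of a tree node
#'
#' Robust children are named `parent.1, parent.2, ...` ordered by
#' descending size (ties broken by the lexicographically smallest cell id);
#' the leftover child is named `parent.L`.
#'
#' @param parent_label Label of the parent node.
#' @param children List of child clusters (each with `cells` and
#'   `is_leftover`), e.g. from [characterize_split()].
#' @return The same list, ordered robust-first, with a `label` field added.
#' @export
assign_labels <- function(parent_label, children) {
  is_left <- vapply(children, function(ch) isTRUE(ch$is_leftover), TRUE)
  robust <- children[!is_left]
  if (length(robust) > 1) {
    sizes <- vapply(robust, function(ch) length(ch$cells), 0L)
    first_cell <- vapply(robust, function(ch) min(ch$cells), "")
    robust <- robust[order(-sizes, first_cell)]
  }
  for (i in seq_along(robust)) {
    robust[[i]]$label <- paste0(parent_label, ".", i)
  }
  leftover <- children[is_left]
  for (i in seq_along(leftover)) {
    leftover[[i]]$label <- paste0(parent_label, ".L")
  }
  c(robust, leftover)
}

#' Extract the leaf clustering of a fitted tree
#'
#' Each cell is labelled by the deepest node containing it (a "leaf
#' cluster": a cluster the recursion could not subdivide). With
#' `include_leftover = FALSE`, cells whose leaf is a leftover node are
#' omitted -- the evaluation protocol that keeps only cells the ensemble is
#' confident about.
#'
#' @param tree An [ensemble_tree()] fit.
#' @param include_leftover Keep cells whose leaf is a leftover cluster?
#' @return A named character vector mapping cell id to leaf label.
#' @export
leaf_clusters <- function(tree, include_leftover = TRUE) {
  stopifnot(inherits(tree, "ensemble_tree"))
  labels <- stats::setNames(rep("C", length(tree$nodes[["C"]]$cells)),
                            tree$nodes[["C"]]$cells)
  # nodes were inserted in BFS order, so later assignments are deeper
  for (node in tree$nodes) {
    if (node$label == "C") next
    labels[node$cells] <- node$label
  }
  if (!include_leftover) {
    leaf_is_leftover <- vapply(tree$nodes, function(n) {
      n$is_leftover && length(n$children) == 0
    }, TRUE)
    drop_labels <- names(tree$nodes)[leaf_is_leftover]
    labels <- labels[!labels %in% drop_labels]
  }
  labels
}

# Assemble the four result tables from the node list.
.result_tables <- function(tree) {
  nodes <- tree$nodes
  meta <- do.call(rbind, lapply(nodes, function(n) {
    data.frame(label = n$label, size = length(n$cells),
               robustness = n$robustness, parent = n$parent,
               is_leftover = n$is_leftover, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL

  cells <- nodes[["C"]]$cells
  max_depth <- max(vapply(nodes, `[[`, 0L, "depth"))
  samples <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  if (max_depth >= 1) {
    level <- matrix("C", nrow = length(cells), ncol = max_depth,
                    dimnames = list(cells, paste0("level_", seq_len(max_depth))))
    for (n in nodes) {
      if (n$depth == 0) next
      level[n$cells, n$depth:max_depth] <- n$label
    }
    # deeper columns inherit the deepest available label; overwrite where
    # true deeper nodes exist (nodes are BFS-ordered so this is already so)
    samples <- cbind(samples, as.data.frame(level, stringsAsFactors = FALSE))
    rownames(samples) <- NULL
  }
  leaves <- leaf_clusters(tree)
  samples$leaf <- unname(leaves[samples$cell_id])

  feat_rows <- lapply(nodes, function(n) {
    if (is.null(n$markers) || nrow(n$markers) == 0) return(NULL)
    cbind(data.frame(label = n$label, stringsAsFactors = FALSE), n$markers)
  })
  features <- do.call(rbind, Filter(Negate(is.null), feat_rows))
  if (is.null(features)) {
    features <- data.frame(label = character(0), gene = character(0),
                           log2_fc = numeric(0), p_value = numeric(0),
                           p_adjusted = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(features) <- NULL

  meth_rows <- lapply(nodes, function(n) {
    if (length(n$methods) == 0) return(NULL)
    data.frame(label = n$label, method = n$methods, stringsAsFactors = FALSE)
  })
  methods_tab <- do.call(rbind, Filter(Negate(is.null), meth_rows))
  if (is.null(methods_tab)) {
    methods_tab <- data.frame(label = character(0), method = character(0),
                              stringsAsFactors = FALSE)
  }
  rownames(methods_tab) <- NULL

  list(meta = meta, samples = samples, features = features,
       methods = methods_tab)
}
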