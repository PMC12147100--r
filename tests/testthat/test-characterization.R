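# Build a "normalized" matrix directly from chosen expression values so the
# fold changes are exact by construction.
norm_from_expr <- function(expr) {
  out <- log1p(expr)
  attr(out, "transform") <- "lognorm"
  out
}

test_that("fold changes follow the pseudocount-shifted mean ratio", {
  in_cells <- paste0("i", 1:20)
  out_cells <- paste0("o", 1:20)
  expr <- matrix(0, 3, 40,
                 dimnames = list(c("strong", "flat", "zero"),
                                 c(in_cells, out_cells)))
  expr["strong", in_cells] <- 310
  expr["strong", out_cells] <- 9   # (310+1)/(9+1) = 31.1-fold
  expr["flat", ] <- 50
  norm <- norm_from_expr(expr)

  mk <- find_markers(norm, in_cells, out_cells, min_log2fc = 4)
  expect_equal(mk$gene, "strong")
  expect_equal(mk$log2_fc, log2(311 / 10))
  expect_lt(mk$p_adjusted, 0.05)
  expect_gte(mk$p_adjusted[1], mk$p_value[1])

  # an all-zero gene has symmetric means and is excluded
  mk_all <- find_markers(norm, in_cells, out_cells, min_log2fc = 0.1,
                         test = FALSE)
  expect_false("zero" %in% mk_all$gene)
  expect_false("flat" %in% mk_all$gene)

  expect_error(find_markers(norm, character(0), out_cells), "non-empty")
  expect_error(find_markers(norm, in_cells, c(in_cells[1], out_cells)),
               "disjoint")
})

test_that("rank-sum p-values match the reference implementation", {
  with_seed(31, {
    x <- rpois(25, 5) + runif(25)
    y <- rpois(30, 7) + runif(30)
  })
  p_ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(scEnsembleTree:::.wilcox_p(x, y), p_ref, tolerance = 1e-10)
  # with heavy ties
  x2 <- rep(c(1, 2), 10)
  y2 <- rep(c(1, 2, 2), 8)
  p_ref2 <- suppressWarnings(
    stats::wilcox.test(x2, y2, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(scEnsembleTree:::.wilcox_p(x2, y2), p_ref2, tolerance = 1e-10)
})

test_that("no markers are detected between identically distributed groups", {
  with_seed(41, {
    expr <- matrix(rpois(200 * 60, 5), 200, 60,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("c%03d", 1:60)))
  })
  norm <- norm_from_expr(expr)
  mk <- find_markers(norm, sprintf("c%03d", 1:30), sprintf("c%03d", 31:60))
  expect_equal(nrow(mk), 0)
})

test_that("the well-characterized rule is a >= 10 marker threshold", {
  fake <- function(n) data.frame(gene = sprintf("g%d", seq_len(n)),
                                 log2_fc = rep(5, n),
                                 p_value = rep(0, n),
                                 p_adjusted = rep(0, n))
  expect_true(is_well_characterized(fake(10)))
  expect_false(is_well_characterized(fake(9)))
  expect_false(is_well_characterized(fake(0)))
  expect_true(is_well_characterized(fake(3), min_markers = 3))
})

test_that("characterization keeps distinct clusters and vetoes clones", {
  # two transcriptomically distinct populations: >= 10 strongly enriched
  # genes each
  sim <- simulate_cells(n_cells = 200, n_clusters = 2, n_genes = 600,
                        seed = 91)
  norm <- log_normalize(sim$counts)
  cl1 <- names(sim$labels)[sim$labels == "p1"]
  cl2 <- names(sim$labels)[sim$labels == "p2"]
  outcome <- structure(list(
    robust = list(list(cells = cl1, robustness = 0.8, methods = "m1",
                       vertices = NULL),
                  list(cells = cl2, robustness = 0.7, methods = "m2",
                       vertices = NULL)),
    leftover = list(cells = character(0), robustness = 0),
    M = 4, pool = names(sim$labels)), class = "consensus_outcome")
  split <- characterize_split(norm, outcome)
  expect_false(is.null(split))
  expect_equal(sum(!vapply(split, `[[`, TRUE, "is_leftover")), 2)
  for (ch in split) {
    if (!ch$is_leftover) expect_gte(nrow(ch$markers), 10)
  }

  # the same population split at random in two: no 16-fold genes, no split
  sim1 <- simulate_cells(n_cells = 200, n_clusters = 1, n_genes = 400,
                         seed = 92)
  norm1 <- log_normalize(sim1$counts)
  cells <- colnames(sim1$counts)
  fake <- structure(list(
    robust = list(list(cells = cells[1:100], robustness = 0.9,
                       methods = "m1", vertices = NULL),
                  list(cells = cells[101:200], robustness = 0.9,
                       methods = "m2", vertices = NULL)),
    leftover = list(cells = character(0), robustness = 0),
    M = 4, pool = cells), class = "consensus_outcome")
  expect_null(characterize_split(norm1, fake))

  # zero robust clusters is always a no-split
  empty <- structure(list(robust = list(),
                          leftover = list(cells = cells, robustness = 0),
                          M = 4, pool = cells),
                     class = "consensus_outcome")
  expect_null(characterize_split(norm1, empty))
})

test_that("merging only moves cells into the leftover and conserves the pool", {
  sim <- simulate_cells(n_cells = 300, n_clusters = 2, n_genes = 600,
                        seed = 93)
  norm <- log_normalize(sim$counts)
  cells <- names(sim$labels)
  cl1 <- cells[sim$labels == "p1"]
  rest <- setdiff(cells, cl1)
  # one real cluster and one arbitrary (uncharacterizable) chunk of the rest
  outcome <- structure(list(
    robust = list(list(cells = cl1, robustness = 0.9, methods = "m1",
                       vertices = NULL),
                  list(cells = rest[1:40], robustness = 0.5, methods = "m2",
                       vertices = NULL)),
    leftover = list(cells = rest[-(1:40)], robustness = 0),
    M = 4, pool = cells), class = "consensus_outcome")
  split <- characterize_split(norm, outcome)
  expect_false(is.null(split))
  left <- split[[which(vapply(split, `[[`, TRUE, "is_leftover"))]]
  # the uncharacterized chunk was merged into the leftover
  expect_true(all(rest[1:40] %in% left$cells))
  expect_identical(left$robustness, 0)
  got <- unlist(lapply(split, `[[`, "cells"))
  expect_setequal(got, cells)
  expect_equal(length(got), length(cells))
})
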