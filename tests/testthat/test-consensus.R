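test_that("pairwise similarity is the minimal shared proportion", {
  pool <- paste0("c", 1:6)
  ps <- make_partition_set(pool, list(
    m1 = c("x", "x", "a", "a", "a", "a"),      # x = {c1,c2}
    m2 = c("y", "y", "y", "y", "b", "b")))     # y = {c1..c4}
  edges <- pairwise_similarities(ps)
  xy <- edges[edges$label_x == "x" & edges$label_y == "y", ]
  expect_equal(xy$n_shared, 2L)
  expect_equal(xy$s, min(2 / 2, 2 / 4)) # 0.5

  # identical clusters score 1, disjoint clusters produce no edge
  ps2 <- make_partition_set(pool, list(
    m1 = c("x", "x", "x", "a", "a", "a"),
    m2 = c("y", "y", "y", "b", "b", "b")))
  e2 <- pairwise_similarities(ps2)
  expect_equal(e2$s[e2$label_x == "x" & e2$label_y == "y"], 1)
  expect_equal(nrow(e2[e2$label_x == "x" & e2$label_y == "b", ]), 0)
})

test_that("weak edges are filtered strictly and components follow", {
  pool <- paste0("c", 1:6)
  # m1 x = {c1,c2}; m2 y = {c1..c4}: s = 0.5 exactly
  ps <- make_partition_set(pool, list(
    m1 = c("x", "x", "a", "a", "a", "a"),
    m2 = c("y", "y", "y", "y", "b", "b")))
  edges <- pairwise_similarities(ps)
  g <- build_cluster_graph(edges, s_lim = 0.5)
  expect_equal(igraph::ecount(g), 0) # s == s_lim is weak (strict rule)

  g2 <- build_cluster_graph(data.frame(method_x = "m1", label_x = "x",
                                       method_y = "m2", label_y = "y",
                                       n_x = 2L, n_y = 2L, n_shared = 2L,
                                       s = 0.6),
                            s_lim = 0.5)
  expect_equal(igraph::ecount(g2), 1)
})

test_that("component robustness follows the weighted subgraph density", {
  pool <- paste0("c", 1:8)
  # all four methods predict the same two clusters
  same <- c("u", "u", "u", "u", "v", "v", "v", "v")
  ps <- make_partition_set(pool, list(m1 = same, m2 = same,
                                      m3 = same, m4 = same))
  out <- consensus_step(ps, s_lim = 0.5, r_threshold = 0.25)
  expect_equal(length(out$robust), 2)
  expect_equal(vapply(out$robust, `[[`, 0, "robustness"), c(1, 1))
  expect_equal(out$leftover$cells, character(0))
  comp_sizes <- vapply(out$components, function(z) z$n_strong_edges, 0)
  expect_setequal(comp_sizes, c(6, 6)) # complete graphs on 4 vertices

  # two vertices joined by s = 0.6 with M = 4: R = 0.6 / 6 = 0.1
  ps2 <- make_partition_set(paste0("c", 1:10), list(
    m1 = c(rep("x", 5), rep("a", 5)),
    m2 = c(rep("y", 3), rep("b", 7)),
    m3 = rep("all", 10),
    m4 = rep("all2", 10)))
  edges2 <- pairwise_similarities(ps2)
  g2 <- build_cluster_graph(edges2, 0.5)
  comps2 <- cluster_components(g2, ps2, M = 4)
  sxy <- edges2$s[edges2$label_x == "x" & edges2$label_y == "y"]
  expect_equal(sxy, 0.6)
  rxy <- Filter(function(z) setequal(z$vertices$label, c("x", "y")), comps2)
  expect_length(rxy, 1)
  expect_equal(rxy[[1]]$robustness, 0.6 / 6)

  # singleton vertices form size-1 components with robustness 0 whose core
  # is their own cell set
  ps3 <- make_partition_set(paste0("c", 1:4), list(
    m1 = c("u", "u", "w", "w"),
    m2 = c("v", "v", "t", "q")))
  g3 <- build_cluster_graph(pairwise_similarities(ps3), 0.5,
                            vertices = data.frame(
                              method = c("m1", "m1", "m2", "m2", "m2"),
                              label = c("u", "w", "v", "t", "q")))
  comps3 <- cluster_components(g3, ps3, M = 2)
  singletons <- Filter(function(z) nrow(z$vertices) == 1, comps3)
  expect_length(singletons, 3) # w, t and q have only weak similarities
  for (z in singletons) {
    expect_equal(z$robustness, 0)
    expect_equal(z$n_strong_edges, 0)
    labs <- ps3$partitions[[z$vertices$method]]
    expect_setequal(z$core_cells, names(labs)[labs == z$vertices$label])
  }
})

test_that("the robustness threshold implements the majority-expectation", {
  expect_identical(robustness_threshold(0.5, 3, 4), 0.25)
  expect_equal(robustness_threshold(0.5, 2, 3), 0.5 / 3)
  for (M in 2:6) expect_equal(robustness_threshold(1.0, M, M), 1.0)
  # default m is the strict majority
  expect_equal(robustness_threshold(0.5, M = 4), 0.25)
  expect_equal(robustness_threshold(0.5, M = 3), robustness_threshold(0.5, 2, 3))
  expect_error(robustness_threshold(0.5, 5, 4), "m")
  expect_error(robustness_threshold(0.5, 1, 4), "m")
})

test_that("consensus accepts by strict robustness and tiles the pool", {
  pool <- paste0("c", 1:12)
  # 3 of 4 methods agree exactly on cluster {c1..c6}; the fourth disagrees
  agree <- c(rep("k", 6), rep("a", 6))
  ps <- make_partition_set(pool, list(
    m1 = agree, m2 = agree, m3 = agree,
    m4 = rep(c("z1", "z2", "z3"), 4)))
  out <- consensus_step(ps, s_lim = 0.5, r_threshold = 0.25)
  rvals <- vapply(out$robust, `[[`, 0, "robustness")
  expect_true(all(rvals > 0.25))
  expect_true(any(abs(rvals - 0.5) < 1e-12)) # 3 edges of weight 1 over 6
  # partition property
  all_cells <- c(unlist(lapply(out$robust, `[[`, "cells")),
                 out$leftover$cells)
  expect_setequal(all_cells, pool)
  expect_equal(length(all_cells), length(pool))
  expect_identical(out$leftover$robustness, 0)

  # same construction under a higher threshold: nothing passes
  out2 <- consensus_step(ps, s_lim = 0.5, r_threshold = 0.6)
  expect_length(out2$robust, 0)
  expect_setequal(out2$leftover$cells, pool)
})

test_that("component and edge extraction agree with brute-force oracles", {
  with_seed(101, {
    for (rep in 1:30) {
      n <- sample(20:80, 1)
      ps <- random_partition_set(n, sample(2:5, 1), sample(2:5, 1))
      edges <- pairwise_similarities(ps)
      oe <- oracle_edges(ps)
      key <- function(d) paste(d$method_x, d$label_x, d$method_y, d$label_y)
      expect_setequal(key(edges), key(oe))
      m <- match(key(oe), key(edges))
      expect_equal(edges$s[m], oe$s)

      s_lim <- runif(1, 0.2, 0.8)
      g <- build_cluster_graph(edges, s_lim,
        vertices = unique(do.call(rbind, lapply(names(ps$partitions),
          function(mm) data.frame(method = mm,
                                  label = unique(ps$partitions[[mm]]),
                                  stringsAsFactors = FALSE)))))
      comps <- cluster_components(g, ps)
      got <- lapply(comps, function(z) {
        sort(paste(z$vertices$method, z$vertices$label, sep = "\r"))
      })
      want <- oracle_components(ps, s_lim)
      expect_setequal(vapply(got, paste, "", collapse = "|"),
                      vapply(want, paste, "", collapse = "|"))
    }
  })
})

test_that("results are invariant to method order and label renaming", {
  with_seed(77, {
    ps <- random_partition_set(60, 4, 3)
  })
  out <- consensus_step(ps, 0.5, 0.1)
  # rename labels of every partition
  renamed <- lapply(ps$partitions, function(p) {
    stats::setNames(paste0("lab_", p), names(p))
  })
  ps_r <- make_partition_set(ps$pool, renamed)
  out_r <- consensus_step(ps_r, 0.5, 0.1)
  cells <- function(o) lapply(o$robust, function(z) sort(z$cells))
  expect_setequal(vapply(cells(out), paste, "", collapse = ","),
                  vapply(cells(out_r), paste, "", collapse = ","))
  expect_setequal(out$leftover$cells, out_r$leftover$cells)

  # method order permutation
  ps_p <- make_partition_set(ps$pool, rev(ps$partitions))
  out_p <- consensus_step(ps_p, 0.5, 0.1)
  expect_setequal(vapply(cells(out), paste, "", collapse = ","),
                  vapply(cells(out_p), paste, "", collapse = ","))
})

test_that("raising thresholds never adds edges or robust clusters", {
  with_seed(55, {
    ps <- random_partition_set(80, 4, 3)
  })
  edges <- pairwise_similarities(ps)
  n_edges <- vapply(c(0.3, 0.5, 0.7), function(sl) {
    igraph::ecount(build_cluster_graph(edges, sl))
  }, 0)
  expect_true(all(diff(n_edges) <= 0))
  n_robust <- vapply(c(0.05, 0.25, 0.5, 0.9), function(rt) {
    length(consensus_step(ps, 0.5, rt)$robust)
  }, 0)
  expect_true(all(diff(n_robust) <= 0))
})
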