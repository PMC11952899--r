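test_that("STRING-style edge loading filters, deduplicates and validates", {
  path <- write_temp_edges(data.frame(
    protein1 = c("a", "b", "a"), protein2 = c("b", "a", "a"),
    combined_score = c(900, 900, 950)))
  g <- load_string_edges(path)
  expect_equal(igraph::ecount(g), 1)  # reciprocal pair merged, loop dropped
  expect_setequal(igraph::V(g)$name, c("a", "b"))

  path2 <- write_temp_edges(data.frame(
    protein1 = c("a", "c"), protein2 = c("b", "d"),
    combined_score = c(900, 960)))
  expect_equal(igraph::ecount(load_string_edges(path2, 950)), 1)
  expect_warning(g0 <- load_string_edges(path2, 999), "no edges")
  expect_equal(igraph::vcount(g0), 0)

  bad <- write_temp_edges(data.frame(protein1 = "a", protein2 = "b"))
  expect_error(load_string_edges(bad), "missing column")
  bad2 <- write_temp_edges(data.frame(protein1 = c("a", "b"),
                                      protein2 = c("b", "c"),
                                      combined_score = c("900", "high")))
  expect_error(load_string_edges(bad2), "line")
})

test_that("propensity-induced subgraphs keep exactly the qualifying nodes", {
  ed <- data.frame(protein1 = c("a", "b", "c"), protein2 = c("b", "c", "d"),
                   combined_score = 900)
  g <- ppi_graph(ed)
  prop <- data.frame(accession = c("a", "b", "c", "d"), p = c(0.9, 0.6, 0.4, 0.55))
  sub <- induce_predicted_subgraph(g, prop, min_p = 0.5)
  expect_setequal(igraph::V(sub)$name, c("a", "b", "d"))  # d kept though isolated
  expect_equal(igraph::ecount(sub), 1)
  expect_identical(induce_predicted_subgraph(g, prop, min_p = 0), g)
  expect_error(induce_predicted_subgraph(g, prop, min_p = 0.95), "no graph node")
  expect_error(induce_predicted_subgraph(g, prop[0, ], 0.5), "empty")
})

test_that("analytic centralities: triangle, path and star", {
  k3 <- adj_to_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  cen <- compute_centralities(k3)
  expect_equal(cen$degree, rep(2, 3))
  expect_equal(cen$clustering_coefficient, rep(1, 3))
  expect_equal(cen$betweenness, rep(0, 3))
  expect_equal(cen$pagerank, rep(1 / 3, 3))
  expect_equal(cen$eigenvector, rep(1, 3))

  path3 <- adj_to_graph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
  cenp <- compute_centralities(path3)
  expect_equal(cenp$betweenness[2], 1)  # the one s-t pair, fully through b
  expect_equal(cenp$betweenness[c(1, 3)], c(0, 0))

  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L; star <- star + t(star)
  cens <- compute_centralities(adj_to_graph(star))
  expect_equal(cens$degree_centrality[1], 1)
  expect_equal(cens$pct_degree[1], 1)  # unique maximum -> percentile 1
})

test_that("all seven centralities match brute-force oracles on random graphs", {
  set.seed(60)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    A <- o_rand_adj(n, runif(1, 0.08, 0.5))
    if (sum(A) == 0) next
    expect_centralities_match(A)
  }
})

test_that("percentile ranks are mid-rank fractions, invariant to monotone maps", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  pr <- percentile_rank(x)
  expect_equal(max(pr), 1)
  expect_equal(pr, percentile_rank(exp(x)))
  expect_equal(pr, percentile_rank(2 * x - 7))
  expect_equal(percentile_rank(c(2, 2, 1))[1:2], rep(2.5 / 3, 2))  # ties averaged
  # PageRank normalization on a random graph
  set.seed(61)
  g <- adj_to_graph(o_rand_adj(40, 0.1))
  expect_equal(sum(compute_centralities(g)$pagerank), 1, tolerance = 1e-9)
})

test_that("probability bins partition nodes and ANOVA handles degeneracy", {
  set.seed(62)
  n <- 60
  ed <- data.frame(protein1 = sprintf("n%02d", sample(n, 150, TRUE)),
                   protein2 = sprintf("n%02d", sample(n, 150, TRUE)),
                   combined_score = 900)
  g <- ppi_graph(ed, vertices = sprintf("n%02d", 1:n))
  cen <- compute_centralities(g)
  prop <- data.frame(accession = sprintf("n%02d", 1:n),
                     p = runif(n, 0.5, 1))
  bb <- bin_by_probability(cen, prop, "degree")
  expect_equal(sum(bb$summary$n), n)  # bins partition the node set
  expect_identical(nrow(bb$anova), 4L)
  expect_true(all(is.na(bb$anova$p) | (bb$anova$p >= 0 & bb$anova$p <= 1)))

  # identical metric values everywhere -> F = 0, p = 1 for every comparison
  cen2 <- cen; cen2$degree <- rep(5, n)
  bb2 <- bin_by_probability(cen2, prop, "degree")
  done <- !is.na(bb2$anova$p)
  expect_true(all(bb2$anova$p[done] == 1))
  expect_true(all(bb2$anova$F[done] == 0))

  expect_error(bin_by_probability(cen, data.frame(accession = "x", p = 0.9),
                                  "degree"), "missing")
  prop_low <- prop; prop_low$p[1] <- 0.3
  expect_error(bin_by_probability(cen, prop_low, "degree"), ">= 0.5")
})

test_that("Louvain separates two bridged cliques and is seeded", {
  clique_edges <- function(nodes) {
    cmb <- t(combn(nodes, 2))
    data.frame(protein1 = cmb[, 1], protein2 = cmb[, 2], combined_score = 900)
  }
  ed <- rbind(clique_edges(sprintf("a%d", 1:5)), clique_edges(sprintf("b%d", 1:5)),
              data.frame(protein1 = "a1", protein2 = "b1", combined_score = 900))
  g <- ppi_graph(ed)
  part <- louvain_partition(g, seed = 4)
  expect_identical(length(part$sizes), 2L)
  mem <- part$membership
  expect_length(unique(mem[sprintf("a%d", 1:5)]), 1L)
  expect_length(unique(mem[sprintf("b%d", 1:5)]), 1L)
  expect_gt(part$modularity, 0.3)
  # cluster 1 is (one of) the largest, by construction of the relabeling
  expect_true(all(diff(as.integer(part$sizes)) <= 0))
  expect_identical(louvain_partition(g, seed = 4)$membership, mem)

  single <- louvain_partition(ppi_graph(clique_edges(sprintf("c%d", 1:6))), seed = 1)
  expect_identical(length(single$sizes), 1L)

  lonely <- suppressWarnings(ppi_graph(ed[0, ], vertices = c("x", "y", "z")))
  expect_warning(p0 <- louvain_partition(lonely, seed = 1), "edgeless")
  expect_identical(length(p0$sizes), 3L)
})

test_that("cluster summaries aggregate high-confidence members only", {
  mem <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L), sprintf("n%d", 1:6))
  part <- structure(list(membership = mem, sizes = table(mem),
                         modularity = 0.5, resolution = 1, seed = 1),
                    class = "community_partition")
  prop <- data.frame(accession = sprintf("n%d", 1:6),
                     p = c(0.9, 0.9, 0.2, 0.9, 0.8, 0.1))
  cen <- data.frame(accession = sprintf("n%d", 1:6),
                    pct_pagerank = c(0.5, 0.5, 0.9, 0.25, 0.75, 0.1))
  sm <- summarize_clusters(part, prop, cen, min_p = 0.7, top_k = 2)
  c1 <- sm$summary[sm$summary$cluster == 1, ]
  expect_identical(c1$hc_size, 2L)
  expect_equal(c1$mean_p, 0.9)
  expect_equal(c1$mean_pagerank_pct, 0.5)
  c3 <- sm$summary[sm$summary$cluster == 3, ]
  expect_identical(c3$hc_size, 0L)
  expect_true(is.na(c3$mean_p))
  expect_identical(nrow(sm$top), 2L)
  expect_lte(sum(sm$summary$hc_size), sum(prop$p > 0.7))
  expect_setequal(sm$members$cluster_1, c("n1", "n2"))
})

test_that("overlap analysis counts Venn regions exactly", {
  res <- overlap_analysis(list(A = c("p1", "p2"), B = c("p2", "p3"), C = "p2"))
  expect_identical(res$union_size, 3L)
  expect_identical(res$all_shared, "p2")
  expect_identical(sum(res$regions), res$union_size)

  same <- overlap_analysis(list(A = c("x", "y"), B = c("y", "x")))
  expect_identical(same$all_shared_size, same$union_size)

  # duplicates inside a list are collapsed before counting
  dup <- overlap_analysis(list(A = c("p1", "p1", "p2"), B = "p2"))
  expect_identical(dup$union_size, 2L)

  expect_error(overlap_analysis(list(A = "x", B = character(0))), "B")
  expect_error(overlap_analysis(list(A = "x")), "between 2 and 8")
  expect_error(overlap_analysis(list("x", "y")), "named")
})

test_that("2D embedding is seeded, finite and one point per node", {
  set.seed(63)
  g <- adj_to_graph(o_rand_adj(15, 0.3))
  xy <- embed_2d(g, seed = 7)
  expect_identical(nrow(xy), 15L)
  expect_true(all(is.finite(xy$c1)) && all(is.finite(xy$c2)))
  expect_identical(embed_2d(g, seed = 7), xy)
  expect_error(embed_2d(adj_to_graph(matrix(0, 2, 2)), 1), "at least 3")
})
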