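test_that("set summaries recover degree, clustering and core on small fixtures", {
  tri <- interaction_graph(data.frame(gene_a = c("a", "b", "c"),
                                      gene_b = c("b", "c", "a")))
  s <- set_network_summary(c("a", "b", "c"), tri)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$mean_clustering, 1)
  expect_equal(s$core_size, 3)

  path <- interaction_graph(data.frame(gene_a = c("a", "b"),
                                       gene_b = c("b", "c")))
  expect_equal(set_network_summary(c("a", "b", "c"), path)$mean_clustering, 0)

  sq <- chorded_square()
  expect_equal(set_network_summary(c("a", "b", "c", "d"), sq)$mean_clustering,
               5 / 6, tolerance = 1e-12)

  # degree counts neighbors outside the set too
  star <- interaction_graph(data.frame(gene_a = "h",
                                       gene_b = c("x1", "x2", "x3")))
  expect_equal(set_network_summary("h", star)$mean_degree, 3)
  # set absent from the graph
  s0 <- set_network_summary(c("q1", "q2"), star)
  expect_equal(s0$n_in_graph, 0)
  expect_true(is.na(s0$mean_degree))
})

test_that("edge partition classifies induced edges and reconciles totals", {
  g <- interaction_graph(data.frame(gene_a = c("x", "x"), gene_b = c("y", "z")))
  p <- edge_partition(c("x", "y"), "z", g)
  expect_equal(p, list(within_a = 1L, within_b = 0L, cross = 1L))
  p0 <- edge_partition("x", "q", interaction_graph(
    data.frame(gene_a = "a", gene_b = "b")))
  expect_equal(unlist(p0), c(within_a = 0, within_b = 0, cross = 0))
  expect_warning(edge_partition(c("x", "y"), c("y", "z"), g), "both sets")
  # brute-force reconciliation on a random graph
  set.seed(31)
  edges <- data.frame(gene_a = sample(letters[1:15], 40, TRUE),
                      gene_b = sample(letters[1:15], 40, TRUE))
  g2 <- interaction_graph(edges)
  a <- toupper(letters[1:6]); b <- toupper(letters[7:11])
  part <- edge_partition(a, b, g2)
  el <- igraph::as_edgelist(igraph::induced_subgraph(
    g2, intersect(c(a, b), igraph::V(g2)$name)))
  expect_equal(part$within_a + part$within_b + part$cross, nrow(el))
})

test_that("first-order expansion is the one-step BFS frontier union", {
  star <- interaction_graph(data.frame(gene_a = "h",
                                       gene_b = c("x1", "x2", "x3")))
  expect_setequal(first_order_expansion("h", star), c("H", "X1", "X2", "X3"))
  expect_equal(first_order_expansion("absent", star), "ABSENT")
  # growth and BFS-oracle agreement on a random graph
  set.seed(17)
  g <- generate_ppi(200, 2, seed = 17)
  seed_set <- igraph::V(g)$name[sample(200, 10)]
  e1 <- first_order_expansion(seed_set, g)
  e2 <- first_order_expansion(e1, g)
  expect_true(all(seed_set %in% e1))
  expect_true(all(e1 %in% e2))
  bfs <- unique(c(seed_set, unlist(lapply(seed_set, function(v) {
    igraph::neighbors(g, v)$name
  }))))
  expect_setequal(e1, toupper(bfs))
})

test_that("co-expression expansion applies the Bonferroni threshold", {
  pairs <- data.frame(gene_a = c("G1", "G1", "X"),
                      gene_b = c("P1", "P2", "G2"),
                      p = c(1e-8, 1e-3, 1e-9))
  out <- coexpression_expansion(c("g1", "g2"), pairs, alpha = 0.05,
                                genome_n = 20183)
  expect_setequal(out, c("G1", "G2", "P1", "X"))  # P2 fails the threshold
  none <- coexpression_expansion("g9", pairs)
  expect_equal(none, "G9")
})

test_that("random degree nulls are reproducible and rank planted hubs high", {
  g <- generate_ppi(500, 2, seed = 3)
  null1 <- random_set_degree_null(20, g, draws = 300, seed = 42)
  null2 <- random_set_degree_null(20, g, draws = 300, seed = 42)
  expect_identical(null1$mean_degrees, null2$mean_degrees)
  # full-size subset always equals the global mean degree
  nfull <- random_set_degree_null(igraph::vcount(g), g, draws = 3, seed = 1)
  expect_true(all(abs(nfull$mean_degrees -
                        mean(igraph::degree(g))) < 1e-12))
  expect_error(random_set_degree_null(501, g), "exceeds")
  # top-degree planted set sits above the 95th percentile of the null
  deg <- sort(igraph::degree(g), decreasing = TRUE)
  hubs <- names(deg)[1:20]
  expect_gt(null1$percentile(mean(igraph::degree(g, hubs))), 0.95)
})

test_that("publication-degree correlation is exact on monotone fixtures", {
  g <- chorded_square()
  deg <- igraph::degree(g)
  up <- stats::setNames(2 * deg + 1, toupper(names(deg)))
  down <- stats::setNames(100 - deg, toupper(names(deg)))
  expect_equal(pub_degree_correlation(up, g), 1)
  expect_equal(pub_degree_correlation(down, g), -1)
  expect_error(pub_degree_correlation(up, interaction_graph(
    data.frame(gene_a = "a", gene_b = "b"))), "at least 3")
  # tie handling matches the average-rank oracle
  set.seed(9)
  g2 <- generate_ppi(60, 1, seed = 9)
  pubs <- stats::setNames(rpois(60, 4), igraph::V(g2)$name)
  d2 <- igraph::degree(g2)
  oracle <- stats::cor(rank(pubs[names(d2)]), rank(d2))
  expect_equal(pub_degree_correlation(pubs, g2), oracle, tolerance = 1e-12)
})

test_that("clustering stays in [0,1] and the handshake identity holds", {
  for (s in 1:3) {
    g <- generate_ppi(150, 2, seed = s)
    cc <- igraph::transitivity(g, type = "local")
    cc[is.nan(cc)] <- 0
    expect_true(all(cc >= 0 & cc <= 1))
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
    members <- igraph::V(g)$name[1:40]
    mc <- set_network_summary(members, g)$mean_clustering
    expect_gte(mc, 0); expect_lte(mc, 1)
  }
})
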