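path3 <- function() build_network(records_tbl(c("A", "B"), c("B", "C")))

star4 <- function() build_network(records_tbl(rep("HUB", 3), c("L1", "L2", "L3")))

test_that("betweenness matches hand-enumerated closed forms", {
  ct <- network_centrality(path3(), mode = "pairs")
  expect_equal(ct$betweenness[ct$node == "B"], 1 / 3)
  expect_equal(ct$betweenness[ct$node %in% c("A", "C")], c(0, 0))

  cp <- network_centrality(star4(), mode = "pairs")
  expect_equal(cp$betweenness[cp$node == "HUB"], 3 / choose(4, 2))  # 0.5
  cs <- network_centrality(star4(), mode = "standard")
  expect_equal(cs$betweenness[cs$node == "HUB"], 1.0)

  two_edges <- build_network(records_tbl(c("A", "C"), c("B", "D")))
  expect_true(all(network_centrality(two_edges)$betweenness == 0))

  ring <- build_network(records_tbl(c("A", "B", "C", "D"), c("B", "C", "D", "A")))
  cr <- network_centrality(ring, mode = "pairs")
  expect_equal(cr$betweenness, rep(1 / 12, 4))  # one antipodal pair, sigma = 2
})

test_that("tiny and degenerate networks give all-zero betweenness", {
  one <- build_network(records_tbl(character(), character()), seeds = "A")
  expect_equal(network_centrality(one)$betweenness, 0)
  two <- build_network(records_tbl("A", "B"))
  expect_equal(network_centrality(two)$betweenness, c(0, 0))
})

test_that("streaming betweenness equals the geodesic-enumeration oracle", {
  withr::with_seed(7, {
    for (rep in 1:40) {
      n <- sample(4:12, 1)
      rg <- random_graph(n, p = runif(1, 0.15, 0.5))
      for (mode in c("pairs", "standard")) {
        got <- network_centrality(rg$graph, mode = mode)
        want <- oracle_betweenness(rg$adj, mode)
        names(want) <- igraph::V(rg$graph)$name
        expect_lt(max(abs(got$betweenness - want[got$node])), 1e-12)
      }
    }
  })
})

test_that("normalization modes differ by exactly N/(N-2) and labels don't matter", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      g <- random_graph(n)$graph
      pairs <- network_centrality(g, mode = "pairs")
      std <- network_centrality(g, mode = "standard")
      expect_equal(std$betweenness, pairs$betweenness * n / (n - 2))

      shuffled <- g
      perm <- sample(n)
      igraph::V(shuffled)$name <- igraph::V(g)$name[perm]
      got <- network_centrality(shuffled, mode = "pairs")
      relabel <- setNames(pairs$betweenness, pairs$node)
      names(relabel) <- igraph::V(shuffled)$name[match(names(relabel), igraph::V(g)$name)]
      expect_equal(setNames(got$betweenness, got$node)[sort(got$node)],
                   relabel[sort(got$node)])
    }
  })
})

test_that("closeness follows the per-component definition", {
  ct <- network_centrality(path3())
  expect_equal(ct$closeness[ct$node == "B"], 1.0)
  expect_equal(ct$closeness[ct$node == "A"], 2 / 3)

  k4 <- build_network(records_tbl(c("A", "A", "A", "B", "B", "C"),
                                  c("B", "C", "D", "C", "D", "D")))
  expect_equal(network_centrality(k4)$closeness, rep(1, 4))

  iso <- build_network(records_tbl("A", "B"), seeds = "Z")
  ci <- network_centrality(iso)
  expect_equal(ci$closeness[ci$node == "Z"], 0)
})

test_that("betweenness spreads over a wider relative range than closeness on scale-free graphs", {
  g <- generate_network(synthetic_spec(n_nodes = 300, seed = 5))
  ct <- network_centrality(g)
  spread <- function(x) {
    pos <- x[x > 0]
    quantile(pos, 0.95) / quantile(pos, 0.50)
  }
  expect_gt(spread(ct$betweenness), spread(ct$closeness))
})

test_that("top-central subnetwork selection is deterministic with documented rules", {
  g <- star4()
  ct <- network_centrality(g)
  expect_equal(igraph::V(top_central_subnetwork(g, ct, 1))$name, "HUB")
  whole <- top_central_subnetwork(g, ct, igraph::vcount(g))
  expect_equal(igraph::vcount(whole), 4)
  expect_error(top_central_subnetwork(g, ct, 0), "positive")
  expect_error(top_central_subnetwork(g, ct, 10), "exceeds")

  # ceiling rule for fractions: 0.2 * 483 = 96.6 -> 97
  gg <- generate_network(synthetic_spec(n_nodes = 483, seed = 2))
  cc <- network_centrality(gg, include_closeness = FALSE)
  expect_equal(igraph::vcount(top_central_subnetwork(gg, cc, 0.2)), 97)
})

test_that("interacting seeds join the top-central cluster with their edges only", {
  # HUB star with seed leaf SL and seed OUT unconnected to HUB
  recs <- records_tbl(c("HUB", "HUB", "HUB", "OUT"), c("L1", "L2", "SL", "OUT2"))
  g <- build_network(recs, seeds = c("SL", "OUT"))
  ct <- network_centrality(g)
  sub <- top_central_subnetwork(g, ct, 1, include_interacting_seeds = TRUE)
  expect_setequal(igraph::V(sub)$name, c("HUB", "SL"))
  expect_equal(igraph::ecount(sub), 1)
})
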