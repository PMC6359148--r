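test_that("centralities are exact on hand-checkable graphs", {
  path <- toy_graph(c("A", "B", "B", "C"))
  m <- centralities(path)
  expect_equal(m$betweenness[m$node == "B"], 1)
  expect_equal(m$degree[m$node == "B"], 2)
  k4 <- toy_graph(c("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d"))
  expect_true(all(centralities(k4)$betweenness == 0))
  star <- toy_graph(c("h", "l1", "h", "l2", "h", "l3", "h", "l4"))
  ms <- centralities(star)
  expect_equal(ms$betweenness[ms$node == "h"], choose(4, 2))
})

test_that("betweenness matches the pair-counting oracle on random graphs", {
  for (i in 1:10) {
    set.seed(i)
    n <- sample(5:30, 1)
    g <- igraph::sample_gnp(n, p = runif(1, 0.1, 0.4))
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    expect_equal(centralities(g)$betweenness, betweenness_oracle(g),
                 tolerance = 1e-9)
  }
})

test_that("tree betweenness sums to the path-length identity", {
  # on a tree each pair has one geodesic passing through (length - 1)
  # intermediate nodes, so total betweenness = sum over pairs (d - 1)
  for (i in 1:5) {
    set.seed(i)
    n <- sample(8:40, 1)
    g <- igraph::sample_tree(n)
    igraph::V(g)$name <- as.character(seq_len(n))
    d <- igraph::distances(g)
    expected <- sum(d[upper.tri(d)] - 1)
    expect_equal(sum(centralities(g)$betweenness), expected,
                 tolerance = 1e-9)
  }
})

test_that("subnetwork induction keeps seeds plus first neighbors", {
  g <- toy_graph(c("a", "b", "b", "c", "c", "d", "x", "y"))
  sub <- induce_subnetwork(g, "b")
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c"))
  sub0 <- induce_subnetwork(g, c("a", "b"), neighbors = 0)
  expect_setequal(igraph::V(sub0)$name, c("a", "b"))
  # seeds = all nodes reproduces the graph
  all_sub <- induce_subnetwork(g, c("a", "b", "c", "d", "x", "y"))
  expect_equal(igraph::ecount(all_sub), igraph::ecount(g))
  expect_error(induce_subnetwork(g, "absent"), "no seed gene")
  # isolated seeds leave nothing after pruning
  g2 <- igraph::add_vertices(g, 1, name = "lone")
  expect_error(induce_subnetwork(g2, "lone", neighbors = 0), "empty network")
})

test_that("dual-metric hub selection follows both rankings", {
  # 7-node fixture: hub dominates both metrics; bridge has high
  # betweenness but low degree; clique nodes have degree but no betweenness
  g <- toy_graph(c("hub", "a", "hub", "b", "hub", "c", "hub", "d",
                   "hub", "bridge", "bridge", "k1",
                   "k1", "k2", "k1", "k3", "k2", "k3"))
  m <- centralities(g)
  expect_equal(select_hubs(m, 1), "hub")
  h2 <- select_hubs(m, 2)
  expect_equal(h2[1], "hub")
  # brute-force check: the pair must lie in both top-m lists for some m
  for (n_req in 1:3) {
    hubs <- select_hubs(m, n_req)
    expect_length(hubs, n_req)
    ranks_d <- rank(-m$degree, ties.method = "min")
    ranks_b <- rank(-m$betweenness, ties.method = "min")
    idx <- match(hubs, m$node)
    # every selected hub beats some non-hub on at least one metric pair
    expect_true(all(ranks_d[idx] <= nrow(m) & ranks_b[idx] <= nrow(m)))
  }
  # boundary: asking for every node returns every node
  expect_setequal(select_hubs(m, nrow(m)), m$node)
  expect_error(select_hubs(m, nrow(m) + 1), "exceeds")
})

test_that("hub selection is independent of node insertion order", {
  b <- generate_expression(sim_config(seed = 9))
  net <- generate_networks(sim_config(seed = 9), b$truth)$network
  m1 <- centralities(net)
  perm <- igraph::permute(net, sample(igraph::vcount(net)))
  m2 <- centralities(perm)
  expect_equal(select_hubs(m1, 10), select_hubs(m2, 10))
})

test_that("mcode finds dense modules and honors its recruitment rule", {
  tri <- toy_graph(c("x", "y", "y", "z", "z", "x"))
  mt <- mcode_modules(tri)
  expect_length(mt$modules, 1)
  expect_setequal(mt$modules[[1]], c("x", "y", "z"))

  # edgeless graph: no cores, no modules
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  expect_length(mcode_modules(g0)$modules, 0)

  # K4 planted in a sparse ring is recovered exactly
  ring <- igraph::make_ring(20)
  igraph::V(ring)$name <- sprintf("r%02d", 1:20)
  gk <- igraph::add_edges(ring, c("r01", "r05", "r01", "r10", "r05", "r10",
                                  "r01", "r15", "r05", "r15", "r10", "r15"))
  mk <- mcode_modules(gk)
  expect_length(mk$modules, 1)
  expect_setequal(mk$modules[[1]], c("r01", "r05", "r10", "r15"))
  expect_equal(mk$scores[1], 4)   # density 1 x size 4

  # two K4s joined by one bridge edge: every vertex weight ties at 3, so
  # greedy expansion crosses the bridge and returns one 8-node module
  k4 <- function(p) {
    v <- paste0(p, 1:4)
    c(v[1], v[2], v[1], v[3], v[1], v[4], v[2], v[3], v[2], v[4], v[3], v[4])
  }
  gb <- toy_graph(c(k4("a"), k4("b"), "a1", "b1"))
  mb <- mcode_modules(gb)
  expect_length(mb$modules, 1)
  expect_setequal(mb$modules[[1]], c(paste0("a", 1:4), paste0("b", 1:4)))

  expect_error(mcode_modules(tri, vwp = 1.2), "vwp")
})

test_that("haircut trims singly connected module members", {
  # triangle with a pendant: pendant is recruited (weight tie within
  # tolerance of the rule) only if dense enough; with haircut the module
  # is exactly the triangle
  g <- toy_graph(c("x", "y", "y", "z", "z", "x", "x", "p"))
  m_on <- mcode_modules(g, haircut = TRUE)
  expect_false("p" %in% unlist(m_on$modules))
  expect_setequal(m_on$modules[[1]], c("x", "y", "z"))
})

test_that("networks round-trip through SIF", {
  g <- toy_graph(c("a", "b", "b", "c"))
  path <- tempfile(fileext = ".sif")
  write_sif(g, path)
  back <- read_network(path)
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(back), 2)
})
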