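# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation paths they check.

# BH step-up by direct evaluation of the definition: sort, apply p(i)*m/i,
# enforce monotonicity from the largest p downwards, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- m / seq_len(m) * p[o]
  for (i in (m - 1):1) {
    if (m == 1) break
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  }
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Upper hypergeometric tail by exhaustive summation of the pmf.
hyper_tail_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Pair-counting betweenness: for every ordered source, BFS gives distances
# and geodesic counts; a node's betweenness accumulates
# sigma(s,v) * sigma(v,t) / sigma(s,t) over pairs s < t with
# d(s,v) + d(v,t) = d(s,t). Independent of Brandes' accumulation.
betweenness_oracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (dist[s, u] >= d) {
            if (is.infinite(dist[s, u])) {
              dist[s, u] <- d
              nxt <- c(nxt, u)
            }
            if (dist[s, u] == d) sigma[s, u] <- sigma[s, u] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  bet <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          bet[v] <- bet[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bet
}

# Small labelled graph from an edge vector, e.g. c("a","b", "b","c").
toy_graph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

# Tiny expression fixture: `n_null` null genes plus optional planted rows
# appended at the bottom.
toy_expression <- function(n_null = 50, n1 = 5, n2 = 5, sd = 1,
                           planted = NULL, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_null * (n1 + n2), mean = 8, sd = sd), n_null)
  if (!is.null(planted)) m <- rbind(m, planted)
  rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  expression_dataset(m, c(rep("case", n1), rep("control", n2)))
}
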