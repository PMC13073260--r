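# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

# single-source shortest path by plain breadth-first search over an
# adjacency list; nodes are character ids
bfs_distances <- function(edges, nodes, source) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]])
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
  }
  dist
}

# separation terms recomputed from scratch with the BFS oracle
oracle_within <- function(edges, nodes, module) {
  if (length(module) == 1L) return(0)
  mean(vapply(module, function(v) {
    d <- bfs_distances(edges, nodes, v)
    min(d[setdiff(module, v)])
  }, numeric(1)))
}

oracle_between <- function(edges, nodes, a, b) {
  from_a <- vapply(a, function(v) {
    d <- bfs_distances(edges, nodes, v)
    other <- setdiff(b, v)
    if (!length(other)) 0 else min(d[other])
  }, numeric(1))
  from_b <- vapply(b, function(v) {
    d <- bfs_distances(edges, nodes, v)
    other <- setdiff(a, v)
    if (!length(other)) 0 else min(d[other])
  }, numeric(1))
  mean(c(from_a, from_b))
}

oracle_separation <- function(edges, nodes, a, b) {
  oracle_between(edges, nodes, a, b) -
    (oracle_within(edges, nodes, a) + oracle_within(edges, nodes, b)) / 2
}

# Benjamini-Hochberg step-up, written directly from the definition:
# q_i = min over j >= i (sorted order) of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exact hypergeometric upper tail P(X >= k) by full enumeration of all
# n-subsets of the universe (feasible for N <= 12)
oracle_hyper_upper <- function(k, K, N, n) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  subsets <- utils::combn(universe, n)
  hits <- colSums(matrix(subsets %in% inset, nrow = n))
  mean(hits >= k)
}

# one-component PLS1 via NIPALS, the reference for fit_oplsda(n_orth = 0)
oracle_pls1 <- function(x, y) {
  xs <- scale(x)
  yc <- y - mean(y)
  w <- crossprod(xs, yc)
  w <- w / sqrt(sum(w^2))
  as.numeric(xs %*% w)
}

# small random graph with named vertices, for property suites
random_named_graph <- function(n, p = 0.4) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

graph_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) matrix(character(), 0, 2) else el
}

# two 10-cliques joined by a single bridge edge
bridged_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::V(g)$name <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  igraph::add_edges(g, c(10, 11))
}
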