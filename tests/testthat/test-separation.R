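path6 <- function() {
  g <- igraph::make_ring(6, circular = FALSE)
  igraph::V(g)$name <- as.character(1:6)
  g
}

test_that("distance terms match the worked path-graph example", {
  g <- path6()
  expect_equal(within_distance(g, c("1", "2")), 1.0)
  expect_equal(between_distance(g, c("1", "2"), c("5", "6")), 3.5)
  expect_equal(separation(g, c("1", "2"), c("5", "6")), 2.5)
})

test_that("degenerate module shapes follow the documented conventions", {
  g <- path6()
  expect_equal(within_distance(g, "3"), 0)            # singleton
  clique <- igraph::make_full_graph(4)
  igraph::V(clique)$name <- letters[1:4]
  expect_equal(within_distance(clique, letters[1:4]), 1.0)
  expect_equal(between_distance(g, "2", "3"), 1.0)    # adjacent singletons
  expect_equal(separation(clique, c("a", "b"), c("c", "d")), 0.0)
  expect_error(within_distance(g, c("1", "99")), "99")
})

test_that("self-separation is exactly zero for connected modules", {
  g <- path6()
  expect_equal(separation(g, c("2", "3", "4"), c("2", "3", "4")), 0)
  set.seed(12)
  for (i in 1:20) {
    gr <- random_named_graph(sample(5:8, 1), 0.5)
    comp <- igraph::components(gr)
    big <- igraph::V(gr)$name[comp$membership == which.max(comp$csize)]
    if (length(big) < 2) next
    mod <- sample(big, sample(2:length(big), 1))
    # restrict to a connected module inside the component
    sub <- igraph::induced_subgraph(gr, mod)
    sc <- igraph::components(sub)
    mod <- igraph::V(sub)$name[sc$membership == which.max(sc$csize)]
    if (length(mod) < 2) next
    expect_equal(separation(gr, mod, mod), 0)
  }
})

test_that("separation matches the brute-force BFS oracle on random graphs", {
  set.seed(3)
  n_checked <- 0
  while (n_checked < 100) {
    g <- random_named_graph(sample(4:8, 1), runif(1, 0.3, 0.8))
    comp <- igraph::components(g)
    big <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    if (length(big) < 3) next
    a <- sample(big, sample(1:2, 1) + 1)
    b <- sample(big, sample(1:2, 1) + 1)
    edges <- graph_edges(g)
    expect_identical(within_distance(g, a), oracle_within(edges, big, a))
    expect_identical(between_distance(g, a, b), oracle_between(edges, big, a, b))
    expect_identical(separation(g, a, b), oracle_separation(edges, big, a, b))
    n_checked <- n_checked + 1
  }
})

test_that("moving a module outward along a path increases separation", {
  g <- igraph::make_ring(12, circular = FALSE)
  igraph::V(g)$name <- as.character(1:12)
  a <- c("1", "2")
  seps <- vapply(3:10, function(start)
    separation(g, a, as.character(c(start, start + 1))), 0)
  expect_true(all(diff(seps) > 0))
})

test_that("separation matrix selects the planted interleaved pair", {
  # blocks: interleaved A1/B1 halves in one dense block, remote A2 and B2
  set.seed(8)
  spec <- synthetic_spec(seed = 15,
                         interactome_blocks = list(c(20, 0.95, 0.02),
                                                   c(10, 0.95, 0.02),
                                                   c(10, 0.95, 0.02)))
  ids <- sprintf("n%03d", 1:50)
  g <- generate_interactome(spec, ids)
  mixed <- ids[1:20]
  mods_a <- structure(list(list(label = "A1", members = mixed[c(TRUE, FALSE)],
                                score = 2, seed = mixed[1]),
                           list(label = "A2", members = ids[21:30], score = 1,
                                seed = ids[21])), class = "module_set")
  mods_b <- structure(list(list(label = "B1", members = mixed[c(FALSE, TRUE)],
                                score = 2, seed = mixed[2]),
                           list(label = "B2", members = ids[31:40], score = 1,
                                seed = ids[31])), class = "module_set")
  res <- separation_matrix(g, mods_a, mods_b)
  expect_identical(res$best_pair, c("A1", "B1"))
  expect_lte(res$best_value, 0.05)
  expect_gt(res$s_ab["A2", "B2"], res$best_value)
  # the formula ties the stored terms together exactly
  expect_equal(res$s_ab, res$d_ab - outer(res$d_aa, res$d_bb, `+`) / 2)
  # symmetric in its arguments
  swapped <- separation_matrix(g, mods_b, mods_a)
  expect_equal(swapped$s_ab["B1", "A1"], res$s_ab["A1", "B1"])
})

test_that("modules stranded outside the main component are flagged", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(3))
  igraph::V(g)$name <- c(paste0("m", 1:5), paste0("x", 1:3))
  mods_a <- structure(list(list(label = "A1", members = paste0("m", 1:3),
                                score = 1, seed = "m1"),
                           list(label = "A2", members = paste0("x", 1:3),
                                score = 1, seed = "x1")), class = "module_set")
  mods_b <- structure(list(list(label = "B1", members = paste0("m", 3:5),
                                score = 1, seed = "m3")), class = "module_set")
  expect_message(res <- separation_matrix(g, mods_a, mods_b), "unevaluable")
  expect_true(is.na(res$s_ab["A2", "B1"]))
  expect_identical(res$best_pair, c("A1", "B1"))
  expect_error(separation_matrix(g, structure(list(), class = "module_set"),
                                 mods_b), "empty")
})
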