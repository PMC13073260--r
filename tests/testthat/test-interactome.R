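test_that("edge lists are read with dedup, self-loop and score handling", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "b\ta", "a\ta"), f)
  expect_message(g <- read_edgelist(f), "1 self-loop")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  writeLines(c("a\tb\t0.9", "b\tc\t0.2", "c\td\t0.4"), f)
  g2 <- read_edgelist(f, min_score = 0.4)
  expect_equal(igraph::ecount(g2), 2)
  expect_false(igraph::are_adjacent(g2, "b", "c"))

  writeLines(c("a\tb\t0.9", "b\tc\tstrong"), f)
  expect_error(read_edgelist(f, min_score = 0.4), "line 2")

  writeLines(character(), f)
  expect_equal(igraph::vcount(read_edgelist(f)), 0)
})

test_that("induced subnetworks restrict and warn about absent features", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  expect_equal(igraph::ecount(induced_subnetwork(g, c("a", "b", "c"))), 3)
  expect_message(sub <- induced_subnetwork(g, c("a", "b", "zz")), "1 feature")
  expect_equal(igraph::ecount(sub), 1)
  expect_message(empty <- induced_subnetwork(g, c("x", "y")), "2 feature")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("mcode recovers a K4 next to an isolated vertex", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_empty_graph(1, directed = FALSE))
  igraph::V(g)$name <- paste0("n", 1:5)
  ms <- mcode(g)
  expect_length(ms, 1)
  expect_identical(ms[[1]]$members, paste0("n", 1:4))
  expect_equal(ms[[1]]$score, 4)   # density 1 x size 4
})

test_that("mcode separates two cliques joined by a bridge when haircut is on", {
  g <- bridged_cliques()
  ms <- mcode(g)
  expect_length(ms, 2)
  members <- lapply(ms, `[[`, "members")
  expect_true(any(vapply(members, identical, TRUE, sprintf("a%02d", 1:10))))
  expect_true(any(vapply(members, identical, TRUE, sprintf("b%02d", 1:10))))
  # each module's induced subgraph is connected with min degree >= 2
  for (m in ms) {
    sub <- igraph::induced_subgraph(g, m$members)
    expect_true(igraph::is_connected(sub))
    expect_gte(min(igraph::degree(sub)), 2)
  }
})

test_that("mcode output is invariant to vertex-insertion order", {
  g <- bridged_cliques()
  base <- mcode(g)
  set.seed(6)
  for (i in 1:3) {
    perm <- sample(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    ms <- mcode(gp)
    expect_identical(lapply(ms, `[[`, "members"), lapply(base, `[[`, "members"))
    expect_equal(vapply(ms, `[[`, 0, "score"), vapply(base, `[[`, 0, "score"))
  }
})

test_that("edgeless and non-simple graphs are handled per contract", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- letters[1:3]
  expect_length(mcode(g), 0)
  loopy <- igraph::graph_from_literal(a - b)
  loopy <- igraph::add_edges(loopy, c(1, 1))
  expect_error(mcode(loopy), "simple")
})

test_that("mcode recovers planted stochastic blocks (Jaccard >= 0.8)", {
  spec <- synthetic_spec(seed = 101,
                         interactome_blocks = list(c(20, 0.9, 0.01),
                                                   c(20, 0.9, 0.01)))
  ids <- sprintf("v%03d", 1:60)
  g <- generate_interactome(spec, ids)
  ms <- mcode(g)
  expect_gte(length(ms), 2)
  blocks <- list(ids[1:20], ids[21:40])
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  top2 <- lapply(ms[1:2], `[[`, "members")
  best <- vapply(blocks, function(b) max(vapply(top2, jac, 0, b = b)), 0)
  expect_gte(mean(best), 0.8)
})

test_that("module sets round-trip through TSV", {
  g <- bridged_cliques()
  ms <- mcode(g)
  f <- tempfile(fileext = ".tsv")
  write_modules(ms, f)
  back <- read_modules(f)
  expect_identical(lapply(back, `[[`, "members"), lapply(ms, `[[`, "members"))
  expect_equal(vapply(back, `[[`, 0, "score"), vapply(ms, `[[`, 0, "score"))
})

test_that("hub ranking is by module-internal degree with lexical ties", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", letters[1:5])
  expect_identical(hub_rank(star, igraph::V(star)$name, top_k = 1), "hub")
  path <- igraph::make_ring(3, circular = FALSE)
  igraph::V(path)$name <- c("a", "b", "c")
  expect_identical(hub_rank(path, c("a", "b", "c"), top_k = 1), "b")
  clique <- igraph::make_full_graph(4)
  igraph::V(clique)$name <- c("d", "b", "c", "a")
  expect_identical(hub_rank(clique, igraph::V(clique)$name),
                   c("a", "b", "c", "d"))
  expect_error(hub_rank(path, c("a", "zz")), "zz")
})
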