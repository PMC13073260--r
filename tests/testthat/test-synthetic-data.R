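test_that("invalid spec fields are rejected by name", {
  expect_error(synthetic_spec(n_per_group = 2), "n_per_group")
  expect_error(synthetic_spec(frac_disease = 1.2), "frac_disease")
  expect_error(synthetic_spec(frac_reversed = -0.1), "frac_reversed")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
})

test_that("generator is deterministic and respects the design", {
  spec <- synthetic_spec(n_features = 80, n_per_group = 4, seed = 7)
  s1 <- generate_dataset(spec)
  s2 <- generate_dataset(spec)
  expect_identical(s1, s2)
  expect_equal(dim(s1$matrix$values), c(80L, 12L))
  expect_setequal(unique(s1$matrix$groups), c("control", "model", "treated"))
  # planted counts follow the fractions
  expect_equal(sum(s1$truth$disease), round(0.2 * 80))
  expect_equal(sum(s1$truth$reversed), round(0.5 * round(0.2 * 80)))
  expect_true(all(s1$truth$feature_id[s1$truth$reversed] %in%
                    s1$truth$feature_id[s1$truth$disease]))
  # unperturbed features carry direction 0, perturbed +/-1
  expect_true(all(s1$truth$direction[!s1$truth$disease] == 0))
  expect_true(all(abs(s1$truth$direction[s1$truth$disease]) == 1))
})

test_that("planted group means follow the reversal construction", {
  spec <- synthetic_spec(n_features = 300, n_per_group = 40,
                         effect_log2 = 2, noise_sd = 0.2, seed = 21)
  sim <- generate_dataset(spec)
  v <- sim$matrix$values
  gm <- function(g) rowMeans(v[, sim$matrix$groups == g])
  diff_mc <- gm("model") - gm("control")
  diff_tc <- gm("treated") - gm("control")
  tr <- sim$truth
  # disease features shifted by ~ +/- 2 in the model group
  expect_equal(unname(diff_mc[tr$disease]),
               2 * tr$direction[tr$disease], tolerance = 0.15)
  # reversed features return to the control mean in the treated group
  expect_lt(max(abs(diff_tc[tr$reversed])), 0.3)
  # non-reversed disease features keep the model-group shift
  persists <- tr$disease & !tr$reversed
  expect_equal(unname(diff_tc[persists]),
               2 * tr$direction[persists], tolerance = 0.15)
})

test_that("null spec does not exceed the nominal false-positive rate", {
  rates <- vapply(c(97, 98, 99), function(s) {
    sim <- generate_dataset(synthetic_spec(n_features = 1000,
                                           frac_disease = 0, seed = s))
    mean(diff_screen(sim$matrix, c("model", "control"))$p < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 3000)
  expect_lte(mean(rates), 0.05 + 2 * se)
})

test_that("interactome generator plants dense blocks deterministically", {
  spec <- synthetic_spec(seed = 5,
                         interactome_blocks = list(c(10, 1.0, 0.0)))
  ids <- sprintf("n%02d", 1:10)
  g <- generate_interactome(spec, ids)
  expect_equal(igraph::ecount(g), 45)       # a 10-clique
  expect_true(igraph::is_simple(g))
  expect_false(igraph::is_directed(g))

  spec2 <- synthetic_spec(seed = 5,
                          interactome_blocks = list(c(15, 0.9, 0.01),
                                                    c(15, 0.9, 0.01)))
  ids2 <- sprintf("n%02d", 1:40)
  g1 <- generate_interactome(spec2, ids2)
  g2 <- generate_interactome(spec2, ids2)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  # within-block density far above between-block density
  b1 <- ids2[1:15]; b2 <- ids2[16:30]
  dens <- function(nodes) {
    sub <- igraph::induced_subgraph(g1, nodes)
    igraph::ecount(sub) / choose(length(nodes), 2)
  }
  cross <- igraph::ecount(g1) - igraph::ecount(igraph::induced_subgraph(g1, b1)) -
    igraph::ecount(igraph::induced_subgraph(g1, b2)) -
    igraph::ecount(igraph::induced_subgraph(g1, setdiff(ids2, c(b1, b2))))
  expect_gt(dens(b1), 0.7)
  expect_gt(dens(b2), 0.7)
  expect_lt(cross / (15 * 25 + 15 * 10), 0.1)
  expect_error(generate_interactome(spec2, ids2[1:20]), "exceed")
})

test_that("packaged metabolite table matches its printed source", {
  tab <- load_table1_fixture()
  expect_equal(nrow(tab), 61)
  expect_equal(tab$name[1], "PC 32:1|PC 16:0_16:1")
  expect_equal(tab$category[1], "Glycerophospholipid")
  expect_equal(tab$trend_mc[1], "up")
  expect_equal(tab$trend_tm[1], "down")
  expect_equal(sum(tab$category == "Leucine, Isoleucine, and Valine Metabolism"), 8)
  # the table is a reversal table: arrows always oppose
  expect_true(all(tab$trend_mc != tab$trend_tm))
})

test_that("malformed fixture files fail with a line number", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tcategory\ttrend_model_vs_control\ttrend_pa_vs_model",
               "a\tcat\tup\tdown", "b\tcat\tup"), bad)
  expect_error(load_table1_fixture(bad), "line 3")
  writeLines(c("name\tcategory\ttrend_model_vs_control\ttrend_pa_vs_model",
               "a\tcat\tup\tsideways"), bad)
  expect_error(load_table1_fixture(bad), "line 2")
})

test_that("matrix round-trips through TSV with its sample sheet", {
  sim <- generate_dataset(synthetic_spec(n_features = 12, seed = 2))
  mp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_omics_matrix(sim$matrix, mp, sp)
  back <- read_omics_matrix(mp, sp, layer = "transcript")
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-12)
  expect_identical(back$groups, sim$matrix$groups)
})
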