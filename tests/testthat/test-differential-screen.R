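make_matrix <- function(vals, groups, layer = "transcript") {
  m <- matrix(vals, nrow = length(vals) / length(groups), byrow = TRUE,
              dimnames = list(paste0("f", seq_len(length(vals) / length(groups))),
                              paste0("s", seq_along(groups))))
  omics_matrix(m, groups, layer = layer)
}

test_that("log2 fold change is the difference of group means", {
  groups <- c("model", "model", "control", "control")
  m <- make_matrix(c(6, 6, 4, 4,
                     3, 5, 3, 5), groups)
  dt <- diff_screen(m, c("model", "control"))
  expect_equal(dt$log2fc[dt$feature_id == "f1"], 2)
  expect_equal(dt$log2fc[dt$feature_id == "f2"], 0)
})

test_that("Welch p matches the closed-form t distribution", {
  groups <- c("a", "a", "a", "b", "b", "b")
  m <- make_matrix(c(1, 2, 3, 4, 5, 6), groups)
  dt <- diff_screen(m, c("a", "b"))
  # t = -3/sqrt(2/3) = -3.674; Welch-Satterthwaite df = 4
  expect_equal(dt$log2fc, -3)
  expect_equal(dt$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(dt$p, 0.02131164, tolerance = 1e-6)
})

test_that("identical groups yield no significant calls and p = 1 ties", {
  groups <- rep(c("a", "b"), each = 3)
  m <- make_matrix(c(5, 5, 5, 5, 5, 5,
                     1, 2, 3, 1, 2, 3), groups)
  dt <- diff_screen(m, c("a", "b"))
  expect_equal(sum(dt$significant), 0)
  expect_equal(dt$p[dt$feature_id == "f1"], 1)  # zero variance, equal means
})

test_that("significance follows raw p and the fold-change threshold", {
  sim <- generate_dataset(synthetic_spec(n_features = 150, seed = 31,
                                         n_per_group = 6))
  dt <- diff_screen(sim$matrix, c("model", "control"),
                    fc_threshold = 1, p_threshold = 0.05)
  expect_identical(dt$significant, abs(dt$log2fc) > 1 & dt$p < 0.05)
  expect_true(all(dt$q >= dt$p))
  # q monotone non-decreasing in p order
  expect_true(all(diff(dt$q[order(dt$p)]) >= -1e-15))
})

test_that("BH q-values equal the brute-force step-up oracle", {
  set.seed(4)
  for (i in 1:5) {
    p <- runif(sample(5:20, 1))^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  sim <- generate_dataset(synthetic_spec(n_features = 18, seed = 8))
  dt <- diff_screen(sim$matrix, c("model", "control"))
  expect_equal(dt$q, oracle_bh(dt$p), tolerance = 1e-12)
})

test_that("reversing the contrast flips log2fc and keeps p", {
  sim <- generate_dataset(synthetic_spec(n_features = 40, seed = 13))
  ab <- diff_screen(sim$matrix, c("model", "control"))
  ba <- diff_screen(sim$matrix, c("control", "model"))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
})

test_that("raw-scale matrices and tiny groups are refused", {
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  raw <- omics_matrix(m, c("a", "a", "b", "b"), layer = "transcript", log2 = FALSE)
  expect_error(diff_screen(raw, c("a", "b")), "log2_transform")
  ok <- log2_transform(raw)
  expect_s3_class(diff_screen(ok, c("a", "b")), "diff_table")
  one <- omics_matrix(m, c("a", "b", "b", "b"), layer = "transcript")
  expect_error(diff_screen(one, c("a", "b")), ">= 2 samples")
})

test_that("PCA separates offset clusters and reports variance fractions", {
  set.seed(9)
  base <- matrix(rnorm(50 * 10, sd = 0.2), 50, 10)
  base[, 6:10] <- base[, 6:10] + 3
  dimnames(base) <- list(paste0("f", 1:50), paste0("s", 1:10))
  m <- omics_matrix(base, rep(c("a", "b"), each = 5), layer = "protein")
  pc <- pca_scores(m, 2)
  expect_true(all(diff(pc$explained) <= 0))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # PC1 separates the clusters regardless of sign
  s1 <- pc$scores[1:5, 1]; s2 <- pc$scores[6:10, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_gt(pc$explained[1], pc$explained[2])
})

test_that("PCA handles rank-1 and duplicated-sample structure", {
  v <- outer(1:6, c(0, 1, 2, 4))
  dimnames(v) <- list(paste0("f", 1:6), paste0("s", 1:4))
  m <- omics_matrix(v, rep("g", 4), layer = "transcript")
  pc <- pca_scores(m, 1)
  expect_equal(pc$explained[1], 1.0, tolerance = 1e-12)
  # duplicated sample columns give duplicated score rows
  v2 <- cbind(v, s5 = v[, 4])
  m2 <- omics_matrix(v2, rep("g", 5), layer = "transcript")
  pc2 <- pca_scores(m2, 1)
  expect_equal(unname(pc2$scores["s4", ]), unname(pc2$scores["s5", ]),
               tolerance = 1e-10)
  const <- omics_matrix(matrix(1, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])),
                        rep("g", 3), layer = "transcript")
  expect_error(pca_scores(const, 1), "constant")
})
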