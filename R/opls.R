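#' Two-class OPLS-DA with VIP scores
#'
#' Orthogonal projections to latent structures discriminant analysis for
#' a two-group omics matrix: class-orthogonal variation is removed from
#' the autoscaled data by iterative deflation before a single predictive
#' PLS component is extracted. Per-feature variable importance in
#' projection (VIP) is computed on the predictive component, so that the
#' mean squared VIP over features is exactly 1 and VIP > 1 marks features
#' with above-average influence. Predictive performance is summarised by
#' R2Y (fitted) and Q2 (7-fold cross-validated by default).
#'
#' @param matrix An \code{\link{omics_matrix}} restricted to exactly two
#'   groups, each with at least 3 samples, on log2 scale.
#' @param n_orth Number of orthogonal components to remove (default 1;
#'   0 gives a plain one-component PLS-DA).
#' @param cv_folds Cross-validation folds for Q2 (default 7; capped at
#'   the number of samples).
#' @param seed Seed controlling the within-class shuffle used before
#'   samples are dealt round-robin into folds; folds are balanced by
#'   class and fully reproducible.
#' @return An object of class \code{opls_model}: list with elements
#'   \code{weights}, \code{loadings}, \code{scores} (predictive),
#'   \code{weights_orth}, \code{loadings_orth}, \code{scores_orth}
#'   (matrices with one column per orthogonal component), \code{vip}
#'   (named per-feature vector), \code{r2y}, \code{q2}, \code{groups},
#'   \code{classes}, \code{center}, \code{scale}, \code{n_orth}.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_features = 40, seed = 3,
#'                                        layer = "metabolite"))
#' two <- subset_omics(sim$matrix, groups = c("model", "control"))
#' fit <- fit_oplsda(two)
#' mean(fit$vip^2)  # 1 by construction
#' @export
fit_oplsda <- function(matrix, n_orth = 1, cv_folds = 7, seed = 1) {
  stopifnot(inherits(matrix, "omics_matrix"))
  classes <- sort(unique(matrix$groups))
  if (length(classes) != 2L)
    stop("OPLS-DA needs exactly two groups, got: ", paste(classes, collapse = ", "))
  ns <- table(matrix$groups)
  if (any(ns < 3L))
    stop("each group needs >= 3 samples for OPLS-DA")
  x <- t(matrix$values)                       # samples x features
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         "; remove them before fitting")
  y <- ifelse(matrix$groups == classes[2L], 1, -1)

  core <- opls_core(x, y, n_orth,
                    center = colMeans(x), scale = sds)
  q2 <- opls_q2(x, y, n_orth, cv_folds, seed)

  p_feat <- ncol(x)
  vip <- sqrt(p_feat) * abs(core$w)
  names(vip) <- colnames(x)

  structure(list(weights = core$w, loadings = core$p, scores = core$t,
                 weights_orth = core$w_o, loadings_orth = core$p_o,
                 scores_orth = core$t_o,
                 c_coef = core$c, vip = vip,
                 r2y = core$r2y, q2 = q2,
                 groups = matrix$groups, classes = classes,
                 center = colMeans(x), scale = sds, n_orth = n_orth,
                 cv_folds = cv_folds, seed = seed),
            class = "opls_model")
}

# O-PLS deflation with a single predictive component.
# x: samples x features (raw); y: +/-1 class vector.
opls_core <- function(x, y, n_orth, center, scale) {
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  yc <- y - mean(y)
  r <- qr(xs)$rank
  if (n_orth >= r)
    stop("n_orth (", n_orth, ") must be smaller than rank(X) = ", r)
  w_o <- p_o <- NULL
  t_o <- NULL
  for (k in seq_len(n_orth)) {
    w <- crossprod(xs, yc) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    tt <- xs %*% w
    p <- crossprod(xs, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no orthogonal variation left at component ", k,
           "; lower n_orth")
    wo <- wo / nwo
    to <- xs %*% wo
    po <- crossprod(xs, to) / sum(to^2)
    xs <- xs - to %*% t(po)
    w_o <- cbind(w_o, as.numeric(wo))
    p_o <- cbind(p_o, as.numeric(po))
    t_o <- cbind(t_o, as.numeric(to))
  }
  w <- crossprod(xs, yc) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  tt <- as.numeric(xs %*% w)
  p <- as.numeric(crossprod(xs, tt) / sum(tt^2))
  cc <- sum(yc * tt) / sum(tt^2)
  r2y <- 1 - sum((yc - tt * cc)^2) / sum(yc^2)
  list(w = as.numeric(w), p = p, t = tt, c = cc,
       w_o = w_o, p_o = p_o, t_o = t_o, r2y = r2y)
}

# deterministic class-balanced fold assignment: shuffle within class under
# the seed, then deal all samples round-robin in interleaved class order
opls_folds <- function(y, k, seed) {
  n <- length(y)
  k <- min(k, n)
  idx_by_class <- split(seq_len(n), y)
  idx_by_class <- with_seed(seed, lapply(idx_by_class, sample))
  ord <- integer(0)
  m <- max(lengths(idx_by_class))
  for (i in seq_len(m))
    for (cl in idx_by_class)
      if (i <= length(cl)) ord <- c(ord, cl[i])
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

opls_q2 <- function(x, y, n_orth, cv_folds, seed) {
  folds <- opls_folds(y, cv_folds, seed)
  yc_all <- y - mean(y)
  press <- 0
  for (f in sort(unique(folds))) {
    test <- folds == f
    xtr <- x[!test, , drop = FALSE]
    ytr <- y[!test]
    ctr <- colMeans(xtr)
    str_ <- apply(xtr, 2L, stats::sd)
    str_[str_ == 0] <- 1
    fit <- opls_core(xtr, ytr, n_orth, center = ctr, scale = str_)
    xte <- sweep(sweep(x[test, , drop = FALSE], 2L, ctr, "-"), 2L, str_, "/")
    if (n_orth > 0)
      for (k in seq_len(n_orth)) {
        to <- xte %*% fit$w_o[, k]
        xte <- xte - to %*% t(fit$p_o[, k])
      }
    yhat <- as.numeric(xte %*% fit$w) * fit$c + mean(ytr)
    press <- press + sum((y[test] - yhat)^2)
  }
  1 - press / sum(yc_all^2)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA: %s vs %s; 1 predictive + %d orthogonal component(s)\n",
              x$classes[2L], x$classes[1L], x$n_orth))
  cat(sprintf("R2Y = %.3f, Q2 (%d-fold) = %.3f\n", x$r2y, x$cv_folds, x$q2))
  cat(sprintf("%d features, %d with VIP > 1\n",
              length(x$vip), sum(x$vip > 1)))
  invisible(x)
}

#' Select metabolites by VIP and p-value
#'
#' The metabolomics screening criterion: features with VIP above
#' \code{vip_threshold} in the OPLS-DA model AND raw p below
#' \code{p_threshold} in the univariate screen of the same contrast.
#'
#' @param model An \code{\link{fit_oplsda}} result.
#' @param diff A \code{\link{diff_screen}} table over the same features.
#' @param vip_threshold VIP cut-off, default 1.
#' @param p_threshold Raw p cut-off, default 0.05.
#' @return Character vector of selected feature ids.
#' @export
screen_metabolites <- function(model, diff, vip_threshold = 1, p_threshold = 0.05) {
  stopifnot(inherits(model, "opls_model"), inherits(diff, "diff_table"))
  a <- names(model$vip); b <- diff$feature_id
  if (!setequal(a, b)) {
    sym <- union(setdiff(a, b), setdiff(b, a))
    stop("model and diff table cover different features; symmetric difference: ",
         paste(sym, collapse = ", "))
  }
  p <- diff$p[match(a, diff$feature_id)]
  a[model$vip > vip_threshold & p < p_threshold]
}

#' Re-flag a differential table with the VIP-based criterion
#'
#' Replaces the fold-change significance flag by the metabolomics
#' criterion VIP > \code{vip_threshold} AND p < \code{p_threshold}, so
#' that the reversal screen can be driven by the multivariate statistic.
#'
#' @inheritParams screen_metabolites
#' @return The \code{diff_table} with its \code{significant} column and
#'   criterion attribute updated, and a \code{vip} column added.
#' @export
vip_criterion <- function(diff, model, vip_threshold = 1, p_threshold = 0.05) {
  stopifnot(inherits(model, "opls_model"), inherits(diff, "diff_table"))
  sel <- screen_metabolites(model, diff, vip_threshold, p_threshold)
  diff$vip <- unname(model$vip[match(diff$feature_id, names(model$vip))])
  diff$significant <- diff$feature_id %in% sel
  attr(diff, "criterion") <- "vip_p"
  attr(diff, "thresholds") <- c(vip = vip_threshold, alpha = p_threshold)
  diff
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model \code{n_perm} times with randomly permuted class
#' labels and reports the permuted R2Y / Q2 distribution together with an
#' empirical p-value for the observed Q2,
#' \eqn{p = (1 + \#\{Q2_{perm} \ge Q2_{obs}\}) / (n_{perm} + 1)}.
#'
#' @inheritParams fit_oplsda
#' @param n_perm Number of label permutations (default 200; fewer than 20
#'   triggers a warning but still runs).
#' @return A list with \code{observed} (R2Y, Q2), \code{permuted}
#'   (data.frame with columns \code{r2y}, \code{q2}) and \code{p_value}.
#' @export
validate_permutation <- function(matrix, n_orth = 1, n_perm = 200, seed = 1,
                                 cv_folds = 7) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (n_perm < 20)
    warning("n_perm < 20 gives a coarse empirical p-value")
  obs <- fit_oplsda(matrix, n_orth = n_orth, cv_folds = cv_folds, seed = seed)
  perms <- with_seed(seed, replicate(n_perm, sample(matrix$groups), simplify = FALSE))
  res <- vapply(perms, function(g) {
    m2 <- matrix
    m2$groups[] <- g
    fit <- fit_oplsda(m2, n_orth = n_orth, cv_folds = cv_folds, seed = seed)
    c(fit$r2y, fit$q2)
  }, numeric(2L))
  permuted <- data.frame(r2y = res[1L, ], q2 = res[2L, ])
  list(observed = c(r2y = obs$r2y, q2 = obs$q2),
       permuted = permuted,
       p_value = (1 + sum(permuted$q2 >= obs$q2)) / (n_perm + 1))
}
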