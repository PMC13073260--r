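#' Two-group differential screen
#'
#' Per-feature contrast of two groups on the log2 scale. The fold change
#' is the difference of log2 group means; the p-value comes from a
#' two-sample t-test (Welch's unequal-variance test by default). A
#' feature is called significant when |log2FC| exceeds
#' \code{fc_threshold} AND the raw p-value is below \code{p_threshold};
#' Benjamini-Hochberg q-values are reported alongside for transparency
#' but do not enter the call.
#'
#' Features that are constant in both groups get \code{p = 1} when the
#' group means are equal; if a feature is constant in both groups but the
#' means differ (no within-group variance at all), \code{p} is set to the
#' smallest representable positive double. Both conventions keep p in
#' (0, 1] without inventing a variance estimate.
#'
#' @param matrix An \code{\link{omics_matrix}} on log2 scale (use
#'   \code{\link{log2_transform}} first for raw counts).
#' @param contrast Character vector \code{c(group, reference)}; the
#'   reported log2FC is \code{mean(group) - mean(reference)}.
#' @param fc_threshold |log2FC| cut-off; default 1.
#' @param p_threshold Raw p-value cut-off; default 0.05.
#' @param var_equal If \code{TRUE}, Student's pooled-variance t-test
#'   instead of Welch's.
#' @return An object of class \code{diff_table}: a data.frame with
#'   columns \code{feature_id}, \code{log2fc}, \code{p}, \code{q},
#'   \code{significant}, and attributes \code{contrast} and
#'   \code{thresholds}.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_features = 50, seed = 1))
#' dt <- diff_screen(sim$matrix, c("model", "control"))
#' head(dt)
#' @export
diff_screen <- function(matrix, contrast, fc_threshold = 1, p_threshold = 0.05,
                        var_equal = FALSE) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (!matrix$log2)
    stop("matrix is on raw scale; apply log2_transform() first")
  if (length(contrast) != 2L)
    stop("'contrast' must be c(group, reference)")
  missing <- setdiff(contrast, unique(matrix$groups))
  if (length(missing))
    stop("contrast group(s) not in sample sheet: ", paste(missing, collapse = ", "))
  ia <- which(matrix$groups == contrast[1L])
  ib <- which(matrix$groups == contrast[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each contrast group needs >= 2 samples (got ",
         length(ia), " and ", length(ib), ")")

  xa <- matrix$values[, ia, drop = FALSE]
  xb <- matrix$values[, ib, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var)
  vb <- apply(xb, 1L, stats::var)
  na <- length(ia); nb <- length(ib)

  log2fc <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- log2fc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- se == 0 | !is.finite(se) | is.na(p)
  p[zero_var] <- ifelse(abs(log2fc[zero_var]) < .Machine$double.eps^0.5,
                        1, .Machine$double.xmin)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_id = rownames(matrix$values),
                    log2fc = unname(log2fc), p = unname(p), q = unname(q),
                    significant = unname(abs(log2fc) > fc_threshold & p < p_threshold),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("diff_table", "data.frame"),
            contrast = contrast,
            thresholds = c(fc = fc_threshold, alpha = p_threshold),
            criterion = "fc_p")
}

#' Serialize / deserialize a differential table
#'
#' @param diff A \code{diff_table}.
#' @param path Output TSV path.
#' @export
write_diff_table <- function(diff, path) {
  stopifnot(inherits(diff, "diff_table"))
  utils::write.table(as.data.frame(diff), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_diff_table
#' @param contrast The contrast the stored table was computed for.
#' @param thresholds Named numeric vector \code{c(fc=, alpha=)}.
#' @export
read_diff_table <- function(path, contrast, thresholds = c(fc = 1, alpha = 0.05)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "log2fc", "p", "q", "significant")
  if (!all(need %in% colnames(df)))
    stop("diff table TSV missing columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  df$significant <- as.logical(df$significant)
  structure(df[, need], class = c("diff_table", "data.frame"),
            contrast = contrast, thresholds = thresholds, criterion = "fc_p")
}

#' Principal component scores of the samples
#'
#' SVD-based PCA of the per-feature mean-centered matrix, used for the
#' group-separation overview that precedes differential screening.
#'
#' @param matrix An \code{\link{omics_matrix}}.
#' @param n_components Number of components to return (default 2).
#' @return A list with \code{scores} (samples x components, with sample
#'   ids as row names), \code{explained} (variance fractions,
#'   non-increasing, summing to <= 1) and \code{groups}.
#' @export
pca_scores <- function(matrix, n_components = 2) {
  stopifnot(inherits(matrix, "omics_matrix"))
  x <- t(matrix$values)               # samples x features
  if (nrow(x) < 2L) stop("PCA needs >= 2 samples")
  maxc <- min(ncol(x), nrow(x) - 1L)
  if (n_components > maxc)
    stop("n_components (", n_components, ") exceeds min(features, samples-1) = ", maxc)
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(centered) < .Machine$double.eps^0.5))
    stop("degenerate input: matrix is constant across samples, PCA undefined")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = (pc$sdev^2 / total)[seq_len(n_components)],
       groups = matrix$groups)
}
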