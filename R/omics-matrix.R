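#' Construct an omics abundance matrix
#'
#' The basic data container of the package: a feature-by-sample numeric
#' matrix (log2 scale unless \code{log2 = FALSE}) together with a group
#' label for every sample and a tag naming the omics layer.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature identifiers, column names sample identifiers.
#' @param groups Character or factor vector, one entry per sample column,
#'   each one of \code{"control"}, \code{"model"}, \code{"treated"} (or any
#'   other label set, but those three are the study design emulated here).
#' @param layer One of \code{"transcript"}, \code{"protein"},
#'   \code{"metabolite"}.
#' @param log2 Logical; \code{TRUE} (default) declares the values to be on
#'   log2 scale. Raw counts must be converted explicitly with
#'   \code{\link{log2_transform}} before screening.
#'
#' @return An object of class \code{omics_matrix}: a list with elements
#'   \code{values}, \code{groups} (named character vector), \code{layer}
#'   and \code{log2}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' om <- omics_matrix(m, c("control", "control", "model", "model", "model"),
#'                    layer = "metabolite")
#' @export
omics_matrix <- function(values, groups, layer = c("transcript", "protein", "metabolite"),
                         log2 = TRUE) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("matrix contains missing values; impute or drop them explicitly before use")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("length(groups) [", length(groups), "] != number of samples [", ncol(values), "]")
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("every sample needs a non-empty group label")
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups, layer = layer, log2 = isTRUE(log2)),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%s scale)\n",
              x$layer, nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "raw"))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Convert a raw-scale matrix to log2 scale
#'
#' Applies \code{log2(x + pseudocount)}. Conversion is always explicit:
#' screening functions refuse raw-scale input rather than transforming
#' silently.
#'
#' @param x An \code{omics_matrix} with \code{log2 = FALSE}.
#' @param pseudocount Added before taking logs; default 1.
#' @return The matrix on log2 scale (\code{log2 = TRUE}).
#' @export
log2_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$log2) stop("matrix is already on log2 scale")
  if (any(x$values + pseudocount <= 0))
    stop("values + pseudocount must be positive")
  x$values <- log2(x$values + pseudocount)
  x$log2 <- TRUE
  x
}

#' Restrict an omics matrix to a subset of samples or features
#'
#' @param x An \code{omics_matrix}.
#' @param features Optional character vector of feature ids to keep.
#' @param samples Optional character vector of sample ids to keep.
#' @param groups Optional character vector of group labels to keep.
#' @return The restricted \code{omics_matrix}.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL, groups = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!is.null(groups)) {
    keep <- names(x$groups)[x$groups %in% groups]
    samples <- if (is.null(samples)) keep else intersect(samples, keep)
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(x$values))
    if (length(missing))
      stop("unknown samples: ", paste(missing, collapse = ", "))
    x$values <- x$values[, samples, drop = FALSE]
    x$groups <- x$groups[samples]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(x$values))
    if (length(missing))
      stop("unknown features: ", paste(missing, collapse = ", "))
    x$values <- x$values[features, , drop = FALSE]
  }
  x
}

#' Write / read an omics matrix as TSV
#'
#' The matrix is stored with a leading \code{feature_id} column; the group
#' assignment goes to a companion sample sheet with columns
#' \code{sample_id} and \code{group}.
#'
#' @param x An \code{omics_matrix}.
#' @param matrix_path Path for the abundance TSV.
#' @param samples_path Path for the sample sheet TSV.
#' @return \code{write_omics_matrix} returns its paths invisibly;
#'   \code{read_omics_matrix} returns an \code{omics_matrix}.
#' @export
write_omics_matrix <- function(x, matrix_path, samples_path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample_id = names(x$groups), group = unname(x$groups),
                   stringsAsFactors = FALSE)
  utils::write.table(ss, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = matrix_path, samples = samples_path))
}

#' @rdname write_omics_matrix
#' @param layer Omics layer tag for the object read back.
#' @param log2 Whether the stored values are on log2 scale.
#' @export
read_omics_matrix <- function(matrix_path, samples_path,
                              layer = c("transcript", "protein", "metabolite"),
                              log2 = TRUE) {
  layer <- match.arg(layer)
  df <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% colnames(df))
    stop("matrix TSV must have a 'feature_id' first column: ", matrix_path)
  vals <- as.matrix(df[, setdiff(colnames(df), "feature_id"), drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance values in ", matrix_path)
  rownames(vals) <- df$feature_id
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(ss)))
    stop("sample sheet must have columns 'sample_id' and 'group': ", samples_path)
  missing <- setdiff(colnames(vals), ss$sample_id)
  if (length(missing))
    stop("samples missing from sample sheet: ", paste(missing, collapse = ", "))
  groups <- ss$group[match(colnames(vals), ss$sample_id)]
  omics_matrix(vals, groups, layer = layer, log2 = log2)
}

# run an expression with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
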