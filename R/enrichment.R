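#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line,
#' \code{set_name<TAB>description<TAB>member1<TAB>member2...}.
#' Duplicate members within a set are removed (the count is reported via
#' \code{message()}).
#'
#' @param path Path to the GMT file.
#' @return An object of class \code{geneset_collection}: a named list of
#'   character vectors, with the per-set descriptions in attribute
#'   \code{description}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", i, ": GMT needs >= 3 tab-separated fields, got ", length(f))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    n_dup <- n_dup + sum(duplicated(members))
    sets[[f[1L]]] <- unique(members)
    desc[f[1L]] <- f[2L]
  }
  if (n_dup > 0L)
    message("removed ", n_dup, " duplicate member(s) within sets")
  structure(sets, description = desc, class = c("geneset_collection", "list"))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each set of a collection for over-representation of a query
#' feature set against a background universe: with N universe features,
#' K of them in the set, and a query of n features overlapping the set in
#' k, the p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)}. Query and sets are intersected with the universe
#' first, so features outside the universe never influence a record.
#' Benjamini-Hochberg q-values are computed across all tested sets.
#'
#' @param query Character vector of feature ids.
#' @param collection A \code{\link{read_gmt}} collection (or named list
#'   of character vectors).
#' @param universe Background feature ids; default is the union of all
#'   collection members.
#' @return A data.frame with columns \code{term}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{q}, sorted by p then term name.
#' @examples
#' sets <- list(a = c("g1", "g2", "g3"), b = c("g4", "g5"))
#' ora(c("g1", "g2"), sets, universe = paste0("g", 1:10))
#' @export
ora <- function(query, collection, universe = NULL) {
  if (is.null(universe))
    universe <- unique(unlist(collection, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  N <- length(universe)
  n <- length(query)
  recs <- lapply(names(collection), function(term) {
    set <- intersect(collection[[term]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
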