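#' Network-separation score between two modules
#'
#' The separation score of two node sets A and B on a shared interactome,
#' \deqn{S_{AB} = \langle d_{AB}\rangle - \frac{\langle d_{AA}\rangle +
#'   \langle d_{BB}\rangle}{2},}
#' computed from unweighted shortest-path (hop-count) distances.
#' \eqn{\langle d_{AA}\rangle} is the mean, over the nodes of A, of the
#' distance to the nearest \emph{other} node of A (0 for a singleton, by
#' convention); \eqn{\langle d_{AB}\rangle} is the mean, over all nodes
#' of A and B, of the distance to the nearest node of the \emph{other}
#' set, self-pairs excluded for nodes the two sets share — which makes
#' \eqn{S_{AA} = 0} an exact identity. A negative \eqn{S_{AB}} means
#' the two modules occupy the same network neighborhood — the criterion
#' used here to call a gene-module/protein-module pair synergistic.
#'
#' @param graph The shared interactome (\code{igraph}, undirected).
#' @param module,module_a,module_b Character vectors of node ids; every
#'   id must be present in the graph.
#' @return A single numeric value.
#' @examples
#' g <- igraph::make_ring(6, circular = FALSE)
#' igraph::V(g)$name <- as.character(1:6)
#' separation(g, c("1", "2"), c("5", "6"))  # 2.5
#' @export
separation <- function(graph, module_a, module_b) {
  between_distance(graph, module_a, module_b) -
    (within_distance(graph, module_a) + within_distance(graph, module_b)) / 2
}

check_in_graph <- function(graph, nodes) {
  missing <- setdiff(nodes, igraph::V(graph)$name)
  if (length(missing))
    stop("node(s) absent from graph: ", paste(missing, collapse = ", "))
}

#' @rdname separation
#' @export
within_distance <- function(graph, module) {
  module <- unique(as.character(module))
  if (!length(module)) stop("empty module")
  check_in_graph(graph, module)
  if (length(module) == 1L) return(0)
  d <- igraph::distances(graph, v = module, to = module)
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' @rdname separation
#' @export
between_distance <- function(graph, module_a, module_b) {
  module_a <- unique(as.character(module_a))
  module_b <- unique(as.character(module_b))
  if (!length(module_a) || !length(module_b)) stop("empty module")
  check_in_graph(graph, c(module_a, module_b))
  d <- igraph::distances(graph, v = module_a, to = module_b)
  # a node present in both sets must not count itself as its nearest
  # cross-set partner: excluding self-pairs makes d_AB(A, A) = d_AA and
  # hence S_AA identically 0
  shared <- intersect(module_a, module_b)
  for (u in shared) d[u, u] <- Inf
  row_min <- apply(d, 1L, min)
  col_min <- apply(d, 2L, min)
  # degenerate overlap: the other set consists of the node itself only
  if (length(module_b) == 1L && module_b %in% module_a)
    row_min[module_b] <- 0
  if (length(module_a) == 1L && module_a %in% module_b)
    col_min[module_a] <- 0
  mean(c(row_min, col_min))
}

#' Pairwise separation matrix between two module sets
#'
#' Computes \eqn{S_{AB}} for every pair of one module from set A (e.g.
#' transcript-layer modules) and one from set B (protein-layer modules)
#' on one shared interactome, and selects the most synergistic pair (the
#' matrix argmin; ties broken by the earlier A label, then the earlier B
#' label).
#'
#' Distances are defined only inside a connected component, so the
#' analysis is restricted to the graph's largest connected component;
#' module members outside it are dropped with a \code{message()}, and any
#' module losing more than half of its members (or all of them) is
#' flagged unevaluable: its row/column is \code{NA} and it cannot be the
#' best pair.
#'
#' @param graph The shared interactome.
#' @param modules_a,modules_b \code{module_set} objects (see
#'   \code{\link{mcode}}).
#' @return An object of class \code{separation_result}: list with
#'   \code{s_ab} (matrix, A labels x B labels), \code{d_ab},
#'   \code{d_aa}, \code{d_bb} (the distance terms), \code{best_pair}
#'   (character vector of the two labels) and \code{best_value}.
#' @export
separation_matrix <- function(graph, modules_a, modules_b) {
  stopifnot(inherits(modules_a, "module_set"), inherits(modules_b, "module_set"))
  if (!length(modules_a) || !length(modules_b))
    stop("empty module set")
  comp <- igraph::components(graph)
  keep <- igraph::V(graph)$name[comp$membership == which.max(comp$csize)]
  if (length(keep) < igraph::vcount(graph))
    message("restricting to largest connected component: ",
            igraph::vcount(graph) - length(keep), " node(s) dropped")
  lcc <- igraph::induced_subgraph(graph, keep)

  prep <- function(ms) {
    lapply(ms, function(m) {
      inside <- intersect(m$members, keep)
      lost <- length(m$members) - length(inside)
      evaluable <- length(inside) >= 1L && lost <= length(m$members) / 2
      if (!evaluable)
        message("module ", m$label, " lost ", lost, "/", length(m$members),
                " member(s) to other components; flagged unevaluable")
      list(label = m$label, members = inside, evaluable = evaluable)
    })
  }
  a <- prep(modules_a); b <- prep(modules_b)
  la <- vapply(a, `[[`, "", "label"); lb <- vapply(b, `[[`, "", "label")
  d_aa <- vapply(a, function(m) if (m$evaluable) within_distance(lcc, m$members) else NA_real_,
                 numeric(1L))
  d_bb <- vapply(b, function(m) if (m$evaluable) within_distance(lcc, m$members) else NA_real_,
                 numeric(1L))
  names(d_aa) <- la; names(d_bb) <- lb
  d_ab <- matrix(NA_real_, length(a), length(b), dimnames = list(la, lb))
  for (i in seq_along(a))
    for (j in seq_along(b))
      if (a[[i]]$evaluable && b[[j]]$evaluable)
        d_ab[i, j] <- between_distance(lcc, a[[i]]$members, b[[j]]$members)
  s_ab <- d_ab - outer(d_aa, d_bb, `+`) / 2
  if (all(is.na(s_ab)))
    stop("no evaluable module pair on the shared interactome")
  best <- which(s_ab == min(s_ab, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  structure(list(s_ab = s_ab, d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
                 best_pair = c(la[best[1L]], lb[best[2L]]),
                 best_value = s_ab[best[1L], best[2L]]),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat("separation matrix (S_AB):\n")
  print(round(x$s_ab, 3))
  cat(sprintf("best pair: %s / %s (S = %.3f)\n",
              x$best_pair[1L], x$best_pair[2L], x$best_value))
  invisible(x)
}
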