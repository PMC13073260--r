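#' Read an interactome edge list
#'
#' Reads a TSV edge list (two node columns, optional third numeric
#' confidence column, \code{#} comment lines allowed) into an undirected
#' simple \code{igraph} graph. Duplicate edges are merged and self-loops
#' dropped; the number of dropped self-loops is reported via
#' \code{message()}.
#'
#' @param path Path to the edge-list TSV.
#' @param min_score Optional confidence cut-off; edges with score below
#'   it are removed (requires a numeric third column).
#' @return An undirected simple \code{igraph} graph; edge attribute
#'   \code{score} is kept when a third column is present.
#' @export
read_edgelist <- function(path, min_score = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(igraph::make_empty_graph(0, directed = FALSE))
  fields <- strsplit(lines, "\t|\\s+")
  nfield <- vapply(fields, length, 1L)
  bad <- which(nfield < 2L)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": expected at least 2 columns")
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  score <- rep(NA_real_, length(from))
  has3 <- nfield >= 3L
  if (any(has3)) {
    raw <- vapply(fields[has3], `[[`, "", 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (!is.null(min_score) && anyNA(val))
      stop("line ", lineno[has3][which(is.na(val))[1L]],
           ": non-numeric score '", raw[which(is.na(val))[1L]],
           "' with min_score requested")
    score[has3] <- val
  }
  if (!is.null(min_score)) {
    if (!any(has3)) stop("min_score requested but the file has no score column")
    sel <- !is.na(score) & score >= min_score
    from <- from[sel]; to <- to[sel]; score <- score[sel]
  }
  loops <- from == to
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    from <- from[!loops]; to <- to[!loops]; score <- score[!loops]
  }
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (any(!is.na(score))) df$score <- score
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Write an interactome as a TSV edge list
#'
#' @param graph An undirected \code{igraph} graph.
#' @param path Output path.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
  if ("score" %in% igraph::edge_attr_names(graph))
    df$score <- igraph::E(graph)$score
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Subnetwork induced by a feature set
#'
#' @param graph An \code{igraph} interactome.
#' @param features Character vector of node ids; ids absent from the
#'   graph are counted and reported via \code{message()}, not errors.
#' @return The subgraph induced by \code{features} intersected with the
#'   graph's node set.
#' @export
induced_subnetwork <- function(graph, features) {
  present <- intersect(features, igraph::V(graph)$name)
  n_missing <- length(setdiff(features, present))
  if (n_missing > 0)
    message(n_missing, " feature(s) absent from the interactome")
  igraph::induced_subgraph(graph, present)
}

# MCODE vertex weight: highest k-core number of the closed neighborhood
# times the density of that k-core.
mcode_weights <- function(graph) {
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  vapply(seq_along(adj), function(i) {
    nb <- unique(c(i, as.integer(adj[[i]])))
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) return(0)
    top <- igraph::induced_subgraph(sub, which(core >= kmax))
    n <- igraph::vcount(top)
    dens <- if (n < 2L) 0 else igraph::ecount(top) / (n * (n - 1) / 2)
    kmax * dens
  }, numeric(1L))
}

#' MCODE-style dense module detection
#'
#' Three-stage molecular-complex detection on a simple undirected graph:
#' \enumerate{
#'   \item \emph{Vertex weighting}: each vertex is weighted by the
#'     highest k-core number of its closed neighborhood times the density
#'     of that k-core (the core-clustering coefficient).
#'   \item \emph{Complex prediction}: seeds are taken in decreasing
#'     weight order (ties broken by node id); a complex grows outward
#'     from the seed, admitting neighbors whose weight is at least
#'     \code{(1 - node_score_cutoff)} times the seed weight, to at most
#'     \code{max_depth} steps from the seed. With \code{haircut} enabled
#'     the haircut rule is applied during growth as well: once a complex
#'     has two or more members, a candidate connected to it by a single
#'     edge is not admitted (it would be shaved off afterwards anyway,
#'     and admitting it would let the complex leak across bridge edges).
#'   \item \emph{Post-processing}: complexes whose subgraph contains no
#'     \code{k_core}-core are discarded; \code{haircut} iteratively
#'     removes members with fewer than 2 within-complex edges;
#'     \code{fluff} optionally adds back neighbors whose closed
#'     neighborhood density exceeds \code{fluff_density}.
#' }
#' Modules are scored by subgraph density times size and returned in
#' decreasing score order. The procedure is deterministic: all ties are
#' broken lexicographically by node id.
#'
#' @param graph Simple undirected \code{igraph} graph with named vertices.
#' @param degree_cutoff Minimum degree for a vertex to be weighted and
#'   seeded (default 2).
#' @param node_score_cutoff Admission slack relative to the seed weight
#'   (default 0.2).
#' @param k_core Complexes without a k-core of this order are dropped
#'   (default 2).
#' @param max_depth Maximum growth distance from the seed (default 100).
#' @param haircut Remove (and refuse) singly-connected members (default
#'   \code{TRUE}).
#' @param fluff Add dense neighbors after haircut (default \code{FALSE}).
#' @param fluff_density Closed-neighborhood density threshold for fluff.
#' @param label_prefix Prefix for module labels (e.g. \code{"A"} for the
#'   transcript layer, \code{"B"} for the protein layer).
#' @return An object of class \code{module_set}: a list of modules, each
#'   with \code{label}, \code{members} (sorted node ids), \code{score}
#'   and \code{seed}.
#' @examples
#' g <- igraph::make_full_graph(4) + igraph::make_empty_graph(1, directed = FALSE)
#' igraph::V(g)$name <- paste0("n", 1:5)
#' mcode(g)
#' @export
mcode <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE, fluff = FALSE,
                  fluff_density = 0.2, label_prefix = "M") {
  if (igraph::is_directed(graph) || any(igraph::which_loop(graph)) ||
      any(igraph::which_multiple(graph)))
    stop("mcode() requires a simple undirected graph")
  n <- igraph::vcount(graph)
  if (n == 0L || igraph::ecount(graph) == 0L)
    return(structure(list(), class = "module_set"))
  nm <- igraph::V(graph)$name
  if (is.null(nm)) stop("graph vertices must be named")
  deg <- igraph::degree(graph)
  w <- mcode_weights(graph)
  w[deg < degree_cutoff] <- 0
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)

  seed_order <- order(-w, nm)
  visited <- logical(n)
  complexes <- list()
  for (s in seed_order) {
    if (visited[s] || w[s] <= 0) next
    thr <- (1 - node_score_cutoff) * w[s]
    members <- s
    visited[s] <- TRUE
    examined <- logical(n)
    examined[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      cands <- unique(unlist(adj[frontier]))
      cands <- cands[!visited[cands] & !examined[cands]]
      cands <- cands[order(nm[cands])]
      added <- integer(0)
      for (v in cands) {
        examined[v] <- TRUE
        if (w[v] < thr) next
        if (haircut && length(members) >= 2L &&
            sum(adj[[v]] %in% members) < 2L) next
        members <- c(members, v)
        visited[v] <- TRUE
        added <- c(added, v)
      }
      frontier <- added
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- list(seed = s, members = members)
  }

  modules <- list()
  for (cx in complexes) {
    mem <- cx$members
    sub <- igraph::induced_subgraph(graph, mem)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      repeat {
        d <- igraph::degree(sub)
        drop <- igraph::V(sub)$name[d < 2]
        if (!length(drop) || igraph::vcount(sub) - length(drop) < 2L) break
        sub <- igraph::induced_subgraph(
          sub, setdiff(igraph::V(sub)$name, drop))
      }
      mem <- match(igraph::V(sub)$name, nm)
    }
    if (fluff) {
      nbrs <- setdiff(unique(unlist(adj[mem])), mem)
      dens_ok <- vapply(nbrs, function(v) {
        nb <- unique(c(v, adj[[v]]))
        k <- length(nb)
        if (k < 2L) return(0)
        igraph::ecount(igraph::induced_subgraph(graph, nb)) / (k * (k - 1) / 2)
      }, numeric(1L))
      mem <- c(mem, nbrs[dens_ok > fluff_density])
      sub <- igraph::induced_subgraph(graph, mem)
    }
    sz <- igraph::vcount(sub)
    dens <- if (sz < 2L) 0 else igraph::ecount(sub) / (sz * (sz - 1) / 2)
    modules[[length(modules) + 1L]] <-
      list(members = sort(nm[mem]), score = dens * sz, seed = nm[cx$seed])
  }
  if (!length(modules))
    return(structure(list(), class = "module_set"))
  first_member <- vapply(modules, function(m) m$members[1L], "")
  ord <- order(-vapply(modules, `[[`, 0, "score"),
               -lengths(lapply(modules, `[[`, "members")), first_member)
  modules <- modules[ord]
  for (i in seq_along(modules))
    modules[[i]]$label <- paste0(label_prefix, i)
  structure(modules, class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  if (!length(x)) {
    cat("module_set: no modules\n")
    return(invisible(x))
  }
  for (m in x)
    cat(sprintf("%s: %d nodes, score %.2f (seed %s)\n",
                m$label, length(m$members), m$score, m$seed))
  invisible(x)
}

#' Serialize / read a module set as TSV
#'
#' Long format with columns \code{module_label}, \code{node},
#' \code{score}.
#'
#' @param modules A \code{module_set}.
#' @param path TSV path.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  rows <- do.call(rbind, lapply(modules, function(m)
    data.frame(module_label = m$label, node = m$members, score = m$score,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(module_label = character(), node = character(),
                       score = numeric(), stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("module_label", "node", "score")
  if (!all(need %in% colnames(df)))
    stop("module TSV missing columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  labels <- unique(df$module_label)
  modules <- lapply(labels, function(lb) {
    sel <- df$module_label == lb
    list(members = sort(df$node[sel]), score = df$score[sel][1L],
         seed = NA_character_, label = lb)
  })
  structure(modules, class = "module_set")
}

#' Rank hub nodes within a module
#'
#' Nodes ranked by degree inside the module-induced subgraph (descending;
#' ties broken lexicographically), the package's nomination rule for hub
#' genes/proteins of a module.
#'
#' @param graph The interactome.
#' @param module A single module from a \code{module_set} (or a character
#'   vector of node ids).
#' @param top_k Number of hubs to return (default 7); capped at the
#'   module size.
#' @return Character vector of node ids, strongest hub first.
#' @export
hub_rank <- function(graph, module, top_k = 7) {
  members <- if (is.list(module)) module$members else as.character(module)
  missing <- setdiff(members, igraph::V(graph)$name)
  if (length(missing))
    stop("module nodes absent from graph: ", paste(missing, collapse = ", "))
  sub <- igraph::induced_subgraph(graph, members)
  d <- igraph::degree(sub)
  nm <- igraph::V(sub)$name
  ord <- order(-d, nm)
  nm[ord][seq_len(min(top_k, length(nm)))]
}
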