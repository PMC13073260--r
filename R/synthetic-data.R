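#' Specify a synthetic three-group multi-omics dataset
#'
#' Describes the simulated study design emulated throughout the package:
#' three groups (control, disease model, treated), a fraction of features
#' perturbed in the model group, and a sub-fraction of those restored to
#' control levels by treatment. Abundances are log-normal: Gaussian noise
#' is added on the log2 scale around per-feature baseline means.
#'
#' @param n_features Number of features in the layer.
#' @param n_per_group Samples per group; default 5, the per-group size of
#'   the emulated study.
#' @param frac_disease Fraction of features perturbed in model vs control.
#' @param frac_reversed Fraction of the perturbed features whose treated
#'   mean returns to the control mean (the others stay at the model mean).
#' @param effect_log2 Planted |log2 fold change| of perturbed features.
#' @param noise_sd Residual SD on the log2 scale.
#' @param seed Integer RNG seed; the same spec is bit-reproducible.
#' @param interactome_blocks List of planted blocks for
#'   \code{\link{generate_interactome}}; each element a numeric vector
#'   \code{c(size, p_within, p_between)}.
#' @param layer Omics layer tag passed through to the generated matrix.
#'
#' @return An object of class \code{synthetic_spec}.
#' @seealso \code{\link{generate_dataset}}, \code{\link{generate_interactome}}
#' @export
synthetic_spec <- function(n_features = 200, n_per_group = 5,
                           frac_disease = 0.2, frac_reversed = 0.5,
                           effect_log2 = 3, noise_sd = 0.3, seed = 1,
                           interactome_blocks = list(c(20, 0.9, 0.01)),
                           layer = "transcript") {
  spec <- list(n_features = n_features, n_per_group = n_per_group,
               frac_disease = frac_disease, frac_reversed = frac_reversed,
               effect_log2 = effect_log2, noise_sd = noise_sd,
               seed = as.integer(seed), interactome_blocks = interactome_blocks,
               layer = layer)
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  check <- function(ok, field, why) {
    if (!ok) stop("invalid synthetic_spec field '", field, "': ", why, call. = FALSE)
  }
  check(is.numeric(spec$n_features) && spec$n_features >= 1, "n_features", "must be >= 1")
  check(is.numeric(spec$n_per_group) && spec$n_per_group >= 3, "n_per_group", "must be >= 3")
  check(is.numeric(spec$frac_disease) && spec$frac_disease >= 0 && spec$frac_disease <= 1,
        "frac_disease", "must lie in [0, 1]")
  check(is.numeric(spec$frac_reversed) && spec$frac_reversed >= 0 && spec$frac_reversed <= 1,
        "frac_reversed", "must lie in [0, 1]")
  check(is.numeric(spec$effect_log2) && spec$effect_log2 >= 0, "effect_log2", "must be >= 0")
  check(is.numeric(spec$noise_sd) && spec$noise_sd > 0, "noise_sd", "must be > 0")
  check(is.numeric(spec$seed) && !is.na(spec$seed), "seed", "must be an integer")
  check(is.list(spec$interactome_blocks) &&
          all(vapply(spec$interactome_blocks, length, 1L) == 3L),
        "interactome_blocks", "each block must be c(size, p_within, p_between)")
  invisible(spec)
}

#' Generate a synthetic three-group omics dataset with planted reversals
#'
#' Baseline feature means are drawn uniformly on log2(8..12); a random
#' subset of features (\code{frac_disease}) gets its model-group mean
#' shifted by \code{effect_log2} with random sign, and a random sub-subset
#' (\code{frac_reversed}) has its treated-group mean set back to the
#' control mean, while the remaining perturbed features keep the model
#' mean in the treated group. Gaussian log2-scale noise of SD
#' \code{noise_sd} is added everywhere.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list with components \code{matrix} (an
#'   \code{\link{omics_matrix}}, samples named
#'   \code{control_1..}, \code{model_1..}, \code{treated_1..}) and
#'   \code{truth}, a data.frame with columns \code{feature_id},
#'   \code{disease} (logical), \code{reversed} (logical) and
#'   \code{direction} (+1/-1 sign of the planted model-vs-control shift,
#'   0 for unperturbed features).
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_features = 50, seed = 7))
#' table(sim$truth$disease, sim$truth$reversed)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  nf <- as.integer(spec$n_features)
  np <- as.integer(spec$n_per_group)
  with_seed(spec$seed, {
    feature_ids <- sprintf("f%04d", seq_len(nf))
    n_disease <- round(spec$frac_disease * nf)
    n_reversed <- round(spec$frac_reversed * n_disease)
    disease_idx <- sort(sample.int(nf, n_disease))
    reversed_idx <- sort(sample(disease_idx, n_reversed))
    direction <- integer(nf)
    direction[disease_idx] <- sample(c(-1L, 1L), n_disease, replace = TRUE)

    base <- stats::runif(nf, 8, 12)
    mu_control <- base
    mu_model <- base + direction * spec$effect_log2
    mu_treated <- mu_model
    mu_treated[reversed_idx] <- mu_control[reversed_idx]

    groups <- rep(c("control", "model", "treated"), each = np)
    sample_ids <- paste(groups, rep(seq_len(np), times = 3), sep = "_")
    mu <- cbind(matrix(mu_control, nf, np), matrix(mu_model, nf, np),
                matrix(mu_treated, nf, np))
    vals <- mu + matrix(stats::rnorm(nf * 3L * np, sd = spec$noise_sd), nf, 3L * np)
    dimnames(vals) <- list(feature_ids, sample_ids)

    truth <- data.frame(feature_id = feature_ids,
                        disease = seq_len(nf) %in% disease_idx,
                        reversed = seq_len(nf) %in% reversed_idx,
                        direction = direction,
                        stringsAsFactors = FALSE)
    list(matrix = omics_matrix(vals, groups, layer = spec$layer, log2 = TRUE),
         truth = truth)
  })
}

#' Generate a modular interactome with planted dense blocks
#'
#' A stochastic block model over the supplied feature identifiers: blocks
#' are filled in order from the start of \code{feature_ids}; each pair of
#' nodes inside block k is connected with probability \code{p_within[k]}.
#' Pairs spanning two blocks (or touching background nodes outside every
#' block) are connected with the mean of the \code{p_between} values of
#' the endpoints' blocks; background nodes carry the mean \code{p_between}
#' over all blocks.
#'
#' @param spec A \code{\link{synthetic_spec}} (provides
#'   \code{interactome_blocks} and \code{seed}).
#' @param feature_ids Node identifiers; block sizes must sum to at most
#'   \code{length(feature_ids)}.
#' @return An undirected simple \code{igraph} graph with a
#'   \code{block} vertex attribute (0 = background).
#' @export
generate_interactome <- function(spec, feature_ids) {
  stopifnot(inherits(spec, "synthetic_spec"))
  blocks <- spec$interactome_blocks
  sizes <- vapply(blocks, `[`, 0, 1L)
  p_in <- vapply(blocks, `[`, 0, 2L)
  p_out <- vapply(blocks, `[`, 0, 3L)
  if (any(p_in < 0 | p_in > 1) || any(p_out < 0 | p_out > 1))
    stop("block edge probabilities must lie in [0, 1]")
  n <- length(feature_ids)
  if (sum(sizes) > n)
    stop("block sizes (", sum(sizes), ") exceed number of feature ids (", n, ")")
  membership <- integer(n)           # 0 = background
  at <- 1L
  for (k in seq_along(sizes)) {
    membership[at:(at + sizes[k] - 1L)] <- k
    at <- at + as.integer(sizes[k])
  }
  p_bg <- if (length(p_out)) mean(p_out) else 0
  node_out <- ifelse(membership == 0L, p_bg, p_out[pmax(membership, 1L)])

  with_seed(spec$seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1L]; j <- pairs[, 2L]
    same <- membership[i] != 0L & membership[i] == membership[j]
    prob <- (node_out[i] + node_out[j]) / 2
    prob[same] <- p_in[membership[i[same]]]
    keep <- stats::runif(length(prob)) < prob
    g <- igraph::graph_from_data_frame(
      data.frame(from = feature_ids[i[keep]], to = feature_ids[j[keep]]),
      directed = FALSE,
      vertices = data.frame(name = feature_ids, block = membership))
    igraph::simplify(g)
  })
}

#' Load the packaged table of treatment-reverted metabolites
#'
#' Returns the packaged 61-row reference table of metabolites whose
#' model-vs-control change was reversed by treatment, with the compound
#' class of each metabolite and the direction arrows of both contrasts
#' encoded as \code{"up"} / \code{"down"}.
#'
#' @param path Optional path to an alternative TSV with the same columns;
#'   default is the fixture shipped in \code{inst/extdata}.
#' @return A data.frame with columns \code{name}, \code{category},
#'   \code{trend_mc} (model vs control) and \code{trend_tm} (treated vs
#'   model).
#' @examples
#' tab <- load_table1_fixture()
#' nrow(tab)  # 61
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_reverted_metabolites.tsv",
                        package = "revnet", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty fixture file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  need <- c("name", "category", "trend_model_vs_control", "trend_pa_vs_model")
  if (!identical(header, need))
    stop("line 1: expected header ", paste(need, collapse = "\t"))
  bad <- which(vapply(fields, length, 1L) != 4L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 4 tab-separated fields, got ",
         length(fields[[bad[1L]]]))
  body <- do.call(rbind, fields[-1L])
  tab <- data.frame(name = body[, 1L], category = body[, 2L],
                    trend_mc = body[, 3L], trend_tm = body[, 4L],
                    stringsAsFactors = FALSE)
  bad_trend <- which(!(tab$trend_mc %in% c("up", "down") &
                         tab$trend_tm %in% c("up", "down")))
  if (length(bad_trend))
    stop("line ", bad_trend[1L] + 1L, ": trends must be 'up' or 'down'")
  tab
}
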