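#' Simulate a complete three-group multi-omics study on disk
#'
#' Builds everything \code{\link{run_pipeline}} needs, with known ground
#' truth: transcript, protein and metabolite layers (5 samples per group
#' by default), a shared interactome over the gene and protein
#' identifiers with three planted dense blocks — one of reverted genes
#' only, one of reverted proteins only, and one \emph{mixed} block of
#' reverted genes and reverted proteins interleaved in a single dense
#' neighborhood (the planted synergistic module pair, which should
#' attain the minimal, negative S_AB) — a small GMT collection in which
#' one set collects the planted synergy members, and a ready-to-run
#' \code{config.yaml}.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param n_features Named vector of per-layer feature counts.
#' @param n_per_group Samples per group (default 5, the emulated design).
#' @param effect_log2 Planted effect size (default 3).
#' @param noise_sd Log2-scale noise SD (default 0.3).
#' @param block_sizes Sizes of the three planted interactome blocks:
#'   gene-only, mixed (split half genes / half proteins), protein-only.
#' @param p_within,p_between Edge probabilities of the planted stochastic
#'   block model.
#' @return Invisibly, a list with \code{config} (path to the YAML),
#'   \code{truth} (per-layer truth tables), and \code{planted} (the node
#'   sets of the three blocks, with \code{synergy_genes} /
#'   \code{synergy_proteins} naming the two halves of the mixed block).
#' @export
simulate_study <- function(dir, seed = 1,
                           n_features = c(transcript = 300, protein = 300,
                                          metabolite = 120),
                           n_per_group = 5, effect_log2 = 3, noise_sd = 0.3,
                           block_sizes = c(gene = 16, mixed = 32, protein = 16),
                           p_within = 0.9, p_between = 0.01) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefixes <- c(transcript = "g", protein = "p", metabolite = "m")
  sims <- list()
  truth <- list()
  for (i in seq_along(prefixes)) {
    layer <- names(prefixes)[i]
    spec <- synthetic_spec(n_features = n_features[[layer]],
                           n_per_group = n_per_group,
                           frac_disease = 0.3, frac_reversed = 0.6,
                           effect_log2 = effect_log2, noise_sd = noise_sd,
                           seed = seed + i - 1L, layer = layer)
    sim <- generate_dataset(spec)
    new_ids <- sub("^f", prefixes[[layer]], rownames(sim$matrix$values))
    rownames(sim$matrix$values) <- new_ids
    sim$truth$feature_id <- new_ids
    sims[[layer]] <- sim
    truth[[layer]] <- sim$truth
    write_omics_matrix(sim$matrix,
                       file.path(dir, paste0(layer, "_matrix.tsv")),
                       file.path(dir, paste0(layer, "_samples.tsv")))
    utils::write.table(sim$truth, file.path(dir, paste0("truth_", layer, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  rev_genes <- truth$transcript$feature_id[truth$transcript$reversed]
  rev_prots <- truth$protein$feature_id[truth$protein$reversed]
  half_mixed <- block_sizes[["mixed"]] %/% 2L
  need_g <- block_sizes[["gene"]] + half_mixed
  need_p <- block_sizes[["protein"]] + half_mixed
  if (length(rev_genes) < need_g || length(rev_prots) < need_p)
    stop("not enough planted reversed features for the requested blocks")
  gene_block <- rev_genes[seq_len(block_sizes[["gene"]])]
  synergy_genes <- rev_genes[block_sizes[["gene"]] + seq_len(half_mixed)]
  prot_block <- rev_prots[seq_len(block_sizes[["protein"]])]
  synergy_prots <- rev_prots[block_sizes[["protein"]] + seq_len(half_mixed)]
  mixed_block <- as.vector(rbind(synergy_genes, synergy_prots))

  all_ids <- c(truth$transcript$feature_id, truth$protein$feature_id)
  ordered_ids <- c(gene_block, mixed_block, prot_block,
                   setdiff(all_ids, c(gene_block, mixed_block, prot_block)))
  net_spec <- synthetic_spec(
    n_features = length(ordered_ids), seed = seed + 10L,
    interactome_blocks = list(c(block_sizes[["gene"]], p_within, p_between),
                              c(length(mixed_block), p_within, p_between),
                              c(block_sizes[["protein"]], p_within, p_between)))
  graph <- generate_interactome(net_spec, ordered_ids)
  write_edgelist(graph, file.path(dir, "interactome.tsv"))

  universe <- sort(all_ids)
  gmt_sets <- with_seed(seed + 20L, list(
    planted_synergy = sort(c(synergy_genes, synergy_prots)),
    planted_gene_block = sort(gene_block),
    planted_protein_block = sort(prot_block),
    random_set_1 = sort(sample(universe, 40L)),
    random_set_2 = sort(sample(universe, 40L))))
  gmt_path <- file.path(dir, "sets.gmt")
  writeLines(vapply(names(gmt_sets), function(nm)
    paste(c(nm, "synthetic set", gmt_sets[[nm]]), collapse = "\t"), ""),
    gmt_path)
  writeLines(universe, file.path(dir, "universe.txt"))

  cfg <- list(transcript_matrix = file.path(dir, "transcript_matrix.tsv"),
              transcript_samples = file.path(dir, "transcript_samples.tsv"),
              protein_matrix = file.path(dir, "protein_matrix.tsv"),
              protein_samples = file.path(dir, "protein_samples.tsv"),
              metabolite_matrix = file.path(dir, "metabolite_matrix.tsv"),
              metabolite_samples = file.path(dir, "metabolite_samples.tsv"),
              interactome = file.path(dir, "interactome.tsv"),
              gmt = gmt_path,
              universe = file.path(dir, "universe.txt"),
              out_dir = file.path(dir, "out"),
              seed = as.integer(seed))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)

  invisible(list(config = config_path, truth = truth,
                 planted = list(gene_block = gene_block,
                                mixed_block = mixed_block,
                                synergy_genes = synergy_genes,
                                synergy_proteins = synergy_prots,
                                protein_block = prot_block)))
}
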