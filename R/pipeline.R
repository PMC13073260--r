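pipeline_defaults <- list(
  fc = 1, alpha = 0.05, vip = 1, n_orth = 1, hub_k = 7, seed = 1,
  min_score = NULL, gmt = NULL, universe = NULL, skip_enrichment = FALSE,
  mcode_degree_cutoff = 2, mcode_node_score_cutoff = 0.2, mcode_k_core = 2,
  mcode_max_depth = 100, mcode_haircut = TRUE, mcode_fluff = FALSE)

pipeline_required <- c("transcript_matrix", "transcript_samples",
                       "protein_matrix", "protein_samples",
                       "metabolite_matrix", "metabolite_samples",
                       "interactome", "out_dir")

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults (fold-change threshold 1,
#' alpha 0.05, VIP threshold 1, one orthogonal OPLS component, canonical
#' MCODE parameters), and checks it: unknown keys (with a nearest-key
#' suggestion), missing required keys, nonexistent input paths and
#' invalid threshold values are all collected and reported together in a
#' single error rather than one at a time.
#'
#' @param path Path to a YAML file. Recognised keys: the input paths
#'   \code{transcript_matrix}, \code{transcript_samples},
#'   \code{protein_matrix}, \code{protein_samples},
#'   \code{metabolite_matrix}, \code{metabolite_samples},
#'   \code{interactome}, optional \code{gmt} and \code{universe};
#'   \code{out_dir}; thresholds \code{fc}, \code{alpha}, \code{vip};
#'   \code{n_orth}, \code{hub_k}, \code{seed}, \code{min_score},
#'   \code{skip_enrichment}; and the \code{mcode_*} parameters of
#'   \code{\link{mcode}}.
#' @return A validated \code{pipeline_config} list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  errors <- character()
  known <- c(pipeline_required, names(pipeline_defaults))
  unknown <- setdiff(names(cfg), known)
  for (key in unknown) {
    dist <- utils::adist(key, known)
    hint <- known[which.min(dist)]
    errors <- c(errors, sprintf("unknown key '%s'%s", key,
                                if (min(dist) <= 3) sprintf(" (did you mean '%s'?)", hint) else ""))
  }
  missing <- setdiff(pipeline_required, names(cfg))
  if (length(missing))
    errors <- c(errors, paste("missing required key(s):",
                              paste(missing, collapse = ", ")))
  for (key in setdiff(names(pipeline_defaults), names(cfg)))
    cfg[[key]] <- pipeline_defaults[[key]]
  path_keys <- c(setdiff(pipeline_required, "out_dir"),
                 "gmt", "universe")
  for (key in path_keys)
    if (key %in% names(cfg) && !is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      errors <- c(errors, sprintf("path for '%s' does not exist: %s", key, cfg[[key]]))
  num_pos <- c("fc", "alpha", "vip", "hub_k", "mcode_degree_cutoff",
               "mcode_node_score_cutoff", "mcode_k_core", "mcode_max_depth")
  for (key in num_pos)
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L || cfg[[key]] <= 0)
      errors <- c(errors, sprintf("'%s' must be a single positive number (got %s)",
                                  key, deparse(cfg[[key]])))
  if (is.numeric(cfg$alpha) && length(cfg$alpha) == 1L && cfg$alpha >= 1)
    errors <- c(errors, "'alpha' must lie in (0, 1)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || cfg$seed != round(cfg$seed))
    errors <- c(errors, "'seed' must be a single integer")
  if (!is.numeric(cfg$n_orth) || cfg$n_orth < 0)
    errors <- c(errors, "'n_orth' must be a non-negative integer")
  if (length(errors))
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full reversal-network analysis pipeline
#'
#' Executes, in order: per-layer differential screens for the disease
#' (model vs control) and treatment (treated vs model) contrasts;
#' OPLS-DA with the VIP-based criterion for the metabolite layer;
#' reversal identification per layer; induction of the
#' reverted-transcript and reverted-protein subnetworks on the shared
#' interactome; MCODE module detection per layer (labels A1.., B1..);
#' the full S_AB separation matrix with best-pair selection; hub ranking
#' inside the best pair; and, when a GMT collection is configured,
#' over-representation analysis of the reverted sets. All tabular
#' outputs are written as TSV to \code{out_dir}, a machine-readable
#' summary to \code{summary.json}, a stage log to \code{log.txt}, and a
#' MANIFEST listing every artifact with its MD5 content hash. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config A \code{pipeline_config} from \code{\link{validate_config}},
#'   or the path to a YAML config file.
#' @return Invisibly, the summary list (also serialized as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  manifest <- data.frame(file = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  emit <- function(fname, writer) {
    fpath <- file.path(out, fname)
    writer(fpath)
    manifest <<- rbind(manifest,
                       data.frame(file = fname,
                                  md5 = unname(tools::md5sum(fpath)),
                                  stringsAsFactors = FALSE))
    fpath
  }
  finish <- function(status) {
    writeLines(log_lines, file.path(out, "log.txt"))
    mf <- rbind(manifest, data.frame(file = "log.txt",
                                     md5 = unname(tools::md5sum(file.path(out, "log.txt"))),
                                     stringsAsFactors = FALSE))
    mf$status <- status
    utils::write.table(mf, file.path(out, "MANIFEST.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  stage_name <- "load_inputs"
  result <- tryCatch({
    layers <- list(
      transcript = read_omics_matrix(config$transcript_matrix,
                                     config$transcript_samples, "transcript"),
      protein = read_omics_matrix(config$protein_matrix,
                                  config$protein_samples, "protein"),
      metabolite = read_omics_matrix(config$metabolite_matrix,
                                     config$metabolite_samples, "metabolite"))
    graph <- read_edgelist(config$interactome, min_score = config$min_score)
    note("load_inputs: %s; interactome %d nodes / %d edges",
         paste(sprintf("%s %dx%d", names(layers),
                       vapply(layers, function(l) nrow(l$values), 1L),
                       vapply(layers, function(l) ncol(l$values), 1L)),
               collapse = ", "),
         igraph::vcount(graph), igraph::ecount(graph))

    stage_name <- "differential_screen"
    screens <- list()
    reverted <- list()
    for (layer in names(layers)) {
      m <- layers[[layer]]
      mc <- diff_screen(m, c("model", "control"),
                        fc_threshold = config$fc, p_threshold = config$alpha)
      tm <- diff_screen(m, c("treated", "model"),
                        fc_threshold = config$fc, p_threshold = config$alpha)
      if (layer == "metabolite") {
        stage_name <- "opls_vip"
        fit_mc <- fit_oplsda(subset_omics(m, groups = c("model", "control")),
                             n_orth = config$n_orth, seed = config$seed)
        fit_tm <- fit_oplsda(subset_omics(m, groups = c("treated", "model")),
                             n_orth = config$n_orth, seed = config$seed)
        mc <- vip_criterion(mc, fit_mc, config$vip, config$alpha)
        tm <- vip_criterion(tm, fit_tm, config$vip, config$alpha)
        note("opls_vip: mc R2Y=%.3f Q2=%.3f; tm R2Y=%.3f Q2=%.3f",
             fit_mc$r2y, fit_mc$q2, fit_tm$r2y, fit_tm$q2)
        stage_name <- "differential_screen"
      }
      screens[[layer]] <- list(mc = mc, tm = tm)
      emit(sprintf("screen_%s_model_vs_control.tsv", layer),
           function(p) write_diff_table(mc, p))
      emit(sprintf("screen_%s_treated_vs_model.tsv", layer),
           function(p) write_diff_table(tm, p))
      rv <- find_reverted(mc, tm)
      reverted[[layer]] <- rv
      emit(sprintf("reverted_%s.tsv", layer),
           function(p) write_reverted(rv, p))
      note("%s: %d features, %d diff (mc), %d diff (tm), %d reverted",
           layer, nrow(mc), sum(mc$significant), sum(tm$significant), nrow(rv))
    }

    stage_name <- "interactome_modules"
    sub_a <- induced_subnetwork(graph, reverted$transcript$feature_id)
    sub_b <- induced_subnetwork(graph, reverted$protein$feature_id)
    mods_a <- mcode(sub_a, degree_cutoff = config$mcode_degree_cutoff,
                    node_score_cutoff = config$mcode_node_score_cutoff,
                    k_core = config$mcode_k_core,
                    max_depth = config$mcode_max_depth,
                    haircut = config$mcode_haircut, fluff = config$mcode_fluff,
                    label_prefix = "A")
    mods_b <- mcode(sub_b, degree_cutoff = config$mcode_degree_cutoff,
                    node_score_cutoff = config$mcode_node_score_cutoff,
                    k_core = config$mcode_k_core,
                    max_depth = config$mcode_max_depth,
                    haircut = config$mcode_haircut, fluff = config$mcode_fluff,
                    label_prefix = "B")
    emit("modules_transcript.tsv", function(p) write_modules(mods_a, p))
    emit("modules_protein.tsv", function(p) write_modules(mods_b, p))
    note("interactome_modules: %d transcript modules, %d protein modules",
         length(mods_a), length(mods_b))

    stage_name <- "module_separation"
    sep <- separation_matrix(graph, mods_a, mods_b)
    emit("separation.tsv", function(p)
      utils::write.table(data.frame(module_a = rownames(sep$s_ab)[row(sep$s_ab)],
                                    module_b = colnames(sep$s_ab)[col(sep$s_ab)],
                                    s_ab = as.vector(sep$s_ab),
                                    stringsAsFactors = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    note("module_separation: best pair %s/%s, S_AB = %.4f",
         sep$best_pair[1L], sep$best_pair[2L], sep$best_value)

    stage_name <- "hub_rank"
    best_a <- mods_a[[match(sep$best_pair[1L],
                            vapply(mods_a, `[[`, "", "label"))]]
    best_b <- mods_b[[match(sep$best_pair[2L],
                            vapply(mods_b, `[[`, "", "label"))]]
    hubs_a <- hub_rank(graph, best_a, top_k = config$hub_k)
    hubs_b <- hub_rank(graph, best_b, top_k = config$hub_k)
    note("hub_rank: %s hubs [%s]; %s hubs [%s]",
         best_a$label, paste(hubs_a, collapse = ", "),
         best_b$label, paste(hubs_b, collapse = ", "))

    stage_name <- "enrichment"
    enrich <- NULL
    if (!is.null(config$gmt) && !isTRUE(config$skip_enrichment)) {
      collection <- read_gmt(config$gmt)
      universe <- if (!is.null(config$universe))
        readLines(config$universe) else NULL
      enrich <- lapply(list(transcript = reverted$transcript$feature_id,
                            protein = reverted$protein$feature_id),
                       ora, collection = collection, universe = universe)
      for (layer in names(enrich)) {
        tab <- enrich[[layer]]
        emit(sprintf("enrichment_%s.tsv", layer), function(p)
          utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
      }
      note("enrichment: top transcript term '%s', top protein term '%s'",
           if (nrow(enrich$transcript)) enrich$transcript$term[1L] else NA,
           if (nrow(enrich$protein)) enrich$protein$term[1L] else NA)
    } else {
      note("enrichment: skipped (no GMT configured)")
    }

    stage_name <- "summary"
    summary <- list(
      seed = config$seed,
      thresholds = list(fc = config$fc, alpha = config$alpha, vip = config$vip),
      layers = lapply(names(layers), function(layer) list(
        layer = layer,
        n_features = nrow(layers[[layer]]$values),
        n_diff_model_vs_control = sum(screens[[layer]]$mc$significant),
        n_diff_treated_vs_model = sum(screens[[layer]]$tm$significant),
        n_reverted = nrow(reverted[[layer]]))),
      n_modules = list(transcript = length(mods_a), protein = length(mods_b)),
      s_ab = list(modules_a = rownames(sep$s_ab), modules_b = colnames(sep$s_ab),
                  matrix = unname(apply(sep$s_ab, 1L, as.numeric, simplify = FALSE))),
      best_pair = list(labels = sep$best_pair, s_ab = sep$best_value,
                       hubs_a = hubs_a, hubs_b = hubs_b),
      top_enrichment = if (!is.null(enrich))
        lapply(enrich, function(tab) utils::head(tab$term, 5L)) else NULL)
    emit("summary.json", function(p)
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null"))
    finish("complete")
    summary
  }, error = function(e) {
    note("FAILED at stage %s: %s", stage_name, conditionMessage(e))
    finish(sprintf("failed:%s", stage_name))
    stop("pipeline stage '", stage_name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
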