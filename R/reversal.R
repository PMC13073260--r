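#' Identify treatment-reverted features
#'
#' The central selection step of the analysis: a feature counts as
#' reverted when it is significant in the disease contrast (model vs
#' control) AND significant in the treatment contrast (treated vs model)
#' with the opposite fold-change sign — the treatment pushes the feature
#' back toward its control level. Each table's own significance criterion
#' applies (fold-change/p for transcripts and proteins,
#' \code{\link{vip_criterion}} for metabolites).
#'
#' An optional stricter mode additionally requires the restoring change
#' to be at least a fraction \code{min_restore} of the disease change in
#' magnitude (\code{|log2fc_tm| >= min_restore * |log2fc_mc|}); the
#' default 0 imposes no magnitude requirement.
#'
#' @param diff_mc \code{diff_table} for the (model, control) contrast.
#' @param diff_tm \code{diff_table} for the (treated, model) contrast,
#'   over the same feature universe.
#' @param min_restore Minimal restored fraction, default 0 (off).
#' @return A data.frame of class \code{reverted_set} with columns
#'   \code{feature_id}, \code{log2fc_mc}, \code{p_mc}, \code{log2fc_tm},
#'   \code{p_tm}, \code{direction} (\code{"up_then_down"} or
#'   \code{"down_then_up"}), sorted by |log2fc_mc| descending with ties
#'   broken by feature id.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_features = 100, seed = 2,
#'                                        n_per_group = 10))
#' mc <- diff_screen(sim$matrix, c("model", "control"))
#' tm <- diff_screen(sim$matrix, c("treated", "model"))
#' rv <- find_reverted(mc, tm)
#' @export
find_reverted <- function(diff_mc, diff_tm, min_restore = 0) {
  stopifnot(inherits(diff_mc, "diff_table"), inherits(diff_tm, "diff_table"))
  if (!setequal(diff_mc$feature_id, diff_tm$feature_id))
    stop("the two tables cover different feature universes")
  c_mc <- attr(diff_mc, "contrast"); c_tm <- attr(diff_tm, "contrast")
  if (!is.null(c_mc) && !is.null(c_tm) && c_mc[1L] != c_tm[2L])
    stop("contrast mismatch: disease contrast is (", paste(c_mc, collapse = ", "),
         ") but treatment contrast is (", paste(c_tm, collapse = ", "),
         "); expected (model, control) then (treated, model)")
  tm <- diff_tm[match(diff_mc$feature_id, diff_tm$feature_id), ]
  keep <- diff_mc$significant & tm$significant &
    sign(diff_mc$log2fc) * sign(tm$log2fc) == -1 &
    abs(tm$log2fc) >= min_restore * abs(diff_mc$log2fc)
  out <- data.frame(feature_id = diff_mc$feature_id[keep],
                    log2fc_mc = diff_mc$log2fc[keep],
                    p_mc = diff_mc$p[keep],
                    log2fc_tm = tm$log2fc[keep],
                    p_tm = tm$p[keep],
                    direction = ifelse(diff_mc$log2fc[keep] > 0,
                                       "up_then_down", "down_then_up"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log2fc_mc), out$feature_id), ]
  rownames(out) <- NULL
  structure(out, class = c("reverted_set", "data.frame"))
}

#' Summarize a reverted feature set
#'
#' Counts reverted features by reversal direction and — when a category
#' annotation is supplied, e.g. the packaged metabolite table from
#' \code{\link{load_table1_fixture}} — by category, with each category's
#' percentage of the total reported to one decimal place.
#'
#' @param reverted A \code{reverted_set} from \code{\link{find_reverted}},
#'   or a data.frame with columns \code{trend_mc}/\code{trend_tm} (arrow
#'   pairs) such as the packaged metabolite table.
#' @param categories Optional data.frame with columns \code{name} and
#'   \code{category} annotating (a superset of) the reverted features.
#' @return A list with \code{n} (total reverted), \code{by_direction}
#'   (named counts) and, when categories are available, \code{by_category}
#'   — a data.frame with \code{category}, \code{count}, \code{percent}
#'   sorted by count descending.
#' @examples
#' tab <- load_table1_fixture()
#' reversal_summary(tab, categories = tab)$by_category[1, ]
#' @export
reversal_summary <- function(reverted, categories = NULL) {
  if (all(c("trend_mc", "trend_tm") %in% colnames(reverted))) {
    opposite <- reverted$trend_mc != reverted$trend_tm
    reverted <- reverted[opposite, , drop = FALSE]
    ids <- reverted$name
    dir <- ifelse(reverted$trend_mc == "up", "up_then_down", "down_then_up")
  } else {
    stopifnot(inherits(reverted, "reverted_set"))
    ids <- reverted$feature_id
    dir <- reverted$direction
  }
  n <- length(ids)
  by_direction <- c(up_then_down = sum(dir == "up_then_down"),
                    down_then_up = sum(dir == "down_then_up"))
  out <- list(n = n, by_direction = by_direction)
  if (!is.null(categories)) {
    cat_of <- categories$category[match(ids, categories$name)]
    if (n == 0L) {
      out$by_category <- data.frame(category = character(), count = integer(),
                                    percent = numeric(), stringsAsFactors = FALSE)
    } else {
      tab <- sort(table(cat_of), decreasing = TRUE)
      out$by_category <- data.frame(category = names(tab),
                                    count = as.integer(tab),
                                    percent = round(100 * as.integer(tab) / n, 1),
                                    stringsAsFactors = FALSE)
    }
  }
  out
}

#' Serialize a reverted feature set as TSV
#'
#' @param reverted A \code{reverted_set}.
#' @param path Output path.
#' @export
write_reverted <- function(reverted, path) {
  stopifnot(inherits(reverted, "reverted_set"))
  df <- as.data.frame(reverted)
  colnames(df)[colnames(df) == "log2fc_mc"] <- "log2fc_model_vs_control"
  colnames(df)[colnames(df) == "log2fc_tm"] <- "log2fc_treated_vs_model"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
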