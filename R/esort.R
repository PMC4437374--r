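#' Electronic sorting: retrieve samples by rank-score range
#'
#' Electronic sorting retrieves the cell states (samples) of a cell group
#' whose rank score for a chosen probe set falls within a chosen score
#' range, together with their raw signals and annotations, and groups the
#' hits by experiment series.  It is the query analogue of flow sorting:
#' score bins play the role of fluorescence intensity gates, and the gate is
#' expressed in rank scores because those are comparable across arrays.
#'
#' @param compendium an [expression_compendium()].
#' @param ranks the matching `RankScoreMatrix`.
#' @param probe_set_id probe set whose score is gated on.
#' @param cell_group group to sort within.
#' @param score_lo,score_hi inclusive score range, `1 <= lo <= hi <= n_bins`.
#' @return an object of class `esort_result`: list with
#'   \describe{
#'     \item{hits}{data frame, one row per retrieved sample: the sample
#'       annotation plus `signal` and `rank_score`.}
#'     \item{series_view}{data frame, one row per series among the hits:
#'       `series_id`, `n_hits`, `n_group_samples_in_series`.}
#'     \item{query}{the query parameters.}
#'   }
#' @export
esort <- function(compendium, ranks, probe_set_id, cell_group,
                  score_lo, score_hi) {
  score_lo <- as.integer(score_lo); score_hi <- as.integer(score_hi)
  if (score_lo > score_hi)
    stop("inverted score range: lo > hi", call. = FALSE)
  if (score_lo < 1L || score_hi > ranks$n_bins)
    stop("score range outside [1, n_bins]", call. = FALSE)
  ids <- group_sample_ids(compendium$samples, cell_group)
  sc <- probe_scores(ranks, probe_set_id, ids)
  hit_ids <- ids[sc >= score_lo & sc <= score_hi]
  hits <- compendium$samples[match(hit_ids, compendium$samples$sample_id), ,
                             drop = FALSE]
  hits$signal <- compendium$signals[probe_set_id, hit_ids]
  hits$rank_score <- sc[hit_ids]
  rownames(hits) <- NULL
  group_series <- compendium$samples$series_id[match(ids, compendium$samples$sample_id)]
  sv <- if (nrow(hits)) {
    agg <- as.data.frame(table(hits$series_id), stringsAsFactors = FALSE)
    names(agg) <- c("series_id", "n_hits")
    agg$n_group_samples_in_series <-
      as.integer(table(group_series)[agg$series_id])
    agg
  } else {
    data.frame(series_id = character(), n_hits = integer(),
               n_group_samples_in_series = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(hits = hits, series_view = sv,
                 query = list(probe_set_id = probe_set_id,
                              cell_group = cell_group,
                              score_lo = score_lo, score_hi = score_hi)),
            class = "esort_result")
}

#' @export
print.esort_result <- function(x, ...) {
  q <- x$query
  cat("electronic sort: ", q$probe_set_id, " in ", q$cell_group,
      ", scores [", q$score_lo, ", ", q$score_hi, "]\n", sep = "")
  cat("  ", nrow(x$hits), " samples from ", nrow(x$series_view),
      " series\n", sep = "")
  invisible(x)
}

#' Tabulate an electronic-sorting result
#'
#' `"sample"` mode lists one row per retrieved sample (GSM-style view);
#' `"series"` mode lists one row per series with its hit count and the
#' series' total sample count within the sorted group (GSE-style view).
#'
#' @param result an [esort()] result.
#' @param mode `"sample"` or `"series"`.
#' @return a data frame (header-only when there are no hits).
#' @export
esort_report <- function(result, mode = c("sample", "series")) {
  stopifnot(inherits(result, "esort_result"))
  mode <- match.arg(mode)
  if (mode == "sample") {
    cols <- c("sample_id", "series_id", "title", "characteristics",
              "signal", "rank_score")
    result$hits[, cols, drop = FALSE]
  } else {
    result$series_view
  }
}
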