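#' Marker panels for sample quality control
#'
#' A marker panel lists, per cell group, the marker genes a sample of that
#' group is required to express.  Each marker names one or more probe sets
#' (alternative probes for the same gene) and the panel carries a rank-score
#' detection threshold, typically the calibrated undetectable-expression
#' cutoff (see [calibrate_detection()]).
#'
#' @param cell_group character vector, one entry per marker row.
#' @param marker_name marker gene name per row.
#' @param probe_set_ids list of character vectors (or pipe-separated
#'   strings), the probe sets measuring each marker.
#' @param detect_threshold integer rank score at or above which a marker
#'   counts as detected; recycled across rows.
#' @return data frame of class `marker_panel`.
#' @export
marker_panel <- function(cell_group, marker_name, probe_set_ids,
                         detect_threshold = 25L) {
  if (!is.list(probe_set_ids))
    probe_set_ids <- strsplit(as.character(probe_set_ids), "|", fixed = TRUE)
  if (any(lengths(probe_set_ids) == 0L))
    stop("every marker must name at least one probe set", call. = FALSE)
  df <- data.frame(cell_group = as.character(cell_group),
                   marker_name = as.character(marker_name),
                   detect_threshold = as.integer(detect_threshold),
                   stringsAsFactors = FALSE)
  df$probe_set_ids <- probe_set_ids
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' @rdname marker_panel
#' @param path TSV path with columns `cell_group`, `marker_name`,
#'   `probe_set_ids` (pipe-separated), `threshold`.
#' @export
read_marker_panel <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  marker_panel(df$cell_group, df$marker_name, df$probe_set_ids,
               as.integer(df$threshold))
}

#' @rdname marker_panel
#' @param panel a `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  df <- data.frame(cell_group = panel$cell_group,
                   marker_name = panel$marker_name,
                   probe_set_ids = vapply(panel$probe_set_ids, paste, "",
                                          collapse = "|"),
                   threshold = panel$detect_threshold,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Marker-based sample admission
#'
#' A sample whose cell group is covered by the panel is kept if and only if,
#' for *every* marker of its group, *at least one* of that marker's probe
#' sets has a rank score at or above the marker's detection threshold.
#' Rejected samples are reported with the first marker (panel row order)
#' that failed.  Samples of groups not covered by the panel are not judged
#' and appear in neither list.
#'
#' @param compendium an [expression_compendium()].
#' @param ranks the matching `RankScoreMatrix`.
#' @param panel a [marker_panel()].
#' @return list with `kept` (character vector of sample IDs) and `rejected`
#'   (data frame `sample_id`, `cell_group`, `failed_marker`).
#' @export
qc_filter <- function(compendium, ranks, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  unknown <- setdiff(unlist(panel$probe_set_ids), rownames(ranks$scores))
  if (length(unknown))
    stop("panel references unknown probe sets: ", toString(unknown),
         call. = FALSE)
  samples <- compendium$samples
  covered <- samples$cell_group %in% panel$cell_group
  kept <- character()
  rej <- list()
  for (i in which(covered)) {
    sid <- samples$sample_id[i]
    rows <- which(panel$cell_group == samples$cell_group[i])
    failed <- NA_character_
    for (r in rows) {
      sc <- ranks$scores[panel$probe_set_ids[[r]], sid]
      if (!any(sc >= panel$detect_threshold[r])) {
        failed <- panel$marker_name[r]
        break
      }
    }
    if (is.na(failed)) {
      kept <- c(kept, sid)
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        sample_id = sid, cell_group = samples$cell_group[i],
        failed_marker = failed, stringsAsFactors = FALSE)
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej)
              else data.frame(sample_id = character(),
                              cell_group = character(),
                              failed_marker = character(),
                              stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}
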