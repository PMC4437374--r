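#' Rank-based expression (RBE) curve
#'
#' For one probe set and one cell group, the distribution of rank scores over
#' the group's samples: `ordinate[s]` is the fraction of group samples whose
#' rank score for the probe set equals `s`.  Ordinates are non-negative and
#' sum to 1, so the area covered by the curve is always 1 regardless of group
#' size — this is what makes curves from groups of different sizes
#' comparable.
#'
#' @param ranks a `RankScoreMatrix` (see [rank_scores()]).
#' @param samples sample annotation data frame (`sample_id`, `cell_group`,
#'   ...), typically `compendium$samples`.
#' @param probe_set_id probe set to profile.
#' @param cell_group cell group whose samples form the distribution.
#' @return an object of class `rbe_curve`: list with `probe_set_id`,
#'   `cell_group`, `ordinates` (length `n_bins`) and `n_samples`.
#' @examples
#' sc <- matrix(c(99L, 99L, 1L, 50L), 1, 4,
#'              dimnames = list("P1", paste0("S", 1:4)))
#' rk <- rank_score_matrix(sc, 100)
#' sm <- data.frame(sample_id = paste0("S", 1:4), series_id = "E1",
#'                  cell_group = "B cell", title = "", characteristics = "")
#' rbe_curve(rk, sm, "P1", "B cell")$ordinates[99]  # 0.5
#' @export
rbe_curve <- function(ranks, samples, probe_set_id, cell_group) {
  ids <- group_sample_ids(samples, cell_group)
  sc <- probe_scores(ranks, probe_set_id, ids)
  n <- length(sc)
  ord <- tabulate(sc, nbins = ranks$n_bins) / n
  structure(list(probe_set_id = probe_set_id, cell_group = cell_group,
                 ordinates = ord, n_samples = n, n_bins = ranks$n_bins),
            class = "rbe_curve")
}

#' @export
print.rbe_curve <- function(x, ...) {
  cat("RBE curve: ", x$probe_set_id, " in ", x$cell_group,
      " (", x$n_samples, " samples)\n", sep = "")
  occ <- which(x$ordinates > 0)
  cat("  occupied scores ", min(occ), "..", max(occ),
      ", mode at ", which.max(x$ordinates), "\n", sep = "")
  invisible(x)
}

#' Plot RBE curves
#'
#' Draws the sample-ratio distribution over rank scores as a step/line curve.
#' Additional curves can be overlaid with `add = TRUE` to compare a gene
#' across cell groups or genes within a group.
#'
#' @param x an `rbe_curve`.
#' @param add overlay on an existing plot.
#' @param col line colour.
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rbe_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  s <- seq_len(x$n_bins)
  if (!add) {
    graphics::plot(s, x$ordinates, type = "h", col = col,
                   xlab = "rank score", ylab = "sample ratio",
                   main = paste0(x$probe_set_id, " in ", x$cell_group), ...)
  } else {
    graphics::lines(s, x$ordinates, type = "h", col = col)
  }
  invisible(x)
}

#' Per-group profile statistics: quartiles, plasticity (GPL) and ARS
#'
#' For every probe set, summarises its rank scores across the samples of one
#' cell group: the first and third quartiles, the gene plasticity score
#' `GPL = Q3 - Q1` (interquartile range; high when expression varies widely
#' under diverse conditions, 0 when it is stable), and the average rank
#' score `ARS` (the arithmetic mean; very small or large ARS indicates
#' stably low or high expression).
#'
#' Quartiles use linear interpolation between order statistics with the
#' p-th quantile located at position `1 + (n - 1) * p` in the sorted scores
#' ([stats::quantile()] type 7).
#'
#' @inheritParams rbe_curve
#' @param cell_group the group to summarise, or `NULL` to pool all samples
#'   (the compendium-wide profile).
#' @return data frame with one row per probe set: `probe_set_id`,
#'   `cell_group`, `n_samples`, `q1`, `q3`, `gpl`, `ars`.
#' @export
profile_stats <- function(ranks, samples, cell_group = NULL) {
  ids <- if (is.null(cell_group)) samples$sample_id
         else group_sample_ids(samples, cell_group)
  if (length(ids) == 0L) stop("empty cell group", call. = FALSE)
  m <- ranks$scores[, ids, drop = FALSE]
  qs <- apply(m, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE,
              type = 7)
  data.frame(probe_set_id = rownames(m),
             cell_group = if (is.null(cell_group)) NA_character_ else cell_group,
             n_samples = length(ids),
             q1 = qs[1L, ], q3 = qs[2L, ],
             gpl = qs[2L, ] - qs[1L, ],
             ars = rowMeans(m),
             row.names = NULL, stringsAsFactors = FALSE)
}
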