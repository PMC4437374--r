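#' Background score vector for a probe set
#'
#' The background against which each cell group is tested is the probe set's
#' rank scores across *all* samples of *all* cell groups; a group under test
#' is therefore included in its own background.
#'
#' @param ranks a `RankScoreMatrix`.
#' @param probe_set_id probe set.
#' @return integer vector of scores, one per sample (named by sample ID).
#' @export
background_scores <- function(ranks, probe_set_id) {
  probe_scores(ranks, probe_set_id)
}

#' Signed marker evaluation score from two score vectors
#'
#' The marker evaluation score (MES) quantifies how specific a probe set's
#' expression is to a cell group: a two-sided Wilcoxon rank-sum test compares
#' the group's rank scores against the background scores, and
#' `MES = |log10 p|`, recorded as positive when the group median is greater
#' than or equal to the background median and negative otherwise.  The score
#' is `NA` when the p-value underflows to exactly zero or when the background
#' scores are all identical (the test is then undefined).
#'
#' For small problems (pooled size at most `exact_limit`) the p-value is the
#' exact conditional permutation p of the rank-sum statistic, which handles
#' ties correctly; larger problems use the normal approximation with tie and
#' continuity correction ([stats::wilcox.test()]).
#'
#' @param group numeric vector of the group's scores.
#' @param background numeric vector of the background scores.
#' @param exact_limit largest pooled sample size for which the exact
#'   permutation null is enumerated (default 20).
#' @return list with `p_value`, `mes`, `group_median`, `background_median`,
#'   `n_group`, `n_background`.
#' @export
mes_score <- function(group, background, exact_limit = 20L) {
  if (length(group) == 0L) stop("empty group", call. = FALSE)
  gm <- stats::median(group)
  bm <- stats::median(background)
  out <- list(p_value = NA_real_, mes = NA_real_,
              group_median = gm, background_median = bm,
              n_group = length(group), n_background = length(background))
  if (length(unique(background)) < 2L) return(out)
  N <- length(group) + length(background)
  p <- if (N <= exact_limit) {
    exact_ranksum_p(group, background)
  } else {
    stats::wilcox.test(group, background, exact = FALSE,
                       correct = TRUE)$p.value
  }
  out$p_value <- p
  if (p > 0) out$mes <- abs(log10(p)) * if (gm >= bm) 1 else -1
  out
}

# Exact two-sided conditional permutation p-value of the rank-sum statistic:
# enumerate every assignment of the pooled midranks to a group of size m and
# count assignments whose rank-sum deviates from the null mean at least as
# much as the observed one.  Valid with ties (midranks keep the null
# distribution symmetric about m(N+1)/2).
exact_ranksum_p <- function(group, background) {
  pooled <- c(group, background)
  r <- rank(pooled)
  m <- length(group)
  N <- length(pooled)
  w_obs <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  sums <- utils::combn(N, m, FUN = function(i) sum(r[i]))
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Marker evaluation score for one probe set in one cell group
#'
#' Compares the probe set's rank scores within `cell_group` against its
#' scores across all samples (see [background_scores()]) and returns the
#' signed MES record.
#'
#' @inheritParams rbe_curve
#' @return one-row data frame: `probe_set_id`, `cell_group`, `n_group`,
#'   `n_background`, `group_median`, `background_median`, `p_value`, `mes`.
#' @export
mes <- function(ranks, samples, probe_set_id, cell_group) {
  ids <- group_sample_ids(samples, cell_group)
  g <- probe_scores(ranks, probe_set_id, ids)
  b <- background_scores(ranks, probe_set_id)
  s <- mes_score(g, b)
  data.frame(probe_set_id = probe_set_id, cell_group = cell_group,
             n_group = s$n_group, n_background = s$n_background,
             group_median = s$group_median,
             background_median = s$background_median,
             p_value = s$p_value, mes = s$mes,
             stringsAsFactors = FALSE)
}

#' Marker evaluation scores for all (probe set, cell group) pairs
#'
#' Batch version of [mes()]: one record per probe set per cell group,
#' identical to calling [mes()] pairwise.
#'
#' @inheritParams rbe_curve
#' @param probe_set_ids probes to evaluate (default: all).
#' @param cell_groups groups to evaluate (default: all groups present).
#' @return data frame with one [mes()] row per (probe, group) pair.
#' @export
mes_table <- function(ranks, samples, probe_set_ids = NULL,
                      cell_groups = NULL) {
  if (is.null(probe_set_ids)) probe_set_ids <- rownames(ranks$scores)
  if (is.null(cell_groups)) cell_groups <- unique(samples$cell_group)
  group_ids <- lapply(cell_groups, group_sample_ids, samples = samples)
  rows <- vector("list", length(probe_set_ids) * length(cell_groups))
  k <- 0L
  for (p in probe_set_ids) {
    b <- background_scores(ranks, p)
    for (gi in seq_along(cell_groups)) {
      s <- mes_score(b[group_ids[[gi]]], b)
      k <- k + 1L
      rows[[k]] <- data.frame(
        probe_set_id = p, cell_group = cell_groups[gi],
        n_group = s$n_group, n_background = s$n_background,
        group_median = s$group_median,
        background_median = s$background_median,
        p_value = s$p_value, mes = s$mes, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
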