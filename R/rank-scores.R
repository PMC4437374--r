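#' Per-array percentile rank scores
#'
#' Converts signal intensities into integer rank scores.  Within one array
#' all probe sets are ranked in ascending order of signal and the rank order
#' is sliced into `n_bins` approximately equal blocks; every probe set in the
#' same block receives the same score, `1` for the lowest block and `n_bins`
#' for the highest.  With `n = q * n_bins + r` probes, the `r` oversized
#' blocks (size `q + 1`) are the first `r` score groups, i.e. the lowest
#' signals; block sizes therefore never differ by more than one.
#'
#' Ties between equal signals are broken by a stable ascending sort with the
#' probe-set ID (C-locale lexicographic) as secondary key, so results are
#' fully deterministic.
#'
#' @param x a numeric vector of non-negative signals for one array, or an
#'   [expression_compendium()] (scored column by column).
#' @param n_bins number of score groups; default 100.
#' @param ... passed between methods.
#' @return for a numeric vector, an integer vector of scores in
#'   `[1, n_bins]` (named like `x`); for a compendium, a `RankScoreMatrix`:
#'   a list with the integer `scores` matrix, `n_bins` and `n_probes`.
#' @examples
#' rank_scores(c(a = 5, b = 1, c = 3, d = 2, e = 4,
#'               f = 6, g = 8, h = 7, i = 9, j = 10), n_bins = 5)
#' @export
rank_scores <- function(x, n_bins = 100, ...) UseMethod("rank_scores")

#' @rdname rank_scores
#' @param ids optional character vector of probe-set IDs used as the tie-break
#'   key; defaults to `names(x)` and falls back to element order.
#' @export
rank_scores.numeric <- function(x, n_bins = 100, ids = names(x), ...) {
  n <- length(x)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  if (n < n_bins)
    stop("fewer probes (", n, ") than bins (", n_bins, ")", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("signals must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (any(x < 0)) stop("signals must be non-negative", call. = FALSE)
  ord <- if (is.null(ids)) order(x, method = "radix")
         else order(x, ids, method = "radix")
  q <- n %/% n_bins
  r <- n %% n_bins
  sizes <- rep.int(q, n_bins)
  if (r > 0L) sizes[seq_len(r)] <- q + 1L
  out <- integer(n)
  out[ord] <- rep.int(seq_len(n_bins), sizes)
  names(out) <- names(x)
  out
}

#' @rdname rank_scores
#' @export
rank_scores.ExpressionCompendium <- function(x, n_bins = 100, ...) {
  sig <- x$signals
  ids <- rownames(sig)
  scores <- matrix(NA_integer_, nrow(sig), ncol(sig), dimnames = dimnames(sig))
  for (j in seq_len(ncol(sig))) {
    scores[, j] <- tryCatch(
      rank_scores.numeric(sig[, j], n_bins = n_bins, ids = ids),
      error = function(e) stop("sample ", colnames(sig)[j], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  rank_score_matrix(scores, n_bins)
}

#' Construct a RankScoreMatrix
#'
#' Low-level constructor wrapping an already-computed integer score matrix.
#' Checks that every entry lies in `[1, n_bins]`.
#'
#' @param scores integer matrix, probes in rows, samples in columns, with
#'   dimnames.
#' @param n_bins number of score groups the scores were computed with.
#' @return a `RankScoreMatrix`.
#' @export
rank_score_matrix <- function(scores, n_bins = 100) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  n_bins <- as.integer(n_bins)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix must have probe and sample dimnames", call. = FALSE)
  if (anyNA(scores) || any(scores < 1L) || any(scores > n_bins))
    stop("scores must be integers in [1, n_bins]", call. = FALSE)
  structure(list(scores = scores, n_bins = n_bins, n_probes = nrow(scores)),
            class = "RankScoreMatrix")
}

#' @export
print.RankScoreMatrix <- function(x, ...) {
  cat("RankScoreMatrix:", nrow(x$scores), "probe sets x", ncol(x$scores),
      "samples, scores 1..", x$n_bins, "\n", sep = " ")
  invisible(x)
}

#' Read / write rank-score matrices as TSV
#'
#' The on-disk shape mirrors the signal matrix: first column `probe_set_id`,
#' one integer column per sample.
#'
#' @param path file path.
#' @param n_bins score range recorded in the returned object.
#' @return [read_rank_scores()] returns a `RankScoreMatrix`;
#'   [write_rank_scores()] returns its input invisibly.
#' @export
read_rank_scores <- function(path, n_bins = 100) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(probe_set_id = "character"))
  rn <- df$probe_set_id
  df$probe_set_id <- NULL
  m <- as.matrix(df)
  rownames(m) <- rn
  rank_score_matrix(m, n_bins)
}

#' @rdname read_rank_scores
#' @param ranks a `RankScoreMatrix`.
#' @export
write_rank_scores <- function(ranks, path) {
  stopifnot(inherits(ranks, "RankScoreMatrix"))
  df <- data.frame(probe_set_id = rownames(ranks$scores), ranks$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ranks)
}

group_sample_ids <- function(samples, cell_group) {
  if (!cell_group %in% samples$cell_group)
    stop("unknown cell group: ", cell_group, call. = FALSE)
  samples$sample_id[samples$cell_group == cell_group]
}

probe_scores <- function(ranks, probe_set_id, sample_ids = NULL) {
  if (!probe_set_id %in% rownames(ranks$scores))
    stop("unknown probe set: ", probe_set_id, call. = FALSE)
  row <- ranks$scores[probe_set_id, , drop = FALSE]
  s <- stats::setNames(as.vector(row), colnames(row))
  if (!is.null(sample_ids)) s <- s[sample_ids]
  s
}
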