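#' Detection-call tables
#'
#' A detection-call table mirrors the rank-score matrix: one P (present),
#' M (marginal) or A (absent) call per probe set per sample, as produced by
#' Affymetrix-style detection algorithms.  The on-disk format is the same
#' TSV shape as the signal matrix with single-character entries.
#'
#' @param calls character matrix with values in `{"P","M","A"}` and the same
#'   dimnames as the paired rank-score matrix.
#' @return an object of class `DetectionCallTable`.
#' @export
detection_call_table <- function(calls) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c("P", "M", "A")))
    stop("calls must be P, M or A", call. = FALSE)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("call matrix must have probe and sample dimnames", call. = FALSE)
  structure(list(calls = calls), class = "DetectionCallTable")
}

#' @rdname detection_call_table
#' @param path TSV path (first column `probe_set_id`).
#' @export
read_detection_calls <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  rn <- df$probe_set_id
  df$probe_set_id <- NULL
  m <- as.matrix(df)
  rownames(m) <- rn
  detection_call_table(m)
}

#' @rdname detection_call_table
#' @param x a `DetectionCallTable`.
#' @export
write_detection_calls <- function(x, path) {
  stopifnot(inherits(x, "DetectionCallTable"))
  df <- data.frame(probe_set_id = rownames(x$calls), x$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Fraction of absent calls at each rank score
#'
#' Pools all (probe set, sample) cells of the compendium and computes, for
#' each rank score `s`, the fraction of cells with score `s` whose detection
#' call is absent (A).  Marginal calls count as not absent.  Scores with no
#' cells yield `NA`.
#'
#' @param calls a [detection_call_table()].
#' @param ranks the paired `RankScoreMatrix` (identical dimnames required).
#' @return numeric vector of length `n_bins`; element `s` is the absent
#'   fraction at score `s`, `NA` where no cells have that score.
#' @export
absent_fraction_by_score <- function(calls, ranks) {
  stopifnot(inherits(calls, "DetectionCallTable"),
            inherits(ranks, "RankScoreMatrix"))
  if (!identical(dimnames(calls$calls), dimnames(ranks$scores)))
    stop("call table and rank-score matrix indices do not match",
         call. = FALSE)
  sc <- as.vector(ranks$scores)
  absent <- as.vector(calls$calls) == "A"
  n_at <- tabulate(sc, nbins = ranks$n_bins)
  a_at <- tabulate(sc[absent], nbins = ranks$n_bins)
  out <- ifelse(n_at > 0L, a_at / n_at, NA_real_)
  names(out) <- seq_len(ranks$n_bins)
  out
}

#' Calibrate the undetectable-expression rank-score threshold
#'
#' Given per-score absent fractions, returns the largest threshold `t` such
#' that every score below `t` has an absent fraction at least
#' `target_fraction` (a score with no data breaks the run).  Scores below
#' the threshold can then be read as "no or undetectable expression".
#' When no score qualifies the threshold is 1 (no undetectable zone); when
#' every score qualifies the threshold saturates at `n_bins` and carries a
#' `saturated` attribute.
#'
#' @param absent_fraction numeric vector as returned by
#'   [absent_fraction_by_score()].
#' @param target_fraction required absent fraction, default 0.99.
#' @return integer threshold with attribute `saturated` (logical).
#' @export
calibrate_threshold <- function(absent_fraction, target_fraction = 0.99) {
  ok <- !is.na(absent_fraction) & absent_fraction >= target_fraction
  n_bins <- length(ok)
  run <- 0L
  while (run < n_bins && ok[run + 1L]) run <- run + 1L
  saturated <- run == n_bins
  t <- if (saturated) n_bins else run + 1L
  structure(as.integer(t), saturated = saturated)
}

#' One-step detection calibration
#'
#' Convenience wrapper combining [absent_fraction_by_score()] and
#' [calibrate_threshold()].
#'
#' @inheritParams absent_fraction_by_score
#' @inheritParams calibrate_threshold
#' @return an object of class `detection_calibration`: list with
#'   `absent_fraction`, `threshold`, `target_fraction`, `saturated`.
#' @export
calibrate_detection <- function(calls, ranks, target_fraction = 0.99) {
  af <- absent_fraction_by_score(calls, ranks)
  t <- calibrate_threshold(af, target_fraction)
  structure(list(absent_fraction = af, threshold = as.integer(t),
                 target_fraction = target_fraction,
                 saturated = attr(t, "saturated")),
            class = "detection_calibration")
}

#' @export
print.detection_calibration <- function(x, ...) {
  cat("detection calibration: >=", x$target_fraction * 100,
      "% absent below rank score ", x$threshold,
      if (x$saturated) " (saturated)" else "", "\n", sep = "")
  invisible(x)
}
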