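#' Annotated expression compendium
#'
#' An `ExpressionCompendium` bundles a non-negative signal matrix (probe sets
#' in rows, samples in columns) with a sample annotation table and a probe-set
#' annotation table.  It is the unit every other operation in the package
#' works on.
#'
#' Probe sets present in the matrix but absent from the probe annotation are
#' retained — they occupy rank positions on the physical array and therefore
#' participate in rank scoring — but they are flagged unannotated and excluded
#' from gene-level query results (see [resolve_gene()]).
#'
#' @param signals numeric matrix of finite, non-negative intensities with
#'   probe-set IDs as rownames and sample IDs as colnames.
#' @param samples data frame with columns `sample_id`, `series_id`,
#'   `cell_group`, `title`, `characteristics`; one row per signal column.
#' @param probes data frame with columns `probe_set_id`, `gene_symbol`,
#'   `gene_id` (integer), `aliases` (list of character vectors, or a
#'   pipe-separated character column); at most one row per probe set.
#'
#' @return an object of class `ExpressionCompendium`: a list with elements
#'   `signals`, `samples`, `probes` and `annotated` (logical vector over
#'   matrix rows).
#' @seealso [read_compendium()], [write_compendium()], [resolve_gene()],
#'   [rank_scores()]
#' @export
expression_compendium <- function(signals, samples, probes) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  if (!is.list(probes$aliases))
    probes$aliases <- strsplit(ifelse(is.na(probes$aliases), "",
                                      as.character(probes$aliases)),
                               "|", fixed = TRUE)
  probes$gene_id <- as.integer(probes$gene_id)
  samples$cell_group <- as.character(samples$cell_group)
  obj <- structure(
    list(signals = signals, samples = samples, probes = probes,
         annotated = rownames(signals) %in% probes$probe_set_id),
    class = "ExpressionCompendium")
  validate_compendium(obj)
  obj
}

#' Validate an expression compendium
#'
#' Checks the structural invariants: unique probe and sample IDs, exact
#' correspondence between matrix columns and the sample table, finite
#' non-negative signals, and at most one annotation row per probe set.
#'
#' @param x an `ExpressionCompendium`.
#' @return `x`, invisibly; signals an error describing every violation found.
#' @export
validate_compendium <- function(x) {
  stopifnot(inherits(x, "ExpressionCompendium"))
  errs <- character()
  sig <- x$signals
  if (is.null(rownames(sig)) || is.null(colnames(sig)))
    errs <- c(errs, "signal matrix must have probe-set rownames and sample colnames")
  dup <- unique(rownames(sig)[duplicated(rownames(sig))])
  if (length(dup))
    errs <- c(errs, paste0("duplicate probe_set_id: ", toString(dup)))
  dup <- unique(colnames(sig)[duplicated(colnames(sig))])
  if (length(dup))
    errs <- c(errs, paste0("duplicate sample_id in matrix: ", toString(dup)))
  dup <- unique(x$samples$sample_id[duplicated(x$samples$sample_id)])
  if (length(dup))
    errs <- c(errs, paste0("duplicate sample_id in annotation: ", toString(dup)))
  dup <- unique(x$probes$probe_set_id[duplicated(x$probes$probe_set_id)])
  if (length(dup))
    errs <- c(errs, paste0("duplicate probe_set_id in annotation: ", toString(dup)))
  miss <- setdiff(colnames(sig), x$samples$sample_id)
  if (length(miss))
    errs <- c(errs, paste0("samples in matrix missing from annotation: ",
                           toString(miss)))
  extra <- setdiff(x$samples$sample_id, colnames(sig))
  if (length(extra))
    errs <- c(errs, paste0("annotated samples missing from matrix: ",
                           toString(extra)))
  if (any(!nzchar(x$samples$series_id) | is.na(x$samples$series_id)))
    errs <- c(errs, "series_id must be non-empty for every sample")
  bad <- which(!is.finite(sig) | sig < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    bad <- bad[seq_len(min(5L, nrow(bad))), , drop = FALSE]
    errs <- c(errs, paste0(
      "non-finite or negative signal at ",
      toString(paste0("(", rownames(sig)[bad[, 1]], ", ",
                      colnames(sig)[bad[, 2]], ")"))))
  }
  if (length(errs))
    stop("invalid compendium:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(x)
}

#' @export
print.ExpressionCompendium <- function(x, ...) {
  cat("ExpressionCompendium:", nrow(x$signals), "probe sets x",
      ncol(x$signals), "samples\n")
  cat("  annotated probe sets:", sum(x$annotated), "\n")
  grp <- table(x$samples$cell_group)
  cat("  cell groups (", length(grp), "): ",
      paste0(names(grp), " [", grp, "]", collapse = ", "), "\n", sep = "")
  cat("  series:", length(unique(x$samples$series_id)), "\n")
  invisible(x)
}

#' Read an expression compendium from tab-separated files
#'
#' The interchange format is plain TSV: `signals` has a `probe_set_id` first
#' column and one column per sample; `samples` has columns `sample_id`,
#' `series_id`, `cell_group`, `title`, `characteristics`; `probes` has columns
#' `probe_set_id`, `gene_symbol`, `gene_id`, `aliases` (pipe-separated).
#'
#' @param signals_path,samples_path,probes_path paths to the three TSV files.
#' @return an [expression_compendium()].
#' @export
read_compendium <- function(signals_path, samples_path, probes_path) {
  sig <- utils::read.delim(signals_path, check.names = FALSE,
                           colClasses = c(probe_set_id = "character"))
  rn <- sig$probe_set_id
  sig$probe_set_id <- NULL
  m <- as.matrix(sig)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    coords <- if (nrow(bad)) paste0(" at (", rn[bad[1, 1]], ", ",
                                    colnames(m)[bad[1, 2]], ")") else ""
    stop("non-numeric signal value", coords, call. = FALSE)
  }
  rownames(m) <- rn
  samples <- utils::read.delim(samples_path, colClasses = "character")
  probes <- utils::read.delim(probes_path, colClasses = "character")
  expression_compendium(m, samples, probes)
}

#' Write an expression compendium to tab-separated files
#'
#' Inverse of [read_compendium()]: signal values are written with full
#' precision (17 significant digits) so a write/read round trip reproduces
#' the matrix exactly.
#'
#' @param x an `ExpressionCompendium`.
#' @param signals_path,samples_path,probes_path output file paths.
#' @return `x`, invisibly.
#' @export
write_compendium <- function(x, signals_path, samples_path, probes_path) {
  stopifnot(inherits(x, "ExpressionCompendium"))
  sig <- x$signals
  df <- data.frame(probe_set_id = rownames(sig),
                   format(sig, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, signals_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pr <- x$probes
  pr$aliases <- vapply(pr$aliases, paste, "", collapse = "|")
  utils::write.table(pr, probes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Resolve a gene query to probe set IDs
#'
#' A query may be a gene symbol, a gene alias, a numeric gene ID, or a
#' probe-set ID.  Symbol and alias matching is case-insensitive; gene-ID
#' matching is exact; a probe-set-ID query returns exactly that probe set.
#' Unannotated probe sets never match symbol/alias/gene-ID queries.
#'
#' @param query character scalar or integer gene ID.
#' @param compendium an `ExpressionCompendium`.
#' @return character vector of matching probe-set IDs (possibly empty).
#' @examples
#' pr <- data.frame(probe_set_id = "205476_at", gene_symbol = "CCL20",
#'                  gene_id = 6364L, aliases = "MIP-3-alpha|LARC")
#' sm <- data.frame(sample_id = "S1", series_id = "E1", cell_group = "PMN",
#'                  title = "", characteristics = "")
#' cp <- expression_compendium(matrix(1, 1, 1,
#'         dimnames = list("205476_at", "S1")), sm, pr)
#' resolve_gene("mip-3-alpha", cp)
#' @export
resolve_gene <- function(query, compendium) {
  stopifnot(inherits(compendium, "ExpressionCompendium"), length(query) == 1L)
  pr <- compendium$probes
  if (is.character(query) && query %in% rownames(compendium$signals))
    return(query)
  hits <- rep(FALSE, nrow(pr))
  if (is.numeric(query) || grepl("^[0-9]+$", as.character(query))) {
    hits <- hits | (!is.na(pr$gene_id) & pr$gene_id == as.integer(query))
  }
  if (is.character(query)) {
    q <- tolower(query)
    hits <- hits | tolower(pr$gene_symbol) == q |
      vapply(pr$aliases, function(a) q %in% tolower(a), logical(1))
  }
  pr$probe_set_id[hits & pr$probe_set_id %in% rownames(compendium$signals)]
}
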