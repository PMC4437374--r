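#' Specification for a synthetic expression compendium
#'
#' Describes a compendium to be generated by [generate_compendium()]:
#' dimensions, cell groups, planted expression patterns, quality-control
#' violations and the detection-call geometry.  The defaults describe a
#' small but fully structured compendium — 2,000 probe sets, five immune
#' cell groups of 60 samples each, 100 score bins — with one planted
#' high-expression marker and one QC marker per group, two planted
#' low-in-group markers, three plastic (bimodal) genes, one disease-shift
#' pair, 12% of samples violating their QC panel, and absent calls
#' concentrated below rank score 25.
#'
#' @param n_probes number of probe sets (must be at least `n_bins`).
#' @param groups character vector of cell-group labels.
#' @param n_samples_per_group samples per group (scalar or named vector).
#' @param n_series_per_group experiment series per group.
#' @param n_bins number of rank-score groups.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param planted_genes list of [planted_gene()] patterns, or `NULL` for
#'   the default set described above.
#' @param qc_violation_fraction fraction of samples whose QC marker is
#'   planted below the detection threshold.
#' @param absent_model list `cutoff_score`, `absent_prob_below`,
#'   `absent_prob_above`: detection calls are absent with the first
#'   probability at rank scores below the cutoff and with the second at or
#'   above it.
#' @param detect_threshold rank score used by the generated marker panel.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_probes = 2000L,
                           groups = c("B cell", "CD4 T cell", "CD8 T cell",
                                      "Monocyte", "PMN/neutrophil"),
                           n_samples_per_group = 60L,
                           n_series_per_group = 6L,
                           n_bins = 100L,
                           seed = 20260401L,
                           planted_genes = NULL,
                           qc_violation_fraction = 0.12,
                           absent_model = list(cutoff_score = 25L,
                                               absent_prob_below = 0.995,
                                               absent_prob_above = 0.02),
                           detect_threshold = 25L) {
  if (length(n_samples_per_group) == 1L)
    n_samples_per_group <- stats::setNames(rep(as.integer(n_samples_per_group),
                                               length(groups)), groups)
  if (is.null(planted_genes)) planted_genes <- default_plants(groups)
  spec <- structure(
    list(n_probes = as.integer(n_probes), groups = groups,
         n_samples_per_group = n_samples_per_group,
         n_series_per_group = as.integer(n_series_per_group),
         n_bins = as.integer(n_bins), seed = as.integer(seed),
         planted_genes = planted_genes,
         qc_violation_fraction = qc_violation_fraction,
         absent_model = absent_model,
         detect_threshold = as.integer(detect_threshold)),
    class = "synthetic_spec")
  if (spec$n_probes < spec$n_bins)
    stop("n_probes must be >= n_bins", call. = FALSE)
  bad <- setdiff(unlist(lapply(planted_genes,
                               function(p) c(p$group, p$group2))), groups)
  bad <- bad[!is.na(bad)]
  if (length(bad))
    stop("planted genes reference unknown groups: ", toString(bad),
         call. = FALSE)
  spec
}

#' A planted expression pattern
#'
#' Declares the rank-score geometry a synthetic gene should realise:
#' * `marker_high` — scores in `band` (default 90–100) in `group`, in
#'   `off_band` (default 10–40) elsewhere: a stable, specific marker.
#' * `marker_low` — scores 1–10 in `group`, 45–80 elsewhere: specifically
#'   silenced in the group.
#' * `plastic_bimodal` — within `group`, a fraction `high_fraction` of
#'   samples in the high band (85–100) and the rest low (5–20), giving a
#'   two-peaked RBE curve and a large plasticity score; 40–60 elsewhere.
#' * `disease_shift` — high (85–100) in `group`, low (1–15) in `group2`,
#'   40–60 elsewhere: a disease-associated expression shift between two
#'   states of the same lineage.
#'
#' @param pattern one of `"marker_high"`, `"marker_low"`,
#'   `"plastic_bimodal"`, `"disease_shift"`.
#' @param group target cell group.
#' @param band integer length-2 in-group score band; pattern-specific
#'   default.
#' @param off_band score band outside the target group(s).
#' @param high_fraction for `plastic_bimodal`, fraction of group samples in
#'   the high band.
#' @param group2 for `disease_shift`, the group planted low.
#' @return a `planted_gene` list.
#' @export
planted_gene <- function(pattern = c("marker_high", "marker_low",
                                     "plastic_bimodal", "disease_shift"),
                         group, band = NULL, off_band = NULL,
                         high_fraction = 0.4, group2 = NULL) {
  pattern <- match.arg(pattern)
  defaults <- switch(pattern,
    marker_high     = list(band = c(90L, 100L), off = c(10L, 40L)),
    marker_low      = list(band = c(1L, 10L),   off = c(45L, 80L)),
    plastic_bimodal = list(band = c(85L, 100L), off = c(40L, 60L)),
    disease_shift   = list(band = c(85L, 100L), off = c(40L, 60L)))
  structure(list(pattern = pattern, group = group,
                 band = if (is.null(band)) defaults$band else as.integer(band),
                 off_band = if (is.null(off_band)) defaults$off
                            else as.integer(off_band),
                 low_band = c(5L, 20L),   # plastic_bimodal low mode
                 shift_low = c(1L, 15L),  # disease_shift band in group2
                 high_fraction = high_fraction,
                 group2 = if (is.null(group2)) NA_character_ else group2),
            class = "planted_gene")
}

default_plants <- function(groups) {
  plants <- lapply(groups, function(g) planted_gene("marker_high", g))
  plants <- c(plants,
              lapply(groups[seq_len(min(2L, length(groups)))],
                     function(g) planted_gene("marker_low", g)))
  pl_groups <- groups[unique(pmin(c(1L, 3L, 5L), length(groups)))]
  plants <- c(plants, lapply(pl_groups, function(g)
    planted_gene("plastic_bimodal", g, high_fraction = 0.4)))
  if (length(groups) >= 4L)
    plants <- c(plants, list(planted_gene("disease_shift", groups[2L],
                                          group2 = groups[4L])))
  plants
}

# block geometry: with n = q*n_bins + r probes, the first r blocks (lowest
# scores) have size q+1, the rest q
block_sizes <- function(n, n_bins) {
  q <- n %/% n_bins
  sizes <- rep.int(q, n_bins)
  r <- n %% n_bins
  if (r > 0L) sizes[seq_len(r)] <- q + 1L
  sizes
}

# values that, ranked together with bg_sorted, land at the given 1-based
# positions of the combined ascending order (positions need not be sorted)
plant_values <- function(bg_sorted, positions) {
  o <- order(positions)
  k <- positions[o]
  n_bg <- length(bg_sorted)
  g <- k - seq_along(k)              # background values below each plant
  if (any(g < 0L) || any(g > n_bg)) stop("plant positions out of range")
  lower <- c(0, bg_sorted)[g + 1L]
  upper <- c(bg_sorted, bg_sorted[n_bg] + 1)[g + 1L]
  vals <- numeric(length(k))
  for (gg in unique(g)) {
    idx <- which(g == gg)
    vals[idx] <- lower[idx[1L]] +
      (upper[idx[1L]] - lower[idx[1L]]) * seq_along(idx) / (length(idx) + 1L)
  }
  out <- numeric(length(positions))
  out[o] <- vals
  out
}

#' Signal value that realises a chosen rank score
#'
#' Given the other signals on an array, returns a signal value that will
#' receive exactly `target_score` when the array is rank-scored with the
#' value included (placed at the middle position of the target score's
#' block).
#'
#' @param background_signals numeric vector of the array's other signals.
#' @param target_score desired rank score in `[1, n_bins]`.
#' @param n_bins number of score groups.
#' @return a single numeric signal value.
#' @export
signal_for_score <- function(background_signals, target_score, n_bins = 100) {
  n <- length(background_signals) + 1L
  sizes <- block_sizes(n, as.integer(n_bins))
  start <- cumsum(c(1L, sizes))[target_score]
  k <- start + (sizes[target_score] - 1L) %/% 2L
  plant_values(sort(background_signals), k)
}

draw_band <- function(band, n) {
  if (band[1L] > band[2L]) stop("empty band", call. = FALSE)
  v <- seq.int(band[1L], band[2L])
  v[sample.int(length(v), n, replace = TRUE)]  # safe for length-1 bands
}

# per-sample target scores for one planted gene
plant_targets <- function(plant, sample_groups) {
  n <- length(sample_groups)
  t <- draw_band(plant$off_band, n)
  in_g <- which(sample_groups == plant$group)
  if (plant$pattern == "plastic_bimodal") {
    hi <- sample(in_g, round(plant$high_fraction * length(in_g)))
    t[hi] <- draw_band(plant$band, length(hi))
    lo <- setdiff(in_g, hi)
    t[lo] <- draw_band(plant$low_band, length(lo))
  } else {
    t[in_g] <- draw_band(plant$band, length(in_g))
  }
  if (plant$pattern == "disease_shift" && !is.na(plant$group2)) {
    in_g2 <- which(sample_groups == plant$group2)
    t[in_g2] <- draw_band(plant$shift_low, length(in_g2))
  }
  t
}

#' Generate a synthetic annotated expression compendium
#'
#' Draws heavy-tailed (log-normal) background signals with probe-specific
#' baselines, then plants every declared pattern exactly: for each planted
#' probe and sample a target rank score is drawn from the pattern's band and
#' the probe's signal is inserted between the order statistics of the
#' sample's background signals so that ranking reproduces the target score.
#' After generation the whole compendium is re-ranked and every planted
#' score is verified against its target; any discrepancy (e.g. an
#' infeasible plant) is an error, so the returned ground truth is exact by
#' construction.  Detection calls follow the spec's absent model on the
#' realised rank scores, and a QC marker probe is planted per group, below
#' the detection threshold in the designated violator samples.
#'
#' Generation is deterministic given the spec (the global RNG state is
#' restored on exit).
#'
#' @param spec a [synthetic_spec()].
#' @return list with components `compendium` ([expression_compendium()]),
#'   `ranks` (the realised `RankScoreMatrix`), `calls`
#'   ([detection_call_table()]), `panel` ([marker_panel()]) and
#'   `ground_truth` (list: `planted` data frame with one row per planted
#'   probe, `violators` data frame, `absent_cutoff`).
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  groups <- spec$groups
  n_per <- spec$n_samples_per_group[groups]
  n_samples <- sum(n_per)
  n_probes <- spec$n_probes
  n_bins <- spec$n_bins

  sample_groups <- rep(groups, n_per)
  sample_ids <- sprintf("GSM%06d", seq_len(n_samples))
  series_within <- unlist(lapply(n_per, function(n)
    rep_len(seq_len(spec$n_series_per_group), n)))
  series_ids <- sprintf("GSE%04d",
                        match(paste(sample_groups, series_within),
                              unique(paste(sample_groups, series_within))))
  samples <- data.frame(
    sample_id = sample_ids, series_id = series_ids,
    cell_group = sample_groups,
    title = paste0(sample_groups, " replicate ",
                   unlist(lapply(n_per, seq_len))),
    characteristics = paste0("cell type: ", sample_groups,
                             "; series: ", series_ids),
    stringsAsFactors = FALSE)

  probe_ids <- sprintf("PS%05d_at", seq_len(n_probes))

  # planted probes: declared patterns first, then one QC marker per group
  plants <- spec$planted_genes
  qc_plants <- lapply(groups, function(g)
    planted_gene("marker_high", g, band = c(90L, 100L),
                 off_band = c(10L, 40L)))
  all_plants <- c(plants, qc_plants)
  roles <- c(rep("analysis", length(plants)), rep("qc_marker", length(groups)))
  K <- length(all_plants)
  plant_idx <- sort(sample.int(n_probes, K))
  plant_ids <- probe_ids[plant_idx]

  # QC violators: planted below the detection threshold on their group's
  # QC marker probe
  n_viol <- round(spec$qc_violation_fraction * n_samples)
  violator_pos <- sort(sample.int(n_samples, n_viol))

  targets <- matrix(NA_integer_, K, n_samples)
  for (i in seq_len(K)) targets[i, ] <- plant_targets(all_plants[[i]],
                                                      sample_groups)
  qc_row_of_group <- stats::setNames(length(plants) + seq_along(groups),
                                     groups)
  if (spec$detect_threshold < 2L && n_viol > 0L)
    stop("detect_threshold too low to plant violators", call. = FALSE)
  for (j in violator_pos) {
    r <- qc_row_of_group[[sample_groups[j]]]
    targets[r, j] <- sample.int(spec$detect_threshold - 1L, 1L)
  }

  # background signals: log-normal with probe-specific baseline
  bg_idx <- setdiff(seq_len(n_probes), plant_idx)
  probe_mu <- stats::rnorm(n_probes, mean = 5, sd = 1.5)
  signals <- matrix(NA_real_, n_probes, n_samples,
                    dimnames = list(probe_ids, sample_ids))
  signals[bg_idx, ] <- exp(probe_mu[bg_idx] +
                             stats::rnorm(length(bg_idx) * n_samples,
                                          sd = 0.6))

  sizes <- block_sizes(n_probes, n_bins)
  starts <- cumsum(c(1L, sizes))[seq_len(n_bins)]
  for (j in seq_len(n_samples)) {
    tj <- targets[, j]
    pos <- integer(K)
    for (s in unique(tj)) {
      at <- which(tj == s)
      if (length(at) > sizes[s])
        stop("infeasible plant: ", length(at), " probes target score ", s,
             " in sample ", sample_ids[j], " but the block holds only ",
             sizes[s], call. = FALSE)
      pos[at] <- starts[s] - 1L + sample.int(sizes[s], length(at))
    }
    signals[plant_idx, j] <- plant_values(sort(signals[bg_idx, j]), pos)
  }

  # probe annotation: planted probes always annotated; ~2% of background
  # probes left unannotated to exercise the gene-query exclusion rule
  unannot <- bg_idx[seq_along(bg_idx) %% 50L == 0L]
  annot_idx <- setdiff(seq_len(n_probes), unannot)
  aliases <- ifelse(annot_idx %% 7L == 0L,
                    paste0("G", annot_idx, "-ALT"), "")
  probes <- data.frame(
    probe_set_id = probe_ids[annot_idx],
    gene_symbol = paste0("GENE", annot_idx),
    gene_id = 10000L + annot_idx,
    aliases = aliases,
    stringsAsFactors = FALSE)

  compendium <- expression_compendium(signals, samples, probes)
  ranks <- rank_scores(compendium, n_bins = n_bins)

  realized <- ranks$scores[plant_idx, , drop = FALSE]
  if (!all(realized == targets))
    stop("planting failed verification: realised rank scores differ from ",
         "targets for ", sum(realized != targets), " cells", call. = FALSE)

  # detection calls from realised rank scores
  am <- spec$absent_model
  sc <- ranks$scores
  below <- sc < am$cutoff_score
  u <- stats::runif(length(sc))
  calls <- matrix("P", n_probes, n_samples,
                  dimnames = dimnames(sc))
  calls[below & u < am$absent_prob_below] <- "A"
  calls[!below & u < am$absent_prob_above] <- "A"
  calls[!below & u >= am$absent_prob_above &
          u < am$absent_prob_above + 0.03] <- "M"
  calls <- detection_call_table(calls)

  panel <- marker_panel(groups,
                        paste0("QCM_", gsub("[^A-Za-z0-9]+", "_", groups)),
                        as.list(plant_ids[qc_row_of_group]),
                        detect_threshold = spec$detect_threshold)

  planted_df <- data.frame(
    probe_set_id = plant_ids,
    pattern = vapply(all_plants, `[[`, "", "pattern"),
    cell_group = vapply(all_plants, `[[`, "", "group"),
    group2 = vapply(all_plants, `[[`, "", "group2"),
    band_lo = vapply(all_plants, function(p) p$band[1L], 1L),
    band_hi = vapply(all_plants, function(p) p$band[2L], 1L),
    high_fraction = vapply(all_plants, function(p)
      if (p$pattern == "plastic_bimodal") p$high_fraction else NA_real_, 1),
    role = roles,
    stringsAsFactors = FALSE)
  violators <- data.frame(
    sample_id = sample_ids[violator_pos],
    cell_group = sample_groups[violator_pos],
    marker_name = paste0("QCM_", gsub("[^A-Za-z0-9]+", "_",
                                      sample_groups[violator_pos])),
    stringsAsFactors = FALSE)

  list(compendium = compendium, ranks = ranks, calls = calls, panel = panel,
       ground_truth = list(planted = planted_df, violators = violators,
                           absent_cutoff = am$cutoff_score))
}
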