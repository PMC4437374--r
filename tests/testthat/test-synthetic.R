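test_that("generation is deterministic given the spec", {
  spec <- synthetic_spec(n_probes = 500L, n_samples_per_group = 5L,
                         groups = c("A", "B"))
  g1 <- generate_compendium(spec)
  g2 <- generate_compendium(spec)
  expect_identical(g1$compendium$signals, g2$compendium$signals)
  expect_identical(g1$ranks$scores, g2$ranks$scores)
  expect_identical(g1$calls$calls, g2$calls$calls)
  expect_identical(g1$ground_truth, g2$ground_truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(generate_compendium(spec)); b <- runif(3)
  expect_identical(a, b)
})

test_that("planted patterns are realised exactly in rank space", {
  g <- default_synth()
  gt <- g$ground_truth$planted
  samples <- g$compendium$samples

  markers <- gt[gt$pattern == "marker_high" & gt$role == "analysis", ]
  for (i in seq_len(nrow(markers))) {
    ids <- samples$sample_id[samples$cell_group == markers$cell_group[i]]
    sc <- g$ranks$scores[markers$probe_set_id[i], ids]
    expect_true(all(sc >= markers$band_lo[i] & sc <= markers$band_hi[i]))
  }

  lows <- gt[gt$pattern == "marker_low", ]
  for (i in seq_len(nrow(lows))) {
    ids <- samples$sample_id[samples$cell_group == lows$cell_group[i]]
    expect_true(all(g$ranks$scores[lows$probe_set_id[i], ids] <= 10))
  }

  plast <- gt[gt$pattern == "plastic_bimodal", ]
  for (i in seq_len(nrow(plast))) {
    grp <- plast$cell_group[i]
    cv <- rbe_curve(g$ranks, samples, plast$probe_set_id[i], grp)
    # two separated modes: mass both below score 25 and above score 80
    expect_gt(sum(cv$ordinates[1:25]), 0.3)
    expect_gt(sum(cv$ordinates[80:100]), 0.2)
    st <- profile_stats(g$ranks, samples, grp)
    expect_gte(st$gpl[st$probe_set_id == plast$probe_set_id[i]], 50)
  }

  shift <- gt[gt$pattern == "disease_shift", ]
  ids_hi <- samples$sample_id[samples$cell_group == shift$cell_group]
  ids_lo <- samples$sample_id[samples$cell_group == shift$group2]
  expect_true(all(g$ranks$scores[shift$probe_set_id, ids_hi] >= 85))
  expect_true(all(g$ranks$scores[shift$probe_set_id, ids_lo] <= 15))
})

test_that("planted markers carry the expected MES sign structure", {
  g <- default_synth()
  gt <- g$ground_truth$planted
  m <- gt[gt$pattern == "marker_high" & gt$role == "analysis", ][1, ]
  for (grp in unique(g$compendium$samples$cell_group)) {
    r <- mes(g$ranks, g$compendium$samples, m$probe_set_id, grp)
    if (grp == m$cell_group) expect_gt(r$mes, 0) else expect_lt(r$mes, 0)
  }
})

test_that("infeasible plants fail loudly", {
  spec <- synthetic_spec(
    n_probes = 100L, groups = "A", n_samples_per_group = 2L,
    planted_genes = list(planted_gene("marker_high", "A", band = c(100L, 100L)),
                         planted_gene("marker_high", "A", band = c(100L, 100L)),
                         planted_gene("marker_high", "A", band = c(100L, 100L))),
    qc_violation_fraction = 0)
  expect_error(generate_compendium(spec), "infeasible plant")
  expect_error(synthetic_spec(groups = "A",
                              planted_genes = list(
                                planted_gene("marker_high", "ZZZ"))),
               "unknown groups")
})

test_that("the generated compendium is structurally valid", {
  g <- default_synth()
  expect_silent(validate_compendium(g$compendium))
  expect_false(all(g$compendium$annotated))  # some probes unannotated
  # panel probes are always annotated
  expect_true(all(unlist(g$panel$probe_set_ids) %in%
                    g$compendium$probes$probe_set_id))
})

test_that("signal_for_score hits the requested score exactly", {
  set.seed(53)
  for (i in 1:25) {
    n_bg <- sample(c(99, 250, 1999), 1)
    bg <- rlnorm(n_bg, 5, 1.5)
    s <- sample.int(100, 1)
    v <- signal_for_score(bg, s, n_bins = 100)
    ids <- sprintf("P%05d", seq_len(n_bg + 1))
    sc <- rank_scores(c(v, bg), n_bins = 100, ids = ids)
    expect_identical(sc[1], s)
  }
})
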