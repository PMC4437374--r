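test_that("electronic sorting equals the brute-force filter", {
  g <- default_synth()
  cp <- g$compendium
  set.seed(41)
  groups <- unique(cp$samples$cell_group)
  probes <- sample(rownames(g$ranks$scores), 40)
  for (p in probes) {
    grp <- sample(groups, 1)
    lo <- sample.int(100, 1)
    hi <- lo - 1L + sample.int(101L - lo, 1)
    res <- esort(cp, g$ranks, p, grp, lo, hi)
    ids <- cp$samples$sample_id[cp$samples$cell_group == grp]
    sc <- g$ranks$scores[p, ids]
    expect_setequal(res$hits$sample_id, ids[sc >= lo & sc <= hi])
    expect_true(all(res$hits$rank_score >= lo & res$hits$rank_score <= hi))
    expect_equal(res$hits$signal,
                 unname(cp$signals[p, res$hits$sample_id]))
    # series view conserves hit counts and partitions by series
    expect_identical(sum(res$series_view$n_hits), nrow(res$hits))
    expect_setequal(res$series_view$series_id, unique(res$hits$series_id))
  }
})

test_that("range additivity: adjacent ranges partition the full range", {
  g <- default_synth()
  cp <- g$compendium
  grp <- cp$samples$cell_group[1]
  p <- rownames(g$ranks$scores)[10]
  a <- esort(cp, g$ranks, p, grp, 1, 50)
  b <- esort(cp, g$ranks, p, grp, 51, 100)
  full <- esort(cp, g$ranks, p, grp, 1, 100)
  expect_length(intersect(a$hits$sample_id, b$hits$sample_id), 0)
  expect_setequal(c(a$hits$sample_id, b$hits$sample_id),
                  full$hits$sample_id)
  # the full range is the identity on the group
  expect_setequal(full$hits$sample_id,
                  cp$samples$sample_id[cp$samples$cell_group == grp])
})

test_that("empty and invalid queries behave per contract", {
  sc <- matrix(c(10L, 20L, 30L), 1, 3,
               dimnames = list("P1", c("S1", "S2", "S3")))
  fx <- scores_fixture(sc, rep("G", 3))
  cp <- expression_compendium(
    matrix(as.numeric(sc), 1, 3, dimnames = dimnames(sc)),
    fx$samples,
    data.frame(probe_set_id = "P1", gene_symbol = "X", gene_id = 1L,
               aliases = "", stringsAsFactors = FALSE))
  res <- esort(cp, fx$ranks, "P1", "G", 55, 55)
  expect_identical(nrow(res$hits), 0L)
  expect_identical(nrow(res$series_view), 0L)
  expect_error(esort(cp, fx$ranks, "P1", "G", 60, 40), "inverted")
  expect_error(esort(cp, fx$ranks, "P1", "G", 0, 40), "outside")
  expect_error(esort(cp, fx$ranks, "P9", "G", 1, 40), "unknown probe")
  expect_error(esort(cp, fx$ranks, "P1", "H", 1, 40), "unknown cell group")
})

test_that("reports render sample and series views", {
  g <- default_synth()
  cp <- g$compendium
  grp <- cp$samples$cell_group[1]
  p <- g$ground_truth$planted$probe_set_id[1]
  res <- esort(cp, g$ranks, p, grp, 90, 100)
  smp <- esort_report(res, "sample")
  expect_identical(nrow(smp), nrow(res$hits))
  expect_named(smp, c("sample_id", "series_id", "title", "characteristics",
                      "signal", "rank_score"))
  ser <- esort_report(res, "series")
  expect_identical(sum(ser$n_hits), nrow(smp))
  expect_true(all(ser$n_hits <= ser$n_group_samples_in_series))
})
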