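test_that("tiny-sample MES matches the exact enumeration example", {
  g <- c(9, 10, 10)
  b <- c(1, 1, 2, 2, 9, 10, 10)
  s <- mes_score(g, b)
  expect_equal(s$p_value, bitmask_ranksum_p(g, b), tolerance = 1e-12)
  expect_gt(s$mes, 0)  # group median 10 >= background median 2
  expect_equal(abs(s$mes), abs(log10(s$p_value)), tolerance = 1e-12)
})

test_that("exact p-values agree with an independent enumeration with ties", {
  set.seed(23)
  for (i in 1:60) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    g <- sample.int(20, m, replace = TRUE)
    b <- sample.int(20, n, replace = TRUE)
    if (length(unique(b)) < 2) next
    s <- mes_score(g, b)
    expect_equal(s$p_value, bitmask_ranksum_p(g, b), tolerance = 1e-12)
    # at p = 1 the score is 0 and carries no sign
    if (s$mes != 0)
      expect_identical(s$mes > 0, s$group_median >= s$background_median)
  }
})

test_that("NA rule: constant background or p-value underflow yields NA", {
  s <- mes_score(c(5, 5, 5), c(5, 5, 5, 5))
  expect_true(is.na(s$mes))
  expect_true(is.na(s$p_value))
  # a probe constant across the whole compendium through the high-level API
  sc <- matrix(c(7L, 7L, 7L, 7L, 1L, 2L, 3L, 4L), 2, 4, byrow = TRUE,
               dimnames = list(c("P1", "P2"), paste0("S", 1:4)))
  fx <- scores_fixture(sc, c("A", "A", "B", "B"))
  expect_true(is.na(mes(fx$ranks, fx$samples, "P1", "A")$mes))
  expect_false(is.na(mes(fx$ranks, fx$samples, "P2", "A")$mes))
})

test_that("a single-group compendium compares a group against itself", {
  sc <- matrix(sample.int(100, 40, replace = TRUE), 1, 40,
               dimnames = list("P1", sprintf("S%02d", 1:40)))
  fx <- scores_fixture(sc, rep("G", 40))
  expect_identical(background_scores(fx$ranks, "P1"), fx$ranks$scores[1, ])
  r <- mes(fx$ranks, fx$samples, "P1", "G")
  expect_gt(r$p_value, 0.9)      # self-comparison: no evidence of difference
  expect_lt(abs(r$mes), 0.1)
  expect_gte(r$mes, 0)           # equal medians take the positive sign
})

test_that("disjoint score ranges give opposite-signed MES", {
  sc <- matrix(c(91:100, 1:10), 1, 20,
               dimnames = list("P1", sprintf("S%02d", 1:20)))
  fx <- scores_fixture(sc, rep(c("hi", "lo"), each = 10))
  expect_gt(mes(fx$ranks, fx$samples, "P1", "hi")$mes, 0)
  expect_lt(mes(fx$ranks, fx$samples, "P1", "lo")$mes, 0)
})

test_that("shifting group scores upward never decreases the MES", {
  set.seed(31)
  for (i in 1:20) {
    b0 <- sample.int(60, 40, replace = TRUE)
    g0 <- sample.int(40, 12, replace = TRUE)
    prev <- -Inf
    for (shift in c(0, 10, 25, 40)) {
      s <- mes_score(g0 + shift, c(b0, g0 + shift))
      expect_gte(s$mes + 1e-9, prev)
      prev <- s$mes
    }
  }
})

test_that("the batch MES table equals pairwise evaluation", {
  g <- generate_compendium(synthetic_spec(n_probes = 400L,
                                          n_samples_per_group = 8L,
                                          groups = c("A", "B", "C")))
  probes <- rownames(g$ranks$scores)[c(2, 50, 399)]
  mt <- mes_table(g$ranks, g$compendium$samples, probe_set_ids = probes)
  expect_identical(nrow(mt), 9L)
  for (k in seq_len(nrow(mt))) {
    single <- mes(g$ranks, g$compendium$samples,
                  mt$probe_set_id[k], mt$cell_group[k])
    expect_equal(mt[k, ], single, ignore_attr = TRUE)
  }
})
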