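test_that("RBE ordinates are sample fractions that sum to one", {
  sc <- matrix(c(42L, 99L, 99L, 13L, 99L), 1, 5,
               dimnames = list("P1", paste0("S", 1:5)))
  fx <- scores_fixture(sc, rep("B cell", 5))
  cv <- rbe_curve(fx$ranks, fx$samples, "P1", "B cell")
  expect_equal(cv$ordinates[99], 3 / 5)
  expect_equal(cv$ordinates[42], 1 / 5)
  expect_equal(sum(cv$ordinates), 1, tolerance = 1e-12)
  # ordinate * n_samples is a count
  expect_true(all(abs(cv$ordinates * cv$n_samples -
                        round(cv$ordinates * cv$n_samples)) < 1e-9))

  one <- scores_fixture(matrix(42L, 1, 1, dimnames = list("P1", "S1")),
                        "B cell")
  cv1 <- rbe_curve(one$ranks, one$samples, "P1", "B cell")
  expect_identical(which(cv1$ordinates > 0), 42L)
  expect_equal(cv1$ordinates[42], 1)

  expect_error(rbe_curve(fx$ranks, fx$samples, "P1", "T cell"),
               "unknown cell group")
  expect_error(rbe_curve(fx$ranks, fx$samples, "NOPE", "B cell"),
               "unknown probe")
})

test_that("quartiles, GPL and ARS follow the declared quantile rule", {
  sc <- matrix(1:5, 1, 5, dimnames = list("P1", paste0("S", 1:5)))
  fx <- scores_fixture(sc, rep("G", 5))
  st <- profile_stats(fx$ranks, fx$samples, "G")
  expect_equal(st$q1, 2)
  expect_equal(st$q3, 4)
  expect_equal(st$gpl, 2)
  expect_equal(st$ars, 3)

  sc87 <- matrix(87L, 1, 200,
                 dimnames = list("P1", sprintf("S%03d", 1:200)))
  fx87 <- scores_fixture(sc87, rep("G", 200))
  st87 <- profile_stats(fx87$ranks, fx87$samples, "G")
  expect_equal(st87$gpl, 0)
  expect_equal(st87$ars, 87)
})

test_that("profile stats match the brute-force oracle on random draws", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:200, 1)
    sc <- matrix(sample.int(100, n, replace = TRUE), 1, n,
                 dimnames = list("P1", sprintf("S%04d", seq_len(n))))
    fx <- scores_fixture(sc, rep("G", n))
    st <- profile_stats(fx$ranks, fx$samples, "G")
    ref <- brute_profile(sc[1, ])
    expect_equal(st$q1, ref$q1, tolerance = 1e-12)
    expect_equal(st$q3, ref$q3, tolerance = 1e-12)
    expect_equal(st$gpl, ref$gpl, tolerance = 1e-12)
    expect_equal(st$ars, ref$ars, tolerance = 1e-12)
    # GPL is invariant under shifting all scores by a constant
    shift <- min(5L, 100L - max(sc))
    fx2 <- scores_fixture(sc + shift, rep("G", n))
    expect_equal(profile_stats(fx2$ranks, fx2$samples, "G")$gpl, st$gpl)
    expect_identical(st$gpl == 0, st$q1 == st$q3)
  }
})

test_that("compendium-wide ARS is the sample-weighted mean of group ARS", {
  g <- default_synth()
  samples <- g$compendium$samples
  overall <- profile_stats(g$ranks, samples)
  groups <- unique(samples$cell_group)
  per <- lapply(groups, function(gr) profile_stats(g$ranks, samples, gr))
  w <- vapply(per, function(p) p$n_samples[1], 1)
  agg <- Reduce(`+`, Map(function(p, wi) p$ars * wi, per, w)) / sum(w)
  expect_equal(overall$ars, agg, tolerance = 1e-9)
})
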