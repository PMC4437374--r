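# Shared fixtures, built in code.

# Tiny hand-written compendium: 3 annotated probes + 1 unannotated, 4 samples
# in 2 groups, 2 series.
toy_compendium <- function() {
  sig <- matrix(c(10, 20, 30, 40,
                  5, 4, 3, 2,
                  100, 90, 80, 70,
                  1, 2, 1, 2),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("205476_at", "1007_s_at", "206398_s_at",
                                  "AFFX-1_at"),
                                c("S1", "S2", "S3", "S4")))
  samples <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    series_id = c("E1", "E1", "E2", "E2"),
    cell_group = c("PMN", "PMN", "B cell", "B cell"),
    title = paste("sample", 1:4),
    characteristics = "cultured",
    stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_set_id = c("205476_at", "1007_s_at", "206398_s_at"),
    gene_symbol = c("CCL20", "DDR1", "CD19"),
    gene_id = c(6364L, 780L, 930L),
    aliases = c("MIP-3-alpha|LARC", "", "B4"),
    stringsAsFactors = FALSE)
  expression_compendium(sig, samples, probes)
}

# Build a RankScoreMatrix directly from a score matrix plus a sample table
# with one group per unique prefix; used where signal-space construction
# would obscure the case under test.
scores_fixture <- function(score_matrix, cell_groups, n_bins = 100) {
  samples <- data.frame(
    sample_id = colnames(score_matrix),
    series_id = paste0("E", rep_len(1:2, ncol(score_matrix))),
    cell_group = cell_groups,
    title = "", characteristics = "",
    stringsAsFactors = FALSE)
  list(ranks = rank_score_matrix(score_matrix, n_bins), samples = samples)
}

# One default synthetic compendium, generated once per test run.
default_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_compendium(synthetic_spec())
    cache
  }
})

# Independent brute-force rank scoring: sort (signal, id) pairs, slice the
# sorted order into blocks sized floor/ceil(n/b) with oversized blocks first.
brute_rank_scores <- function(x, n_bins, ids = names(x)) {
  n <- length(x)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(n))
  o <- order(x, ids, method = "radix")
  q <- n %/% n_bins
  r <- n %% n_bins
  out <- integer(n)
  pos <- 1L
  for (s in seq_len(n_bins)) {
    size <- q + as.integer(s <= r)
    out[o[seq.int(pos, length.out = size)]] <- s
    pos <- pos + size
  }
  out
}

# Independent exact two-sided rank-sum p-value: enumerate group assignments
# as bit masks over the pooled vector.
bitmask_ranksum_p <- function(group, background) {
  pooled <- c(group, background)
  r <- rank(pooled)
  N <- length(pooled)
  m <- length(group)
  masks <- 0:(2^N - 1)
  bits <- matrix(0L, length(masks), N)
  for (b in seq_len(N))
    bits[, b] <- bitwAnd(bitwShiftR(masks, b - 1L), 1L)
  keep <- rowSums(bits) == m
  sums <- as.vector(bits[keep, , drop = FALSE] %*% r)
  mu <- m * (N + 1) / 2
  w_obs <- sum(r[seq_len(m)])
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

# Independent quartile/ARS computation: manual type-7 interpolation.
brute_profile <- function(scores) {
  s <- sort(unname(scores))
  n <- length(s)
  qat <- function(p) {
    h <- 1 + (n - 1) * p
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- qat(0.25); q3 <- qat(0.75)
  list(q1 = q1, q3 = q3, gpl = q3 - q1, ars = sum(scores) / n)
}
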