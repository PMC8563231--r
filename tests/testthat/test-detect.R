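test_that("window flags respect the het and missing allowances", {
  p <- roh_params()
  expect_equal(window_homozygosity(rep(0L, 50), p), TRUE)
  calls <- rep(0L, 50); calls[c(10, 30)] <- 1L
  expect_equal(window_homozygosity(calls, p), FALSE)  # 2 het > allowance
  calls <- rep(0L, 50); calls[10] <- 1L; calls[20:24] <- NA
  expect_equal(window_homozygosity(calls, p), TRUE)   # 1 het, 5 missing: ok
  calls[25] <- NA
  expect_equal(window_homozygosity(calls, p), FALSE)  # 6 missing
  expect_equal(window_homozygosity(integer(0), p), logical(0))
  # shorter than one window: a single all-SNP window is evaluated
  expect_equal(window_homozygosity(rep(0L, 7), p), TRUE)
  expect_length(window_homozygosity(rep(0L, 120), p), 71L)
})

test_that("window flags match a direct per-window recount on random input", {
  set.seed(42)
  for (trial in 1:5) {
    calls <- sample(c(0L, 0L, 0L, 1L, NA), 200, replace = TRUE)
    p <- roh_params(window_snps = sample(10:60, 1),
                    window_max_het = sample(0:2, 1),
                    window_max_missing = sample(0:6, 1))
    got <- window_homozygosity(calls, p)
    w <- min(p$window_snps, length(calls))
    want <- vapply(seq_len(length(calls) - w + 1L), function(a) {
      win <- calls[a:(a + w - 1L)]
      sum(win == 1L, na.rm = TRUE) <= p$window_max_het &&
        sum(is.na(win)) <= p$window_max_missing
    }, logical(1))
    expect_equal(got, want)
  }
})

test_that("SNP hit fractions match explicit window enumeration", {
  p <- roh_params(window_snps = 50L)
  expect_equal(snp_hit_fractions(rep(TRUE, 71), 120, p), rep(1, 120))
  expect_equal(snp_hit_fractions(rep(FALSE, 71), 120, p), rep(0, 120))
  set.seed(7)
  flags <- runif(71) < 0.5
  got <- snp_hit_fractions(flags, 120, p)
  want <- vapply(1:120, function(i) {
    wins <- which(seq_along(flags) <= i & i <= seq_along(flags) + 49L)
    mean(flags[wins])
  }, numeric(1))
  expect_equal(got, want)
})

test_that("saturated and heterozygous chromosomes call as expected", {
  pos <- seq(1e6, by = 10000, length.out = 200)   # spans ~2 Mb
  segs <- call_segments(make_matrix(rep(0L, 200), pos = pos), roh_params())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$start, pos[1])
  expect_equal(segs$end, pos[200])
  expect_equal(segs$length_bp, pos[200] - pos[1] + 1)

  het <- call_segments(make_matrix(rep(1L, 200), pos = pos), roh_params())
  expect_equal(nrow(het), 0L)
})

test_that("single-SNP chromosome behaves at the degenerate bound", {
  m <- make_matrix(0L, pos = 5000)
  loose <- roh_params(min_snps = 1L, min_length_bp = 1)
  seg <- call_segments(m, loose)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end, seg$length_bp), c(5000, 5000, 1))
  expect_equal(nrow(call_segments(m, roh_params())), 0L)  # fails min_snps
  expect_equal(nrow(brute_force_roh(m, roh_params())), 0L)
  expect_equal(brute_force_roh(m, loose), seg)
})

test_that("runs are split at gaps wider than max_gap_bp", {
  pos <- c(seq(1000, by = 500, length.out = 60),
           seq(2e6, by = 500, length.out = 60))   # ~1.97 Mb hole
  p <- roh_params(window_snps = 10L, min_snps = 20L, min_length_bp = 1e4,
                  max_gap_bp = 1e6)
  segs <- call_segments(make_matrix(rep(0L, 120), pos = pos), p)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(1000, 2e6))
  wide <- call_segments(make_matrix(rep(0L, 120), pos = pos),
                        roh_params(window_snps = 10L, min_snps = 20L,
                                   min_length_bp = 1e4, max_gap_bp = 2e6,
                                   min_density_bp_per_snp = 5e5))
  expect_equal(nrow(wide), 1L)
})

test_that("fast caller equals the brute-force oracle on random instances", {
  set.seed(101)
  for (trial in 1:30) {
    m <- random_small_matrix(n_snps = sample(80:300, 1),
                             n_samples = sample(1:3, 1))
    p <- roh_params(window_snps = sample(c(10L, 20L, 50L), 1),
                    window_max_het = sample(0:2, 1),
                    window_max_missing = sample(0:5, 1),
                    min_snps = sample(c(10L, 25L, 50L), 1),
                    min_length_bp = sample(c(1e3, 1e4, 1e5), 1),
                    max_gap_bp = sample(c(1e5, 1e6), 1))
    expect_equal(call_segments(m, p), brute_force_roh(m, p),
                 label = sprintf("trial %d", trial))
  }
})

test_that("emitted segments satisfy every segment-level threshold and are disjoint", {
  sim <- simulate_genotypes(sim_config(
    n_samples = 5, chromosomes = c("1" = 8e6, "2" = 6e6),
    target_autozygosity = 0.4, seed = 31))
  p <- roh_params(min_length_bp = 1e5)
  segs <- call_segments(sim$matrix, p)
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$n_snps >= p$min_snps))
  expect_true(all(segs$length_bp >= p$min_length_bp))
  expect_true(all(segs$length_bp / segs$n_snps <= p$min_density_bp_per_snp))
  expect_equal(segs$length_bp, segs$end - segs$start + 1)
  for (grp in split(segs, paste(segs$sample, segs$chrom))) {
    if (nrow(grp) < 2L) next
    expect_true(!is.unsorted(grp$start, strictly = TRUE))
    expect_true(all(grp$start[-1L] > grp$end[-nrow(grp)]))
  }
})

test_that("raising min_length or min_snps never adds segments", {
  sim <- simulate_genotypes(sim_config(
    n_samples = 4, chromosomes = c("1" = 1e7),
    target_autozygosity = 0.5, tract_mean_bp = 1e6, seed = 17))
  n_prev <- Inf
  for (min_len in c(1e5, 5e5, 1e6, 2e6)) {
    n <- nrow(call_segments(sim$matrix, roh_params(min_length_bp = min_len)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (min_snps in c(50L, 100L, 500L, 2000L)) {
    n <- nrow(call_segments(sim$matrix,
                            roh_params(min_snps = min_snps,
                                       min_length_bp = 1e5)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("implanted tracts are recovered with high overlap and total-length agreement", {
  cfg <- sim_config(n_samples = 6, chromosomes = c("1" = 2e7),
                    target_autozygosity = 0.35, tract_mean_bp = 2e6,
                    snp_spacing_bp = 500, het_error_rate = 0.001, seed = 9)
  sim <- simulate_genotypes(cfg)
  p <- roh_params(min_length_bp = 1e6)
  segs <- call_segments(sim$matrix, p)
  # every truth tract >= 1.5 Mb is covered >= 80% by a called segment
  big <- sim$tracts[sim$tracts$end - sim$tracts$start + 1 >= 1.5e6, ]
  for (r in seq_len(nrow(big))) {
    s <- segs[segs$sample == big$sample[r] & segs$chrom == big$chrom[r], ]
    ov <- pmin(s$end, big$end[r]) - pmax(s$start, big$start[r]) + 1
    expect_gte(max(c(ov, 0)),
               0.8 * (big$end[r] - big$start[r] + 1))
  }
  # total called length within 10% of total truth length above min_length
  truth_len <- sim$tracts$end - sim$tracts$start + 1
  total_truth <- sum(truth_len[truth_len >= p$min_length_bp])
  expect_lt(abs(sum(segs$length_bp) - total_truth) / total_truth, 0.10)
})
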