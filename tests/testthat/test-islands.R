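test_that("per-SNP incidence counts covering samples", {
  pos <- seq(1000, 20000, by = 1000)
  m <- make_matrix(matrix(0L, 20, length(pos)), pos = pos)
  # segments of 10 of the 20 samples cover SNPs 5..15
  segs <- data.frame(sample = m$samples[1:10], chrom = "1",
                     start = 5000, end = 15000, n_snps = 11L,
                     length_bp = 10001, n_het = 0L, n_missing = 0L)
  tr <- snp_incidence(segs, m)
  expect_equal(tr$chroms[["1"]]$incidence[pos >= 5000 & pos <= 15000],
               rep(0.5, 11))
  expect_equal(tr$chroms[["1"]]$incidence[pos < 5000], rep(0, 4))

  none <- snp_incidence(segs[0, ], m)
  expect_equal(none$chroms[["1"]]$incidence, rep(0, 20))

  bad <- segs; bad$chrom <- "7"
  expect_error(snp_incidence(bad, m), "absent")
})

test_that("incidence equals an interval-stabbing brute force on random data", {
  set.seed(55)
  sim <- simulate_genotypes(sim_config(
    n_samples = 5, chromosomes = c("1" = 3e6, "2" = 2e6),
    target_autozygosity = 0.4, seed = 55))
  segs <- call_segments(sim$matrix, small_params())
  tr <- snp_incidence(segs, sim$matrix)
  for (cn in chrom_names(sim$matrix)) {
    pos <- sim$matrix$chroms[[cn]]$pos
    want <- vapply(pos, function(p) {
      covered <- vapply(sim$matrix$samples, function(s)
        any(segs$sample == s & segs$chrom == cn &
              segs$start <= p & p <= segs$end), logical(1))
      mean(covered)
    }, numeric(1))
    expect_equal(tr$chroms[[cn]]$incidence, want)
  }
})

test_that("threshold modes: fixed passes through, quantile is nearest-rank", {
  m <- make_matrix(matrix(0L, 4, 3), pos = c(1, 2, 3) * 1000)
  tr <- snp_incidence(data.frame(sample = "S01", chrom = "1", start = 1,
                                 end = 3000, n_snps = 3L, length_bp = 3000,
                                 n_het = 0L, n_missing = 0L), m)
  expect_equal(incidence_threshold(tr, "fixed", 0.30), 0.30)
  expect_error(incidence_threshold(tr, "fixed", 1.5), "\\[0, 1\\]")

  # constant incidence -> the quantile is that constant
  all_cov <- data.frame(sample = m$samples, chrom = "1", start = 1,
                        end = 3000, n_snps = 3L, length_bp = 3000,
                        n_het = 0L, n_missing = 0L)
  trc <- snp_incidence(all_cov, m)
  expect_equal(incidence_threshold(trc, "quantile", 0.01), 1)

  # 1000 simulated incidences vs sort-and-index brute force
  set.seed(77)
  inc <- runif(1000)
  fake <- structure(list(n_samples = 100L, chroms = list(
    "1" = list(pos = seq_len(1000) * 100, incidence = inc))),
    class = "snp_incidence_track")
  for (tail in c(0.01, 0.05, 0.25)) {
    got <- incidence_threshold(fake, "quantile", tail)
    expect_equal(got, sort(inc)[ceiling((1 - tail) * 1000)])
  }
})

test_that("island merging finds maximal runs with gap allowance", {
  mk_track <- function(inc, pos = seq_along(inc) * 1000)
    structure(list(n_samples = 10L,
                   chroms = list("1" = list(pos = pos, incidence = inc))),
              class = "snp_incidence_track")

  expect_equal(nrow(merge_islands(mk_track(rep(0.1, 50)), 0.3)), 0L)

  inc <- rep(0, 50); inc[20:24] <- 1
  one <- merge_islands(mk_track(inc), 0.3)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end, one$n_snps), c(20000, 24000, 5))

  # a single below-threshold SNP splits unless the gap allowance covers it
  inc[22] <- 0.1
  expect_equal(nrow(merge_islands(mk_track(inc), 0.3, max_gap_snps = 0L)), 2L)
  joined <- merge_islands(mk_track(inc), 0.3, max_gap_snps = 1L)
  expect_equal(nrow(joined), 1L)
  expect_equal(joined$n_gap_snps, 1L)
  expect_equal(joined$n_snps, 4L)

  # min_snps counts above-threshold members only
  expect_equal(nrow(merge_islands(mk_track(inc), 0.3, min_snps = 3L)), 0L)
  expect_equal(nrow(merge_islands(mk_track(inc), 0.3, max_gap_snps = 1L,
                                  min_snps = 3L)), 1L)
  expect_equal(nrow(merge_islands(mk_track(inc), 0.3, max_gap_snps = 1L,
                                  min_snps = 5L)), 0L)
})

test_that("island merging equals an exhaustive run finder on random tracks", {
  set.seed(91)
  for (trial in 1:20) {
    inc <- round(runif(200), 2)
    thr <- runif(1, 0.2, 0.8)
    track <- structure(list(n_samples = 50L, chroms = list(
      "1" = list(pos = cumsum(sample(200:2000, 200, TRUE)),
                 incidence = inc))), class = "snp_incidence_track")
    got <- merge_islands(track, thr, max_gap_snps = 0L, min_snps = 1L)
    # exhaustive: walk the SNPs, open a run at every above-threshold SNP
    runs <- list(); i <- 1L
    while (i <= 200L) {
      if (inc[i] >= thr) {
        j <- i
        while (j < 200L && inc[j + 1L] >= thr) j <- j + 1L
        runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    expect_equal(nrow(got), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(got$start[k], track$chroms[["1"]]$pos[runs[[k]][1]])
      expect_equal(got$end[k], track$chroms[["1"]]$pos[runs[[k]][2]])
    }
  }
})

test_that("raising the threshold never increases SNPs inside islands", {
  set.seed(13)
  sim <- simulate_genotypes(sim_config(
    n_samples = 8, chromosomes = c("1" = 4e6),
    target_autozygosity = 0.5, seed = 13))
  segs <- call_segments(sim$matrix, small_params())
  tr <- snp_incidence(segs, sim$matrix)
  prev <- Inf
  for (thr in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    isl <- merge_islands(tr, thr, min_snps = 1L)
    tot <- sum(isl$n_snps)
    expect_lte(tot, prev)
    expect_true(all(isl$max_incidence >= thr | nrow(isl) == 0L))
    prev <- tot
  }
})

test_that("Manhattan export round-trips values and threshold", {
  sim <- simulate_genotypes(sim_config(
    n_samples = 3, chromosomes = c("1" = 1e6, "2" = 8e5), seed = 3))
  segs <- call_segments(sim$matrix, small_params())
  tr <- snp_incidence(segs, sim$matrix)
  f <- tempfile(fileext = ".tsv")
  manhattan_export(tr, 0.30, f)
  expect_equal(length(readLines(f)),
               2L + sum(vapply(tr$chroms, function(ch) length(ch$pos),
                               numeric(1))))
  back <- read_manhattan(f, n_samples = 3L)
  expect_equal(back$threshold, 0.30)
  for (cn in names(tr$chroms)) {
    expect_equal(back$track$chroms[[cn]]$pos, tr$chroms[[cn]]$pos)
    expect_equal(back$track$chroms[[cn]]$incidence,
                 tr$chroms[[cn]]$incidence)
  }
})
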