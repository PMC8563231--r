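# fixture builders shared across test files; everything is generated in code

# quick genotype matrix: `calls` is a vector (one sample) or samples x sites
# matrix of codes 0 (hom), 1 (het), NA (missing)
make_matrix <- function(calls, pos = NULL, qual = NULL, chrom = "1",
                        samples = NULL) {
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1L)
  n <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  if (is.null(qual)) qual <- rep(50, n)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(calls)))
  ch <- list(list(pos = pos, qual = qual, calls = calls))
  names(ch) <- chrom
  genotype_matrix(samples, ch)
}

# random small instance for oracle-equivalence checks: mixed hom tracts and
# noisy background, irregular spacing, occasional missing calls
random_small_matrix <- function(n_snps = 200L, n_samples = 2L,
                                spacing = 500) {
  gaps <- pmax(1, round(rexp(n_snps, 1 / spacing)))
  # sprinkle a few large gaps to exercise max_gap splitting
  big <- sample.int(n_snps, size = max(1L, n_snps %/% 80L))
  gaps[big] <- gaps[big] + round(runif(length(big), 0.5e6, 2e6))
  pos <- cumsum(gaps)
  calls <- matrix(0L, nrow = n_samples, ncol = n_snps)
  for (s in seq_len(n_samples)) {
    state <- runif(1) < 0.5  # start inside or outside a hom stretch
    i <- 1L
    while (i <= n_snps) {
      len <- sample(5:120, 1L)
      j <- min(n_snps, i + len - 1L)
      p_het <- if (state) runif(1, 0, 0.05) else runif(1, 0.15, 0.5)
      calls[s, i:j] <- ifelse(runif(j - i + 1L) < p_het, 1L, 0L)
      state <- !state
      i <- j + 1L
    }
    calls[s, runif(n_snps) < 0.02] <- NA_integer_
  }
  make_matrix(calls, pos = pos)
}

# loose-threshold parameters that actually emit segments on small fixtures
small_params <- function(...) {
  roh_params(window_snps = 20L, min_snps = 25L, min_length_bp = 1e4,
             max_gap_bp = 5e5, min_density_bp_per_snp = 5e4, ...)
}
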