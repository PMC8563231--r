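#' Flag sliding windows as homozygous
#'
#' Slides a window of `window_snps` consecutive SNPs along one sample's call
#' sequence and flags each window `TRUE` when it contains at most
#' `window_max_het` heterozygous and at most `window_max_missing` missing
#' calls.  Only windows fully inside the sequence are evaluated; a sequence
#' shorter than one window is evaluated as a single all-SNP window, so short
#' chromosomes are not silently dropped.
#'
#' @param calls integer vector of zygosity codes: `0` hom, `1` het, `NA`
#'   missing.
#' @param params a [roh_params()].
#' @return logical vector of per-window flags (length
#'   `max(length(calls) - window_snps + 1, 1)`; empty for empty input).
#' @export
window_homozygosity <- function(calls, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  n <- length(calls)
  if (n == 0L) return(logical(0))
  w <- min(params$window_snps, n)
  het <- cumsum(c(0L, !is.na(calls) & calls == 1L))
  mis <- cumsum(c(0L, is.na(calls)))
  i <- seq_len(n - w + 1L)
  (het[i + w] - het[i]) <= params$window_max_het &
    (mis[i + w] - mis[i]) <= params$window_max_missing
}

#' Per-SNP fraction of homozygous windows
#'
#' For each SNP, the fraction of windows containing it that were flagged
#' homozygous by [window_homozygosity()].  A SNP is eligible for run
#' construction when this fraction reaches the `snp_hit_threshold`.
#'
#' @param flags logical window flags from [window_homozygosity()].
#' @param n_snps number of SNPs the windows were computed over.
#' @param params a [roh_params()].
#' @return numeric vector of length `n_snps` with values in `[0, 1]`.
#' @export
snp_hit_fractions <- function(flags, n_snps, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  if (n_snps == 0L) return(numeric(0))
  if (length(flags) == 1L) return(rep(as.numeric(flags), n_snps))
  w <- params$window_snps
  nw <- length(flags)  # == n_snps - w + 1
  cs <- cumsum(c(0L, flags))
  i <- seq_len(n_snps)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call ROH segments with the sliding-window scan
#'
#' For every sample and chromosome: flag windows, score SNP eligibility,
#' build maximal runs of consecutive eligible SNPs, split runs wherever
#' adjacent SNPs are more than `max_gap_bp` apart, and keep a candidate run
#' as a segment when it has at least `min_snps` SNPs, spans at least
#' `min_length_bp`, and averages at most `min_density_bp_per_snp` bp per SNP.
#' Segment endpoints are the positions of the first and last SNP of the run.
#'
#' @param matrix a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data.frame of segments (`sample`, `chrom`, `start`, `end`,
#'   `n_snps`, `length_bp`, `n_het`, `n_missing`), sorted by sample,
#'   chromosome, start; rows are pairwise disjoint within a
#'   sample-chromosome.
#' @examples
#' sim <- simulate_genotypes(sim_config(n_samples = 2,
#'   chromosomes = c("1" = 5e6), target_autozygosity = 0.4, seed = 3))
#' segs <- call_segments(sim$matrix, roh_params(min_length_bp = 1e5))
#' @export
call_segments <- function(matrix, params = roh_params()) {
  stopifnot(inherits(matrix, "genotype_matrix"),
            inherits(params, "roh_params"))
  out <- list()
  for (cn in names(matrix$chroms)) {
    ch <- matrix$chroms[[cn]]
    pos <- ch$pos
    for (s in matrix$samples) {
      calls <- ch$calls[s, ]
      flags <- window_homozygosity(calls, params)
      frac <- snp_hit_fractions(flags, length(calls), params)
      eligible <- frac >= params$snp_hit_threshold
      runs <- eligible_runs(eligible, pos, params$max_gap_bp)
      for (r in runs) {
        i1 <- r[1]; i2 <- r[2]
        n_snp <- i2 - i1 + 1L
        len <- pos[i2] - pos[i1] + 1
        if (n_snp >= params$min_snps && len >= params$min_length_bp &&
            len / n_snp <= params$min_density_bp_per_snp) {
          seg <- calls[i1:i2]
          out[[length(out) + 1L]] <- data.frame(
            sample = s, chrom = cn, start = pos[i1], end = pos[i2],
            n_snps = n_snp, length_bp = len,
            n_het = sum(seg == 1L, na.rm = TRUE),
            n_missing = sum(is.na(seg)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_segments())
  sort_segments(do.call(rbind, out))
}

## maximal runs of TRUE, split where adjacent positions are > max_gap apart;
## returns list of c(first_index, last_index)
eligible_runs <- function(eligible, pos, max_gap) {
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- list()
  for (k in which(r$values)) {
    i <- starts[k]
    for (j in seq(starts[k], ends[k])) {
      if (j > i && pos[j] - pos[j - 1L] > max_gap) {
        runs[[length(runs) + 1L]] <- c(i, j - 1L)
        i <- j
      }
    }
    runs[[length(runs) + 1L]] <- c(i, ends[k])
  }
  runs
}

#' Naive brute-force ROH caller (verification oracle)
#'
#' Same contract as [call_segments()], computed by explicit re-enumeration:
#' every window is recounted with a loop, each SNP's eligibility is found by
#' scanning every window that contains it, and runs are assembled one SNP at
#' a time.  Quadratic and intended for small inputs (hundreds of SNPs per
#' chromosome) as ground truth in tests.
#'
#' @inheritParams call_segments
#' @return data.frame of segments, identical in layout to [call_segments()].
#' @export
brute_force_roh <- function(matrix, params = roh_params()) {
  stopifnot(inherits(matrix, "genotype_matrix"),
            inherits(params, "roh_params"))
  rows <- list()
  for (cn in names(matrix$chroms)) {
    ch <- matrix$chroms[[cn]]
    pos <- ch$pos
    n <- length(pos)
    w <- min(params$window_snps, n)
    for (s in matrix$samples) {
      calls <- ch$calls[s, ]
      ## every window, recounted naively
      win_ok <- logical(n - w + 1L)
      for (a in seq_len(n - w + 1L)) {
        nh <- 0L; nm <- 0L
        for (b in a:(a + w - 1L)) {
          if (is.na(calls[b])) nm <- nm + 1L
          else if (calls[b] == 1L) nh <- nh + 1L
        }
        win_ok[a] <- nh <= params$window_max_het &&
          nm <= params$window_max_missing
      }
      ## per-SNP eligibility by scanning all windows containing it
      eligible <- logical(n)
      for (i in seq_len(n)) {
        cnt <- 0L; tot <- 0L
        for (a in seq_along(win_ok)) {
          if (a <= i && i <= a + w - 1L) {
            tot <- tot + 1L
            if (win_ok[a]) cnt <- cnt + 1L
          }
        }
        eligible[i] <- tot > 0L && cnt / tot >= params$snp_hit_threshold
      }
      ## exhaustive run construction
      i <- 1L
      while (i <= n) {
        if (!eligible[i]) { i <- i + 1L; next }
        j <- i
        while (j < n && eligible[j + 1L] &&
               pos[j + 1L] - pos[j] <= params$max_gap_bp) j <- j + 1L
        n_snp <- j - i + 1L
        len <- pos[j] - pos[i] + 1
        if (n_snp >= params$min_snps && len >= params$min_length_bp &&
            len / n_snp <= params$min_density_bp_per_snp)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, chrom = cn, start = pos[i], end = pos[j],
            n_snps = n_snp, length_bp = len,
            n_het = sum(calls[i:j] == 1L, na.rm = TRUE),
            n_missing = sum(is.na(calls[i:j])),
            stringsAsFactors = FALSE)
        i <- j + 1L
      }
    }
  }
  if (!length(rows)) return(empty_segments())
  sort_segments(do.call(rbind, rows))
}
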