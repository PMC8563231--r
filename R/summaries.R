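#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH = L_ROH / L_genome`: the ratio of the total length of the genome
#' covered by ROH to the total length of the genome covered by SNPs.
#'
#' @param l_roh total ROH length in bp (one individual, or a population
#'   total).
#' @param l_genome SNP-covered genome length in bp.
#' @return the inbreeding coefficient, a fraction in `[0, 1]`.
#' @examples
#' compute_froh(1274547767, 2435262063)  # 0.5234
#' @export
compute_froh <- function(l_roh, l_genome) {
  if (length(l_genome) != 1L || is.na(l_genome) || l_genome <= 0)
    stop("l_genome must be a single positive length")
  if (any(is.na(l_roh)) || any(l_roh < 0))
    stop("l_roh must be non-negative")
  if (any(l_roh > l_genome))
    stop("l_roh exceeds l_genome: inconsistent inputs")
  l_roh / l_genome
}

#' SNP-covered genome span
#'
#' Sum over chromosomes of `last SNP position - first SNP position + 1`:
#' the denominator of `F_ROH`.
#'
#' @param matrix a [genotype_matrix()].
#' @return total span in bp.
#' @export
genome_span <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (length(matrix$chroms) == 0L) stop("empty genotype matrix")
  sum(chrom_spans(matrix))
}

#' Per-chromosome SNP-covered spans
#' @param matrix a [genotype_matrix()].
#' @return named numeric vector of spans in bp.
#' @export
chrom_spans <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  vapply(matrix$chroms, function(ch) max(ch$pos) - min(ch$pos) + 1,
         numeric(1))
}

#' Per-sample F_ROH
#'
#' Sums each sample's segment lengths (`L_ROH`) and divides by the
#' SNP-covered genome span of the matrix (`L_genome`).
#'
#' @param segments segment data.frame from [call_segments()].
#' @param matrix the [genotype_matrix()] the segments were called on, or
#'   `NULL` if `l_genome` is given directly.
#' @param l_genome SNP-covered genome length in bp; computed from `matrix`
#'   by default.
#' @return data.frame with columns `sample`, `l_roh_bp`, `froh`, carrying
#'   attributes `l_genome` and `mean_froh`.
#' @export
froh_per_sample <- function(segments, matrix = NULL, l_genome = NULL) {
  if (is.null(l_genome)) {
    if (is.null(matrix)) stop("give either 'matrix' or 'l_genome'")
    l_genome <- genome_span(matrix)
  }
  samples <- if (!is.null(matrix)) matrix$samples
             else sort(unique(segments$sample))
  l_roh <- vapply(samples, function(s)
    sum(segments$length_bp[segments$sample == s]), numeric(1))
  res <- data.frame(sample = samples, l_roh_bp = unname(l_roh),
                    froh = compute_froh(unname(l_roh), l_genome),
                    stringsAsFactors = FALSE)
  attr(res, "l_genome") <- l_genome
  attr(res, "mean_froh") <- mean(res$froh)
  res
}

## round half up to `digits` decimals (2 dp percentage convention)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' ROH length-class summary table
#'
#' Classifies segments into half-open length classes (default
#' `[100, 500)`, `[500, 1000)`, `[1000, Inf)` kb; a segment of exactly
#' 500 kb falls in the second class) and tabulates the count, the percentage
#' of the total count (2 decimals, half-up), the mean and SD of the class
#' lengths in Mb, and the percentage of the genome covered, plus a totals
#' row.  Segments shorter than the first class edge are excluded from the
#' table.
#'
#' @param segments segment data.frame (only `length_bp` is used).
#' @param bounds_kb increasing class edges in kb; the last class is
#'   unbounded above.
#' @param l_genome SNP-covered genome length in bp for the coverage column
#'   (`NA` coverage when omitted).
#' @return data.frame with columns `class`, `n`, `pct`, `mean_mb`, `sd_mb`,
#'   `coverage_pct`; the final row is the total.
#' @export
length_class_table <- function(segments, bounds_kb = c(100, 500, 1000),
                               l_genome = NULL) {
  if (is.unsorted(bounds_kb, strictly = TRUE) || length(bounds_kb) < 1L)
    stop("bounds_kb must be strictly increasing")
  edges_bp <- c(bounds_kb * 1000, Inf)
  labels <- c(paste0(bounds_kb[-length(bounds_kb)], "-",
                     bounds_kb[-1]),
              paste0(">", bounds_kb[length(bounds_kb)]))
  len <- segments$length_bp
  len <- len[!is.na(len) & len >= edges_bp[1]]
  cls <- findInterval(len, edges_bp)          # 1..K
  k <- length(labels)
  n <- tabulate(cls, nbins = k)
  total <- sum(n)
  pct <- if (total > 0) round_half_up(n / total * 100, 2) else rep(0, k)
  mean_mb <- vapply(seq_len(k), function(i)
    if (n[i] > 0) mean(len[cls == i]) / 1e6 else 0, numeric(1))
  sd_mb <- vapply(seq_len(k), function(i)
    if (n[i] > 1) sd(len[cls == i]) / 1e6 else 0, numeric(1))
  cov_pct <- vapply(seq_len(k), function(i) {
    if (is.null(l_genome)) return(NA_real_)
    sum(len[cls == i]) / l_genome * 100
  }, numeric(1))
  out <- data.frame(
    class = c(labels, paste0("total>", bounds_kb[1])),
    n = c(n, total),
    pct = c(pct, if (total > 0) 100 else 0),
    mean_mb = c(mean_mb, if (total > 0) mean(len) / 1e6 else 0),
    sd_mb = c(sd_mb, if (total > 1) sd(len) / 1e6 else 0),
    coverage_pct = c(cov_pct,
                     if (is.null(l_genome)) NA_real_
                     else sum(len) / l_genome * 100),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-chromosome ROH count and coverage
#'
#' For each chromosome: the pooled (all samples) segment count and the mean
#' over samples of the percentage of the chromosome's SNP-covered span lying
#' in ROH — the quantities behind a per-chromosome count/coverage plot.
#'
#' @param segments segment data.frame from [call_segments()].
#' @param matrix the [genotype_matrix()] the segments were called on.
#' @return data.frame with columns `chrom`, `n_roh`, `mean_coverage_pct`.
#' @export
per_chromosome_summary <- function(segments, matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  spans <- chrom_spans(matrix)
  ns <- length(matrix$samples)
  rows <- lapply(names(matrix$chroms), function(cn) {
    seg <- segments[segments$chrom == cn, , drop = FALSE]
    per_sample <- vapply(matrix$samples, function(s)
      sum(seg$length_bp[seg$sample == s]), numeric(1))
    data.frame(chrom = cn, n_roh = nrow(seg),
               mean_coverage_pct = mean(per_sample / spans[[cn]] * 100),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
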