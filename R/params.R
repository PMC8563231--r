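#' ROH calling parameters
#'
#' Every threshold governing the sliding-window homozygosity scan and the
#' segment-level filters.  Defaults follow PLINK v1.07 `--homozyg` behaviour
#' for the window scheme (50-SNP windows, SNP hit threshold 0.05, density
#' 50 kb/SNP, maximum internal gap 1 Mb) combined with the published criteria
#' for this analysis: at most one heterozygous and five missing calls per
#' window, at least 100 SNPs per segment, and a 1 Mb minimum segment length.
#'
#' @param window_snps number of SNPs per sliding window.
#' @param window_max_het maximum heterozygous calls tolerated in a window for
#'   it to count as homozygous.
#' @param window_max_missing maximum missing calls tolerated in a window.
#' @param snp_hit_threshold minimum fraction of homozygous windows covering a
#'   SNP for the SNP to be eligible for inclusion in a run.
#' @param min_snps minimum number of SNPs in an emitted segment.
#' @param min_length_bp minimum physical length (bp) of an emitted segment.
#'   The 1 Mb default suits resequencing-density data; short-ROH summaries
#'   (length classes starting at 100 kb) use `1e5`.
#' @param min_density_bp_per_snp maximum average bp per SNP inside a segment
#'   (i.e. at least one SNP per this many bp).
#' @param max_gap_bp maximum gap (bp) between consecutive SNPs of a run;
#'   larger gaps split the run.
#'
#' @return A list of class `roh_params`.
#' @examples
#' roh_params(min_length_bp = 1e5)
#' @export
roh_params <- function(window_snps = 50L,
                       window_max_het = 1L,
                       window_max_missing = 5L,
                       snp_hit_threshold = 0.05,
                       min_snps = 100L,
                       min_length_bp = 1e6,
                       min_density_bp_per_snp = 5e4,
                       max_gap_bp = 1e6) {
  p <- list(window_snps = as.integer(window_snps),
            window_max_het = as.integer(window_max_het),
            window_max_missing = as.integer(window_max_missing),
            snp_hit_threshold = as.numeric(snp_hit_threshold),
            min_snps = as.integer(min_snps),
            min_length_bp = as.numeric(min_length_bp),
            min_density_bp_per_snp = as.numeric(min_density_bp_per_snp),
            max_gap_bp = as.numeric(max_gap_bp))
  if (p$window_snps < 1L) stop("window_snps must be >= 1")
  if (p$window_max_het < 0L || p$window_max_missing < 0L)
    stop("window allowances must be >= 0")
  if (p$snp_hit_threshold < 0 || p$snp_hit_threshold > 1)
    stop("snp_hit_threshold must be in [0, 1]")
  if (p$min_snps < 1L) stop("min_snps must be >= 1")
  if (p$min_length_bp <= 0) stop("min_length_bp must be > 0")
  if (p$min_density_bp_per_snp <= 0) stop("min_density_bp_per_snp must be > 0")
  if (p$max_gap_bp <= 0) stop("max_gap_bp must be > 0")
  class(p) <- "roh_params"
  p
}

#' @exportS3Method base::print
print.roh_params <- function(x, ...) {
  cat("ROH calling parameters:\n")
  cat(sprintf("  window: %d SNPs, <= %d het, <= %d missing; SNP hit threshold %.3g\n",
              x$window_snps, x$window_max_het, x$window_max_missing,
              x$snp_hit_threshold))
  cat(sprintf("  segment: >= %d SNPs, >= %s bp, <= %s bp/SNP, gap <= %s bp\n",
              x$min_snps, format(x$min_length_bp, big.mark = ","),
              format(x$min_density_bp_per_snp, big.mark = ","),
              format(x$max_gap_bp, big.mark = ",")))
  invisible(x)
}

#' Simulation configuration for synthetic autozygous genomes
#'
#' Defines the synthetic study: diploid genotypes on a shared SNP panel with
#' autozygous tracts implanted per sample at known locations.  Inside a tract
#' every site is homozygous apart from a small heterozygous-call error rate;
#' outside tracts, sites are heterozygous at the background rate typical of
#' segregating SNP sites.  Any call may additionally be missing.
#'
#' @param n_samples number of diploid individuals.
#' @param chromosomes named numeric vector of chromosome lengths in bp,
#'   e.g. `c("1" = 2e7)`.
#' @param snp_spacing_bp mean inter-SNP distance in bp; gaps are drawn from an
#'   exponential with this mean (rounded, floored at 1 bp).
#' @param target_autozygosity autozygous genome fraction per sample in
#'   `[0, 1]`; scalar (recycled) or one value per sample.
#' @param tract_mean_bp mean of the exponential tract-length distribution.
#' @param tract_min_bp minimum tract length; shorter draws are floored here.
#' @param het_error_rate probability that a site inside a true tract is called
#'   heterozygous (genotyping error).
#' @param missing_rate probability that any call is missing.
#' @param background_het_rate probability that a site outside tracts is
#'   heterozygous.
#' @param forced_tracts optional data.frame with columns `chrom`, `start`,
#'   `end`, `frequency`: intervals implanted as autozygous tracts in a random
#'   `frequency` fraction of samples (for island-recovery experiments).
#' @param low_qual_fraction fraction of sites assigned QUAL below 10
#'   (uniform on `[0, 10)`) to exercise site-quality filtering; remaining
#'   sites draw QUAL uniform on `[20, 60]`.
#' @param seed integer seed; the same configuration always yields
#'   byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(n_samples = 2, chromosomes = c("1" = 5e6),
#'            target_autozygosity = 0.3, seed = 7)
#' @export
sim_config <- function(n_samples = 20L,
                       chromosomes = c("1" = 2e7),
                       snp_spacing_bp = 500,
                       target_autozygosity = 0.3,
                       tract_mean_bp = 2e6,
                       tract_min_bp = 1e5,
                       het_error_rate = 0.001,
                       missing_rate = 0.01,
                       background_het_rate = 0.25,
                       forced_tracts = NULL,
                       low_qual_fraction = 0,
                       seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be a positive integer")
  if (length(chromosomes) == 0L || is.null(names(chromosomes)) ||
      any(!nzchar(names(chromosomes))))
    stop("chromosomes must be a non-empty named vector of lengths")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be > 0")
  if (snp_spacing_bp <= 0) stop("snp_spacing_bp must be > 0")
  ta <- as.numeric(target_autozygosity)
  if (!length(ta) %in% c(1L, n_samples))
    stop("target_autozygosity must be scalar or one value per sample")
  if (any(ta < 0 | ta > 1)) stop("target_autozygosity must be in [0, 1]")
  rates <- c(het_error_rate, missing_rate, background_het_rate,
             low_qual_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (tract_mean_bp <= 0 || tract_min_bp <= 0 || tract_min_bp > tract_mean_bp * 100)
    stop("invalid tract length distribution")
  if (!is.null(forced_tracts)) {
    need <- c("chrom", "start", "end", "frequency")
    if (!is.data.frame(forced_tracts) || !all(need %in% names(forced_tracts)))
      stop("forced_tracts needs columns chrom, start, end, frequency")
    if (any(!as.character(forced_tracts$chrom) %in% names(chromosomes)))
      stop("forced_tracts reference unknown chromosomes")
    if (any(forced_tracts$start > forced_tracts$end) ||
        any(forced_tracts$frequency < 0 | forced_tracts$frequency > 1))
      stop("invalid forced_tracts")
  }
  structure(list(n_samples = n_samples,
                 chromosomes = chromosomes,
                 snp_spacing_bp = as.numeric(snp_spacing_bp),
                 target_autozygosity = rep_len(ta, n_samples),
                 tract_mean_bp = as.numeric(tract_mean_bp),
                 tract_min_bp = as.numeric(tract_min_bp),
                 het_error_rate = as.numeric(het_error_rate),
                 missing_rate = as.numeric(missing_rate),
                 background_het_rate = as.numeric(background_het_rate),
                 forced_tracts = forced_tracts,
                 low_qual_fraction = as.numeric(low_qual_fraction),
                 seed = as.integer(seed)),
            class = "sim_config")
}
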