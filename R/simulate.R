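#' Simulate diploid genotypes with implanted autozygous tracts
#'
#' Generates a shared SNP panel per chromosome (exponential inter-SNP
#' spacing), implants non-overlapping autozygous tracts per sample until each
#' sample's target autozygous fraction is reached, and draws genotype calls:
#' homozygous inside tracts (up to the heterozygous-error rate), heterozygous
#' at the background rate outside, with missingness applied to any call.
#' Tract lengths are exponential with the configured mean, floored at the
#' configured minimum, and placed uniformly among the remaining free
#' intervals; after placement, tracts are extended into adjacent free space
#' so the realised autozygous fraction matches the target closely (within a
#' tract-minimum per chromosome).
#'
#' @param config a [sim_config()].
#' @return A list with components `matrix` (a [genotype_matrix()]) and
#'   `tracts` (data.frame of truth tracts: `sample`, `chrom`, `start`, `end`,
#'   1-based inclusive, sorted, non-overlapping within a sample-chromosome).
#' @examples
#' sim <- simulate_genotypes(sim_config(n_samples = 2,
#'   chromosomes = c("1" = 2e6), target_autozygosity = 0.3, seed = 7))
#' head(sim$tracts)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  chrom_names <- names(config$chromosomes)
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  ## shared SNP panel
  panel <- lapply(chrom_names, function(cn) {
    L <- config$chromosomes[[cn]]
    pos <- draw_positions(L, config$snp_spacing_bp)
    qual <- round(runif(length(pos), 20, 60), 2)
    if (config$low_qual_fraction > 0) {
      low <- runif(length(pos)) < config$low_qual_fraction
      qual[low] <- round(runif(sum(low), 0, 9.99), 2)
    }
    list(pos = pos, qual = qual)
  })
  names(panel) <- chrom_names

  ## per-sample carrier status for forced tracts
  forced <- config$forced_tracts
  carrier <- NULL
  if (!is.null(forced) && nrow(forced) > 0L)
    carrier <- matrix(runif(config$n_samples * nrow(forced)) <= rep(
      forced$frequency, each = config$n_samples),
      nrow = config$n_samples)

  tracts <- vector("list", config$n_samples * length(chrom_names))
  calls <- lapply(chrom_names, function(cn)
    matrix(NA_integer_, nrow = config$n_samples, ncol = length(panel[[cn]]$pos)))
  names(calls) <- chrom_names

  k <- 0L
  for (s in seq_len(config$n_samples)) {
    target <- config$target_autozygosity[s]
    for (cn in chrom_names) {
      L <- config$chromosomes[[cn]]
      fixed <- NULL
      if (!is.null(carrier)) {
        rows <- which(as.character(forced$chrom) == cn & carrier[s, ])
        if (length(rows))
          fixed <- cbind(pmax(1, forced$start[rows]),
                         pmin(L, forced$end[rows]))
      }
      tr <- place_tracts(L, budget = target * L,
                         mean_bp = config$tract_mean_bp,
                         min_bp = config$tract_min_bp,
                         fixed = fixed, saturate = target >= 1)
      k <- k + 1L
      if (nrow(tr))
        tracts[[k]] <- data.frame(sample = samples[s], chrom = cn,
                                  start = tr[, 1], end = tr[, 2],
                                  stringsAsFactors = FALSE)
      calls[[cn]][s, ] <- draw_calls(panel[[cn]]$pos, tr, config)
    }
  }

  tracts <- do.call(rbind, tracts[!vapply(tracts, is.null, logical(1))])
  if (is.null(tracts))
    tracts <- data.frame(sample = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         stringsAsFactors = FALSE)
  tracts <- tracts[order(tracts$sample,
                         match(tracts$chrom, chrom_names),
                         tracts$start), , drop = FALSE]
  rownames(tracts) <- NULL

  chroms <- lapply(chrom_names, function(cn)
    list(pos = panel[[cn]]$pos, qual = panel[[cn]]$qual, calls = calls[[cn]]))
  names(chroms) <- chrom_names
  list(matrix = genotype_matrix(samples, chroms), tracts = tracts)
}

## strictly increasing SNP positions on [1, L], exponential gaps (mean
## spacing, floored at 1 bp); guarantees at least one site
draw_positions <- function(L, spacing) {
  pos <- numeric(0)
  last <- 0
  repeat {
    n <- max(100L, ceiling((L - last) / spacing * 1.2))
    gaps <- pmax(1, round(rexp(n, 1 / spacing)))
    new <- last + cumsum(gaps)
    pos <- c(pos, new[new <= L])
    if (length(new) == 0L || new[length(new)] > L) break
    last <- new[length(new)]
  }
  if (length(pos) == 0L) pos <- ceiling(L / 2)
  pos
}

## place non-overlapping tracts on [1, L] totalling ~budget bp.
## `fixed` (matrix start,end) are pre-placed and count toward the budget.
## Random lengths: exponential(mean_bp) floored at min_bp; starts uniform
## over the free space that can hold the tract.  A final extension pass
## grows tracts into adjacent free space to close the remaining deficit.
place_tracts <- function(L, budget, mean_bp, min_bp, fixed = NULL,
                         saturate = FALSE) {
  if (saturate) return(cbind(1, L))
  tr <- if (is.null(fixed)) matrix(numeric(0), ncol = 2) else fixed
  if (nrow(tr) > 1L) tr <- tr[order(tr[, 1]), , drop = FALSE]
  total <- if (nrow(tr)) sum(tr[, 2] - tr[, 1] + 1) else 0
  free <- free_intervals(L, tr)

  while (budget - total >= min_bp && nrow(free) > 0L) {
    remaining <- budget - total
    len <- min(max(round(rexp(1, 1 / mean_bp)), min_bp), remaining)
    widths <- free[, 2] - free[, 1] + 1
    ok <- which(widths >= len)
    if (!length(ok)) {
      len <- max(widths)
      if (len < min_bp) break
      ok <- which.max(widths)
    }
    slots <- widths[ok] - len + 1
    i <- ok[sample.int(length(ok), 1L, prob = slots)]
    start <- free[i, 1] + floor(runif(1) * (free[i, 2] - free[i, 1] + 2 - len))
    tr <- rbind(tr, c(start, start + len - 1))
    total <- total + len
    free <- split_free(free, i, start, start + len - 1)
  }

  ## extension pass: grow tracts into adjacent free gaps to hit the budget
  if (nrow(tr)) {
    tr <- tr[order(tr[, 1]), , drop = FALSE]
    deficit <- budget - total
    j <- 1L
    while (deficit >= 1 && j <= nrow(tr)) {
      gap_right <- (if (j < nrow(tr)) tr[j + 1L, 1] - 1 else L) - tr[j, 2]
      take <- min(gap_right, deficit)
      if (take > 0) {
        tr[j, 2] <- tr[j, 2] + take
        deficit <- deficit - take
      }
      j <- j + 1L
    }
  }
  tr
}

free_intervals <- function(L, tr) {
  if (!nrow(tr)) return(cbind(1, L))
  tr <- tr[order(tr[, 1]), , drop = FALSE]
  starts <- c(1, tr[, 2] + 1)
  ends <- c(tr[, 1] - 1, L)
  keep <- ends >= starts
  cbind(starts[keep], ends[keep])
}

split_free <- function(free, i, s, e) {
  left <- if (free[i, 1] <= s - 1) c(free[i, 1], s - 1) else NULL
  right <- if (e + 1 <= free[i, 2]) c(e + 1, free[i, 2]) else NULL
  rbind(free[-i, , drop = FALSE], left, right, deparse.level = 0)
}

## zygosity calls for one sample on one chromosome
draw_calls <- function(pos, tr, config) {
  n <- length(pos)
  inside <- rep(FALSE, n)
  if (nrow(tr)) {
    tr <- tr[order(tr[, 1]), , drop = FALSE]
    idx <- findInterval(pos, tr[, 1])
    inside <- idx >= 1L & pos <= tr[pmax(idx, 1L), 2]
  }
  p_het <- ifelse(inside, config$het_error_rate, config$background_het_rate)
  calls <- ifelse(runif(n) < p_het, 1L, 0L)
  calls[runif(n) < config$missing_rate] <- NA_integer_
  as.integer(calls)
}

#' Realised autozygous fraction per sample
#'
#' Total truth-tract length divided by the total simulated genome length.
#'
#' @param tracts truth-tract data.frame from [simulate_genotypes()].
#' @param config the [sim_config()] used to generate them.
#' @return named numeric vector, one fraction per sample.
#' @export
realized_autozygosity <- function(tracts, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- sum(config$chromosomes)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  tot <- vapply(samples, function(s) {
    rows <- tracts$sample == s
    if (!any(rows)) 0 else sum(tracts$end[rows] - tracts$start[rows] + 1)
  }, numeric(1))
  tot / L
}

#' Write a genotype matrix as a VCF 4.2 fixture
#'
#' Emits a minimal, deterministic multi-sample VCF: fixed alleles A/G
#' (allele identity is irrelevant to zygosity-based ROH calling), `GT`-only
#' FORMAT, per-site QUAL, genotypes `0/0` (hom), `0/1` (het) or `./.`
#' (missing).  The file round-trips through [read_vcf()] to an equal matrix.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (sum(n_sites(matrix)) == 0L) stop("empty genotype matrix")
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohscan",
           sprintf("##contig=<ID=%s,length=%s>", names(matrix$chroms),
                   format(vapply(matrix$chroms, function(ch) max(ch$pos),
                                 numeric(1)), scientific = FALSE, trim = TRUE)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", matrix$samples), collapse = "\t"))
  writeLines(hdr, con)
  gt_code <- c("0/0", "0/1")
  for (cn in names(matrix$chroms)) {
    ch <- matrix$chroms[[cn]]
    gt <- matrix(gt_code[ch$calls + 1L], nrow = nrow(ch$calls))
    gt[is.na(ch$calls)] <- "./."
    lines <- paste(cn,
                   format(ch$pos, scientific = FALSE, trim = TRUE),
                   ".", "A", "G",
                   sprintf("%.2f", ch$qual),
                   "PASS", ".", "GT",
                   apply(gt, 2L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write truth tracts as a BED file
#'
#' Converts 1-based inclusive truth tracts to BED's 0-based half-open
#' convention; the BED name column carries the sample id.
#'
#' @param tracts truth-tract data.frame from [simulate_genotypes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(tracts, path) {
  df <- data.frame(chrom = tracts$chrom,
                   start = format(tracts$start - 1, scientific = FALSE,
                                  trim = TRUE),
                   end = format(tracts$end, scientific = FALSE, trim = TRUE),
                   name = tracts$sample)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
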