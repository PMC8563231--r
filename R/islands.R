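#' Per-SNP ROH incidence across individuals
#'
#' For every SNP position in the matrix, the fraction of samples having at
#' least one ROH segment whose `[start, end]` contains the position — the
#' statistic underlying ROH-island detection and the Manhattan plot of ROH
#' frequency.
#'
#' @param segments segment data.frame from [call_segments()] on the same
#'   matrix.
#' @param matrix a [genotype_matrix()].
#' @return An object of class `snp_incidence_track`: a list with
#'   `n_samples` and, per chromosome, `pos` and `incidence` vectors.
#' @export
snp_incidence <- function(segments, matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  unknown <- setdiff(unique(segments$chrom), names(matrix$chroms))
  if (length(unknown))
    stop("segments reference chromosomes absent from the matrix: ",
         paste(unknown, collapse = ", "))
  ns <- length(matrix$samples)
  chroms <- lapply(names(matrix$chroms), function(cn) {
    pos <- matrix$chroms[[cn]]$pos
    covered <- matrix(FALSE, nrow = ns, ncol = length(pos),
                      dimnames = list(matrix$samples, NULL))
    seg <- segments[segments$chrom == cn, , drop = FALSE]
    if (nrow(seg)) {
      i1 <- findInterval(seg$start - 0.5, pos) + 1L  # first pos >= start
      i2 <- findInterval(seg$end, pos)               # last pos <= end
      for (r in seq_len(nrow(seg)))
        if (i1[r] <= i2[r])
          covered[seg$sample[r], i1[r]:i2[r]] <- TRUE
    }
    list(pos = pos, incidence = colSums(covered) / ns)
  })
  names(chroms) <- names(matrix$chroms)
  structure(list(n_samples = ns, chroms = chroms),
            class = "snp_incidence_track")
}

#' @exportS3Method base::print
print.snp_incidence_track <- function(x, ...) {
  ns <- vapply(x$chroms, function(ch) length(ch$pos), numeric(1))
  cat("snp_incidence_track:", x$n_samples, "samples,",
      sum(ns), "SNPs on", length(x$chroms), "chromosomes\n")
  invisible(x)
}

#' Incidence threshold for island calling
#'
#' Either the empirical top-`value` quantile of all SNP incidences
#' (`mode = "quantile"`, nearest-rank: the `ceiling((1 - value) * n)`-th
#' order statistic; `value = 0.01` marks the top 1 percent) or a fixed
#' proportion returned unchanged (`mode = "fixed"`, e.g. `0.30` for a 30
#' percent line).  Both modes are first-class because published practice
#' uses both conventions.
#'
#' @param track a [snp_incidence()] track (ignored in fixed mode).
#' @param mode `"quantile"` or `"fixed"`.
#' @param value tail fraction in `(0, 1)` for quantile mode; proportion in
#'   `[0, 1]` for fixed mode.
#' @return the threshold, a fraction in `[0, 1]`.
#' @export
incidence_threshold <- function(track, mode = c("fixed", "quantile"),
                                value = 0.30) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (value < 0 || value > 1) stop("fixed threshold must be in [0, 1]")
    return(value)
  }
  if (value <= 0 || value >= 1) stop("quantile tail must be in (0, 1)")
  stopifnot(inherits(track, "snp_incidence_track"))
  x <- unlist(lapply(track$chroms, `[[`, "incidence"), use.names = FALSE)
  if (length(x) == 0L) stop("empty incidence track")
  s <- sort(x)
  s[ceiling((1 - value) * length(s))]
}

#' Merge above-threshold SNPs into ROH islands
#'
#' Builds maximal runs of consecutive SNPs with incidence at or above the
#' threshold, tolerating up to `max_gap_snps` consecutive below-threshold
#' SNPs inside a run (default 0), and emits runs with at least `min_snps`
#' above-threshold SNPs.  Island endpoints are the first and last
#' above-threshold SNP of the run; islands never span chromosomes.
#'
#' @param track a [snp_incidence()] track.
#' @param threshold incidence threshold in `[0, 1]` (see
#'   [incidence_threshold()]).
#' @param max_gap_snps below-threshold SNPs tolerated inside an island.
#' @param min_snps minimum above-threshold SNPs per island.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_snps`
#'   (above-threshold members), `n_gap_snps` (tolerated below-threshold
#'   SNPs), `max_incidence`, `mean_incidence` (over members); sorted and
#'   disjoint per chromosome.
#' @export
merge_islands <- function(track, threshold, max_gap_snps = 0L,
                          min_snps = 2L) {
  stopifnot(inherits(track, "snp_incidence_track"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  rows <- list()
  for (cn in names(track$chroms)) {
    ch <- track$chroms[[cn]]
    hot <- which(ch$incidence >= threshold)
    if (!length(hot)) next
    grp <- cumsum(c(1L, diff(hot) - 1L > max_gap_snps))
    for (g in split(hot, grp)) {
      if (length(g) < min_snps) next
      inc <- ch$incidence[g]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = ch$pos[g[1L]], end = ch$pos[g[length(g)]],
        n_snps = length(g),
        n_gap_snps = (g[length(g)] - g[1L] + 1L) - length(g),
        max_incidence = max(inc), mean_incidence = mean(inc),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      n_gap_snps = integer(), max_incidence = numeric(),
                      mean_incidence = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  lev <- unique(out$chrom)[chrom_order(unique(out$chrom))]
  out <- out[order(match(out$chrom, lev), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an incidence track for Manhattan plotting
#'
#' Writes a TSV of `chrom`, `pos`, `incidence` preceded by a comment line
#' recording the threshold, e.g. `# threshold=0.3`; [read_manhattan()]
#' restores both.
#'
#' @param track a [snp_incidence()] track.
#' @param threshold the threshold value to record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
manhattan_export <- function(track, threshold, path) {
  stopifnot(inherits(track, "snp_incidence_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# threshold=%.17g", threshold),
               "chrom\tpos\tincidence"), con)
  for (cn in names(track$chroms)) {
    ch <- track$chroms[[cn]]
    writeLines(paste(cn, fmt_bp(ch$pos), sprintf("%.17g", ch$incidence),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a Manhattan export back into a track
#' @param path file written by [manhattan_export()].
#' @param n_samples number of samples to record on the track (optional).
#' @return list with `track` (a `snp_incidence_track`) and `threshold`.
#' @export
read_manhattan <- function(path, n_samples = NA_integer_) {
  lines <- readLines(path, n = 1L)
  thr <- as.numeric(sub("^# threshold=", "", lines[1]))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c(chrom = "character"))
  chroms <- lapply(split(df, factor(df$chrom, levels = unique(df$chrom))),
                   function(d) list(pos = d$pos, incidence = d$incidence))
  list(track = structure(list(n_samples = n_samples, chroms = chroms),
                         class = "snp_incidence_track"),
       threshold = thr)
}

#' Write islands as BED and TSV
#'
#' @param islands island data.frame from [merge_islands()].
#' @param tsv_path optional TSV path (1-based inclusive, full columns).
#' @param bed_path optional BED path (0-based half-open).
#' @return invisibly, the paths written.
#' @export
write_islands <- function(islands, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- islands
    df$start <- fmt_bp(df$start); df$end <- fmt_bp(df$end)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(islands$chrom, fmt_bp(islands$start - 1),
                      fmt_bp(islands$end),
                      sprintf("island_%d", seq_len(nrow(islands))))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}

#' Manhattan plot of per-SNP ROH incidence
#'
#' Renders the incidence track with a horizontal threshold line (requires
#' \pkg{ggplot2}).
#'
#' @param track a [snp_incidence()] track.
#' @param threshold threshold line to draw.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(track, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_manhattan requires the ggplot2 package")
  stopifnot(inherits(track, "snp_incidence_track"))
  df <- do.call(rbind, lapply(names(track$chroms), function(cn)
    data.frame(chrom = cn, pos = track$chroms[[cn]]$pos,
               incidence = track$chroms[[cn]]$incidence)))
  df$chrom <- factor(df$chrom, levels = names(track$chroms))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                        y = .data$incidence,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "ROH incidence") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "red")
  p
}
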