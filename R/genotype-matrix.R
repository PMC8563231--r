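#' Construct a genotype matrix
#'
#' The internal container for multi-sample diploid genotype calls on a set of
#' chromosomes.  Only zygosity is retained: each call is coded `0` (homozygous,
#' either allele), `1` (heterozygous) or `NA` (missing).  Positions are 1-based
#' base-pair coordinates and must be strictly increasing within a chromosome;
#' all samples share one SNP panel.
#'
#' @param samples character vector of sample identifiers (unique, non-empty).
#' @param chroms named list, one element per chromosome, each a list with
#'   components `pos` (integer/numeric positions, strictly increasing),
#'   `qual` (numeric site quality, same length as `pos`, all `>= 0`) and
#'   `calls` (integer matrix, `length(samples)` rows x `length(pos)` columns,
#'   values in `{0, 1, NA}`).
#'
#' @return An object of class `genotype_matrix`.
#' @seealso [read_vcf()], [simulate_genotypes()]
#' @export
genotype_matrix <- function(samples, chroms) {
  samples <- as.character(samples)
  if (length(samples) == 0L || anyDuplicated(samples) || any(!nzchar(samples)))
    stop("'samples' must be a non-empty vector of unique, non-empty ids")
  if (!is.list(chroms) || length(chroms) == 0L || is.null(names(chroms)) ||
      any(!nzchar(names(chroms))))
    stop("'chroms' must be a non-empty named list")
  for (cn in names(chroms)) {
    ch <- chroms[[cn]]
    if (!all(c("pos", "qual", "calls") %in% names(ch)))
      stop("chromosome '", cn, "' must have components pos, qual, calls")
    pos <- ch$pos
    if (length(pos) == 0L)
      stop("chromosome '", cn, "' has no sites")
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions on chromosome '", cn, "' must be strictly increasing")
    if (any(pos < 1))
      stop("positions on chromosome '", cn, "' must be >= 1")
    if (length(ch$qual) != length(pos) || any(ch$qual < 0, na.rm = TRUE))
      stop("site quality on chromosome '", cn,
           "' must be non-negative and match the number of sites")
    calls <- ch$calls
    if (!is.matrix(calls) || nrow(calls) != length(samples) ||
        ncol(calls) != length(pos))
      stop("calls on chromosome '", cn, "' must be a samples x sites matrix")
    if (!all(calls %in% c(0L, 1L, NA)))
      stop("calls must be coded 0 (hom), 1 (het) or NA (missing)")
    chroms[[cn]]$pos <- as.numeric(pos)
    chroms[[cn]]$qual <- as.numeric(ch$qual)
    storage.mode(chroms[[cn]]$calls) <- "integer"
    rownames(chroms[[cn]]$calls) <- samples
  }
  structure(list(samples = samples, chroms = chroms),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  ns <- vapply(x$chroms, function(ch) length(ch$pos), numeric(1))
  cat("genotype_matrix:", length(x$samples), "samples,",
      length(x$chroms), "chromosomes,", sum(ns), "sites\n")
  for (cn in names(x$chroms)) {
    ch <- x$chroms[[cn]]
    cat(sprintf("  %s: %d sites, span %s-%s bp\n", cn, length(ch$pos),
                format(min(ch$pos), big.mark = ","),
                format(max(ch$pos), big.mark = ",")))
  }
  invisible(x)
}

#' Chromosome names of a genotype matrix
#' @param matrix a [genotype_matrix()].
#' @return character vector of chromosome names.
#' @export
chrom_names <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  names(matrix$chroms)
}

#' Number of sites per chromosome
#' @param matrix a [genotype_matrix()].
#' @return named integer vector.
#' @export
n_sites <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  vapply(matrix$chroms, function(ch) length(ch$pos), integer(1))
}

## order chromosomes numerically where possible ("1" < "2" < "10" < "X")
chrom_order <- function(chroms) {
  num <- suppressWarnings(as.numeric(chroms))
  order(is.na(num), num, chroms)
}

## normalise chromosome naming: strip an optional "chr"/"Chr" prefix
normalize_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))

## empty segment table with the canonical column set
empty_segments <- function() {
  data.frame(sample = character(), chrom = character(),
             start = numeric(), end = numeric(),
             n_snps = integer(), length_bp = numeric(),
             n_het = integer(), n_missing = integer(),
             stringsAsFactors = FALSE)
}

## sort segments by sample, chromosome (natural order), start
sort_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  co <- chrom_order(unique(segments$chrom))
  lev <- unique(segments$chrom)[co]
  o <- order(segments$sample, match(segments$chrom, lev), segments$start)
  res <- segments[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}
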