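#' Intersect ROH islands with gene models
#'
#' Reports every (island, gene) pair on the same chromosome whose 1-based
#' closed intervals overlap by at least `min_overlap_bp` (default 1 bp — the
#' weakest defensible reading of a gene being "harboured" by an island;
#' `containment = TRUE` restricts hits to genes lying entirely inside the
#' island).  Overlap computation is delegated to
#' [IRanges][IRanges::findOverlaps] on [GenomicRanges::GRanges] objects;
#' strand is ignored.  Chromosome names on both sides are normalised by
#' stripping an optional `chr` prefix.
#'
#' @param islands island data.frame from [merge_islands()] (columns `chrom`,
#'   `start`, `end`).
#' @param genes gene data.frame from [read_gene_models()] (columns
#'   `gene_id`, `gene_name`, `chrom`, `start`, `end`).
#' @param min_overlap_bp minimum overlap in bp for a hit.
#' @param containment require the gene to lie entirely within the island.
#' @return data.frame with one row per hit: `chrom`, `island_start`,
#'   `island_end`, `gene_id`, `gene_name`, `gene_start`, `gene_end`,
#'   `overlap_bp` (`min(ends) - max(starts) + 1`).  The attribute
#'   `empty_islands` holds the islands with no hits.
#' @examples
#' isl <- data.frame(chrom = "3", start = 95800000, end = 96000000)
#' gen <- data.frame(gene_id = "CAMKMT", gene_name = "CAMKMT", chrom = "3",
#'                   start = 95854107, end = 95918246)
#' overlap_islands_genes(isl, gen)
#' @export
overlap_islands_genes <- function(islands, genes, min_overlap_bp = 1L,
                                  containment = FALSE) {
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  empty <- data.frame(chrom = character(), island_start = numeric(),
                      island_end = numeric(), gene_id = character(),
                      gene_name = character(), gene_start = numeric(),
                      gene_end = numeric(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(islands) == 0L || nrow(genes) == 0L) {
    attr(empty, "empty_islands") <- islands
    return(empty)
  }
  ig <- GenomicRanges::GRanges(
    normalize_chrom(islands$chrom),
    IRanges::IRanges(start = islands$start, end = islands$end))
  gg <- GenomicRanges::GRanges(
    normalize_chrom(genes$chrom),
    IRanges::IRanges(start = genes$start, end = genes$end))
  if (containment) {
    ## "within" is query-within-subject, so query with the genes
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gg, ig, type = "within",
                                  ignore.strand = TRUE))
    qi <- S4Vectors::subjectHits(hits); gi <- S4Vectors::queryHits(hits)
  } else {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(ig, gg, minoverlap = min_overlap_bp,
                                  ignore.strand = TRUE))
    qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  }
  if (!length(qi)) {
    attr(empty, "empty_islands") <- islands
    return(empty)
  }
  ov <- pmin(islands$end[qi], genes$end[gi]) -
    pmax(islands$start[qi], genes$start[gi]) + 1
  keep <- ov >= min_overlap_bp
  qi <- qi[keep]; gi <- gi[keep]; ov <- ov[keep]
  out <- data.frame(chrom = normalize_chrom(islands$chrom[qi]),
                    island_start = islands$start[qi],
                    island_end = islands$end[qi],
                    gene_id = as.character(genes$gene_id[gi]),
                    gene_name = as.character(genes$gene_name[gi]),
                    gene_start = genes$start[gi],
                    gene_end = genes$end[gi],
                    overlap_bp = ov,
                    stringsAsFactors = FALSE)
  lev <- unique(out$chrom)[chrom_order(unique(out$chrom))]
  out <- out[order(match(out$chrom, lev), out$island_start,
                   out$gene_start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "empty_islands") <-
    islands[-unique(qi), , drop = FALSE]
  out
}

#' Write the candidate-gene report
#'
#' One row per island-gene hit: chromosome, gene location, gene size, gene
#' name and the host island, ordered by chromosome, gene start and gene id.
#' The gene `size_bp` column follows the span convention (`end - start`),
#' the convention under which published candidate-gene tables of this kind
#' reproduce exactly; `size_convention = "inclusive"` reports
#' `end - start + 1` instead.
#'
#' @param hits data.frame from [overlap_islands_genes()].
#' @param path output TSV path.
#' @param size_convention `"span"` (`end - start`) or `"inclusive"`
#'   (`end - start + 1`).
#' @return `path`, invisibly.
#' @export
gene_report <- function(hits, path, size_convention = c("span", "inclusive")) {
  size_convention <- match.arg(size_convention)
  size <- hits$gene_end - hits$gene_start +
    (size_convention == "inclusive")
  df <- data.frame(chrom = hits$chrom,
                   gene_start = fmt_bp(hits$gene_start),
                   gene_end = fmt_bp(hits$gene_end),
                   size_bp = fmt_bp(size),
                   gene_name = hits$gene_name,
                   gene_id = hits$gene_id,
                   island_start = fmt_bp(hits$island_start),
                   island_end = fmt_bp(hits$island_end),
                   overlap_bp = fmt_bp(hits$overlap_bp),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene interval size
#'
#' @param start,end 1-based inclusive coordinates.
#' @param convention `"span"` (`end - start`) or `"inclusive"`
#'   (`end - start + 1`).
#' @return size in bp.
#' @examples
#' gene_size(95854107, 95918246)               # 64139
#' gene_size(48486919, 48499992, "inclusive")  # 13074
#' @export
gene_size <- function(start, end, convention = c("span", "inclusive")) {
  convention <- match.arg(convention)
  if (any(end < start)) stop("end must be >= start")
  end - start + (convention == "inclusive")
}
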