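#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads diploid genotypes from a VCF v4.2 file (plain or bgzipped) via
#' \pkg{vcfR}, keeping biallelic SNPs only, applying the site-quality filter
#' and (optionally) an autosome allow-list.  Genotype calls are collapsed to
#' zygosity: two identical alleles = homozygous, two distinct alleles =
#' heterozygous, any missing allele = missing.  Chromosome names are
#' normalised by stripping an optional `chr` prefix.
#'
#' @param path VCF file.
#' @param min_site_quality sites with `QUAL` below this are excluded
#'   (default 10, the minimum base/site quality used for ROH input regions).
#'   Sites with missing QUAL (`.`) are kept.
#' @param autosomes_only if `TRUE`, keep only chromosomes in `allowed_chroms`.
#' @param allowed_chroms chromosome allow-list used when `autosomes_only`;
#'   defaults to `"1".."18"`, the pig (Sus scrofa) autosomes.
#' @return A [genotype_matrix()].
#' @examples
#' sim <- simulate_genotypes(sim_config(n_samples = 2,
#'   chromosomes = c("1" = 1e6), seed = 1))
#' f <- tempfile(fileext = ".vcf")
#' write_fixture_vcf(sim$matrix, f)
#' gm <- read_vcf(f, autosomes_only = FALSE)
#' @export
read_vcf <- function(path, min_site_quality = 10, autosomes_only = TRUE,
                     allowed_chroms = as.character(1:18)) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) stop("no variant records in ", path)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("no sample genotypes in ", path)
  samples <- colnames(gt_raw)[-1L]

  chrom <- normalize_chrom(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  keep <- !is.na(pos) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) & alt != "." &
    (is.na(qual) | qual >= min_site_quality)
  if (autosomes_only) keep <- keep & chrom %in% normalize_chrom(allowed_chroms)
  if (!any(keep)) stop("no sites pass filters in ", path)

  ## GT is the first FORMAT key per VCF spec; strip any trailing fields
  gt <- sub(":.*$", "", gt_raw[keep, -1L, drop = FALSE])
  chrom <- chrom[keep]; pos <- pos[keep]; qual <- qual[keep]
  qual[is.na(qual)] <- 0

  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  miss <- a1 == "." | a2 == "." | gt == "." | !grepl("[/|]", gt)
  code <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt))
  code[a1 != a2] <- 1L
  code[miss] <- NA_integer_

  lev <- unique(chrom)[chrom_order(unique(chrom))]
  chroms <- lapply(lev, function(cn) {
    i <- which(chrom == cn)
    i <- i[order(pos[i])]
    list(pos = pos[i], qual = qual[i],
         calls = t(code[i, , drop = FALSE]))
  })
  names(chroms) <- lev
  genotype_matrix(samples, chroms)
}

#' Read gene models from GFF3 or BED
#'
#' Imports gene models through \pkg{rtracklayer} and returns them as a
#' data.frame of 1-based inclusive records.  For GFF3, only features of the
#' requested type (default `"gene"`) are kept; BED intervals (0-based
#' half-open on disk) are converted at the boundary.  Chromosome names are
#' normalised by stripping an optional `chr` prefix.
#'
#' @param path gene-model file.
#' @param format `"gff3"` or `"bed"`; guessed from the file extension when
#'   omitted.
#' @param feature_type GFF3 feature type to keep.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed"),
                             feature_type = "gene") {
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed",
                     stop("cannot guess gene-model format from '", path,
                          "'; pass format = \"gff3\" or \"bed\""))
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(mc)) gr <- gr[as.character(mc$type) == feature_type]
    mc <- S4Vectors::mcols(gr)
    id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
          else if ("ID" %in% names(mc)) as.character(mc$ID)
          else as.character(seq_along(gr))
    nm <- if ("Name" %in% names(mc)) as.character(mc$Name)
          else if ("gene" %in% names(mc)) as.character(mc$gene)
          else id
  } else {
    nm <- if ("name" %in% names(mc)) as.character(mc$name)
          else as.character(seq_along(gr))
    id <- nm
  }
  nm[is.na(nm)] <- id[is.na(nm)]
  out <- data.frame(gene_id = id, gene_name = nm,
                    chrom = normalize_chrom(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(out$chrom)[chrom_order(unique(out$chrom))]),
                   out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ROH segments as a tab-separated table
#'
#' Columns (documented header): `sample`, `chrom`, `start`, `end` (1-based
#' inclusive bp), `length_bp`, `kb` (length in kilobases), `n_snps`,
#' `density_bp_per_snp`, `n_het`, `n_missing` — the analogue of a PLINK
#' `.hom` table.  [read_segments()] restores the canonical segment
#' data.frame; `bed_path` additionally exports the intervals as BED
#' (0-based half-open, name = sample).
#'
#' @param segments segment data.frame from [call_segments()].
#' @param path output TSV path.
#' @param bed_path optional BED export path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, bed_path = NULL) {
  df <- data.frame(sample = segments$sample,
                   chrom = segments$chrom,
                   start = fmt_bp(segments$start),
                   end = fmt_bp(segments$end),
                   length_bp = fmt_bp(segments$length_bp),
                   kb = sprintf("%.3f", segments$length_bp / 1000),
                   n_snps = segments$n_snps,
                   density_bp_per_snp = sprintf(
                     "%.3f", segments$length_bp / segments$n_snps),
                   n_het = segments$n_het,
                   n_missing = segments$n_missing,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(segments$chrom, fmt_bp(segments$start - 1),
                      fmt_bp(segments$end), segments$sample)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path TSV path.
#' @return segment data.frame (`sample`, `chrom`, `start`, `end`, `n_snps`,
#'   `length_bp`, `n_het`, `n_missing`).
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment table not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(sample = "character", chrom = "character"))
  if (nrow(df) == 0L) return(empty_segments())
  out <- data.frame(sample = df$sample, chrom = df$chrom,
                    start = as.numeric(df$start), end = as.numeric(df$end),
                    n_snps = as.integer(df$n_snps),
                    length_bp = as.numeric(df$length_bp),
                    n_het = as.integer(df$n_het),
                    n_missing = as.integer(df$n_missing),
                    stringsAsFactors = FALSE)
  sort_segments(out)
}

fmt_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
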