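#' Build a pipeline run configuration
#'
#' A single serialised source of truth for an end-to-end run: input paths,
#' ROH calling parameters, island settings, summary class bounds and seed.
#' Configurations can also be loaded from YAML with [read_run_config()].
#'
#' @param vcf input VCF path.
#' @param genes gene-model path (GFF3 or BED), or `NULL` to skip the gene
#'   report stage.
#' @param out_dir output directory (created if absent).
#' @param params a [roh_params()].
#' @param min_site_quality QUAL filter passed to [read_vcf()].
#' @param autosomes_only,allowed_chroms chromosome filtering for
#'   [read_vcf()].
#' @param island_mode,island_value threshold mode/value for
#'   [incidence_threshold()].
#' @param island_max_gap_snps,island_min_snps run rules for
#'   [merge_islands()].
#' @param bounds_kb length-class edges for [length_class_table()].
#' @param seed integer seed recorded in the manifest (the detection path is
#'   deterministic; the seed matters when the VCF itself is simulated).
#' @param force overwrite existing outputs.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, genes = NULL, out_dir,
                       params = roh_params(),
                       min_site_quality = 10,
                       autosomes_only = FALSE,
                       allowed_chroms = as.character(1:18),
                       island_mode = "fixed", island_value = 0.30,
                       island_max_gap_snps = 0L, island_min_snps = 2L,
                       bounds_kb = c(100, 500, 1000),
                       seed = 1L, force = FALSE, log_level = "info") {
  cfg <- list(vcf = vcf, genes = genes, out_dir = out_dir,
              params = params, min_site_quality = min_site_quality,
              autosomes_only = autosomes_only,
              allowed_chroms = allowed_chroms,
              island_mode = island_mode, island_value = island_value,
              island_max_gap_snps = as.integer(island_max_gap_snps),
              island_min_snps = as.integer(island_min_snps),
              bounds_kb = bounds_kb, seed = as.integer(seed),
              force = isTRUE(force), log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; ROH parameters
#' sit under a `params:` mapping with [roh_params()] argument names.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read (CLI flags beat the
#'   file).
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  pars <- do.call(roh_params, as.list(y$params))
  y$params <- NULL
  args <- utils::modifyList(y, list(...))
  args$params <- pars
  do.call(run_config, args)
}

#' Run the full ROH pipeline
#'
#' Orchestrates read -> detect -> summarise -> islands -> annotate and
#' writes, under `out_dir`: `segments.tsv`, `table1.tsv` (length classes),
#' `per_chrom.tsv`, `froh.tsv`, `incidence.tsv`, `islands.bed` (plus
#' `islands.tsv`), `gene_report.tsv`, and `manifest.json` recording package
#' and R versions, parameters, seed, input checksums and the MD5 of every
#' output.  Re-running with identical config and inputs yields byte-identical
#' outputs; existing outputs are only overwritten with `force = TRUE`.  A
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$vcf))
    stop("pipeline stage 'read_vcf' failed: VCF not found: ", config$vcf)
  if (!is.null(config$genes) && !file.exists(config$genes))
    stop("pipeline stage 'annotate' failed: gene models not found: ",
         config$genes)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- c("segments.tsv", "table1.tsv", "per_chrom.tsv", "froh.tsv",
             "incidence.tsv", "islands.tsv", "islands.bed",
             "gene_report.tsv")
  existing <- files[file.exists(vapply(files, out, character(1)))]
  if (length(existing) && !config$force)
    stop("outputs already exist in ", config$out_dir,
         " (use force = TRUE): ", paste(existing, collapse = ", "))

  log_msg <- function(stage, msg) {
    if (identical(config$log_level, "quiet")) return(invisible())
    message(sprintf("[rohscan] %-10s %s", stage, msg))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_msg(name, sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
    res
  }

  set.seed(config$seed)
  matrix <- stage("read_vcf", read_vcf(
    config$vcf, min_site_quality = config$min_site_quality,
    autosomes_only = config$autosomes_only,
    allowed_chroms = config$allowed_chroms))
  segments <- stage("detect", call_segments(matrix, config$params))
  write_segments(segments, out("segments.tsv"))

  l_genome <- genome_span(matrix)
  stage("summarise", {
    tab1 <- length_class_table(segments, config$bounds_kb, l_genome)
    write_tsv_num(tab1, out("table1.tsv"))
    perc <- per_chromosome_summary(segments, matrix)
    write_tsv_num(perc, out("per_chrom.tsv"))
    froh <- froh_per_sample(segments, matrix)
    write_tsv_num(froh, out("froh.tsv"))
  })

  threshold <- NULL
  stage("islands", {
    track <- snp_incidence(segments, matrix)
    threshold <- incidence_threshold(track, config$island_mode,
                                     config$island_value)
    manhattan_export(track, threshold, out("incidence.tsv"))
    islands <- merge_islands(track, threshold,
                             max_gap_snps = config$island_max_gap_snps,
                             min_snps = config$island_min_snps)
    write_islands(islands, out("islands.tsv"), out("islands.bed"))
    islands
  }) -> islands

  stage("annotate", {
    if (is.null(config$genes)) {
      hits <- overlap_islands_genes(islands,
                                    data.frame(gene_id = character(),
                                               gene_name = character(),
                                               chrom = character(),
                                               start = numeric(),
                                               end = numeric()))
    } else {
      genes <- read_gene_models(config$genes)
      hits <- overlap_islands_genes(islands, genes)
    }
    gene_report(hits, out("gene_report.tsv"))
  })

  manifest <- list(
    tool = "rohscan",
    version = as.character(packageVersion("rohscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    inputs = list(vcf = unname(tools::md5sum(config$vcf)),
                  genes = if (is.null(config$genes)) NULL
                          else unname(tools::md5sum(config$genes))),
    parameters = unclass(config$params),
    island = list(mode = config$island_mode, value = config$island_value,
                  threshold = threshold,
                  max_gap_snps = config$island_max_gap_snps,
                  min_snps = config$island_min_snps),
    bounds_kb = config$bounds_kb,
    n_samples = length(matrix$samples),
    n_segments = nrow(segments),
    n_islands = nrow(islands),
    l_genome_bp = l_genome,
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("manifest", sprintf("%d files, %d segments, %d islands",
                              length(files), nrow(segments), nrow(islands)))
  invisible(manifest)
}

## deterministic numeric TSV writer (full precision, no scientific notation)
write_tsv_num <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
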