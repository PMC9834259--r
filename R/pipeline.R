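#' Pipeline configuration
#'
#' Paths and parameters for the end-to-end analysis: count, filter,
#' normalize, estimate dispersion, test, adjust, call DMRs, annotate,
#' and optionally associate genes and run the DMR-window PCA. Parameter
#' defaults are the analysis defaults used throughout the package:
#' 1000 bp windows, mean-depth filter 10, seed threshold 1e-05,
#' extension threshold 0.1 within 1000 bp, relaxed threshold 0.05, gene
#' distance 10 kb.
#'
#' @param genome_fasta Reference FASTA path.
#' @param sam_dir Directory holding `<sample>.sam` for every design
#'   sample (alternative: `counts_tsv`).
#' @param counts_tsv Pre-computed count matrix TSV (skips counting).
#' @param design_tsv Design table path (`sample`, `group`).
#' @param gff3 Optional gene-model GFF3 for DMR-gene association.
#' @param out_dir Output directory.
#' @param window_size,min_avg_depth,p_seed,p_extend,neighborhood_bp
#'   Analysis parameters (see module functions).
#' @param p_relaxed Relaxed seed threshold for extended-overlap use.
#' @param gene_max_distance Gene association distance in bp.
#' @param contrast Optional `c(numerator, denominator)` group pair.
#' @param rng_seed Seed recorded in the manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, design_tsv, out_dir,
                            sam_dir = NULL, counts_tsv = NULL, gff3 = NULL,
                            window_size = 1000L, min_avg_depth = 10,
                            p_seed = 1e-05, p_extend = 0.1,
                            neighborhood_bp = 1000L, p_relaxed = 0.05,
                            gene_max_distance = 10000L, contrast = NULL,
                            rng_seed = 1L) {
  cfg <- list(genome_fasta = genome_fasta, design_tsv = design_tsv,
              out_dir = out_dir, sam_dir = sam_dir, counts_tsv = counts_tsv,
              gff3 = gff3, window_size = as.integer(window_size),
              min_avg_depth = min_avg_depth, p_seed = p_seed,
              p_extend = p_extend,
              neighborhood_bp = as.integer(neighborhood_bp),
              p_relaxed = p_relaxed,
              gene_max_distance = as.integer(gene_max_distance),
              contrast = contrast, rng_seed = as.integer(rng_seed))
  for (thr in c("p_seed", "p_extend", "p_relaxed"))
    if (cfg[[thr]] <= 0 || cfg[[thr]] >= 1)
      stop("parameter ", thr, " must lie in (0, 1)")
  if (is.null(cfg$sam_dir) && is.null(cfg$counts_tsv))
    stop("one of sam_dir or counts_tsv is required")
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key: value pipeline configuration file
#'
#' One `key: value` per line; `#` comments and blank lines ignored.
#' Numeric-looking values are converted.
#'
#' @param path Config file path.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    suppressWarnings(if (!is.na(as.numeric(v))) as.numeric(v) else v)
  })
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals[names(list(...))] <- list(...)
  do.call(pipeline_config, vals)
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the end-to-end DMR pipeline
#'
#' Executes count -> filter -> normalize -> dispersion -> exact test ->
#' FDR -> DMR calling -> CpG annotation -> optional gene association and
#' DMR-window RPKM PCA, writing TSV/BED artifacts and a manifest (inputs,
#' parameters, versions, seed, per-stage record counts, output
#' checksums) to `out_dir`. Re-running with identical inputs and seed
#' reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("package_version: %s",
                        as.character(utils::packageVersion("medipdmr"))),
                sprintf("rng_seed: %d", config$rng_seed))
  for (p in c("genome_fasta", "design_tsv", "sam_dir", "counts_tsv", "gff3"))
    if (!is.null(config[[p]]))
      manifest <- c(manifest, sprintf("%s: %s", p, config[[p]]))
  for (p in c("window_size", "min_avg_depth", "p_seed", "p_extend",
              "neighborhood_bp", "p_relaxed", "gene_max_distance"))
    manifest <- c(manifest, sprintf("%s: %s", p, config[[p]]))

  genome <- run_stage("genome", read_genome_fasta(config$genome_fasta))
  design <- run_stage("design", read_design_tsv(config$design_tsv))
  windows <- tile_genome(genome, config$window_size)
  .stage_log("tile", paste(nrow(windows), "windows"))

  counts <- run_stage("count", {
    if (!is.null(config$counts_tsv)) read_counts_tsv(config$counts_tsv)
    else {
      sams <- stats::setNames(file.path(config$sam_dir,
                                        paste0(design$sample, ".sam")),
                              design$sample)
      absent <- sams[!file.exists(sams)]
      if (length(absent)) stop("missing SAM file(s): ",
                               paste(absent, collapse = ", "))
      count_reads(sams, windows, design)
    }
  })
  .stage_log("count", paste(nrow(counts$counts), "windows x",
                            ncol(counts$counts), "samples"))
  write_counts_tsv(counts, file.path(config$out_dir, "counts.tsv"))
  manifest <- c(manifest, sprintf("n_windows_total: %d", nrow(counts$counts)))

  filtered <- run_stage("filter", filter_windows(counts, config$min_avg_depth))
  .stage_log("filter", paste(nrow(filtered$counts), "windows retained"))
  manifest <- c(manifest, sprintf("n_windows_tested: %d",
                                  nrow(filtered$counts)))

  factors <- run_stage("normalize", tmm_factors(filtered))
  phi <- run_stage("dispersion",
                   estimate_common_dispersion(filtered, factors))
  .stage_log("dispersion", paste("phi =", signif(phi$phi, 4)))
  manifest <- c(manifest, sprintf("dispersion_phi: %s", .fmt_num(phi$phi)))

  tests <- run_stage("test", exact_test(filtered, factors, phi$phi,
                                        contrast = config$contrast))
  write_results_tsv(tests, file.path(config$out_dir, "results.tsv"))

  dmrs <- run_stage("calldmr",
                    call_dmrs(tests, p_seed = config$p_seed,
                              p_extend = config$p_extend,
                              neighborhood_bp = config$neighborhood_bp))
  dmrs <- run_stage("annotate", annotate_dmrs(dmrs, genome))
  .stage_log("calldmr", paste(nrow(dmrs), "DMRs"))
  manifest <- c(manifest, sprintf("n_dmrs: %d", nrow(dmrs)))
  write_dmr_bed(dmrs, file.path(config$out_dir, "dmrs.bed"))
  write_dmr_tsv(dmrs, file.path(config$out_dir, "dmrs.tsv"))

  assoc <- NULL
  if (!is.null(config$gff3)) {
    genes <- run_stage("genes", read_gene_models(config$gff3))
    assoc <- run_stage("associate",
                       associate_genes(dmrs, genes,
                                       config$gene_max_distance))
    utils::write.table(assoc,
                       file.path(config$out_dir, "gene_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, sprintf("n_gene_associations: %d", nrow(assoc)))
  }

  pca <- NULL
  if (nrow(dmrs) >= 1L && ncol(counts$counts) >= 3L) {
    dmr_windows <- counts$windows[
      overlaps_dmr(counts$windows, dmrs), , drop = FALSE]
    if (nrow(dmr_windows) >= 2L) {
      rpkm <- rpkm_matrix(counts, dmr_windows)
      pca <- run_stage("pca", dmr_pca(rpkm, groups = counts$design$group))
      sc <- data.frame(sample = rownames(pca$scores),
                       group = counts$design$group,
                       PC1 = .fmt_num(pca$scores[, 1]),
                       PC2 = .fmt_num(pca$scores[, 2]))
      utils::write.table(sc, file.path(config$out_dir, "pca_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  outputs <- list.files(config$out_dir, pattern = "\\.(tsv|bed)$",
                        full.names = TRUE)
  sums <- tools::md5sum(outputs)
  manifest <- c(manifest, sprintf("md5_%s: %s", basename(names(sums)), sums))
  manifest_path <- file.path(config$out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  .stage_log("done", paste("manifest at", manifest_path))
  invisible(list(counts = counts, filtered = filtered, factors = factors,
                 dispersion = phi, tests = tests, dmrs = dmrs,
                 associations = assoc, pca = pca,
                 manifest = manifest_path))
}

#' Which windows overlap any DMR span (>= 1 bp)?
#' @param windows Window frame.
#' @param dmrs A `dmr_set` or coordinate data frame.
#' @return Logical vector over `windows` rows.
#' @export
overlaps_dmr <- function(windows, dmrs) {
  if (!nrow(dmrs)) return(rep(FALSE, nrow(windows)))
  IRanges::overlapsAny(.to_granges(windows), .to_granges(dmrs))
}
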