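# Doubles are serialized with %.17g so every TSV round-trips to the exact
# same binary value (and therefore to byte-identical re-writes).
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Write / read a window count matrix as TSV
#'
#' Columns: `chrom`, `start`, `end`, `index`, then one integer column per
#' sample. Library sizes and the design are carried in `#`-prefixed
#' header lines so a filtered matrix round-trips exactly.
#'
#' @param matrix A [medip_counts()].
#' @param path Output TSV path.
#' @return `path` invisibly (write); a [medip_counts()] (read).
#' @export
write_counts_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "medip_counts"))
  hdr <- c(paste0("#library_sizes\t",
                  paste(sprintf("%s=%s", names(matrix$library_sizes),
                                .fmt_num(matrix$library_sizes)),
                        collapse = ";")),
           paste0("#design\t",
                  paste(sprintf("%s=%s", matrix$design$sample,
                                matrix$design$group), collapse = ";")))
  df <- cbind(matrix$windows[c("chrom", "start", "end", "index")],
              as.data.frame(matrix$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts TSV not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  parse_meta <- function(tag) {
    ln <- meta[startsWith(meta, paste0("#", tag))]
    if (!length(ln)) return(NULL)
    kv <- strsplit(strsplit(ln, "\t")[[1]][2], ";")[[1]]
    parts <- strsplit(kv, "=")
    stats::setNames(vapply(parts, `[[`, character(1), 2L),
                    vapply(parts, `[[`, character(1), 1L))
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  .check_columns(df, c("chrom", "start", "end", "index"), "counts TSV")
  samples <- setdiff(names(df), c("chrom", "start", "end", "index"))
  if (!length(samples)) stop("schema error in counts TSV: no sample columns")
  counts <- as.matrix(df[samples])
  storage.mode(counts) <- "integer"
  lib_raw <- parse_meta("library_sizes")
  des_raw <- parse_meta("design")
  design <- if (is.null(des_raw))
    data.frame(sample = samples, group = NA_character_) else
      data.frame(sample = names(des_raw), group = unname(des_raw),
                 stringsAsFactors = FALSE)
  lib <- if (is.null(lib_raw)) NULL else
    stats::setNames(as.numeric(lib_raw), names(lib_raw))
  medip_counts(df[c("chrom", "start", "end", "index")], counts, design,
               library_sizes = lib)
}

#' Write / read per-window test results as TSV
#'
#' Columns: `chrom`, `start`, `end`, `index`, `log2fc`, `p_value`,
#' `fdr`; dispersion and contrast are carried in `#` header lines.
#'
#' @param results A `window_tests` data frame.
#' @param path TSV path.
#' @export
write_results_tsv <- function(results, path) {
  .check_columns(results, c("chrom", "start", "end", "log2fc",
                            "p_value", "fdr"), "results")
  hdr <- c(sprintf("#phi\t%s", .fmt_num(attr(results, "phi") %||% NA_real_)),
           sprintf("#contrast\t%s",
                   paste(attr(results, "contrast") %||% c("case", "control"),
                         collapse = ";")))
  df <- as.data.frame(results)
  for (col in c("log2fc", "p_value", "fdr")) df[[col]] <- .fmt_num(df[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  if (!file.exists(path)) stop("results TSV not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(tag) {
    ln <- meta[startsWith(meta, paste0("#", tag))]
    if (!length(ln)) NA_character_ else strsplit(ln[1], "\t")[[1]][2]
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_columns(df, c("chrom", "start", "end", "log2fc", "p_value", "fdr"),
                 "results TSV")
  structure(df, class = c("window_tests", "data.frame"),
            phi = as.numeric(get_meta("phi")),
            contrast = strsplit(get_meta("contrast"), ";")[[1]])
}

#' Write DMRs as BED6+ and as a supplemental-style TSV
#'
#' BED columns: chrom, start, end, name, score
#' (`round(-10 log10 min_p)`, capped at 1000), strand ".", then
#' `n_significant_windows`, `log2fc`, `cpg_count`, `cpg_per_100bp`,
#' `fdr_at_min`.
#'
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  stopifnot(inherits(dmrs, "dmr_set"))
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$min_p, 1e-300))))
  df <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$name, score, ".",
                   dmrs$n_significant_windows, .fmt_num(dmrs$log2fc),
                   dmrs$cpg_count, .fmt_num(dmrs$cpg_per_100bp),
                   .fmt_num(dmrs$fdr_at_min))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
write_dmr_tsv <- function(dmrs, path) {
  stopifnot(inherits(dmrs, "dmr_set"))
  df <- as.data.frame(dmrs)
  for (col in c("min_p", "fdr_at_min", "log2fc", "cpg_per_100bp"))
    df[[col]] <- .fmt_num(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_tsv <- function(path) {
  if (!file.exists(path)) stop("DMR TSV not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_columns(df, c("chrom", "start", "end", "name",
                       "n_significant_windows", "min_p", "log2fc"),
                 "DMR TSV")
  structure(df, class = c("dmr_set", "data.frame"))
}

#' Write / read spiked-truth regions as BED (name + signed log2fc)
#' @param truth Truth data frame (`chrom`, `start`, `end`, `log2fc`).
#' @param path BED path.
#' @export
write_truth_bed <- function(truth, path) {
  df <- data.frame(truth$chrom, truth$start, truth$end,
                   sprintf("spike_%03d", seq_len(nrow(truth))),
                   .fmt_num(truth$log2fc))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  if (!file.exists(path)) stop("truth BED not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "log2fc"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric"))
  structure(df[c("chrom", "start", "end", "log2fc")],
            class = c("dmr_truth", "data.frame"))
}

#' Write / read the sample design table (sample_id, group)
#' @param design Data frame with `sample`, `group`.
#' @param path TSV path.
#' @export
write_design_tsv <- function(design, path) {
  .check_columns(design, c("sample", "group"), "design")
  utils::write.table(design[c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("design TSV not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_columns(df, c("sample", "group"), "design TSV")
  df
}

#' Write windows as BED
#' @param windows Window frame from [tile_genome()].
#' @param path BED path.
#' @export
write_windows_bed <- function(windows, path) {
  utils::write.table(windows[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
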