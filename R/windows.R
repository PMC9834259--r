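#' Window-level count matrix with design and library sizes
#'
#' Container for deduplicated MeDIP read counts per (window, sample),
#' the sample design (group labels), and per-sample library sizes.
#' Library sizes are the per-sample totals over ALL windows and are fixed
#' before any depth filtering, so normalization reflects sequencing
#' effort rather than the filter.
#'
#' @param windows Data frame with columns `chrom`, `start`, `end`,
#'   `index` (0-based half-open coordinates, `index` = ordinal within
#'   chromosome), as produced by [tile_genome()].
#' @param counts Integer matrix, rows = windows, columns = samples
#'   (column names are the sample ids).
#' @param design Data frame with columns `sample`, `group` covering every
#'   count column.
#' @param library_sizes Optional named per-sample totals; defaults to the
#'   column sums of `counts` (correct when `counts` covers all windows).
#' @return An object of class `medip_counts`.
#' @export
medip_counts <- function(windows, counts, design, library_sizes = NULL) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end") %in% names(windows)),
            is.matrix(counts), nrow(counts) == nrow(windows))
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (!all(c("sample", "group") %in% names(design)))
    stop("design must have columns 'sample' and 'group'")
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(windows$index))
    windows$index <- stats::ave(seq_len(nrow(windows)), windows$chrom,
                                FUN = seq_along) - 1L
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- library_sizes[colnames(counts)]
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(windows = windows, counts = counts,
                 samples = colnames(counts),
                 library_sizes = library_sizes, design = design),
            class = "medip_counts")
}

#' @export
print.medip_counts <- function(x, ...) {
  cat("medip_counts:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$design$group)),
                                 table(x$design$group)), collapse = ", "), "\n")
  cat("  library sizes:", paste(format(x$library_sizes, trim = TRUE),
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.medip_counts <- function(x) dim(x$counts)

#' @export
summary.medip_counts <- function(object, ...) {
  cat("Windows:", nrow(object$counts), " Samples:", ncol(object$counts), "\n")
  cat("Mean depth per window:",
      round(mean(rowMeans(object$counts)), 2), "\n")
  invisible(object)
}

#' Tile a genome into fixed-size windows
#'
#' Per chromosome, windows are `[0,w), [w,2w), ...` with the final window
#' truncated at the chromosome end; the union covers every base exactly
#' once. Partial final windows are kept — their true length is what RPKM
#' uses downstream.
#'
#' @param genome A [genome_index()].
#' @param window_size Window size in bp (>= 1); the analysis default is
#'   1000 bp.
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `index` (0-based ordinal within chromosome).
#' @export
tile_genome <- function(genome, window_size = 1000L) {
  stopifnot(inherits(genome, "genome_index"))
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("window_size must be >= 1")
  out <- lapply(names(genome$lengths), function(ch) {
    L <- genome$lengths[[ch]]
    starts <- seq.int(0L, L - 1L, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, L),
               index = seq_along(starts) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Reference span consumed by a CIGAR string (M/D/N/=/X operations).
.cigar_ref_span <- function(cigar) {
  spans <- integer(length(cigar))
  ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  for (i in seq_along(cigar)) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", m))
    op <- sub("^\\d+", "", m)
    spans[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  spans
}

# Parse the alignment fields of one plain-text SAM file.
.read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@")]
  rec <- rec[nzchar(rec)]
  if (!length(rec))
    return(list(header = hdr,
                records = data.frame(flag = integer(), rname = character(),
                                     pos = integer(), cigar = character())))
  fields <- strsplit(rec, "\t", fixed = TRUE)
  bad <- lengths(fields) < 11L
  if (any(bad)) stop("malformed SAM record(s) at line(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "))
  list(header = hdr,
       records = data.frame(
         flag = as.integer(vapply(fields, `[[`, character(1), 2L)),
         rname = vapply(fields, `[[`, character(1), 3L),
         pos = as.integer(vapply(fields, `[[`, character(1), 4L)),
         cigar = vapply(fields, `[[`, character(1), 6L),
         stringsAsFactors = FALSE))
}

#' Count deduplicated reads per window and sample
#'
#' Reads one plain-text SAM file per sample, drops unmapped records,
#' removes PCR duplicates — records identical in (chromosome, 5' alignment
#' start, strand) within a sample are collapsed to one — and assigns each
#' retained read to the single window containing its midpoint. The 5'
#' start of a reverse-strand read is its rightmost aligned base. Library
#' sizes are the per-sample retained totals over all windows.
#'
#' @param sam_files Named character vector of SAM paths; names are sample
#'   ids and must all appear in `design$sample`.
#' @param windows Window frame from [tile_genome()].
#' @param design Data frame with columns `sample`, `group`.
#' @return A [medip_counts()].
#' @export
count_reads <- function(sam_files, windows, design) {
  if (is.null(names(sam_files)) || any(!nzchar(names(sam_files))))
    stop("sam_files must be a named vector (names = sample ids)")
  missing <- setdiff(names(sam_files), design$sample)
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  chroms <- unique(windows$chrom)
  counts <- matrix(0L, nrow = nrow(windows), ncol = length(sam_files),
                   dimnames = list(NULL, names(sam_files)))
  lib <- stats::setNames(numeric(length(sam_files)), names(sam_files))
  # per-chromosome row offsets for midpoint -> window lookup
  by_chrom <- split(seq_len(nrow(windows)), windows$chrom)
  for (s in names(sam_files)) {
    sam <- .read_sam(sam_files[[s]])
    r <- sam$records
    r <- r[bitwAnd(r$flag, 4L) == 0L, , drop = FALSE]  # mapped only
    unknown <- !(r$rname %in% chroms)
    if (any(unknown)) {
      warning(sum(unknown), " read(s) on unknown chromosome(s) skipped in ",
              s, ": ", paste(unique(r$rname[unknown]), collapse = ", "))
      r <- r[!unknown, , drop = FALSE]
    }
    if (nrow(r)) {
      span <- .cigar_ref_span(r$cigar)
      strand <- ifelse(bitwAnd(r$flag, 16L) == 16L, "-", "+")
      pos0 <- r$pos - 1L
      five_prime <- ifelse(strand == "-", pos0 + span - 1L, pos0)
      dup <- duplicated(paste(r$rname, five_prime, strand))
      r <- r[!dup, , drop = FALSE]
      span <- span[!dup]
      pos0 <- pos0[!dup]
      mid <- pos0 + span %/% 2L
      for (ch in unique(r$rname)) {
        rows <- by_chrom[[ch]]
        sel <- r$rname == ch
        bin <- findInterval(mid[sel], windows$start[rows])
        ok <- bin >= 1L & mid[sel] < max(windows$end[rows])
        if (any(!ok))
          warning(sum(!ok), " read(s) beyond ", ch, " window span skipped")
        counts[, s] <- counts[, s] +
          tabulate(rows[bin[ok]], nbins = nrow(windows))
      }
    }
    lib[[s]] <- sum(counts[, s])
  }
  medip_counts(windows, counts, design[design$sample %in% names(sam_files), ,
                                       drop = FALSE],
               library_sizes = lib)
}

#' Filter windows by average read depth
#'
#' Retains windows whose mean raw count across all samples (cases and
#' controls pooled) meets `min_avg_depth`; the analysis default keeps
#' windows averaging at least 10 reads. Library sizes are left untouched
#' (they were fixed pre-filter).
#'
#' @param matrix A [medip_counts()].
#' @param min_avg_depth Minimum mean raw count per window (default 10).
#' @return A filtered [medip_counts()]; idempotent.
#' @export
filter_windows <- function(matrix, min_avg_depth = 10) {
  stopifnot(inherits(matrix, "medip_counts"))
  keep <- rowMeans(matrix$counts) >= min_avg_depth
  if (!any(keep))
    stop("all windows fall below min_avg_depth = ", min_avg_depth,
         "; lower the threshold or increase depth")
  out <- matrix
  out$windows <- matrix$windows[keep, , drop = FALSE]
  rownames(out$windows) <- NULL
  out$counts <- matrix$counts[keep, , drop = FALSE]
  out
}
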