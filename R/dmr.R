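#' Call differential methylation regions from window tests
#'
#' Seeds are windows with `p < p_seed`. Each seed's span is iteratively
#' extended: any tested window with `p < p_extend` whose edge-to-edge
#' distance from the current span is at most `neighborhood_bp` is
#' absorbed, until no such window remains; spans that meet or overlap are
#' merged. Equivalently, extension-eligible windows chain transitively
#' whenever consecutive ones are within `neighborhood_bp`, and a chain
#' containing at least one seed becomes a DMR. Windows removed by the
#' depth filter carry no p value: they can be spanned but never trigger
#' or block extension. An immediately adjacent window (gap 0) always
#' qualifies.
#'
#' @param results A `window_tests` data frame (or any data frame with
#'   `chrom`, `start`, `end`, `log2fc`, `p_value`, `fdr`), sorted by
#'   chromosome block and start.
#' @param p_seed Seed threshold (default 1e-05).
#' @param p_extend Extension threshold (default 0.1).
#' @param neighborhood_bp Extension reach in bp, edge-to-edge
#'   (default 1000).
#' @return Data frame of class `dmr_set`: `chrom`, `start`, `end`,
#'   `name` ("chrom:start-end"), `n_significant_windows`, `min_p`,
#'   `fdr_at_min`, `log2fc` (from the minimum-p window), `length_bp`,
#'   and `cpg_count`/`cpg_per_100bp` (NA until [annotate_dmrs()]).
#' @export
call_dmrs <- function(results, p_seed = 1e-05, p_extend = 0.1,
                      neighborhood_bp = 1000L) {
  stopifnot(is.data.frame(results),
            all(c("chrom", "start", "end", "p_value") %in% names(results)))
  if (p_seed <= 0 || p_seed >= 1 || p_extend <= 0 || p_extend >= 1)
    stop("thresholds must lie in (0, 1)")
  if (p_seed > p_extend) stop("p_seed must be <= p_extend")
  ord_ok <- all(vapply(split(results$start, results$chrom),
                       function(s) !is.unsorted(s), logical(1))) &&
    !anyDuplicated(rle(as.character(results$chrom))$values)
  if (!ord_ok) stop("results must be sorted by chromosome block and start")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), n_significant_windows = integer(),
                      min_p = numeric(), fdr_at_min = numeric(),
                      log2fc = numeric(), length_bp = integer(),
                      cpg_count = integer(), cpg_per_100bp = numeric())
  out <- list()
  for (ch in unique(results$chrom)) {
    r <- results[results$chrom == ch, , drop = FALSE]
    ext <- which(r$p_value < p_extend)
    if (!length(ext)) next
    # chain extension-eligible windows whose edge-to-edge gap <= reach
    gap <- r$start[ext][-1] - r$end[ext][-length(ext)]
    cluster <- cumsum(c(1L, as.integer(gap > neighborhood_bp)))
    for (cl in unique(cluster)) {
      idx <- ext[cluster == cl]
      seeds <- idx[r$p_value[idx] < p_seed]
      if (!length(seeds)) next
      span_start <- min(r$start[idx])
      span_end <- max(r$end[idx])
      inside <- r$start >= span_start & r$end <= span_end
      imin <- which(inside)[which.min(r$p_value[inside])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = span_start, end = span_end,
        name = sprintf("%s:%d-%d", ch, span_start, span_end),
        n_significant_windows = length(seeds),
        min_p = r$p_value[imin],
        fdr_at_min = if ("fdr" %in% names(r)) r$fdr[imin] else NA_real_,
        log2fc = if ("log2fc" %in% names(r)) r$log2fc[imin] else NA_real_,
        length_bp = span_end - span_start,
        cpg_count = NA_integer_, cpg_per_100bp = NA_real_)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  structure(res, class = c("dmr_set", "data.frame"),
            p_seed = p_seed, p_extend = p_extend,
            neighborhood_bp = neighborhood_bp)
}

#' Annotate DMRs with CpG count and density from the reference
#'
#' Fills `cpg_count` (CG dinucleotides in the span; a CG straddling the
#' end boundary counts when its C is inside) and
#' `cpg_per_100bp = 100 * cpg_count / length_bp`.
#'
#' @param dmrs A `dmr_set`.
#' @param genome The [genome_index()] the DMRs were called on.
#' @return The annotated `dmr_set`.
#' @export
annotate_dmrs <- function(dmrs, genome) {
  stopifnot(inherits(dmrs, "dmr_set"), inherits(genome, "genome_index"))
  if (!nrow(dmrs)) return(dmrs)
  dmrs$cpg_count <- vapply(seq_len(nrow(dmrs)), function(i)
    count_cpg(genome, dmrs$chrom[i], dmrs$start[i], dmrs$end[i]),
    integer(1))
  dmrs$length_bp <- dmrs$end - dmrs$start
  dmrs$cpg_per_100bp <- 100 * dmrs$cpg_count / dmrs$length_bp
  dmrs
}

#' DMR counts across seed-threshold choices
#'
#' Re-calls DMRs at each seed threshold and tabulates the total number
#' and the number containing at least two significant windows.
#'
#' @param results A `window_tests` data frame.
#' @param thresholds Seed p thresholds, each in (0, 1) and <= `p_extend`.
#' @inheritParams call_dmrs
#' @return Data frame: `threshold`, `all_window_dmrs`,
#'   `multiple_window_dmrs`.
#' @export
threshold_table <- function(results, thresholds, p_extend = 0.1,
                            neighborhood_bp = 1000L) {
  if (any(thresholds >= 1) || any(thresholds <= 0))
    stop("thresholds must lie in (0, 1)")
  if (any(thresholds > p_extend))
    stop("thresholds must not exceed p_extend")
  rows <- lapply(thresholds, function(t) {
    d <- call_dmrs(results, p_seed = t, p_extend = p_extend,
                   neighborhood_bp = neighborhood_bp)
    data.frame(threshold = t, all_window_dmrs = nrow(d),
               multiple_window_dmrs = sum(d$n_significant_windows >= 2L))
  })
  do.call(rbind, rows)
}

#' Histogram of DMRs by significant-window count
#' @param dmrs A `dmr_set`.
#' @return Named integer vector: count of DMRs per number of significant
#'   windows.
#' @export
window_histogram <- function(dmrs) {
  stopifnot(inherits(dmrs, "dmr_set"))
  if (!nrow(dmrs)) return(stats::setNames(integer(0), character(0)))
  tab <- table(dmrs$n_significant_windows)
  stats::setNames(as.integer(tab), names(tab))
}

#' Histogram of DMRs by length class (1 kb / 2 kb / >= 3 kb)
#' @param dmrs A `dmr_set`.
#' @return Named integer vector over classes "1kb", "2kb", ">=3kb".
#' @export
size_histogram <- function(dmrs) {
  stopifnot(inherits(dmrs, "dmr_set"))
  cls <- cut(dmrs$length_bp, breaks = c(-Inf, 1000, 2000, Inf),
             labels = c("1kb", "2kb", ">=3kb"))
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("dmr_set:", nrow(x), "DMR(s) [seed p <", attr(x, "p_seed"),
      ", extend p <", attr(x, "p_extend"), "]\n")
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more)\n", sep = "")
  invisible(x)
}

#' @export
summary.dmr_set <- function(object, ...) {
  cat("DMRs:", nrow(object), "\n")
  if (nrow(object)) {
    cat("  hypermethylated (log2fc > 0):", sum(object$log2fc > 0), "\n")
    cat("  hypomethylated  (log2fc < 0):", sum(object$log2fc < 0), "\n")
    cat("  length classes:\n")
    print(size_histogram(object))
    if (!all(is.na(object$cpg_per_100bp)))
      cat("  median CpG/100bp:",
          round(stats::median(object$cpg_per_100bp, na.rm = TRUE), 2), "\n")
  }
  invisible(object)
}
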