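# 0-based half-open data frame -> GRanges (1-based closed)
.to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and returns gene-type features (all features when
#' no `gene` type is present) with coordinates converted to the
#' package's 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @return Data frame: `gene_id`, `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    paste0("gene", seq_along(gr))
  sym <- if ("Name" %in% names(md)) as.character(md$Name) else id
  data.frame(gene_id = id, symbol = sym,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Associate DMRs with genes within a distance
#'
#' Emits one association per (DMR, gene) pair whose edge-to-edge gap is
#' at most `max_distance` (inclusive; default 10 kb, covering proximal
#' and distal promoter regions). Overlapping pairs get distance 0.
#' Distance is measured to the annotated gene body, not the TSS only. A
#' DMR may associate with several genes and vice versa.
#'
#' @param dmrs A `dmr_set` (or data frame with `chrom`, `start`, `end`,
#'   `name`).
#' @param genes Gene models from [read_gene_models()].
#' @param max_distance Maximum gap in bp (default 10000).
#' @return Data frame: `dmr`, `gene_id`, `symbol`, `distance_bp`.
#' @export
associate_genes <- function(dmrs, genes, max_distance = 10000L) {
  stopifnot(is.data.frame(dmrs), is.data.frame(genes))
  empty <- data.frame(dmr = character(), gene_id = character(),
                      symbol = character(), distance_bp = integer())
  if (!nrow(dmrs) || !nrow(genes)) return(empty)
  lost <- setdiff(unique(dmrs$chrom), unique(genes$chrom))
  if (length(lost))
    message("no gene annotations on chromosome(s): ",
            paste(lost, collapse = ", "))
  gd <- .to_granges(dmrs)
  gg <- .to_granges(genes)
  hits <- GenomicRanges::findOverlaps(gd, gg, maxgap = max_distance)
  if (!length(hits)) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gd[qh], gg[sh])
  nm <- if ("name" %in% names(dmrs)) dmrs$name else
    sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end)
  out <- data.frame(dmr = nm[qh], gene_id = genes$gene_id[sh],
                    symbol = genes$symbol[sh],
                    distance_bp = as.integer(dist),
                    stringsAsFactors = FALSE)
  out[order(out$dmr, out$distance_bp), , drop = FALSE]
}

#' Genomic-overlap Venn analysis of DMR sets
#'
#' Two DMRs from different sets overlap when their genomic spans share
#' at least one base. For each DMR the membership pattern — which named
#' sets it overlaps, plus its own — defines its Venn region; counts are
#' reported per set perspective and pooled.
#'
#' @param dmr_sets Named list of 2-4 `dmr_set` (or coordinate data
#'   frames).
#' @return Object of class `overlap_report`: `sizes` (per-set DMR
#'   counts), `pairwise` (matrix, entry (i, j) = DMRs of set i
#'   overlapping set j), `regions` (data.frame set, pattern, count).
#' @export
venn_overlap <- function(dmr_sets) {
  if (is.null(names(dmr_sets)) || any(!nzchar(names(dmr_sets))))
    stop("dmr_sets must be a named list")
  k <- length(dmr_sets)
  if (k < 2L || k > 4L) stop("venn_overlap supports 2-4 sets, got ", k)
  nms <- names(dmr_sets)
  grs <- lapply(dmr_sets, .to_granges)
  sizes <- vapply(dmr_sets, nrow, integer(1))
  pairwise <- matrix(0L, k, k, dimnames = list(nms, nms))
  member <- lapply(nms, function(a)
    matrix(FALSE, sizes[[a]], k, dimnames = list(NULL, nms)))
  names(member) <- nms
  for (a in nms) {
    for (b in nms) {
      if (sizes[[a]] == 0L) next
      ov <- if (a == b) rep(TRUE, sizes[[a]]) else
        IRanges::overlapsAny(grs[[a]], grs[[b]], minoverlap = 1L)
      member[[a]][, b] <- ov
      pairwise[a, b] <- sum(ov)
    }
  }
  regions <- do.call(rbind, lapply(nms, function(a) {
    if (sizes[[a]] == 0L)
      return(data.frame(set = character(), pattern = character(),
                        count = integer()))
    pat <- apply(member[[a]], 1L, function(m)
      paste(nms[m], collapse = "&"))
    tab <- table(pat)
    data.frame(set = a, pattern = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  structure(list(sizes = sizes, pairwise = pairwise, regions = regions),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("DMR set overlap report\n  sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  cat("  pairwise overlap counts (row overlapping column):\n")
  print(x$pairwise)
  invisible(x)
}

#' Extended overlap of strict DMRs with a relaxed comparison
#'
#' Calls DMRs in a second comparison at a relaxed seed threshold (same
#' extension rule) and reports how many of the strict set's DMRs overlap
#' any relaxed DMR by at least one base, plus that count as a percentage
#' of the strict set.
#'
#' @param strict_dmrs A `dmr_set` called at the strict threshold.
#' @param relaxed_results `window_tests` for the comparison set, over the
#'   same window grid.
#' @param p_relaxed Relaxed seed threshold (default 0.05).
#' @inheritParams call_dmrs
#' @return List: `count`, `percentage`, `n_strict`, `n_relaxed_dmrs`.
#' @export
extended_overlap <- function(strict_dmrs, relaxed_results, p_relaxed = 0.05,
                             p_extend = 0.1, neighborhood_bp = 1000L) {
  stopifnot(is.data.frame(strict_dmrs))
  relaxed <- call_dmrs(relaxed_results, p_seed = p_relaxed,
                       p_extend = max(p_relaxed, p_extend),
                       neighborhood_bp = neighborhood_bp)
  if (!nrow(strict_dmrs)) {
    warning("empty strict DMR set; percentage reported as 0")
    return(list(count = 0L, percentage = 0, n_strict = 0L,
                n_relaxed_dmrs = nrow(relaxed)))
  }
  ov <- if (nrow(relaxed))
    IRanges::overlapsAny(.to_granges(strict_dmrs), .to_granges(relaxed)) else
      rep(FALSE, nrow(strict_dmrs))
  list(count = sum(ov), percentage = 100 * sum(ov) / nrow(strict_dmrs),
       n_strict = nrow(strict_dmrs), n_relaxed_dmrs = nrow(relaxed))
}

#' RPKM matrix for a set of windows
#'
#' RPKM(w, s) = count(w, s) / (length_kb(w) x library_size(s) / 1e6),
#' using raw (pre-normalization) library sizes. Partial windows use
#' their true length.
#'
#' @param matrix A [medip_counts()].
#' @param windows Data frame subset of `matrix$windows` (default: all).
#' @return Numeric matrix, rows = windows ("chrom:start-end"),
#'   columns = samples.
#' @export
rpkm_matrix <- function(matrix, windows = NULL) {
  stopifnot(inherits(matrix, "medip_counts"))
  if (any(matrix$library_sizes == 0)) stop("zero library size")
  if (is.null(windows)) windows <- matrix$windows
  key <- function(w) paste(w$chrom, w$start, w$end)
  idx <- match(key(windows), key(matrix$windows))
  if (anyNA(idx)) stop("requested windows absent from the count matrix")
  len_kb <- (windows$end - windows$start) / 1000
  r <- sweep(matrix$counts[idx, , drop = FALSE], 2L,
             matrix$library_sizes / 1e6, `/`) / len_kb
  rownames(r) <- sprintf("%s:%d-%d", windows$chrom, windows$start,
                         windows$end)
  r
}

#' PCA of samples over DMR-window RPKM
#'
#' Samples are observations and windows are features; features are
#' centered but not scaled (RPKM is already on a common scale).
#' Components come from the covariance decomposition, ordered by
#' decreasing explained variance; each component's sign is fixed by
#' making its largest-magnitude loading positive, so results are fully
#' deterministic.
#'
#' @param rpkm Matrix from [rpkm_matrix()] (windows x samples), needing
#'   at least 3 samples and 2 windows.
#' @param groups Optional per-sample group labels for plotting.
#' @return Object of class `dmr_pca`: `scores` (samples x 2),
#'   `explained_variance` (fractions for PC1, PC2), `groups`.
#' @export
dmr_pca <- function(rpkm, groups = NULL) {
  if (ncol(rpkm) < 3L) stop("PCA needs at least 3 samples")
  if (nrow(rpkm) < 2L) stop("PCA needs at least 2 windows")
  x <- t(rpkm)  # samples as observations
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  npc <- min(2L, ncol(pc$rotation))
  scores <- pc$x[, seq_len(npc), drop = FALSE]
  if (npc < 2L)  # degenerate: pad a zero second component
    scores <- cbind(scores, PC2 = 0)
  for (k in seq_len(npc)) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) scores[, k] <- -scores[, k]
  }
  ev <- if (tot > 0) (pc$sdev^2 / tot) else rep(0, length(pc$sdev))
  ev <- c(ev, 0, 0)[1:2]
  if (tot <= .Machine$double.eps * max(abs(x))^2) {
    scores[] <- 0
    ev <- c(0, 0)
  }
  structure(list(scores = scores, explained_variance = ev,
                 groups = groups), class = "dmr_pca")
}

#' @export
print.dmr_pca <- function(x, ...) {
  cat("dmr_pca:", nrow(x$scores), "samples; explained variance",
      paste(sprintf("PC%d=%.1f%%", 1:2, 100 * x$explained_variance),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dmr_pca <- function(x, ...) {
  col <- if (is.null(x$groups)) "black" else as.integer(factor(x$groups)) + 1L
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 col = col, pch = 19, ...)
  if (!is.null(x$groups))
    graphics::legend("topright", legend = levels(factor(x$groups)),
                     col = seq_along(levels(factor(x$groups))) + 1L, pch = 19)
  invisible(x)
}
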