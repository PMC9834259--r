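#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors between samples. The
#' reference sample is the one whose 75th-percentile count fraction is
#' closest to the across-sample mean of those fractions. For each sample,
#' per-window log2 count-fraction ratios (M) and mean log2 abundances (A)
#' against the reference are computed over windows with positive counts
#' in both; the upper and lower 30% of M and 5% of A are trimmed and the
#' factor is 2 to the precision-weighted mean of the remaining M values
#' (weights = inverse asymptotic binomial variance). Factors are rescaled
#' to geometric mean 1, so they redistribute, not change, total effective
#' library size.
#'
#' @param matrix A [medip_counts()] with at least two samples.
#' @param logratio_trim,abundance_trim Total trim fractions for M and A
#'   (defaults 0.30 and 0.05, the established TMM settings).
#' @return Object of class `tmm_factors`: named numeric factors with
#'   attributes `effective_lib_sizes` (library_size x factor) and
#'   `ref_sample`.
#' @export
tmm_factors <- function(matrix, logratio_trim = 0.30, abundance_trim = 0.05) {
  stopifnot(inherits(matrix, "medip_counts"))
  y <- matrix$counts
  lib <- matrix$library_sizes
  if (ncol(y) < 2L) stop("TMM needs at least 2 samples")
  if (any(lib <= 0)) stop("library sizes must be positive")
  f75 <- apply(y, 2L, stats::quantile, probs = 0.75) / lib
  if (all(f75 == 0)) stop("no usable windows for TMM (all 75th percentiles zero)")
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- y[, ref]
  f <- stats::setNames(rep(1, ncol(y)), colnames(y))
  for (s in seq_len(ncol(y))) {
    if (s == ref) next
    ys <- y[, s]
    use <- ys > 0 & yr > 0
    if (!any(use)) stop("no windows with positive counts in both ",
                        colnames(y)[s], " and the reference")
    ps <- ys[use] / lib[s]
    pr <- yr[use] / lib[ref]
    M <- log2(ps / pr)
    A <- (log2(ps) + log2(pr)) / 2
    # asymptotic variance of M (delta method on two binomial proportions)
    v <- (lib[s] - ys[use]) / (lib[s] * ys[use]) +
         (lib[ref] - yr[use]) / (lib[ref] * yr[use])
    n <- sum(use)
    loM <- floor(n * logratio_trim / 2) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim / 2) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)  # tiny-n safeguard: no trimming
    f[s] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- f / exp(mean(log(f)))
  structure(f, class = "tmm_factors",
            effective_lib_sizes = lib * f,
            ref_sample = colnames(y)[ref])
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:", attr(x, "ref_sample"), ")\n")
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}
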