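#' Conditional negative-binomial exact p value for two group sums
#'
#' Given group-summed counts `y1` (from `n1` samples) and `y2` (from
#' `n2` samples) at common per-sample library size, the test conditions
#' on the total `s = y1 + y2`. Each group sum is negative binomial with
#' mean proportional to its group size and size parameter `n_g / phi`
#' (the dispersion of a sum of `n_g` iid NB counts). The two-sided
#' p value is the total conditional probability of all outcomes no more
#' likely than the observed one (minimum-likelihood rule). At `phi = 0`
#' the conditional law is exactly Binomial(s, n1/(n1+n2)).
#'
#' @param y1,y2 Non-negative integer group sums.
#' @param n1,n2 Group sizes (numbers of samples).
#' @param phi Common NB dispersion (>= 0).
#' @return p value in (0, 1].
#' @export
nb_exact_pvalue <- function(y1, y2, n1, n2, phi) {
  if (phi < 0) stop("phi must be >= 0")
  if (n1 < 1 || n2 < 1) stop("both groups must be nonempty")
  s <- y1 + y2
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    lq <- stats::dbinom(k, s, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- s / (n1 + n2)  # per-sample null mean given the total
    lq <- stats::dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(s - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  q <- exp(lq - max(lq))
  q <- q / sum(q)
  # relative slack keeps mathematically tied outcomes (e.g. the mirror
  # outcome under equal group sizes) together despite rounding
  min(1, sum(q[q <= q[y1 + 1] * (1 + 1e-8)]))
}

#' Per-window negative-binomial exact test
#'
#' Counts are scaled to a common effective library size (pseudo-counts at
#' the geometric mean of the TMM-effective sizes), summed within groups,
#' rounded to the nearest integer, and tested with [nb_exact_pvalue()].
#' The log2 fold change is the ratio of group mean pseudo-counts with a
#' prior count added to each mean; positive values mean a higher
#' methylation signal in the first contrast group.
#'
#' @param matrix A filtered [medip_counts()].
#' @param factors [tmm_factors()] for the matrix (optional; unit factors
#'   if omitted).
#' @param phi Common NB dispersion, e.g. from
#'   [estimate_common_dispersion()].
#' @param contrast Character vector `c(numerator_group,
#'   denominator_group)`; defaults to the two groups in order of first
#'   appearance in the design.
#' @param prior_count Prior added to each group mean for the fold change
#'   (default 0.5), preventing infinite values on zero groups.
#' @return Data frame of class `window_tests`: window coordinates plus
#'   `log2fc`, `p_value`, `fdr` (Benjamini-Hochberg across all tested
#'   windows). Attributes: `phi`, `contrast`, `factors`.
#' @export
exact_test <- function(matrix, factors = NULL, phi, contrast = NULL,
                       prior_count = 0.5) {
  stopifnot(inherits(matrix, "medip_counts"))
  if (phi < 0) stop("phi must be >= 0")
  groups <- matrix$design$group
  if (is.null(contrast)) contrast <- unique(groups)[1:2]
  if (length(contrast) != 2L || !all(contrast %in% groups))
    stop("contrast must name two groups present in the design")
  eff <- if (is.null(factors)) matrix$library_sizes else
    attr(factors, "effective_lib_sizes")
  pseudo <- .pseudo_counts(matrix$counts, eff)
  g1 <- groups == contrast[1]
  g2 <- groups == contrast[2]
  n1 <- sum(g1)
  n2 <- sum(g2)
  s1 <- round(rowSums(pseudo[, g1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, g2, drop = FALSE]))
  p <- vapply(seq_along(s1), function(i)
    nb_exact_pvalue(s1[i], s2[i], n1, n2, phi), numeric(1))
  log2fc <- log2((s1 / n1 + prior_count) / (s2 / n2 + prior_count))
  log2fc[s1 + s2 == 0] <- 0
  out <- cbind(matrix$windows,
               data.frame(log2fc = log2fc, p_value = p, fdr = bh_fdr(p)))
  rownames(out) <- NULL
  structure(out, class = c("window_tests", "data.frame"),
            phi = phi, contrast = contrast,
            factors = if (is.null(factors)) NULL else unclass(factors))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false discovery rate adjustment, order-preserving, computed in
#' a single family across all tested windows.
#'
#' @param p_values Numeric vector of raw p values, each in (0, 1].
#' @return Adjusted p values, same order, each in (0, 1] and >= raw.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' One-call window testing: TMM, dispersion, exact test, FDR
#'
#' Convenience fit for the statistical stage: computes TMM factors,
#' estimates the common dispersion by conditional maximum likelihood,
#' runs the per-window exact test and attaches BH-adjusted p values.
#'
#' @inheritParams exact_test
#' @param min_avg_depth Depth filter applied first (default 10; set 0 to
#'   skip).
#' @return A `window_tests` data frame (see [exact_test()]).
#' @export
test_windows <- function(matrix, contrast = NULL, min_avg_depth = 10,
                         prior_count = 0.5) {
  stopifnot(inherits(matrix, "medip_counts"))
  if (min_avg_depth > 0) matrix <- filter_windows(matrix, min_avg_depth)
  f <- tmm_factors(matrix)
  d <- estimate_common_dispersion(matrix, f)
  exact_test(matrix, f, d$phi, contrast = contrast,
             prior_count = prior_count)
}

#' @export
print.window_tests <- function(x, ...) {
  cat("window_tests:", nrow(x), "windows; contrast",
      paste(attr(x, "contrast"), collapse = " vs "),
      "; phi =", signif(attr(x, "phi"), 4), "\n")
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more)\n", sep = "")
  invisible(x)
}

#' @export
summary.window_tests <- function(object, ...) {
  cat("Tested windows:", nrow(object), "\n")
  for (thr in c(0.05, 1e-3, 1e-5))
    cat(sprintf("  p < %g: %d\n", thr, sum(object$p_value < thr)))
  cat("  min p:", format(min(object$p_value)), "\n")
  invisible(object)
}
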