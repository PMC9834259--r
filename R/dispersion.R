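# Per-window, per-group negative-binomial conditional log-likelihood
# given the group total, at size r = 1/phi. Independent of the mean, and
# defined for non-integer (pseudo) counts through the gamma function:
#   l = sum_j [lgamma(y_j + r) - lgamma(r) - lgamma(y_j + 1)]
#       - [lgamma(s + n r) - lgamma(n r) - lgamma(s + 1)]
.cond_loglik_group <- function(y, r) {
  n <- ncol(y)
  s <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) - rowSums(lgamma(y + 1)) -
    (lgamma(s + n * r) - lgamma(n * r) - lgamma(s + 1))
}

#' Estimate the common negative-binomial dispersion
#'
#' One dispersion phi shared by all windows (variance mu + phi mu^2),
#' estimated by maximizing the sum over windows of the conditional
#' log-likelihood of the within-group counts given each group's total —
#' the conditional likelihood is free of the window means, so no
#' per-window mean need be estimated. Counts are first scaled to a common
#' effective library size (pseudo-counts at the geometric mean), making
#' the within-group counts exchangeable as the conditional argument
#' requires. The search is bounded on phi in [0, 5]; if optimization
#' fails, a method-of-moments estimate is returned with a warning.
#'
#' @param matrix A filtered [medip_counts()].
#' @param factors [tmm_factors()] for the matrix (optional; defaults to
#'   unit factors).
#' @return Object of class `dispersion_estimate`: list with `phi` and
#'   `method` ("qCML" or "moments").
#' @export
estimate_common_dispersion <- function(matrix, factors = NULL) {
  stopifnot(inherits(matrix, "medip_counts"))
  groups <- matrix$design$group
  tab <- table(groups)
  if (length(tab) < 2L || any(tab == 0))
    stop("both groups must be nonempty")
  eff <- if (is.null(factors)) matrix$library_sizes else
    attr(factors, "effective_lib_sizes")
  pseudo <- .pseudo_counts(matrix$counts, eff)
  grp_names <- names(tab)
  obj <- function(log_phi) {
    r <- 1 / exp(log_phi)
    sum(vapply(grp_names, function(g) {
      sum(.cond_loglik_group(pseudo[, groups == g, drop = FALSE], r))
    }, numeric(1)))
  }
  est <- tryCatch({
    opt <- stats::optimize(obj, interval = c(log(1e-6), log(5)),
                           maximum = TRUE, tol = 1e-6)
    phi <- exp(opt$maximum)
    # boundary at the lower end means "indistinguishable from Poisson"
    if (phi <= 1.5e-6) phi <- 0
    list(phi = phi, method = "qCML")
  }, error = function(e) {
    warning("conditional-likelihood optimization failed (", conditionMessage(e),
            "); falling back to method of moments")
    mom <- .moments_dispersion(pseudo, groups)
    list(phi = mom, method = "moments")
  })
  if (!is.finite(est$phi) || est$phi < 0) est$phi <- 0
  structure(est, class = "dispersion_estimate")
}

# Scale counts to the geometric mean of the positive effective library
# sizes; a zero-library sample (all-zero column) stays all zero.
.pseudo_counts <- function(counts, eff) {
  pos <- eff > 0
  if (!any(pos)) stop("all library sizes are zero")
  common <- exp(mean(log(eff[pos])))
  scale <- ifelse(pos, common / eff, 0)
  sweep(counts, 2L, scale, `*`)
}

# Method-of-moments fallback: pooled within-group excess variance.
.moments_dispersion <- function(pseudo, groups) {
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    yg <- pseudo[, groups == g, drop = FALSE]
    if (ncol(yg) < 2L) next
    m <- rowMeans(yg)
    v <- apply(yg, 1L, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  max(0, num / max(den, .Machine$double.eps))
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("Common NB dispersion: phi =", signif(x$phi, 4),
      paste0("(", x$method, ")"),
      "  BCV =", signif(sqrt(x$phi), 3), "\n")
  invisible(x)
}
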