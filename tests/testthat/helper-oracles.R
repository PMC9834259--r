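# Independent oracles and small fixture builders shared across tests.

# Brute-force conditional NB p value, computed from the combinatorial
# form of the conditional law (no dnbinom): for group sums of n1 and n2
# iid NB(mu, phi) counts, P(Y1 = k | Y1 + Y2 = s) is proportional to
#   Gamma(k + n1/phi) / (Gamma(n1/phi) k!) *
#   Gamma(s - k + n2/phi) / (Gamma(n2/phi) (s-k)!)
# because the NB probability parameter is common to both groups and
# cancels. phi = 0 degenerates to Binomial(s, n1/(n1+n2)).
oracle_nb_exact_p <- function(y1, y2, n1, n2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    lw <- lchoose(s, k) + k * log(n1 / (n1 + n2)) +
      (s - k) * log(n2 / (n1 + n2))
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    lw <- lgamma(k + r1) - lfactorial(k) + lgamma(s - k + r2) -
      lfactorial(s - k)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  min(1, sum(w[w <= w[y1 + 1] * (1 + 1e-8)]))
}

# A tiny deterministic genome for window/annotation tests.
tiny_genome <- function(seqs = c(chr1 = strrep("ACGT", 1000),
                                 chr2 = strrep("AT", 800))) {
  genome_index(seqs)
}

# Build a medip_counts directly from a count matrix over uniform windows.
counts_fixture <- function(counts, window_size = 1000L, chrom = "chrIx",
                           groups = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(groups))
    groups <- rep(c("case", "control"), length.out = ncol(counts))
  windows <- data.frame(chrom = chrom,
                        start = (seq_len(n) - 1L) * window_size,
                        end = seq_len(n) * window_size,
                        index = seq_len(n) - 1L)
  medip_counts(windows, counts,
               data.frame(sample = colnames(counts), group = groups))
}

# window_tests-shaped frame from a p-value track over consecutive windows.
p_track <- function(p, chrom = "chr1", window_size = 1000L,
                    log2fc = rep(1, length(p))) {
  n <- length(p)
  structure(data.frame(chrom = chrom,
                       start = (seq_len(n) - 1L) * window_size,
                       end = seq_len(n) * window_size,
                       index = seq_len(n) - 1L,
                       log2fc = log2fc, p_value = p,
                       fdr = bh_fdr(pmin(pmax(p, 1e-300), 1))),
            class = c("window_tests", "data.frame"))
}

# Plain perceptron; returns TRUE when it finds a separating line.
perceptron_separable <- function(x, labels, max_epochs = 2000L) {
  y <- ifelse(labels == labels[1], 1, -1)
  x <- cbind(1, as.matrix(x))
  w <- rep(0, ncol(x))
  for (e in seq_len(max_epochs)) {
    errs <- 0L
    for (i in seq_len(nrow(x))) {
      if (y[i] * sum(w * x[i, ]) <= 0) {
        w <- w + y[i] * x[i, ]
        errs <- errs + 1L
      }
    }
    if (errs == 0L) return(TRUE)
  }
  FALSE
}

# Count CG dinucleotides in a FASTA file with a plain string scan,
# independent of the package's Biostrings-based counter.
scan_fasta_cg <- function(path) {
  lines <- readLines(path)
  seqs <- split(lines[!startsWith(lines, ">")],
                cumsum(startsWith(lines, ">"))[!startsWith(lines, ">")])
  sum(vapply(seqs, function(s) {
    str <- paste(s, collapse = "")
    length(gregexpr("(?=CG)", str, perl = TRUE)[[1]]) *
      (regexpr("CG", str, fixed = TRUE) > 0)
  }, numeric(1)))
}
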