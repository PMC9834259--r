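#' Generate a synthetic reference genome with controlled CpG density
#'
#' Chromosome sequences are drawn iid over {A,C,G,T} with
#' P(C) = P(G) = sqrt(background_cpg_per_100bp / 100), so the expected
#' CG-dinucleotide density equals the configured target. The resulting
#' low-GC composition emulates the CpG-poor ("CpG desert") context in
#' which most MeDIP DMRs are observed. Deterministic given
#' `config$rng_seed`; per-chromosome sub-streams are derived from it so a
#' chromosome's sequence does not depend on how many precede it.
#'
#' @param config A [simulation_config()].
#' @return A [genome_index()] with chromosomes `chr1`, `chr2`, ...
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_sim_config(config)
  q <- sqrt(config$background_cpg_per_100bp / 100)
  probs <- c(A = (1 - 2 * q) / 2, C = q, G = q, T = (1 - 2 * q) / 2)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    with_seed(config$rng_seed * 131L + i, {
      paste(sample(names(probs), config$chromosome_length,
                   replace = TRUE, prob = probs), collapse = "")
    })
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
  genome_index(seqs)
}

# CG-dinucleotide count per tiling window, by chromosome-wide scan.
# A CG whose C lies in the window counts for that window (straddle rule).
.cpg_per_window <- function(genome, windows) {
  cpg <- integer(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    idx <- which(windows$chrom == chrom)
    hits <- Biostrings::matchPattern("CG", genome$seqs[[chrom]])
    cstart0 <- BiocGenerics::start(hits) - 1L  # 0-based C position
    if (length(cstart0)) {
      bin <- findInterval(cstart0, windows$start[idx])
      tab <- tabulate(bin, nbins = length(idx))
      cpg[idx] <- tab
    }
  }
  cpg
}

# Window-aligned, non-overlapping spike placement with a minimum
# separation of `min_gap_windows` between regions. Randomized greedy with
# rejection; errors when the genome cannot host the requested spikes.
.place_spikes <- function(windows, config, min_gap_windows = 3L) {
  n <- config$n_spiked_regions
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), log2fc = numeric()))
  w <- config$window_size
  lens <- config$spike_length_bp
  chroms <- unique(windows$chrom)
  chrom_len <- vapply(chroms, function(ch) max(windows$end[windows$chrom == ch]),
                      numeric(1))
  placed <- data.frame(chrom = character(), start = numeric(), end = numeric())
  spike_len <- sample(lens, n, replace = TRUE)
  gap <- min_gap_windows * w
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      ch <- sample(chroms, 1L)
      max_start_w <- (chrom_len[[ch]] - spike_len[i]) %/% w
      if (max_start_w < 0) next
      s <- sample.int(max_start_w + 1L, 1L) - 1L
      start <- s * w
      end <- start + spike_len[i]
      same <- placed[placed$chrom == ch, , drop = FALSE]
      if (!nrow(same) || all(end + gap <= same$start | start >= same$end + gap)) {
        placed <- rbind(placed, data.frame(chrom = ch, start = start, end = end))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("spike placement failed: cannot fit ", n, " non-overlapping ",
           "regions with ", min_gap_windows, "-window separation; ",
           "enlarge the genome or reduce n_spiked_regions")
  }
  n_up <- round(config$fraction_up * n)
  sign_vec <- rep(-1, n)
  sign_vec[sample.int(n, n_up)] <- 1
  placed$log2fc <- sign_vec * config$spike_log2fc_magnitude
  placed <- placed[order(match(placed$chrom, chroms), placed$start), ]
  rownames(placed) <- NULL
  placed$start <- as.integer(placed$start)
  placed$end <- as.integer(placed$end)
  class(placed) <- c("dmr_truth", "data.frame")
  placed
}

#' Simulate MeDIP window counts with spiked differential regions
#'
#' Per window w and sample s, counts are negative binomial with mean
#' `mu_w * lib_s * effect_ws` and dispersion `phi` (variance
#' `mu + phi mu^2`; `phi = 0` gives Poisson). The window baseline
#' `mu_w` is proportional to `cpg_count_w + 1`, scaled so the genome-wide
#' mean equals `mean_depth_per_window`; the `+1` floor keeps zero-CpG
#' windows at nonzero background so the depth filter is exercisable.
#' Case samples in spiked regions are multiplied by `2^(signed log2fc)`.
#'
#' @param genome A [genome_index()], normally from [generate_genome()].
#' @param config A [simulation_config()].
#' @return A list with `counts` (a [medip_counts()]) and `truth`
#'   (data.frame of spiked regions: chrom, start, end, signed log2fc).
#' @export
simulate_counts <- function(genome, config) {
  stopifnot(inherits(genome, "genome_index"),
            inherits(config, "simulation_config"))
  .validate_sim_config(config)
  windows <- tile_genome(genome, config$window_size)
  cpg <- .cpg_per_window(genome, windows)
  mu_w <- config$mean_depth_per_window * (cpg + 1) / mean(cpg + 1)
  n_case <- config$n_case_samples
  n_ctrl <- config$n_control_samples
  n <- n_case + n_ctrl
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("control_%02d", seq_len(n_ctrl)))
  design <- data.frame(sample = samples,
                       group = rep(c("case", "control"), c(n_case, n_ctrl)),
                       stringsAsFactors = FALSE)
  with_seed(config$rng_seed * 131L + 104729L, {
    lib <- config$library_size_factors
    if (is.null(lib)) lib <- exp(stats::runif(n, log(0.7), log(1.4)))
    truth <- .place_spikes(windows, config)
    effect <- matrix(1, nrow = nrow(windows), ncol = n,
                     dimnames = list(NULL, samples))
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        inside <- windows$chrom == truth$chrom[i] &
          windows$start >= truth$start[i] & windows$end <= truth$end[i]
        effect[inside, seq_len(n_case)] <- 2^truth$log2fc[i]
      }
    }
    mu <- (mu_w * effect) %*% diag(lib)
    counts <- matrix(0L, nrow(windows), n, dimnames = list(NULL, samples))
    if (config$dispersion == 0) {
      counts[] <- as.integer(stats::rpois(length(mu), lambda = mu))
    } else {
      counts[] <- as.integer(stats::rnbinom(length(mu), mu = mu,
                                            size = 1 / config$dispersion))
    }
    cm <- medip_counts(windows, counts, design)
    list(counts = cm, truth = truth)
  })
}

#' Emit aligned SAM records realizing a count matrix
#'
#' Writes one plain-text SAM file per sample. Each counted read becomes a
#' single-end aligned record of ~`read_length` bp whose midpoint falls in
#' its window (midpoints are drawn uniformly without replacement within
#' the window, so distinct reads never share an alignment start). Exact
#' positional duplicates — the PCR artifacts that deduplicated recounting
#' must remove — are added per read with probability `duplicate_rate`, so
#' recounting with duplicate removal recovers the matrix exactly.
#'
#' @param counts A [medip_counts()].
#' @param genome The [genome_index()] the counts refer to.
#' @param dir Output directory for `<sample>.sam` files.
#' @param duplicate_rate Probability, in [0,1), that a read receives one
#'   exact positional duplicate.
#' @param read_length Read length in bp (default 50).
#' @param rng_seed Seed for read placement and duplication.
#' @return Named character vector of SAM paths (names = sample ids).
#' @export
emit_sam <- function(counts, genome, dir, duplicate_rate = 0,
                     read_length = 50L, rng_seed = 1L) {
  stopifnot(inherits(counts, "medip_counts"), inherits(genome, "genome_index"))
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must be in [0, 1)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- as.integer(read_length)
  half <- rl %/% 2L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths),
                      genome$lengths))
  w <- counts$windows
  paths <- stats::setNames(file.path(dir, paste0(counts$samples, ".sam")),
                           counts$samples)
  with_seed(rng_seed * 131L + 15485863L, {
    for (s in counts$samples) {
      lines <- vector("list", nrow(w))
      k_col <- counts$counts[, s]
      nonzero <- which(k_col > 0L)
      for (i in nonzero) {
        k <- k_col[i]
        L <- genome$lengths[[w$chrom[i]]]
        lo <- max(w$start[i], half)
        hi <- min(w$end[i], L - (rl - half))
        if (hi - lo < k)
          stop("window ", w$chrom[i], ":", w$start[i], "-", w$end[i],
               " too small to place ", k, " reads of length ", rl)
        mids <- lo + sample.int(hi - lo, k) - 1L
        pos0 <- mids - half
        strand_rev <- stats::runif(k) < 0.5
        flag <- ifelse(strand_rev, 16L, 0L)
        seqs <- substring(as.character(
          Biostrings::subseq(genome$seqs[[w$chrom[i]]],
                             start = min(pos0) + 1L,
                             end = min(max(pos0) + rl, L))),
          pos0 - min(pos0) + 1L, pos0 - min(pos0) + rl)
        rec <- sprintf("r%s_%d_%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       s, i, seq_len(k), flag, w$chrom[i], pos0 + 1L, rl, seqs)
        dup <- stats::runif(k) < duplicate_rate
        if (any(dup))
          rec <- c(rec, sub("^r", "d", rec[dup]))
        lines[[i]] <- rec
      }
      writeLines(c(header, unlist(lines)), paths[[s]])
    }
  })
  paths
}
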