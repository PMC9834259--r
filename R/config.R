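#' Simulation configuration
#'
#' Parameters for the synthetic MeDIP-seq generator. Defaults emulate the
#' study conditions this package validates itself against: a CpG-poor
#' genome (~2 CpG/100 bp, the density range in which most DMRs are found),
#' 1000 bp analysis windows, negative-binomial counting noise with common
#' dispersion, moderate library-size variation, and spiked differential
#' regions of 1-2 kb with an even hyper/hypo split.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param chromosome_length Length of each chromosome in bp (>= 1).
#' @param background_cpg_per_100bp Target CG-dinucleotide density per
#'   100 bp (the study's DMRs sit predominantly at 1-3 CpG/100 bp).
#' @param n_case_samples,n_control_samples Group sizes (>= 1).
#' @param mean_depth_per_window Mean read count per 1000 bp window at
#'   library-size factor 1.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param library_size_factors Per-sample positive multipliers of library
#'   size, recycled/validated to `n_case_samples + n_control_samples`.
#'   `NULL` draws them log-uniformly from [0.7, 1.4].
#' @param n_spiked_regions Number of spiked differential regions.
#' @param spike_length_bp Spike lengths in bp (window-aligned); a vector is
#'   sampled from per region. Default `c(1000, 2000)`.
#' @param spike_log2fc_magnitude Absolute log2 fold change of spikes (> 0).
#' @param fraction_up Fraction of spikes hypermethylated in cases, in [0,1].
#' @param window_size Analysis window size in bp.
#' @param rng_seed Integer seed; all generator output is deterministic
#'   given the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 2L,
                              chromosome_length = 100000L,
                              background_cpg_per_100bp = 2,
                              n_case_samples = 5L,
                              n_control_samples = 5L,
                              mean_depth_per_window = 30,
                              dispersion = 0.1,
                              library_size_factors = NULL,
                              n_spiked_regions = 10L,
                              spike_length_bp = c(1000L, 2000L),
                              spike_log2fc_magnitude = 2,
                              fraction_up = 0.5,
                              window_size = 1000L,
                              rng_seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              background_cpg_per_100bp = background_cpg_per_100bp,
              n_case_samples = as.integer(n_case_samples),
              n_control_samples = as.integer(n_control_samples),
              mean_depth_per_window = mean_depth_per_window,
              dispersion = dispersion,
              library_size_factors = library_size_factors,
              n_spiked_regions = as.integer(n_spiked_regions),
              spike_length_bp = as.integer(spike_length_bp),
              spike_log2fc_magnitude = spike_log2fc_magnitude,
              fraction_up = fraction_up,
              window_size = as.integer(window_size),
              rng_seed = as.integer(rng_seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.cfg_fail <- function(field, why) {
  stop("invalid simulation_config field '", field, "': ", why, call. = FALSE)
}

.validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) if (!isTRUE(ok)) .cfg_fail(field, why)
  chk(cfg$n_chromosomes >= 1L, "n_chromosomes", "must be >= 1")
  chk(cfg$chromosome_length >= 1L, "chromosome_length", "must be >= 1")
  chk(cfg$background_cpg_per_100bp > 0 && cfg$background_cpg_per_100bp < 25,
      "background_cpg_per_100bp", "must be in (0, 25)")
  chk(cfg$n_case_samples >= 1L, "n_case_samples", "must be >= 1")
  chk(cfg$n_control_samples >= 1L, "n_control_samples", "must be >= 1")
  chk(cfg$mean_depth_per_window > 0, "mean_depth_per_window", "must be > 0")
  chk(cfg$dispersion >= 0 && is.finite(cfg$dispersion),
      "dispersion", "must be finite and >= 0")
  n <- cfg$n_case_samples + cfg$n_control_samples
  if (!is.null(cfg$library_size_factors)) {
    chk(length(cfg$library_size_factors) == n, "library_size_factors",
        paste0("must have length ", n))
    chk(all(cfg$library_size_factors > 0), "library_size_factors",
        "must all be > 0")
  }
  chk(cfg$n_spiked_regions >= 0L, "n_spiked_regions", "must be >= 0")
  chk(all(cfg$spike_length_bp >= cfg$window_size), "spike_length_bp",
      "must be >= window_size")
  chk(all(cfg$spike_length_bp %% cfg$window_size == 0L), "spike_length_bp",
      "must be a multiple of window_size (spikes are window-aligned)")
  chk(cfg$spike_log2fc_magnitude > 0, "spike_log2fc_magnitude", "must be > 0")
  chk(cfg$fraction_up >= 0 && cfg$fraction_up <= 1,
      "fraction_up", "must be in [0, 1]")
  chk(cfg$window_size >= 1L, "window_size", "must be >= 1")
  chk(is.finite(cfg$rng_seed), "rng_seed", "must be a finite integer")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", nm, ": ", if (is.null(v)) "(auto)" else paste(v, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
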