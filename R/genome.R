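#' Genome index: named chromosome sequences with lengths
#'
#' A `genome_index` wraps a [Biostrings::DNAStringSet] of chromosome
#' sequences and provides 0-based half-open sequence slicing, CpG
#' dinucleotide counting, and FASTA round-tripping. All coordinates in
#' this package are 0-based half-open.
#'
#' @param seqs A named `DNAStringSet` (or named character vector) of
#'   chromosome sequences. Names must be unique, lengths positive.
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (!methods::is(seqs, "DNAStringSet"))
    stop("seqs must be a DNAStringSet or named character vector")
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    stop("chromosome names must be present and unique")
  len <- Biostrings::width(seqs)
  if (any(len <= 0)) stop("chromosome lengths must be > 0")
  structure(list(seqs = seqs, lengths = stats::setNames(as.integer(len), nm)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$lengths), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  for (nm in utils::head(names(x$lengths), 8L))
    cat("  ", nm, ": ", x$lengths[[nm]], " bp\n", sep = "")
  if (length(x$lengths) > 8L) cat("  ...\n")
  invisible(x)
}

#' Extract a sequence slice (0-based half-open)
#'
#' @param genome A `genome_index`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; must satisfy
#'   `0 <= start < end <= chromosome length`.
#' @return A character scalar of exactly `end - start` bases.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_index"))
  if (!chrom %in% names(genome$lengths)) stop("unknown chromosome: ", chrom)
  L <- genome$lengths[[chrom]]
  if (start < 0 || end > L || end <= start)
    stop("slice [", start, ",", end, ") outside chromosome ", chrom,
         " (length ", L, ")")
  as.character(Biostrings::subseq(genome$seqs[[chrom]], start = start + 1L,
                                  end = end))
}

#' Count CpG (CG) dinucleotides in a genomic span
#'
#' Counts occurrences of the CG dinucleotide within a 0-based half-open
#' span. A CG straddling the end boundary is counted when its C lies
#' inside the span; a CG straddling the start boundary (C outside) is not.
#'
#' @inheritParams genome_slice
#' @return Integer CG count.
#' @export
count_cpg <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_index"))
  L <- genome$lengths[[chrom]]
  if (is.null(L)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > L || end <= start)
    stop("span [", start, ",", end, ") outside chromosome ", chrom)
  # extend one base past the end (if available) so a straddling C counts
  ext_end <- min(end + 1L, L)
  s <- Biostrings::subseq(genome$seqs[[chrom]], start = start + 1L, end = ext_end)
  Biostrings::countPattern("CG", s)
}

#' Write a genome to FASTA (60-column wrapped)
#' @param genome A `genome_index`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_index"))
  Biostrings::writeXStringSet(genome$seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return A `genome_index`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the name
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  genome_index(seqs)
}
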