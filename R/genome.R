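#' Genome specification
#'
#' A genome is described by an ordered set of chromosomes, each with a
#' physical length in base pairs and a genetic length in centimorgans.
#' The genetic length controls how many crossovers occur per meiosis
#' (expected \code{genetic_length_cM / 100} per chromosome) and therefore
#' how quickly mutagen-induced variants decouple from a selected locus.
#'
#' @param chrom Character vector of unique chromosome names, in the order
#'   used for all downstream output (windows, VCF contigs, plots).
#' @param length_bp Integer vector of physical lengths in bp; all positive.
#' @param genetic_length_cM Numeric vector (recycled) of genetic lengths in
#'   centimorgans; non-negative. A chromosome with 0 cM never recombines.
#' @return A \code{genome_spec}: a data frame with columns \code{chrom},
#'   \code{length_bp} and \code{genetic_length_cM}.
#' @examples
#' genome_spec(c("I", "II"), c(15e6, 16e6), 50)
#' @export
genome_spec <- function(chrom, length_bp, genetic_length_cM = 50) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  genetic_length_cM <- rep_len(as.numeric(genetic_length_cM), length(chrom))
  if (length(chrom) == 0L) {
    stop("a genome needs at least one chromosome")
  }
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique")
  }
  if (length(length_bp) != length(chrom)) {
    stop("'chrom' and 'length_bp' must have the same length")
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  if (any(!is.finite(genetic_length_cM)) || any(genetic_length_cM < 0)) {
    stop("genetic lengths must be non-negative centimorgans")
  }
  structure(
    data.frame(
      chrom = chrom,
      length_bp = length_bp,
      genetic_length_cM = genetic_length_cM,
      stringsAsFactors = FALSE
    ),
    class = c("genome_spec", "data.frame")
  )
}

#' A C. elegans-like default genome
#'
#' Six chromosomes with the physical lengths of the worm reference assembly
#' (I, II, III, IV, V, X) and a genetic length of ~50 cM each, the classic
#' figure for *C. elegans* autosomes.
#'
#' @param genetic_length_cM Genetic length per chromosome in cM (default 50).
#' @return A \code{genome_spec} with six chromosomes totalling ~100 Mb.
#' @export
ce_genome <- function(genetic_length_cM = 50) {
  genome_spec(
    chrom = c("I", "II", "III", "IV", "V", "X"),
    length_bp = c(15072423, 15279345, 13783700, 17493793, 20924149, 17718866),
    genetic_length_cM = genetic_length_cM
  )
}

is_genome_spec <- function(x) inherits(x, "genome_spec")

assert_genome <- function(genome) {
  if (!is_genome_spec(genome)) {
    # accept plain data frames with the right columns
    need <- c("chrom", "length_bp", "genetic_length_cM")
    if (is.data.frame(genome) && all(need %in% names(genome))) {
      genome <- genome_spec(genome$chrom, genome$length_bp,
                            genome$genetic_length_cM)
    } else {
      stop("'genome' must be a genome_spec (see genome_spec())")
    }
  }
  genome
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "genome_spec: %d chromosome(s), %.1f Mb, %.0f cM\n",
    nrow(x), sum(x$length_bp) / 1e6, sum(x$genetic_length_cM)
  ))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
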