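#' Allele-fraction bands for zygosity classification of pooled calls
#'
#' In a pooled sample, zygosity is a statement about the pooled allele
#' fraction, not about any single diploid genotype: a locus heterozygous in
#' every pooled animal sits near an alt fraction of one half, a fixed locus
#' near one. Calls are classified from the alt read fraction \code{af}:
#' \itemize{
#'   \item depth below \code{min_depth}, or zero depth: \code{no_call}
#'   \item \code{af >= hom_alt_min}: \code{hom_alt}
#'   \item \code{het_low <= af <= het_high}: \code{het}
#'   \item \code{af < het_low}: \code{hom_ref}
#'   \item the gap \code{(het_high, hom_alt_min)}: \code{no_call} —
#'     intermediate frequencies are left unlabelled rather than guessed,
#'     which keeps the window peak sharp.
#' }
#'
#' @param het_low,het_high Heterozygous band (defaults 0.3, 0.7).
#' @param hom_alt_min Minimum alt fraction for \code{hom_alt} (default 0.9).
#' @param min_depth Minimum total depth to classify at all (default 10).
#' @return A list of class \code{zygosity_bands}.
#' @export
zygosity_bands <- function(het_low = 0.3, het_high = 0.7,
                           hom_alt_min = 0.9, min_depth = 10L) {
  if (!(0 < het_low && het_low < het_high && het_high < hom_alt_min &&
        hom_alt_min <= 1)) {
    stop("need 0 < het_low < het_high < hom_alt_min <= 1")
  }
  if (min_depth < 1L) stop("min_depth must be >= 1")
  structure(list(het_low = het_low, het_high = het_high,
                 hom_alt_min = hom_alt_min, min_depth = as.integer(min_depth)),
            class = "zygosity_bands")
}

#' Classify zygosity of calls from allele fractions
#'
#' @param calls A \code{variant_calls} data frame with depths present.
#' @param bands A \code{zygosity_bands}.
#' @return Character vector of zygosity labels, one per call.
#' @export
classify_zygosity <- function(calls, bands = zygosity_bands()) {
  total <- calls$ref_depth + calls$alt_depth
  af <- calls$alt_depth / total
  out <- rep("no_call", nrow(calls))
  ok <- !is.na(total) & total >= bands$min_depth
  out[ok & af >= bands$hom_alt_min] <- "hom_alt"
  out[ok & af >= bands$het_low & af <= bands$het_high] <- "het"
  out[ok & af < bands$het_low] <- "hom_ref"
  out
}

#' Remove variants present in the parental strain
#'
#' Keeps the mutant-pool calls whose \code{(chrom, pos, ref, alt)} tuple
#' does not occur among the parental calls. Matching is on the exact tuple:
#' a different alt allele at the same position is a different mutation and
#' is kept.
#'
#' @param mutant_calls,parental_calls \code{variant_calls} data frames.
#' @return The surviving mutant calls.
#' @export
subtract_background <- function(mutant_calls, parental_calls) {
  if (nrow(parental_calls) == 0L || nrow(mutant_calls) == 0L) {
    return(mutant_calls)
  }
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = "\r")
  out <- mutant_calls[!key(mutant_calls) %in% key(parental_calls), ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep high-quality calls
#'
#' Retains calls with \code{qual >= min_qual} (the boundary is inclusive:
#' a call at exactly the threshold survives). Calls with missing quality
#' are dropped and counted in the \code{n_missing_qual} attribute.
#'
#' @param calls A \code{variant_calls} data frame.
#' @param min_qual Minimum phred-scaled quality (default 300).
#' @return The surviving calls, with attribute \code{n_missing_qual}.
#' @export
filter_quality <- function(calls, min_qual = 300) {
  if (min_qual < 0) stop("min_qual must be >= 0")
  missing_q <- is.na(calls$qual)
  out <- calls[!missing_q & calls$qual >= min_qual, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_qual") <- sum(missing_q)
  out
}
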