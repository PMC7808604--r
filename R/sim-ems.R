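#' Induce random EMS variants across a genome
#'
#' Draws \code{n} point mutations at positions uniform over the total
#' physical length (so per-chromosome counts are multinomial with
#' probabilities proportional to chromosome length). By default the
#' substitution signature is the canonical EMS chemistry: G:C -> A:T
#' transitions (a mutated G becomes A, a mutated C becomes T). Exactly one
#' variant is flagged as the causal, phenotype-producing mutation — chosen
#' uniformly unless \code{causal} pins it to a position.
#'
#' @param genome A \code{genome_spec}.
#' @param n Number of variants to induce (>= 1).
#' @param signature \code{"GC_to_AT"} (default, EMS transitions) or
#'   \code{"uniform"} (any base to any other).
#' @param causal \code{NULL} for a uniformly chosen causal variant, an
#'   integer index into the induced set, or a \code{list(chrom =, pos =)}
#'   to place the causal variant at a fixed site.
#' @return Data frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{is_causal}, sorted in genome order.
#' @export
induce_ems <- function(genome, n, signature = c("GC_to_AT", "uniform"),
                       causal = NULL) {
  genome <- assert_genome(genome)
  signature <- match.arg(signature)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  total_bp <- sum(genome$length_bp)
  if (total_bp < 1) stop("zero-length genome")
  if (n > total_bp) {
    stop(sprintf("cannot place %d distinct variants in %.0f bp", n, total_bp))
  }

  draw_sites <- function(k) {
    ci <- sample.int(nrow(genome), k, replace = TRUE,
                     prob = genome$length_bp / total_bp)
    pos <- floor(stats::runif(k) * genome$length_bp[ci]) + 1
    data.frame(chrom = genome$chrom[ci], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }
  sites <- draw_sites(n)
  # resample collisions until all (chrom, pos) are distinct
  for (tries in 1:100) {
    dup <- duplicated(paste(sites$chrom, sites$pos))
    if (!any(dup)) break
    sites[dup, ] <- draw_sites(sum(dup))
  }
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("could not place ", n, " distinct variant positions; genome too small")
  }

  if (signature == "GC_to_AT") {
    ref <- sample(c("G", "C"), n, replace = TRUE)
    alt <- ifelse(ref == "G", "A", "T")
  } else {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  }

  out <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
    is_causal = FALSE, stringsAsFactors = FALSE
  )

  if (is.null(causal)) {
    out$is_causal[sample.int(n, 1L)] <- TRUE
  } else if (is.numeric(causal) && length(causal) == 1L) {
    ci <- as.integer(causal)
    if (ci < 1L || ci > n) stop("causal index out of range")
    out$is_causal[ci] <- TRUE
  } else if (is.list(causal) && all(c("chrom", "pos") %in% names(causal))) {
    if (!causal$chrom %in% genome$chrom) {
      stop("causal chromosome not in genome: ", causal$chrom)
    }
    cl <- genome$length_bp[match(causal$chrom, genome$chrom)]
    if (causal$pos < 1 || causal$pos > cl) stop("causal position out of range")
    k <- sample.int(n, 1L)
    out$chrom[k] <- causal$chrom
    out$pos[k] <- as.integer(causal$pos)
    out$is_causal[k] <- TRUE
    # keep positions distinct after the overwrite
    dup <- duplicated(paste(out$chrom, out$pos)) |
      duplicated(paste(out$chrom, out$pos), fromLast = TRUE)
    dup[k] <- FALSE
    if (any(dup & !out$is_causal)) {
      repl <- draw_sites(sum(dup))
      out$chrom[dup] <- repl$chrom
      out$pos[dup] <- repl$pos
    }
  } else {
    stop("'causal' must be NULL, an index, or list(chrom =, pos =)")
  }

  ord <- order(match(out$chrom, genome$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  out$id <- sprintf("v%04d", seq_len(n))
  rownames(out) <- NULL
  out[, c("id", "chrom", "pos", "ref", "alt", "is_causal")]
}
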