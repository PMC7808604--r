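# map the user-facing mode name onto a zygosity label
mode_to_zygosity <- function(mode) {
  switch(mode,
         hom = "hom_alt",
         het = "het",
         hom_ref = "hom_ref",
         no_call = "no_call",
         stop("unknown mode: ", mode))
}

# tiling windows for one genome: [k w, (k+1) w) per chromosome, last window
# truncated at the chromosome end; 0-based half-open coordinates
genome_windows <- function(genome, window_bp) {
  genome <- assert_genome(genome)
  if (window_bp < 1) stop("window_bp must be >= 1")
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    starts <- seq(0, len - 1, by = window_bp)
    data.frame(
      chrom = genome$chrom[i],
      start = starts,
      end = pmin(starts + window_bp, len),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Count candidate SNPs in sequential genomic windows
#'
#' The mapping statistic: candidate SNPs are counted in non-overlapping
#' windows (1 Mb by default) tiling each chromosome, to expose the region
#' of increased variant density that marks the causal locus. Only calls
#' whose zygosity matches \code{mode} are counted — \code{"hom"}
#' (homozygous SNPs, for viable mutants) or \code{"het"} (heterozygous
#' SNPs, the Het-Map statistic for sterile mutants). A call at 1-based
#' position p falls in the window containing p - 1, so position 1,000,000
#' is counted in [0, 1e6).
#'
#' @param calls \code{variant_calls}, already background-subtracted,
#'   quality-filtered and zygosity-classified.
#' @param genome A \code{genome_spec}.
#' @param window_bp Window size in bp (default 1e6).
#' @param mode Which zygosity class to count: \code{"hom"}, \code{"het"},
#'   \code{"hom_ref"} or \code{"no_call"}.
#' @return Data frame of windows in genome order: \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{n_snps},
#'   \code{mode}.
#' @export
window_density <- function(calls, genome, window_bp = 1e6,
                           mode = c("hom", "het", "hom_ref", "no_call")) {
  genome <- assert_genome(genome)
  mode <- match.arg(mode)
  windows <- genome_windows(genome, window_bp)
  windows$n_snps <- 0L
  windows$mode <- mode

  bad <- which(!calls$chrom %in% genome$chrom)
  if (length(bad)) {
    stop(sprintf("call at %s:%d is on a chromosome not in the genome",
                 calls$chrom[bad[1L]], calls$pos[bad[1L]]))
  }
  use <- calls$zygosity == mode_to_zygosity(mode)
  if (any(use)) {
    chrom <- calls$chrom[use]
    win_in_chrom <- (calls$pos[use] - 1) %/% window_bp
    # index into the tiled window table
    first_win <- match(genome$chrom, windows$chrom)  # first window per chrom
    idx <- first_win[match(chrom, genome$chrom)] + win_in_chrom
    counts <- table(factor(idx, levels = seq_len(nrow(windows))))
    windows$n_snps <- as.integer(counts)
  }
  windows
}

#' Find the window of maximal SNP density
#'
#' Returns the window with the largest \code{n_snps}. Ties are broken
#' deterministically in favour of the earliest window in the order given
#' (genome order, then start, as produced by \code{\link{window_density}}).
#'
#' @param windows Window table from \code{\link{window_density}}.
#' @return The peak window (a one-row data frame).
#' @export
find_peak <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("empty window list: nothing to find a peak in")
  }
  peak <- windows[which.max(windows$n_snps), , drop = FALSE]
  rownames(peak) <- NULL
  peak
}

#' Candidate interval around the density peak
#'
#' The operational "approximate location" of the causal mutation: the
#' maximal run of contiguous windows on the peak's chromosome, containing
#' the peak, in which every window holds at least \code{frac} times the
#' peak count. The run is returned merged into one 0-based half-open
#' interval.
#'
#' @param windows Window table from \code{\link{window_density}}.
#' @param peak Peak window from \code{\link{find_peak}} (recomputed when
#'   omitted).
#' @param frac Fraction of the peak count a window needs to join the run
#'   (default 0.5; in \code{(0, 1]}).
#' @return Data frame with \code{chrom}, \code{start}, \code{end}.
#' @export
candidate_interval <- function(windows, peak = find_peak(windows),
                               frac = 0.5) {
  if (!(frac > 0 && frac <= 1)) stop("frac must be in (0, 1]")
  if (peak$n_snps < 1L) {
    stop("the peak window contains no SNPs; no candidate region to report")
  }
  w <- windows[windows$chrom == peak$chrom, , drop = FALSE]
  w <- w[order(w$start), , drop = FALSE]
  pk <- which(w$start == peak$start)
  if (length(pk) != 1L) stop("peak window not found among the windows")
  ok <- w$n_snps >= frac * peak$n_snps
  lo <- pk
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- pk
  while (hi < nrow(w) && ok[hi + 1L]) hi <- hi + 1L
  data.frame(chrom = peak$chrom, start = w$start[lo], end = w$end[hi],
             stringsAsFactors = FALSE)
}

#' Rank candidate SNPs within an interval
#'
#' Calls inside the interval that match the mapping mode's zygosity,
#' ordered by quality (descending) and then by closeness of the allele
#' fraction to its expectation — 0.5 in het mode (every pooled animal a
#' carrier) or 1.0 in hom mode (the pool fixed for the mutation). Position
#' breaks remaining ties.
#'
#' @param calls Classified \code{variant_calls}.
#' @param interval Data frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), e.g. from \code{\link{candidate_interval}}.
#' @param mode \code{"hom"} or \code{"het"}.
#' @return The ordered candidate calls, with an \code{af} column added.
#' @export
rank_candidates <- function(calls, interval, mode = c("hom", "het")) {
  mode <- match.arg(mode)
  expected_af <- if (mode == "het") 0.5 else 1.0
  inside <- calls$chrom == interval$chrom &
    (calls$pos - 1) >= interval$start & (calls$pos - 1) < interval$end &
    calls$zygosity == mode_to_zygosity(mode)
  out <- calls[inside, , drop = FALSE]
  out$af <- allele_fraction(out)
  out <- out[order(-out$qual, abs(out$af - expected_af), out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a causal mutation from pooled sequencing variant calls
#'
#' The end-to-end mapping pipeline: read the mutant-pool and parental
#' calls, subtract the parental background, keep high-quality SNVs,
#' classify zygosity from pooled allele fractions, count SNPs of the
#' mode's class in sequential windows, locate the density peak, and report
#' the candidate interval with its ranked SNPs. Use \code{mode = "hom"}
#' for viable mutants (pool homozygous for the mutation) and
#' \code{mode = "het"} for sterile mutants mapped through pooled carrier
#' progeny (Het-Map).
#'
#' @param mutant Mutant-pool calls: a \code{variant_calls} data frame or a
#'   path to a VCF file.
#' @param parental Parental-strain calls, same forms accepted.
#' @param genome A \code{genome_spec}.
#' @param mode \code{"hom"} or \code{"het"}.
#' @param window_bp Window size in bp (default 1e6).
#' @param min_qual Quality threshold (default 300, inclusive).
#' @param frac Candidate-interval threshold, see
#'   \code{\link{candidate_interval}}.
#' @param bands \code{\link{zygosity_bands}} for classification.
#' @param out_dir Optional output directory; writes \code{windows.tsv},
#'   \code{interval.bed}, \code{candidates.tsv} and the two diagnostic
#'   plots.
#' @param make_plots Write PNG plots when \code{out_dir} is given
#'   (default \code{TRUE}).
#' @return A list of class \code{mapping_result}: \code{mode},
#'   \code{windows}, \code{peak}, \code{interval}, \code{candidates},
#'   \code{calls} (the classified, filtered calls) and \code{log}
#'   (call counts surviving each stage).
#' @export
map_mutation <- function(mutant, parental, genome, mode = c("hom", "het"),
                         window_bp = 1e6, min_qual = 300, frac = 0.5,
                         bands = zygosity_bands(), out_dir = NULL,
                         make_plots = TRUE) {
  genome <- assert_genome(genome)
  mode <- match.arg(mode)
  if (is.character(mutant)) mutant <- read_vcf(mutant)
  if (is.character(parental)) parental <- read_vcf(parental)

  log <- list(n_mutant_raw = nrow(mutant), n_parental = nrow(parental))
  calls <- subtract_background(mutant, parental)
  log$n_after_background <- nrow(calls)
  calls <- filter_quality(calls, min_qual)
  log$n_missing_qual <- attr(calls, "n_missing_qual")
  log$n_after_quality <- nrow(calls)
  if (nrow(calls) == 0L) {
    stop("no calls survive background subtraction and the quality filter; ",
         "consider relaxing --min-qual")
  }
  calls$zygosity <- classify_zygosity(calls, bands)
  log$n_mode_matched <- sum(calls$zygosity == mode_to_zygosity(mode))
  if (log$n_mode_matched == 0L) {
    stop(sprintf(
      "no %s-classified SNPs among the %d filtered calls; consider the other mapping mode or wider allele-fraction bands",
      mode_to_zygosity(mode), nrow(calls)
    ))
  }

  windows <- window_density(calls, genome, window_bp, mode)
  peak <- find_peak(windows)
  interval <- candidate_interval(windows, peak, frac)
  candidates <- rank_candidates(calls, interval, mode)

  result <- structure(
    list(mode = mode, windows = windows, peak = peak, interval = interval,
         candidates = candidates, calls = calls, log = log,
         params = list(window_bp = window_bp, min_qual = min_qual,
                       frac = frac, bands = bands)),
    class = "mapping_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_windows_tsv(windows, file.path(out_dir, "windows.tsv"))
    write_bed(interval, file.path(out_dir, "interval.bed"))
    write_candidates_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    if (make_plots) {
      plot_snp_scatter(calls, genome, out = file.path(out_dir, "snp_scatter.png"),
                       min_qual = min_qual)
      plot_density_bars(windows, out = file.path(out_dir, "density_bars.png"),
                        peak = peak)
    }
  }
  result
}

write_candidates_tsv <- function(candidates, path) {
  df <- candidates[, c("chrom", "pos", "ref", "alt", "qual",
                       "ref_depth", "alt_depth", "zygosity", "af")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    lines <- paste(df$chrom, df$pos, df$ref, df$alt, fmt_num(df$qual),
                   df$ref_depth, df$alt_depth, df$zygosity,
                   formatC(df$af, format = "g", digits = 6), sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result (%s mode)\n", x$mode))
  cat(sprintf("  calls: %d raw -> %d after background subtraction -> %d after quality filter (%d %s)\n",
              x$log$n_mutant_raw, x$log$n_after_background,
              x$log$n_after_quality, x$log$n_mode_matched,
              mode_to_zygosity(x$mode)))
  cat(sprintf("  peak window: %s:%s-%s (%d SNPs)\n", x$peak$chrom,
              format(x$peak$start, big.mark = ","),
              format(x$peak$end, big.mark = ","), x$peak$n_snps))
  cat(sprintf("  candidate interval: %s:%s-%s (%.1f Mb, %d candidate SNPs)\n",
              x$interval$chrom, format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ","),
              (x$interval$end - x$interval$start) / 1e6,
              nrow(x$candidates)))
  invisible(x)
}

#' Does an interval contain a position?
#'
#' @param interval Data frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open).
#' @param chrom,pos Chromosome and 1-based position of the site.
#' @return Logical.
#' @export
interval_contains <- function(interval, chrom, pos) {
  interval$chrom == chrom && (pos - 1) >= interval$start &&
    (pos - 1) < interval$end
}
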