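zygosity_colours <- c(het = "red", hom_alt = "black",
                      hom_ref = "grey60", no_call = "grey80")

#' Dot plot of SNP quality along chromosomes
#'
#' One panel per chromosome; x is physical position (Mb), y is call
#' quality, heterozygous SNPs in red and homozygous in black, with a
#' horizontal guide at the quality threshold (300 by default).
#'
#' @param calls Classified \code{variant_calls}.
#' @param genome A \code{genome_spec} (fixes panel order and x ranges).
#' @param out Optional PNG path; written with \code{ggplot2::ggsave}.
#' @param min_qual Position of the quality guide line (default 300).
#' @return The ggplot object, invisibly.
#' @export
plot_snp_scatter <- function(calls, genome, out = NULL, min_qual = 300) {
  genome <- assert_genome(genome)
  df <- as.data.frame(calls)
  df$chrom <- factor(df$chrom, levels = genome$chrom)
  limits <- data.frame(
    chrom = factor(genome$chrom, levels = genome$chrom),
    pos_mb = genome$length_bp / 1e6, qual = 0
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$qual,
                                        colour = .data$zygosity)) +
    ggplot2::geom_blank(data = limits,
                        ggplot2::aes(x = .data$pos_mb, y = .data$qual),
                        inherit.aes = FALSE) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = min_qual, linetype = "dashed",
                        colour = "blue", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = zygosity_colours, drop = FALSE) +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x", drop = FALSE) +
    ggplot2::labs(x = "position (Mb)", y = "SNP quality",
                  colour = "zygosity") +
    ggplot2::theme_bw()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 10, height = 3, dpi = 150)
  }
  invisible(p)
}

#' Bar plot of windowed SNP density
#'
#' One panel per chromosome; bar height is the number of mode-matched SNPs
#' per window, with the peak window highlighted.
#'
#' @param windows Window table from \code{\link{window_density}}.
#' @param out Optional PNG path.
#' @param peak Peak window to highlight (default: recomputed).
#' @return The ggplot object, invisibly.
#' @export
plot_density_bars <- function(windows, out = NULL, peak = NULL) {
  df <- windows
  if (is.null(peak) && nrow(df) > 0L && max(df$n_snps) > 0L) {
    peak <- find_peak(df)
  }
  df$chrom <- factor(df$chrom, levels = unique(windows$chrom))
  df$is_peak <- FALSE
  if (!is.null(peak)) {
    df$is_peak <- df$chrom == peak$chrom & df$start == peak$start
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$n_snps,
    fill = .data$is_peak
  )) +
    ggplot2::geom_col(width = (df$end - df$start) / 1e6, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                               guide = "none") +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x", drop = FALSE) +
    ggplot2::labs(x = "position (Mb)",
                  y = sprintf("%s SNPs per window",
                              if (length(unique(windows$mode))) windows$mode[1] else "")) +
    ggplot2::theme_bw()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 10, height = 2.5, dpi = 150)
  }
  invisible(p)
}
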