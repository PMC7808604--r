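ZYGOSITY_LEVELS <- c("hom_ref", "het", "hom_alt", "no_call")

#' Construct a table of variant calls
#'
#' The in-memory representation of one sample's variant calls: one row per
#' biallelic SNV with per-site read support. Positions are 1-based (VCF
#' convention); all window arithmetic elsewhere in the package is 0-based
#' half-open, and the conversion happens only at the I/O boundary.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (>= 1).
#' @param ref,alt Reference / alternate alleles (single bases for SNVs).
#' @param qual Phred-scaled site quality; \code{NA} if missing.
#' @param ref_depth,alt_depth Reads supporting each allele; \code{NA} if the
#'   source had no allele-depth annotation.
#' @param zygosity One of \code{"hom_ref"}, \code{"het"}, \code{"hom_alt"},
#'   \code{"no_call"}.
#' @return A data frame of class \code{variant_calls}.
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qual = numeric(), ref_depth = integer(),
                          alt_depth = integer(),
                          zygosity = character()) {
  n <- length(chrom)
  if (n == 0L) {
    out <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), qual = numeric(), ref_depth = integer(),
      alt_depth = integer(), zygosity = character(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  if (length(zygosity) == 0L) zygosity <- rep("no_call", n)
  out <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = as.numeric(qual),
    ref_depth = as.integer(ref_depth),
    alt_depth = as.integer(alt_depth),
    zygosity = as.character(zygosity),
    stringsAsFactors = FALSE
  )
  if (any(out$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1 (1-based)")
  if (any(out$ref == out$alt, na.rm = TRUE)) stop("ref and alt must differ")
  bad_dp <- (!is.na(out$ref_depth) & out$ref_depth < 0L) |
    (!is.na(out$alt_depth) & out$alt_depth < 0L)
  if (any(bad_dp)) stop("allele depths must be non-negative")
  if (any(!is.na(out$qual) & out$qual < 0)) stop("qual must be >= 0 or NA")
  if (!all(out$zygosity %in% ZYGOSITY_LEVELS)) {
    stop("zygosity must be one of: ", paste(ZYGOSITY_LEVELS, collapse = ", "))
  }
  class(out) <- c("variant_calls", "data.frame")
  out
}

as_variant_calls <- function(df) {
  variant_calls(df$chrom, df$pos, df$ref, df$alt, df$qual,
                df$ref_depth, df$alt_depth, df$zygosity)
}

#' Allele fraction of calls
#'
#' \code{alt_depth / (ref_depth + alt_depth)}; \code{NaN} at zero total depth.
#'
#' @param calls A \code{variant_calls} data frame.
#' @return Numeric vector in \code{[0, 1]} (or \code{NaN}/\code{NA}).
#' @export
allele_fraction <- function(calls) {
  calls$alt_depth / (calls$ref_depth + calls$alt_depth)
}

zygosity_to_gt <- function(z) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", no_call = "./.")[z]
}

gt_to_zygosity <- function(gt) {
  # normalise phased separators; anything unexpected becomes no_call
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("no_call", length(gt))
  out[gt == "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt == "1/1"] <- "hom_alt"
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = 15))
}

#' Write variant calls to a VCF 4.2 file
#'
#' Emits a minimal single-sample VCF with \code{FORMAT GT:AD:DP}. Output is
#' deterministic (no timestamps) so identical inputs give byte-identical
#' files. Records are written in the order given; use
#' \code{\link{sort_calls}} first for genome order.
#'
#' @param calls A \code{variant_calls} data frame.
#' @param path Output file path.
#' @param genome Optional \code{genome_spec}; adds \code{##contig} lines.
#' @param sample Sample name for the header (default \code{"SAMPLE"}).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(calls, path, genome = NULL, sample = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=screenmap"
  )
  if (!is.null(genome)) {
    genome <- assert_genome(genome)
    header <- c(header, sprintf(
      "##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length_bp)
    ))
  }
  header <- c(
    header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t")
  )
  if (nrow(calls) > 0L) {
    ad <- ifelse(is.na(calls$ref_depth) | is.na(calls$alt_depth), ".",
                 paste0(calls$ref_depth, ",", calls$alt_depth))
    dp <- ifelse(is.na(calls$ref_depth) | is.na(calls$alt_depth), ".",
                 as.character(calls$ref_depth + calls$alt_depth))
    records <- paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt, fmt_num(calls$qual),
      ".", ".", "GT:AD:DP",
      paste(zygosity_to_gt(calls$zygosity), ad, dp, sep = ":"),
      sep = "\t"
    )
  } else {
    records <- character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, records), con, sep = "\n")
  invisible(path)
}

#' Read a single-sample VCF into a variant_calls table
#'
#' A deliberately minimal reader for VCF 4.x with one sample column and a
#' \code{GT} (and usually \code{AD}) FORMAT field. Only biallelic SNVs are
#' kept: records with symbolic, multi-base or multiple ALT alleles are
#' skipped and counted (multiallelic splitting is not attempted). Zygosity
#' is taken from \code{GT}; when \code{AD} is absent the depths are set to
#' \code{NA}.
#'
#' @param path Path to an uncompressed VCF file.
#' @param verbose Emit a message with the number of skipped records.
#' @return A \code{variant_calls} data frame, with attributes
#'   \code{n_skipped_non_snv} and \code{n_skipped_multiallelic}.
#' @export
read_vcf <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat=VCF")) {
    stop("malformed VCF header (line 1): expected '##fileformat=VCF...'")
  }
  hdr <- startsWith(lines, "#")
  body_idx <- which(!hdr)
  col_line <- which(startsWith(lines, "#CHROM"))
  if (length(col_line) != 1L) {
    stop("malformed VCF: expected exactly one #CHROM header line")
  }
  cols <- strsplit(lines[col_line], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) {
    stop(sprintf("malformed VCF (line %d): need FORMAT plus one sample column",
                 col_line))
  }
  n_non_snv <- 0L
  n_multi <- 0L
  keep <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) {
      stop(sprintf("malformed VCF record (line %d): %d field(s), expected >= 10",
                   i, length(f)))
    }
    alt <- f[5L]
    if (grepl(",", alt, fixed = TRUE)) {
      n_multi <- n_multi + 1L
      next
    }
    if (nchar(f[4L]) != 1L || nchar(alt) != 1L ||
        !f[4L] %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      n_non_snv <- n_non_snv + 1L
      next
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos)) {
      stop(sprintf("malformed VCF record (line %d): bad POS '%s'", i, f[2L]))
    }
    qual <- if (f[6L] == ".") NA_real_ else suppressWarnings(as.numeric(f[6L]))
    if (f[6L] != "." && is.na(qual)) {
      stop(sprintf("malformed VCF record (line %d): bad QUAL '%s'", i, f[6L]))
    }
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    smp <- strsplit(f[10L], ":", fixed = TRUE)[[1L]]
    gt_i <- match("GT", fmt)
    ad_i <- match("AD", fmt)
    gt <- if (!is.na(gt_i) && gt_i <= length(smp)) smp[gt_i] else "./."
    rd <- NA_integer_
    ad_alt <- NA_integer_
    if (!is.na(ad_i) && ad_i <= length(smp) && smp[ad_i] != ".") {
      ad <- suppressWarnings(as.integer(strsplit(smp[ad_i], ",", fixed = TRUE)[[1L]]))
      if (length(ad) >= 2L && !anyNA(ad[1:2])) {
        rd <- ad[1L]
        ad_alt <- ad[2L]
      }
    }
    keep[[k]] <- data.frame(
      chrom = f[1L], pos = pos, ref = f[4L], alt = alt, qual = qual,
      ref_depth = rd, alt_depth = ad_alt, zygosity = gt_to_zygosity(gt),
      stringsAsFactors = FALSE
    )
  }
  keep <- keep[!vapply(keep, is.null, logical(1L))]
  out <- if (length(keep)) as_variant_calls(do.call(rbind, keep)) else variant_calls()
  if (verbose && (n_non_snv > 0L || n_multi > 0L)) {
    message(sprintf("read_vcf: skipped %d non-SNV and %d multiallelic record(s)",
                    n_non_snv, n_multi))
  }
  attr(out, "n_skipped_non_snv") <- n_non_snv
  attr(out, "n_skipped_multiallelic") <- n_multi
  out
}

#' Sort calls into genome order
#'
#' @param calls A \code{variant_calls} data frame.
#' @param genome A \code{genome_spec} providing the chromosome order.
#' @return The calls ordered by chromosome (genome order) then position.
#' @export
sort_calls <- function(calls, genome) {
  genome <- assert_genome(genome)
  ord <- order(match(calls$chrom, genome$chrom), calls$pos)
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write genomic intervals as BED3
#'
#' BED convention: 0-based half-open, no header, tab-separated.
#'
#' @param intervals Data frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(intervals) > 0L) {
    writeLines(paste(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
                     format(intervals$end, scientific = FALSE, trim = TRUE), sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a BED3 file
#'
#' @param path Path to a BED file (first three columns used).
#' @return Data frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Write window densities as a headered TSV
#'
#' Columns: \code{chrom}, \code{window_start}, \code{window_end},
#' \code{n_snps}, \code{mode}. Starts are 0-based half-open.
#'
#' @param windows Data frame from \code{\link{window_density}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  df <- data.frame(
    chrom = windows$chrom,
    window_start = format(windows$start, scientific = FALSE, trim = TRUE),
    window_end = format(windows$end, scientific = FALSE, trim = TRUE),
    n_snps = windows$n_snps,
    mode = windows$mode,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Read a window-density TSV written by \code{write_windows_tsv}
#'
#' @param path Path to the TSV.
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}, \code{mode}.
#' @export
read_windows_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "integer", "character"))
  data.frame(
    chrom = df$chrom, start = df$window_start, end = df$window_end,
    n_snps = df$n_snps, mode = df$mode, stringsAsFactors = FALSE
  )
}
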