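# shared fixtures and oracles, built in code

tiny_genome <- function(n_chrom = 2, length_bp = 5e6, cM = 50) {
  genome_spec(paste0("chr", seq_len(n_chrom)), rep(length_bp, n_chrom),
              rep(cM, n_chrom))
}

make_calls <- function(chrom = "I", pos = 100L, ref = "G", alt = "A",
                       qual = 500, ref_depth = 50L, alt_depth = 50L,
                       zygosity = "het") {
  n <- max(lengths(list(chrom, pos, ref, alt, qual, ref_depth, alt_depth,
                        zygosity)))
  variant_calls(rep_len(chrom, n), rep_len(pos, n), rep_len(ref, n),
                rep_len(alt, n), rep_len(qual, n), rep_len(ref_depth, n),
                rep_len(alt_depth, n), rep_len(zygosity, n))
}

# a screen configuration scaled down for unit tests
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_ems_variants = 60L, n_pooled_lines = 10L,
                   f3_per_line = 30L, n_noise_sites = 50L, seed = 1L)
  do.call(screen_config, utils::modifyList(defaults, args))
}

# independent window-count oracle: per-call loop over all windows
oracle_window_counts <- function(calls, genome, window_bp, zygosity) {
  wins <- list()
  for (i in seq_len(nrow(genome))) {
    starts <- seq(0, genome$length_bp[i] - 1, by = window_bp)
    for (s in starts) {
      e <- min(s + window_bp, genome$length_bp[i])
      n <- 0L
      for (k in seq_len(nrow(calls))) {
        if (calls$chrom[k] == genome$chrom[i] && calls$zygosity[k] == zygosity &&
            calls$pos[k] - 1 >= s && calls$pos[k] - 1 < e) {
          n <- n + 1L
        }
      }
      wins[[length(wins) + 1L]] <- data.frame(
        chrom = genome$chrom[i], start = s, end = e, n_snps = n,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, wins)
}

# a two-haplotype individual defined directly from logical vectors
ind_from <- function(h1, h2) new_individual(as.logical(h1), as.logical(h2))
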