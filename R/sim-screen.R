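#' Configuration of a simulated EMS screen
#'
#' Bundles the knobs of the forward-genetics screen simulator. The defaults
#' reproduce the mapping protocol the package models: a single backcross,
#' ~30 pooled F3 populations, ~300 EMS-induced SNVs per mutagenised genome,
#' and ~100x pooled sequencing.
#'
#' @param mode \code{"viable"}: the mutant is homozygous-viable, F2 lines
#'   are selected homozygous for the causal variant and their F3 progeny
#'   pooled. \code{"sterile"}: homozygotes are sterile, so F2 lines are
#'   selected as heterozygous carriers and *all* their F3 self-progeny
#'   (including sterile homozygotes, which are present on the plate) are
#'   pooled — the Het-Map design.
#' @param n_ems_variants EMS variants induced in the founder (default 300,
#'   a typical per-genome load for a standard EMS dose).
#' @param n_backcrosses Backcrosses to the clean parental background with
#'   carrier selection (default 1).
#' @param n_pooled_lines Independent F2 lines whose F3 broods are pooled
#'   (default 30).
#' @param f3_per_line F3 individuals contributed by each pooled line
#'   (default 100).
#' @param depth_mean Mean sequencing depth per site (reads; default 100).
#' @param seq_error_rate Per-base sequencing error rate in \code{[0, 0.5)}
#'   (default 1e-3); errors are spread uniformly over the three non-ref
#'   bases.
#' @param min_alt_reads Minimum alt-supporting reads for the simulated
#'   caller to emit a record (default 2).
#' @param n_noise_sites Extra random genome positions per sample at which
#'   sequencing error can create spurious low-quality calls (default 1000).
#' @param signature EMS substitution signature, see \code{\link{induce_ems}}.
#' @param causal Optional fixed causal site, see \code{\link{induce_ems}}.
#' @param misclassification_rate Probability that carrier selection during
#'   the pedigree picks an animal of the wrong genotype (default 0:
#'   selection by phenotype/progeny testing is assumed perfect).
#' @param max_tries Bound on draws per selection step before erroring.
#' @param seed Integer seed; fixes every random choice of the screen.
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(mode = c("viable", "sterile"),
                          n_ems_variants = 300L,
                          n_backcrosses = 1L,
                          n_pooled_lines = 30L,
                          f3_per_line = 100L,
                          depth_mean = 100,
                          seq_error_rate = 1e-3,
                          min_alt_reads = 2L,
                          n_noise_sites = 1000L,
                          signature = "GC_to_AT",
                          causal = NULL,
                          misclassification_rate = 0,
                          max_tries = 2000L,
                          seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    n_ems_variants = as.integer(n_ems_variants),
    n_backcrosses = as.integer(n_backcrosses),
    n_pooled_lines = as.integer(n_pooled_lines),
    f3_per_line = as.integer(f3_per_line),
    depth_mean = as.numeric(depth_mean),
    seq_error_rate = as.numeric(seq_error_rate),
    min_alt_reads = as.integer(min_alt_reads),
    n_noise_sites = as.integer(n_noise_sites),
    signature = signature,
    causal = causal,
    misclassification_rate = as.numeric(misclassification_rate),
    max_tries = as.integer(max_tries),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  if (cfg$n_ems_variants < 1L) stop("n_ems_variants must be >= 1")
  if (cfg$n_backcrosses < 0L) stop("n_backcrosses must be >= 0")
  if (cfg$n_pooled_lines < 1L) stop("n_pooled_lines must be >= 1")
  if (cfg$f3_per_line < 1L) stop("f3_per_line must be >= 1")
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0")
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate >= 0.5) {
    stop("seq_error_rate must be in [0, 0.5)")
  }
  if (cfg$misclassification_rate < 0 || cfg$misclassification_rate > 1) {
    stop("misclassification_rate must be in [0, 1]")
  }
  class(cfg) <- "screen_config"
  cfg
}

# One genotype-selection step, with optional imperfect carrier
# identification: with probability misclassification_rate the selected
# animal is an unselected random offspring instead.
select_step <- function(a, b, map, locus, target, cfg, what) {
  if (cfg$misclassification_rate > 0 &&
      stats::runif(1L) < cfg$misclassification_rate) {
    return(cross(a, b, map))
  }
  select_offspring(a, b, map, locus, target, max_tries = cfg$max_tries,
                   what = what)
}

#' Simulate the pedigree of a mapping-by-sequencing screen
#'
#' Runs the screen forward from a mutagenised founder to the pooled F3
#' sample, with the causal variant's location as known ground truth:
#'
#' \enumerate{
#'   \item Founder: heterozygous for every EMS variant (random phase).
#'   \item Screen isolate: a self-progeny (F2 of the screen) selected
#'     homozygous for the causal variant (viable mode) or heterozygous
#'     carrier (sterile mode, where homozygotes are sterile).
#'   \item Backcrossing: for each pooled line independently, the isolate is
#'     backcrossed \code{n_backcrosses} times to the clean parental strain,
#'     selecting a heterozygous carrier each round. Lines descend from
#'     independent backcross F1 animals, as when several cross-progeny are
#'     singled from the mating plate.
#'   \item F2 lines: each line's F2 parent is a self-progeny of its carrier,
#'     selected homozygous-causal (viable) or heterozygous (sterile).
#'   \item Pool: every line contributes \code{f3_per_line} F3 self-progeny.
#'     In sterile mode all F3s are pooled, including the quarter of sterile
#'     homozygotes that sit on the plate — which is what places the causal
#'     allele at a pooled frequency of one half.
#' }
#'
#' @param genome A \code{genome_spec}.
#' @param cfg A \code{screen_config}.
#' @return A list of class \code{screen_pool}: \code{variants},
#'   \code{truth} (variants plus \code{true_pool_af}), \code{pool_dosage}
#'   (individuals x variants), \code{causal_id}, \code{genome}, \code{cfg}.
#' @export
run_screen <- function(genome, cfg) {
  genome <- assert_genome(genome)
  stopifnot(inherits(cfg, "screen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  variants <- induce_ems(genome, cfg$n_ems_variants,
                         signature = cfg$signature, causal = cfg$causal)
  map <- marker_map(variants, genome)
  ci <- which(variants$is_causal)
  nv <- nrow(variants)

  founder <- founder_individual(variants)
  clean <- clean_individual(variants)
  isolate_target <- if (cfg$mode == "viable") 2L else 1L
  isolate <- select_offspring(founder, founder, map, ci, isolate_target,
                              max_tries = cfg$max_tries,
                              what = "screen isolate")

  line_target <- if (cfg$mode == "viable") 2L else 1L
  n_pool <- cfg$n_pooled_lines * cfg$f3_per_line
  pool <- matrix(0L, nrow = n_pool, ncol = nv)
  for (i in seq_len(cfg$n_pooled_lines)) {
    carrier <- isolate
    for (b in seq_len(cfg$n_backcrosses)) {
      carrier <- select_step(carrier, clean, map, ci, 1L, cfg,
                             what = sprintf("backcross-%d carrier (line %d)", b, i))
    }
    line_parent <- select_step(carrier, carrier, map, ci, line_target, cfg,
                               what = sprintf("F2 line parent (line %d)", i))
    rows <- ((i - 1L) * cfg$f3_per_line + 1L):(i * cfg$f3_per_line)
    pool[rows, ] <- progeny_dosage(line_parent, map, cfg$f3_per_line)
  }

  truth <- variants
  truth$true_pool_af <- colMeans(pool) / 2
  structure(
    list(variants = variants, truth = truth, pool_dosage = pool,
         causal_id = variants$id[ci], genome = genome, cfg = cfg),
    class = "screen_pool"
  )
}

#' @export
print.screen_pool <- function(x, ...) {
  ci <- which(x$truth$is_causal)
  cat(sprintf(
    "screen_pool (%s mode): %d variants, pool of %d individuals\ncausal %s at %s:%d, pooled allele frequency %.3f\n",
    x$cfg$mode, nrow(x$truth), nrow(x$pool_dosage), x$causal_id,
    x$truth$chrom[ci], x$truth$pos[ci], x$truth$true_pool_af[ci]
  ))
  invisible(x)
}

# random positions for error-only noise calls, uniform over the genome
noise_sites <- function(genome, n) {
  if (n < 1L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  ci <- sample.int(nrow(genome), n, replace = TRUE,
                   prob = genome$length_bp / sum(genome$length_bp))
  pos <- as.integer(floor(stats::runif(n) * genome$length_bp[ci]) + 1)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(chrom = genome$chrom[ci], pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Simulate read support at a set of sites with true alt frequencies f.
# depth ~ Poisson(depth_mean); alt reads ~ Binomial(depth, p) with
# p = f (1 - e) + (1 - f) e / 3: a true alt read survives unless it is
# mis-read, a ref read is mis-read to the specific alt base e/3 of the
# time. QUAL = min(3000, 10 * alt_depth), a monotone evidence score that
# spans the >= 300 filter used downstream. Only sites with at least
# min_alt_reads supporting reads are emitted, as a caller would.
sample_calls <- function(sites, f, cfg, bands = zygosity_bands()) {
  n <- nrow(sites)
  if (n == 0L) return(variant_calls())
  depth <- stats::rpois(n, cfg$depth_mean)
  e <- cfg$seq_error_rate
  p_alt <- f * (1 - e) + (1 - f) * (e / 3)
  alt_depth <- stats::rbinom(n, depth, p_alt)
  keep <- alt_depth >= cfg$min_alt_reads
  calls <- variant_calls(
    chrom = sites$chrom[keep], pos = sites$pos[keep],
    ref = sites$ref[keep], alt = sites$alt[keep],
    qual = pmin(3000, 10 * alt_depth[keep]),
    ref_depth = depth[keep] - alt_depth[keep],
    alt_depth = alt_depth[keep]
  )
  calls$zygosity <- classify_zygosity(calls, bands)
  calls
}

#' Sequence a pooled screen sample (and its parental control)
#'
#' Turns the true pooled allele frequencies of a simulated screen into
#' variant calls for the mutant pool and for the unmutagenised parental
#' strain. Depth is Poisson per site; alt reads are binomial with success
#' probability \code{f (1 - e) + (1 - f) e / 3} where \code{f} is the true
#' pooled frequency and \code{e} the per-base error rate. The parental
#' strain carries no variants by default, so its calls are error-only noise
#' (at EMS sites and at \code{n_noise_sites} random positions) whose
#' \code{QUAL = min(3000, 10 * alt_depth)} stays far below the 300 filter.
#'
#' @param screen A \code{screen_pool} from \code{\link{run_screen}}.
#' @param cfg A \code{screen_config}; defaults to the screen's own.
#' @param seed Optional seed for the sequencing step alone.
#' @return List with \code{variant_calls} elements \code{mutant} and
#'   \code{parental}, each sorted in genome order.
#' @export
sequence_pool <- function(screen, cfg = screen$cfg, seed = NULL) {
  stopifnot(inherits(screen, "screen_pool"))
  if (!is.null(seed)) set.seed(seed)
  genome <- screen$genome
  ems <- screen$truth[, c("chrom", "pos", "ref", "alt")]

  mut_noise <- noise_sites(genome, cfg$n_noise_sites)
  mutant <- rbind(
    sample_calls(ems, screen$truth$true_pool_af, cfg),
    sample_calls(mut_noise, rep(0, nrow(mut_noise)), cfg)
  )
  par_noise <- noise_sites(genome, cfg$n_noise_sites)
  parental <- rbind(
    sample_calls(ems, rep(0, nrow(ems)), cfg),
    sample_calls(par_noise, rep(0, nrow(par_noise)), cfg)
  )

  list(
    mutant = sort_calls(as_variant_calls(mutant), genome),
    parental = sort_calls(as_variant_calls(parental), genome)
  )
}

#' Simulate a complete screen: pedigree plus pooled sequencing
#'
#' Convenience wrapper: \code{\link{run_screen}} then
#' \code{\link{sequence_pool}} under a single seed, optionally writing the
#' mutant VCF, parental VCF and ground-truth TSV.
#'
#' @param genome A \code{genome_spec} (default \code{\link{ce_genome}()}).
#' @param cfg A \code{screen_config}.
#' @param out_dir Optional directory for \code{mutant.vcf},
#'   \code{parental.vcf} and \code{truth.tsv}.
#' @return List with \code{screen}, \code{mutant_calls},
#'   \code{parental_calls}, \code{truth} and (if written) \code{files}.
#' @export
simulate_screen <- function(genome = ce_genome(), cfg = screen_config(),
                            out_dir = NULL) {
  screen <- run_screen(genome, cfg)      # sets the seed from cfg
  seqd <- sequence_pool(screen, cfg)
  out <- list(
    screen = screen,
    mutant_calls = seqd$mutant,
    parental_calls = seqd$parental,
    truth = screen$truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      mutant_vcf = file.path(out_dir, "mutant.vcf"),
      parental_vcf = file.path(out_dir, "parental.vcf"),
      truth_tsv = file.path(out_dir, "truth.tsv")
    )
    write_vcf(seqd$mutant, files$mutant_vcf, genome = genome,
              sample = "MUTANT_POOL")
    write_vcf(seqd$parental, files$parental_vcf, genome = genome,
              sample = "PARENTAL")
    write_truth_tsv(screen$truth, files$truth_tsv)
    out$files <- files
  }
  out
}

write_truth_tsv <- function(truth, path) {
  df <- truth[, c("chrom", "pos", "ref", "alt", "is_causal", "true_pool_af")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  lines <- paste(df$chrom, df$pos, df$ref, df$alt,
                 ifelse(df$is_causal, "TRUE", "FALSE"),
                 formatC(df$true_pool_af, format = "g", digits = 15),
                 sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
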