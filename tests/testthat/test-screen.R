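test_that("screen_config validates its fields", {
  expect_error(screen_config(depth_mean = 0), "depth_mean")
  expect_error(screen_config(seq_error_rate = 0.5), "seq_error_rate")
  expect_error(screen_config(n_pooled_lines = 0), "n_pooled_lines")
  cfg <- screen_config()
  expect_identical(cfg$n_pooled_lines, 30L)
  expect_identical(cfg$n_backcrosses, 1L)
  expect_identical(cfg$n_ems_variants, 300L)
})

test_that("viable-mode pools are fixed for the causal variant (af exactly 1)", {
  scr <- run_screen(tiny_genome(), small_cfg(mode = "viable"))
  causal <- scr$truth[scr$truth$is_causal, ]
  expect_identical(causal$true_pool_af, 1)
})

test_that("sterile-mode pools carry the causal variant at frequency ~1/2", {
  # 10 lines x 60 F3 = 600 pooled individuals
  scr <- run_screen(tiny_genome(), small_cfg(mode = "sterile",
                                             n_pooled_lines = 10L,
                                             f3_per_line = 60L, seed = 4L))
  causal_af <- scr$truth$true_pool_af[scr$truth$is_causal]
  se <- sqrt(0.25 / (2 * 600))
  expect_lt(abs(causal_af - 0.5), 3 * se)
})

test_that("truth allele frequencies equal mean pooled dosage / 2", {
  scr <- run_screen(tiny_genome(), small_cfg(seed = 6L))
  expect_equal(scr$truth$true_pool_af, colMeans(scr$pool_dosage) / 2)
  expect_identical(sum(scr$truth$is_causal), 1L)
})

test_that("unlinked variants are diluted relative to causal-flanking ones", {
  # viable mode: after backcross and homozygous selection, variants within
  # 1 Mb of the causal site stay near fixation while variants on other
  # chromosomes average ~1/4
  near <- c()
  far <- c()
  for (i in 1:12) {
    scr <- run_screen(ce_genome(), small_cfg(mode = "viable",
                                             n_ems_variants = 150L,
                                             seed = 100L + i))
    tr <- scr$truth
    causal <- tr[tr$is_causal, ]
    on_chrom <- tr$chrom == causal$chrom & !tr$is_causal
    near_i <- on_chrom & abs(tr$pos - causal$pos) <= 1e6
    far_i <- tr$chrom != causal$chrom
    near <- c(near, tr$true_pool_af[near_i])
    far <- c(far, tr$true_pool_af[far_i])
  }
  tt <- t.test(near, far, alternative = "greater")
  expect_lt(tt$p.value, 1e-3)
})

test_that("detected-variant frequency declines with genetic distance (Het-Map)", {
  # sterile mode; pooled af of variants present in the pool, binned by
  # genetic distance to the causal locus
  # linkage decays over the first ~10 cM and flattens at the unlinked
  # level beyond that, so the bins cover the decay range
  bins <- list(b1 = c(), b2 = c(), b3 = c(), unlinked = c())
  for (i in 1:60) {
    scr <- run_screen(ce_genome(), small_cfg(mode = "sterile",
                                             n_ems_variants = 150L,
                                             seed = 500L + i))
    tr <- scr$truth
    causal <- tr[tr$is_causal, ]
    cm_per_bp <- 50 / scr$genome$length_bp[match(causal$chrom,
                                                 scr$genome$chrom)]
    d_cm <- abs(tr$pos - causal$pos) * cm_per_bp
    detected <- tr$true_pool_af > 0 & !tr$is_causal
    same <- tr$chrom == causal$chrom
    bins$b1 <- c(bins$b1, tr$true_pool_af[detected & same & d_cm < 3])
    bins$b2 <- c(bins$b2, tr$true_pool_af[detected & same & d_cm >= 3 &
                                            d_cm < 8])
    bins$b3 <- c(bins$b3, tr$true_pool_af[detected & same & d_cm >= 8 &
                                            d_cm < 30])
    bins$unlinked <- c(bins$unlinked, tr$true_pool_af[detected & !same])
  }
  m <- vapply(bins, mean, 0)
  expect_gt(m[["b1"]], m[["b2"]])
  expect_gt(m[["b2"]], m[["b3"]])
  expect_gt(m[["b1"]], m[["unlinked"]])
})

test_that("identical seeds reproduce the screen and its VCF bit for bit", {
  cfg <- small_cfg(mode = "sterile", seed = 77L)
  a <- simulate_screen(tiny_genome(), cfg)
  b <- simulate_screen(tiny_genome(), cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$mutant_calls, b$mutant_calls)

  fa <- tempfile(fileext = ".vcf")
  fb <- tempfile(fileext = ".vcf")
  write_vcf(a$mutant_calls, fa, genome = tiny_genome())
  write_vcf(b$mutant_calls, fb, genome = tiny_genome())
  expect_identical(readLines(fa), readLines(fb))
})

test_that("read sampling matches its binomial model", {
  cfg <- small_cfg(depth_mean = 100, seq_error_rate = 0)
  sites <- data.frame(chrom = "chr1", pos = 1:2000, ref = "G", alt = "A",
                      stringsAsFactors = FALSE)
  set.seed(10)
  # f = 1: every read carries the alt allele
  calls1 <- screenmap:::sample_calls(sites, rep(1, nrow(sites)), cfg)
  expect_true(all(calls1$ref_depth == 0L))
  # f = 0.5: mean alt fraction close to one half over >= 1000 sites
  calls5 <- screenmap:::sample_calls(sites, rep(0.5, nrow(sites)), cfg)
  expect_gt(nrow(calls5), 1000)
  af <- mean(allele_fraction(calls5))
  expect_gt(af, 0.48)
  expect_lt(af, 0.52)
  # QUAL is the stated monotone function of alt support
  expect_equal(calls5$qual, pmin(3000, 10 * calls5$alt_depth))
})

test_that("the sterile-mode causal call classifies het in >= 95% of replicates", {
  scr <- run_screen(tiny_genome(), small_cfg(mode = "sterile",
                                             n_pooled_lines = 10L,
                                             f3_per_line = 60L, seed = 12L))
  cfg0 <- small_cfg(mode = "sterile", depth_mean = 100, seq_error_rate = 0)
  causal <- scr$truth[scr$truth$is_causal, ]
  hits <- 0L
  for (r in 1:100) {
    seqd <- sequence_pool(scr, cfg0, seed = 9000L + r)
    m <- seqd$mutant
    row <- m[m$chrom == causal$chrom & m$pos == causal$pos, ]
    if (nrow(row) == 1L && row$zygosity == "het") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("viable-mode linked SNPs within 1 cM classify hom_alt", {
  n_hom <- 0L
  n_all <- 0L
  for (i in 1:20) {
    cfg <- screen_config(mode = "viable", f3_per_line = 50L,
                         seq_error_rate = 0, seed = 3000L + i)
    sim <- simulate_screen(ce_genome(), cfg)
    tr <- sim$truth
    causal <- tr[tr$is_causal, ]
    cm_per_bp <- 50 / ce_genome()$length_bp[match(causal$chrom,
                                                  ce_genome()$chrom)]
    linked <- tr[!tr$is_causal & tr$chrom == causal$chrom &
                   abs(tr$pos - causal$pos) * cm_per_bp <= 1, ]
    if (nrow(linked) == 0L) next
    calls <- filter_quality(sim$mutant_calls, 300)
    calls$zygosity <- classify_zygosity(calls)
    hit <- calls[paste(calls$chrom, calls$pos) %in%
                   paste(linked$chrom, linked$pos), ]
    n_all <- n_all + nrow(hit)
    n_hom <- n_hom + sum(hit$zygosity == "hom_alt")
  }
  expect_gt(n_all, 10L)
  expect_gte(n_hom / n_all, 0.95)
})
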