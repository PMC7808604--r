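test_that("windows tile each chromosome and truncate at its end", {
  g <- genome_spec(c("A", "B"), c(2.5e6, 1e6))
  w <- window_density(variant_calls(), g, 1e6, mode = "hom")
  expect_identical(nrow(w), 4L)
  expect_equal(w$end[3], 2.5e6)           # truncated last window
  expect_true(all(w$n_snps == 0L))
  expect_equal(w$start[w$chrom == "A"], c(0, 1e6, 2e6))
})

test_that("a call at position 1e6 lands in the first window", {
  g <- genome_spec("A", 2e6)
  calls <- make_calls(chrom = "A", pos = c(1000000L, 1000001L),
                      zygosity = "het")
  w <- window_density(calls, g, 1e6, mode = "het")
  expect_identical(w$n_snps, c(1L, 1L))
})

test_that("only mode-matched zygosity classes are counted, conserving totals", {
  g <- tiny_genome(1, 4e6)
  set.seed(3)
  n <- 200L
  calls <- make_calls(chrom = "chr1", pos = sample.int(4e6, n),
                      zygosity = sample(c("hom_alt", "het", "hom_ref",
                                          "no_call"), n, replace = TRUE))
  totals <- vapply(c("hom", "het", "hom_ref", "no_call"), function(m) {
    sum(window_density(calls, g, 1e6, mode = m)$n_snps)
  }, 0L)
  expect_identical(sum(totals), n)
  expect_identical(totals[["hom"]], sum(calls$zygosity == "hom_alt"))
})

test_that("window counts equal the brute-force assignment on random instances", {
  set.seed(91)
  for (rep in 1:10) {
    g <- genome_spec("c", 20e6)
    n <- 500
    calls <- make_calls(chrom = "c", pos = sample.int(20e6, n),
                        zygosity = sample(c("het", "hom_alt"), n, TRUE))
    for (m in c("het", "hom")) {
      fast <- window_density(calls, g, 1e6, mode = m)
      slow <- oracle_window_counts(calls, g, 1e6,
                                   screenmap:::mode_to_zygosity(m))
      expect_identical(fast$n_snps, slow$n_snps)
      expect_equal(fast$start, slow$start)
    }
  }
})

test_that("calls on unknown chromosomes are rejected by name", {
  g <- tiny_genome(1)
  calls <- make_calls(chrom = "chrX", pos = 5L)
  expect_error(window_density(calls, g, 1e6, mode = "het"), "chrX:5")
})

test_that("find_peak returns the maximum with a deterministic tie rule", {
  w <- data.frame(chrom = "c", start = (0:3) * 1e6, end = (1:4) * 1e6,
                  n_snps = c(3L, 9L, 9L, 1L), mode = "hom",
                  stringsAsFactors = FALSE)
  peak <- find_peak(w)
  expect_equal(peak$start, 1e6)  # first of the tied pair
  expect_identical(peak$n_snps, 9L)

  expect_equal(find_peak(w[2, ])$start, 1e6)   # single window
  expect_error(find_peak(w[0, ]), "empty")
})

test_that("candidate_interval follows the contiguous half-peak rule", {
  w <- data.frame(chrom = "c", start = (0:4) * 1e6, end = (1:5) * 1e6,
                  n_snps = c(2L, 8L, 10L, 9L, 1L), mode = "hom",
                  stringsAsFactors = FALSE)
  peak <- find_peak(w)
  iv <- candidate_interval(w, peak, frac = 0.5)  # threshold 5: windows 1..3
  expect_equal(iv$start, 1e6)
  expect_equal(iv$end, 4e6)

  # frac 1: only the run tied at the maximum
  iv1 <- candidate_interval(w, peak, frac = 1)
  expect_equal(c(iv1$start, iv1$end), c(2e6, 3e6))

  # isolated peak: interval is the peak window alone
  w$n_snps <- c(0L, 0L, 4L, 0L, 0L)
  iv2 <- candidate_interval(w, find_peak(w), frac = 0.5)
  expect_equal(c(iv2$start, iv2$end), c(2e6, 3e6))

  expect_error(candidate_interval(w, find_peak(w), frac = 0), "frac")
  w$n_snps <- rep(0L, 5)
  expect_error(candidate_interval(w, find_peak(w)), "no SNPs")
})

test_that("rank_candidates sorts by quality then allele-fraction closeness", {
  iv <- data.frame(chrom = "c", start = 0, end = 1e6)
  calls <- make_calls(
    chrom = "c", pos = c(10L, 20L, 30L, 40L),
    qual = c(400, 900, 900, 500),
    ref_depth = c(50L, 35L, 50L, 50L),
    alt_depth = c(50L, 65L, 50L, 50L),
    zygosity = c("het", "het", "het", "hom_alt")
  )
  ranked <- rank_candidates(calls, iv, mode = "het")
  # qual 900 ties: af 0.5 beats af 0.65; hom_alt call excluded in het mode
  expect_identical(ranked$pos, c(30L, 20L, 10L))

  # outside the interval: nothing
  iv2 <- data.frame(chrom = "c", start = 2e6, end = 3e6)
  expect_identical(nrow(rank_candidates(calls, iv2, "het")), 0L)
})

test_that("interval containment uses 0-based half-open convention", {
  iv <- data.frame(chrom = "c", start = 1e6, end = 2e6)
  expect_true(interval_contains(iv, "c", 1000001))
  expect_true(interval_contains(iv, "c", 2000000))
  expect_false(interval_contains(iv, "c", 1000000))
  expect_false(interval_contains(iv, "c", 2000001))
  expect_false(interval_contains(iv, "d", 1500000))
})

test_that("the simulated sterile screen peaks on the causal chromosome", {
  # a high-contrast configuration: two chromosomes, so half the EMS load
  # is linked to the causal site
  sim <- simulate_screen(tiny_genome(2, 8e6),
                         small_cfg(mode = "sterile", n_ems_variants = 80L,
                                   n_pooled_lines = 20L, seed = 424L))
  causal <- sim$truth[sim$truth$is_causal, ]
  res <- map_mutation(sim$mutant_calls, sim$parental_calls,
                      tiny_genome(2, 8e6), mode = "het")
  expect_identical(res$peak$chrom, causal$chrom)
  expect_true(all(res$candidates$zygosity == "het"))
  expect_true(all(res$candidates$chrom == res$interval$chrom))
})

test_that("map_mutation is deterministic and logs stage counts", {
  sim <- simulate_screen(tiny_genome(), small_cfg(seed = 55L))
  r1 <- map_mutation(sim$mutant_calls, sim$parental_calls, tiny_genome(),
                     mode = "hom")
  r2 <- map_mutation(sim$mutant_calls, sim$parental_calls, tiny_genome(),
                     mode = "hom")
  expect_identical(r1$windows, r2$windows)
  expect_identical(r1$interval, r2$interval)
  expect_identical(r1$candidates, r2$candidates)
  expect_lte(r1$log$n_after_background, r1$log$n_mutant_raw)
  expect_lte(r1$log$n_after_quality, r1$log$n_after_background)
  expect_identical(r1$log$n_mode_matched,
                   sum(r1$calls$zygosity == "hom_alt"))
})

test_that("an empty candidate set produces an advisory error", {
  mutant <- make_calls(pos = 1:3, qual = c(10, 20, 30))
  parental <- variant_calls()
  expect_error(
    map_mutation(mutant, parental, genome_spec("I", 1e6), mode = "hom"),
    "min-qual"
  )
  # calls survive quality but none matches the mode
  mutant2 <- make_calls(pos = 1:3, qual = 500, ref_depth = 50L,
                        alt_depth = 50L)
  expect_error(
    map_mutation(mutant2, parental, genome_spec("I", 1e6), mode = "hom"),
    "mode|bands"
  )
})
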