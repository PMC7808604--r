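---
title: "Mapping-by-sequencing for forward genetic screens: model and methods"
author: "screenmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing for forward genetic screens: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmap)
```

## The mapping problem

A chemical mutagenesis screen (EMS in *C. elegans* is the motivating
system) produces a mutant whose phenotype is caused by one recessive point
mutation hidden among a few hundred mutagen-induced SNVs scattered across
the genome. Mapping-by-sequencing locates the causal mutation without any
marker crosses: the mutant is backcrossed to the unmutagenised parental
strain, progeny are selected for the phenotype, and a pooled DNA sample of
selected progeny is sequenced. Selection keeps the causal variant — and,
by linkage, the mutagen-induced variants physically near it — at high
frequency in the pool, while unlinked variants segregate away. Counting
candidate SNPs (high-quality calls absent from the parental strain) in
sequential 1 Mb windows exposes the region of elevated density.

Two zygosity statistics cover the two kinds of mutants:

* **hom mode** (viable mutants): selected animals are homozygous for the
  causal variant, so every read at linked sites carries the alt allele;
  homozygous-classified SNPs are counted.
* **het mode, "Het-Map"** (sterile mutants): homozygotes cannot be
  propagated, so the pool is built from *all* self-progeny of heterozygous
  carrier lines. Mendelian segregation of a selfed heterozygote gives
  1/4 wild-type : 1/2 heterozygous : 1/4 homozygous offspring, and the
  causal allele therefore sits at a pooled frequency of one half — about
  half the reads at the causal site carry the mutation. Heterozygous-
  classified SNPs (pooled allele fraction in a band around 0.5) are
  counted.

## The simulator

`run_screen()` simulates the pedigree forward with the causal variant's
position as ground truth:

1. **Mutagenesis.** `induce_ems()` places `n_ems_variants` (default 300, a
   typical per-genome load for a standard EMS dose) uniformly over the
   physical genome; the default substitution signature is the canonical
   EMS chemistry, G:C→A:T transitions. Every variant is heterozygous in
   the founder with independently random phase. One variant is flagged
   causal.
2. **Screen isolate.** A self-progeny of the founder (the F2 of the
   screen) is selected homozygous for the causal variant (viable mode) or
   as a heterozygous carrier (sterile mode).
3. **Backcross.** Each of the `n_pooled_lines` (default 30) pooled lines
   descends from an *independent* backcross-F1 carrier, as when several
   cross-progeny are singled from the mating plate; `n_backcrosses`
   defaults to 1, matching the protocol the package models. Carrier
   identification is perfect by default (`misclassification_rate = 0`).
4. **Lines and pool.** Each line's F2 parent is selected
   homozygous-causal (viable) or heterozygous (sterile) from its F1's
   selfing; each line contributes `f3_per_line` (default 100) F3
   self-progeny. In sterile mode all F3s are pooled — including the
   quarter of sterile homozygotes, which are present on the plate even
   though they cannot reproduce. This is precisely what places the causal
   allele at frequency 0.5 in the pooled DNA.
5. **Sequencing.** `sequence_pool()` draws per-site depth from
   Poisson(`depth_mean`, default 100) and alt reads from
   Binomial(depth, `f(1−e) + (1−f)e/3`), where `f` is the true pooled
   frequency and `e` the per-base error rate (default `1e-3`, errors
   spread uniformly over the three non-reference bases). Site quality is
   the monotone evidence score `QUAL = min(3000, 10 × alt_depth)`, which
   spans the downstream ≥ 300 filter; a record is emitted only with at
   least two supporting reads, as a realistic caller would. The parental
   sample carries no true variants, only error-driven noise calls far
   below the quality threshold.

### Recombination model

Crossovers follow the Haldane model: counts are Poisson with mean equal to
the chromosome's map length in Morgans, positions are uniform on the
genetic map, and there is no interference. Genetic lengths default to
50 cM per chromosome (the classic *C. elegans* figure), with a uniform
cM/bp rate within each chromosome. Because disjoint intervals recombine
independently under this model, inheritance at the ordered marker
positions is exactly a Markov chain whose switch probability across a gap
of *d* Morgans is Haldane's map function `r(d) = (1 − e^(−2d))/2`;
`gamete()` samples that chain directly, which is mathematically identical
to sampling crossover positions and reading off the mosaic, and is what
the package's map-function tests verify at d = 0.01, 0.1 and 0.5 Morgans.

### What the simulator does not model

No read-level artefacts (mapping error, coverage bias, GC effects), no
indels or structural variants, no balancer chromosomes, no germline
mosaicism in the mutagenised founder, and equal DNA contribution per
pooled animal (including sterile homozygotes). Passing tests on simulated
pools therefore demonstrate the statistical behaviour of the pedigree,
pooling and counting machinery — not robustness to alignment or calling
artefacts in real data.

## The mapping pipeline

`map_mutation()` composes the stages, logging call counts at each:

1. `read_vcf()` — minimal single-sample VCF 4.2 with `GT:AD:DP`.
2. `subtract_background()` — drop calls whose exact
   (chrom, pos, ref, alt) tuple occurs in the parental sample. Matching
   the full tuple (not position alone) means a different substitution at
   the same site still counts as a new mutation.
3. `filter_quality()` — keep `QUAL ≥ 300`; the boundary is inclusive.
4. `classify_zygosity()` — pooled-sample zygosity from the alt read
   fraction, not from the caller's diploid GT: a pool of 1/4 : 1/2 : 1/4
   genotypes is "heterozygous" at a linked site in the sense that its
   allele fraction is near 0.5. Defaults: het band [0.3, 0.7], homozygous
   at ≥ 0.9, minimum depth 10. The gap (0.7, 0.9) is deliberately
   unclassified: intermediate frequencies carry ambiguous information and
   guessing them blurs the window peak.
5. `window_density()` — counts of mode-matched SNPs in non-overlapping
   1 Mb tiles (sequential, not sliding, windows). Internally all interval
   arithmetic is 0-based half-open; VCF positions are 1-based and
   converted only at the I/O boundary, so a call at position 1,000,000
   falls in the window [0, 1e6).
6. `find_peak()` — maximal window; ties break deterministically to the
   earliest window in genome order (visual inspection has no tie rule, so
   the package fixes one).
7. `candidate_interval()` — the operational "approximate location": the
   maximal contiguous run of windows containing the peak in which every
   window holds at least `frac` (default 0.5) of the peak count.
8. `rank_candidates()` — SNPs inside the interval, ordered by quality and
   then by closeness of the allele fraction to its expectation (0.5 in
   het mode, 1.0 in hom mode).

Smoothing of the window counts is deliberately omitted: the method's
contract is the raw count in each sequential window, and the diagnostic
bar plots show exactly that statistic.

## Choices made where the design was open

* **Independent backcross F1 per line.** The protocol text does not say
  how many F1 animals found the singled F2 lines. One shared F1 would
  make the pooled frequency of every surviving unlinked variant
  concentrate at 0.5 (its self-progeny segregate 1:2:1 around one half in
  every line), erasing the dilution the method relies on. Singling F2s
  from several independent cross-progeny is both standard practice and
  the structure under which unlinked variants dilute to a mean pooled
  frequency of 1/4; the simulator does the latter.
* **Caller emission threshold.** Two alt reads minimum. A side effect at
  the default error rate is that roughly 0.5% of true variant sites gain
  an error-only parental call and are then background-subtracted — a
  realistic, rare loss.
* **Pooled-zygosity bands instead of GT.** A diploid caller's GT on
  pooled DNA is not meaningful; the bands are explicit, documented and
  configurable (`--het-band`, `--hom-min`, `--min-depth`).
* **Problem sizes in the test-suite and acceptance runs.** Replicate
  counts (30–60 screens per experiment, 10–20 thousand gametes or progeny
  for segregation checks) were chosen to give three-standard-error
  resolution on the quantities asserted while keeping a full run in the
  minutes range on one core.

## Statistical behaviour, and the limits of a single backcross

The simulator makes two properties of the protocol quantitative; both are
measured by the package's tests rather than asserted.

**Pooled frequencies.** In viable mode the causal variant's pooled
frequency is exactly 1 (every line is fixed for it), and at zero
sequencing error every read at the causal site carries the alt allele. In
sterile mode the causal variant sits at 0.5 with binomial read noise, and
detected neutral variants decline in frequency with genetic distance from
the causal locus — from ≈ 0.5 when tightly linked to ≈ 1/3 when unlinked
(conditional on still being present in the pool at all; dilution acts
mostly by *loss*, and the unconditional mean frequency of neutral
variants is flat near 1/4 at every distance).

**Density contrast and its ceiling.** With one backcross the homozygous
statistic is sharply selective: essentially no unlinked variant can reach
a pooled frequency ≥ 0.9 across 30 independent lines, so hom-mode window
counts are near zero away from the causal region and the peak chromosome
is identified essentially always. The heterozygous statistic is
intrinsically noisier after a *single* backcross: an unlinked variant that
happens to be homozygous in the screen isolate (probability 1/4) is
heterozygous in every backcross F1 and lands at pooled frequency ≈ 0.5 —
inside the het band, indistinguishable from a linked SNP. Together with
leakage from the frequency-1/4 class, the genome-wide het background is
roughly one SNP per Mb against a near-causal density of about 1.4 per Mb:
an enrichment of only ~1.4-fold. Each additional backcross would halve
that background, but with the single backcross the protocol prescribes,
Het-Map's window peak is informative rather than definitive at a
per-genome mutation load of ~300, and candidate intervals from sparse
counts (a handful of SNPs per window) frequently exclude the causal
window itself even when the peak is nearby. The package reports both
recovery rates honestly in its acceptance experiments; at these study
conditions the hom-mode peak chromosome is essentially always correct,
while strict interval containment is markedly below that, and het-mode
containment is lower still.

## Worked example

```{r example, eval = FALSE}
genome <- ce_genome()
cfg <- screen_config(mode = "sterile", seed = 42)
sim <- simulate_screen(genome, cfg)
sim$truth[sim$truth$is_causal, ]

res <- map_mutation(sim$mutant_calls, sim$parental_calls, genome,
                    mode = "het")
res
interval_contains(res$interval, "V", 14072917)
```

## Known limitations

* The heterozygous statistic's contrast ceiling under one backcross,
  discussed above, is a property of the protocol being modelled, not of
  the implementation; simulated recovery rates should be read with that
  in mind.
* The simulator emits variant calls directly; conclusions about upstream
  steps (alignment, raw calling) are out of scope.
* One mutant pool and one parental background per run; no joint mapping
  of multiple mutants and no effect annotation of candidate SNPs.
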