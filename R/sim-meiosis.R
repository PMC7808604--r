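#' Marker map: genetic positions of variants
#'
#' Converts physical variant positions to genetic positions (Morgans),
#' assuming a uniform recombination rate per chromosome
#' (\code{genetic_length_cM / length_bp}). The map is the lookup structure
#' used by \code{\link{gamete}} and the pedigree simulator.
#'
#' @param variants Variant table from \code{\link{induce_ems}}.
#' @param genome A \code{genome_spec}.
#' @return A list (class \code{marker_map}) with one element per chromosome:
#'   \code{idx} (row indices into \code{variants}, sorted by position) and
#'   \code{gpos} (genetic positions in Morgans).
#' @export
marker_map <- function(variants, genome) {
  genome <- assert_genome(genome)
  bad <- setdiff(unique(variants$chrom), genome$chrom)
  if (length(bad)) stop("variant chromosome(s) not in genome: ",
                        paste(bad, collapse = ", "))
  out <- lapply(seq_len(nrow(genome)), function(i) {
    idx <- which(variants$chrom == genome$chrom[i])
    idx <- idx[order(variants$pos[idx])]
    list(
      chrom = genome$chrom[i],
      idx = idx,
      gpos = (variants$pos[idx] / genome$length_bp[i]) *
        (genome$genetic_length_cM[i] / 100)
    )
  })
  names(out) <- genome$chrom
  attr(out, "n_variants") <- nrow(variants)
  class(out) <- "marker_map"
  out
}

#' Construct a diploid individual
#'
#' An individual is a two-column logical matrix over the variant set: entry
#' \code{[v, h]} is \code{TRUE} when haplotype \code{h} carries the alt
#' allele of variant \code{v}. Genotypes at any locus are therefore hom-ref
#' (0 copies), het (1) or hom-alt (2).
#'
#' @param h1,h2 Logical vectors over the variant set.
#' @return A matrix of class \code{individual}.
#' @export
new_individual <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("haplotypes must have equal length")
  structure(cbind(h1 = as.logical(h1), h2 = as.logical(h2)),
            class = "individual")
}

#' @rdname new_individual
#' @param variants Variant table; gives the number of loci.
#' @export
clean_individual <- function(variants) {
  n <- nrow(variants)
  new_individual(rep(FALSE, n), rep(FALSE, n))
}

#' A mutagenised founder: heterozygous at every induced variant
#'
#' Each EMS lesion arises on one DNA strand, so every variant is
#' heterozygous in the founder, with its haplotype of origin (phase) drawn
#' uniformly and independently per variant.
#'
#' @param variants Variant table from \code{\link{induce_ems}}.
#' @return An \code{individual}.
#' @export
founder_individual <- function(variants) {
  n <- nrow(variants)
  phase <- sample.int(2L, n, replace = TRUE)
  new_individual(phase == 1L, phase == 2L)
}

#' Genotype dosage of an individual
#'
#' @param ind An \code{individual}.
#' @return Integer vector of alt-allele counts (0, 1 or 2) per variant.
#' @export
dosage <- function(ind) {
  as.integer(ind[, 1L]) + as.integer(ind[, 2L])
}

# n gametes from one parent, as an n x n_variants logical matrix.
#
# Crossovers follow the Haldane model: counts Poisson in map length, no
# interference. Under that model recombination events in disjoint intervals
# are independent, so at marker resolution a gamete is generated exactly by
# a Markov chain along each chromosome: the starting haplotype is uniform
# and the chain switches between the two parental haplotypes across each
# inter-marker gap of d Morgans with probability r = (1 - exp(-2 d)) / 2,
# Haldane's map function.
gamete_batch <- function(parent, map, n) {
  nv <- attr(map, "n_variants")
  out <- matrix(FALSE, nrow = n, ncol = nv)
  for (cm in map) {
    m <- length(cm$idx)
    if (m == 0L) next
    p_switch <- c(0.5, 0.5 * (1 - exp(-2 * diff(cm$gpos))))
    s <- matrix(stats::rbinom(n * m, 1L, rep(p_switch, each = n)), n, m)
    h <- if (m == 1L) s else t(apply(s, 1L, cumsum)) %% 2L
    a1 <- matrix(parent[cm$idx, 1L], n, m, byrow = TRUE)
    a2 <- matrix(parent[cm$idx, 2L], n, m, byrow = TRUE)
    out[, cm$idx] <- (h == 0L & a1) | (h == 1L & a2)
  }
  out
}

#' Draw one gamete from a parent
#'
#' Meiosis under the Haldane model: crossover counts are Poisson with mean
#' equal to the chromosome's map length in Morgans and there is no
#' interference, so the returned haplotype is a mosaic of the two parental
#' haplotypes and the recombinant fraction between two loci d Morgans apart
#' is \code{0.5 * (1 - exp(-2 d))}.
#'
#' @param parent An \code{individual}.
#' @param map A \code{marker_map} over the same variant set.
#' @return Logical vector: the alt alleles carried by the gamete.
#' @export
gamete <- function(parent, map) {
  drop(gamete_batch(parent, map, 1L))
}

#' @rdname gamete
#' @param n Number of independent gametes to draw.
#' @return \code{gametes} returns an \code{n} x n_variants logical matrix,
#'   one gamete per row.
#' @export
gametes <- function(parent, map, n) {
  gamete_batch(parent, map, n)
}

#' Cross two individuals / self an individual
#'
#' The offspring receives one independent gamete from each parent.
#'
#' @param a,b Parent \code{individual}s.
#' @param map A \code{marker_map} shared by both parents.
#' @return An \code{individual}.
#' @export
cross <- function(a, b, map) {
  new_individual(gamete(a, map), gamete(b, map))
}

#' @rdname cross
#' @export
self_cross <- function(a, map) {
  cross(a, a, map)
}

# dosage matrix (n x n_variants) for n self-progeny of one parent
progeny_dosage <- function(parent, map, n) {
  gamete_batch(parent, map, n) + gamete_batch(parent, map, n)
}

#' Mendelian genotype frequencies for self-progeny of a heterozygote
#'
#' Enumerates the four equally likely gamete pairings of an Aa x Aa cross
#' and tabulates offspring genotypes, giving the classic 1/4 : 1/2 : 1/4
#' segregation. For a recessive sterile mutation this is the composition of
#' a carrier's brood: 1/4 wild-type, 1/2 heterozygous carriers, 1/4 sterile
#' homozygotes.
#'
#' @return Named numeric vector \code{(hom_ref, het, hom_alt)} summing to 1.
#' @export
mendelian_progeny_freqs <- function() {
  gametes <- c(0L, 1L)                     # a heterozygote transmits A or a
  d <- outer(gametes, gametes, `+`)        # the four equally likely pairings
  f <- tabulate(as.vector(d) + 1L, nbins = 3L) / length(d)
  c(hom_ref = f[1L], het = f[2L], hom_alt = f[3L])
}

# Draw offspring of a x b until the genotype at locus `locus` has dosage
# `target`. Errors after max_tries draws: the selection the pedigree calls
# for could not be satisfied (e.g. requesting a homozygote from a cross
# that cannot produce one).
select_offspring <- function(a, b, map, locus, target, max_tries = 2000L,
                             batch = 16L, what = "offspring") {
  tried <- 0L
  while (tried < max_tries) {
    k <- min(batch, max_tries - tried)
    g1 <- gamete_batch(a, map, k)
    g2 <- gamete_batch(b, map, k)
    d <- as.integer(g1[, locus]) + as.integer(g2[, locus])
    hit <- which(d == target)
    if (length(hit)) {
      i <- hit[1L]
      return(new_individual(g1[i, ], g2[i, ]))
    }
    tried <- tried + k
  }
  stop(sprintf(
    "selection failed: no %s with dosage %d at locus %d among %d draws",
    what, target, locus, max_tries
  ))
}
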