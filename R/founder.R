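#' Allele frequency from genotype counts
#'
#' @param n_hom_alt,n_het,n_hom_ref genotype class counts.
#' @return alternate allele frequency (2*hom_alt + het) / (2n).
#' @examples
#' allele_frequency(3, 11, 396)   # ~0.021
#' @export
allele_frequency <- function(n_hom_alt, n_het, n_hom_ref) {
  n <- n_hom_alt + n_het + n_hom_ref
  if (any(n == 0)) abort("no genotypes")
  if (any(c(n_hom_alt, n_het, n_hom_ref) < 0)) abort("negative counts")
  (2 * n_hom_alt + n_het) / (2 * n)
}

#' Hardy-Weinberg test with Yates continuity correction
#'
#' Expected genotype counts (n p^2, 2 n p q, n q^2) come from the sample
#' allele frequency; the statistic is
#' sum(max(|O - E| - 0.5, 0)^2 / E) over the three genotype classes,
#' referred to a 1-df chi-square. Flooring the corrected deviation at zero
#' means tables exactly at their expectations give chi-square 0 (continuity
#' correction conventions differ; this one is deliberately conservative).
#' Monomorphic sites return p = 1 by convention.
#'
#' @inheritParams allele_frequency
#' @return tibble: n, allele_freq, chi2, df, p_value.
#' @examples
#' hwe_yates_test(3, 11, 396)   # chi2 ~ 32.2, p ~ 1.4e-8
#' @export
hwe_yates_test <- function(n_hom_alt, n_het, n_hom_ref) {
  n <- n_hom_alt + n_het + n_hom_ref
  if (n == 0) abort("no genotypes")
  q <- allele_frequency(n_hom_alt, n_het, n_hom_ref)
  if (q == 0 || q == 1) {
    return(tibble(n = n, allele_freq = q, chi2 = 0, df = 1L, p_value = 1))
  }
  p <- 1 - q
  e <- n * c(p^2, 2 * p * q, q^2)
  o <- c(n_hom_ref, n_het, n_hom_alt)
  chi2 <- sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  tibble(n = n, allele_freq = q, chi2 = chi2, df = 1L,
         p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Maximum shared haplotype around a focal variant
#'
#' Finds the maximal marker interval containing the focal site over which
#' all carrier chromosomes are allelically identical, scanning outward from
#' the focal marker. Genetic length comes from a uniform cM/Mb rate or an
#' interpolated genetic map.
#'
#' @param haplotypes matrix (carrier chromosomes x markers) of phased
#'   alleles; rows may be named.
#' @param positions physical marker positions (bp), increasing.
#' @param focal_index column index of the focal variant.
#' @param map_rate cM per Mb (default 1); ignored when `map` is given.
#' @param map optional genetic map tibble (`pos` bp, `cm`) for
#'   interpolation.
#' @return list of class `rb_shared_haplotype`: carriers, interval
#'   (start/end bp, inclusive), length_bp, length_cm, focal_pos.
#' @export
max_shared_haplotype <- function(haplotypes, positions, focal_index,
                                 map_rate = 1, map = NULL) {
  stopifnot(is.matrix(haplotypes), length(positions) == ncol(haplotypes))
  m <- nrow(haplotypes)
  if (m < 2) abort("need at least two carrier chromosomes")
  focal_alleles <- haplotypes[, focal_index]
  if (length(unique(focal_alleles)) > 1) {
    bad <- which(focal_alleles != focal_alleles[1])[1]
    abort(sprintf("carrier chromosome %s does not carry the focal allele",
                  rownames(haplotypes)[bad] %||% as.character(bad)))
  }
  shared <- matrixStats_all_equal(haplotypes)
  l <- focal_index
  while (l > 1 && shared[l - 1]) l <- l - 1
  r <- focal_index
  while (r < ncol(haplotypes) && shared[r + 1]) r <- r + 1
  start <- positions[l]
  end <- positions[r]
  length_bp <- end - start + 1
  length_cm <- if (is.null(map)) {
    length_bp / 1e6 * map_rate
  } else {
    cm_at <- stats::approx(map$pos, map$cm, xout = c(start, end), rule = 2)$y
    diff(cm_at)
  }
  structure(list(
    n_carriers = m,
    interval = c(start = start, end = end),
    length_bp = length_bp, length_cm = length_cm,
    focal_pos = positions[focal_index],
    marker_range = c(l, r)
  ), class = "rb_shared_haplotype")
}

# columns where all rows agree
matrixStats_all_equal <- function(x) {
  if (nrow(x) == 1) return(rep(TRUE, ncol(x)))
  colSums(x == rep(x[1, ], each = nrow(x))) == nrow(x)
}

#' Moment estimate of founder allele age from a shared haplotype
#'
#' Each of the m carrier chromosomes descends from the founder through g
#' generations, so its one-sided shared-segment length is exponential with
#' rate g per Morgan; the common shared interval's one-sided lengths are
#' minima of m exponentials (rate m g each side), giving total length
#' L ~ Gamma(2, m g) and the moment estimator g = 2 / (m L). The
#' confidence interval inverts the exact pivot m L g ~ Gamma(2, 1).
#'
#' @param shared an `rb_shared_haplotype`, or a shared genetic length in cM.
#' @param n_chromosomes number of carrier chromosomes m (>= 2); taken from
#'   `shared` when available.
#' @param conf confidence level (default 0.95).
#' @return tibble: generations, ci_low, ci_high, length_cm, n_chromosomes.
#' @examples
#' estimate_allele_age(0.657, n_chromosomes = 6)   # ~51 generations
#' @export
estimate_allele_age <- function(shared, n_chromosomes = NULL, conf = 0.95) {
  if (inherits(shared, "rb_shared_haplotype")) {
    length_cm <- shared$length_cm
    n_chromosomes <- n_chromosomes %||% shared$n_carriers
  } else {
    length_cm <- shared
  }
  if (is.null(n_chromosomes) || n_chromosomes < 2) {
    abort("`n_chromosomes` must be at least 2")
  }
  if (length_cm <= 0) abort("shared haplotype has zero genetic length")
  L <- length_cm / 100     # Morgans
  m <- n_chromosomes
  g <- 2 / (m * L)
  a <- (1 - conf) / 2
  tibble(
    generations = g,
    ci_low = qgamma(a, shape = 2) / (m * L),
    ci_high = qgamma(1 - a, shape = 2) / (m * L),
    length_cm = length_cm, n_chromosomes = m
  )
}

#' Random-mating homozygote frequency
#'
#' @param q allele frequency in [0,1].
#' @return q^2, the Hardy-Weinberg homozygote expectation.
#' @examples
#' predicted_homozygote_frequency(0.02)   # 4e-4 = 1/2500
#' @export
predicted_homozygote_frequency <- function(q) {
  stopifnot(all(q >= 0 & q <= 1))
  q^2
}

#' Share of a population's recessive contribution carried by founder alleles
#'
#' Relates the number of probands whose RG involves identified founder
#' variants to the population's estimated total recessive contribution.
#'
#' @param n_founder_probands probands carrying a founder-variant RG.
#' @param n_probands probands in the population subgroup.
#' @param contribution_fraction the subgroup's attributable fraction
#'   (proportion).
#' @return the founder share as a proportion.
#' @examples
#' founder_attributable_share(14, 410, 0.046)   # ~0.74
#' @export
founder_attributable_share <- function(n_founder_probands, n_probands,
                                       contribution_fraction) {
  if (contribution_fraction <= 0) abort("contribution fraction must be positive")
  (n_founder_probands / n_probands) / contribution_fraction
}

#' Summary report for a founder variant
#'
#' @param counts named list or vector with n_hom_alt, n_het, n_hom_ref.
#' @param shared optional `rb_shared_haplotype`.
#' @param n_chromosomes carrier chromosomes for the age estimate.
#' @return list (JSON-ready) with frequency, Hardy-Weinberg test, predicted
#'   homozygote frequency, and (when a haplotype is given) shared-segment
#'   and age estimates.
#' @export
founder_report <- function(counts, shared = NULL, n_chromosomes = NULL) {
  counts <- as.list(counts)
  hwe <- hwe_yates_test(counts$n_hom_alt, counts$n_het, counts$n_hom_ref)
  out <- list(
    genotype_counts = counts,
    allele_frequency = hwe$allele_freq,
    predicted_homozygote_frequency =
      predicted_homozygote_frequency(hwe$allele_freq),
    hwe = as.list(hwe)
  )
  if (!is.null(shared)) {
    age <- estimate_allele_age(shared, n_chromosomes)
    out$shared_haplotype <- list(
      interval = as.list(shared$interval),
      length_bp = shared$length_bp, length_cm = shared$length_cm,
      n_carriers = shared$n_carriers
    )
    out$age <- as.list(age)
  }
  out
}
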