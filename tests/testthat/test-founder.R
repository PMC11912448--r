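test_that("allele frequency and homozygote prediction match the founder example", {
  q <- allele_frequency(3, 11, 396)
  expect_equal(q, 17 / 820)
  expect_equal(round(100 * q, 1), 2.1)
  expect_equal(allele_frequency(0, 0, 50), 0)
  expect_equal(allele_frequency(50, 0, 0), 1)
  expect_error(allele_frequency(0, 0, 0), "no genotypes")

  expect_equal(predicted_homozygote_frequency(0.02), 1 / 2500)
  expect_equal(predicted_homozygote_frequency(0), 0)
  expect_equal(predicted_homozygote_frequency(1), 1)
})

test_that("the Yates-corrected HWE test reproduces the founder variant deviation", {
  res <- hwe_yates_test(3, 11, 396)
  expect_equal(res$chi2, 32.2, tolerance = 0.01)
  expect_equal(res$p_value, 1.4e-8, tolerance = 0.05)

  # table exactly at HWE: the floored correction gives chi-square 0
  n <- 1000; q <- 0.2
  at_hwe <- hwe_yates_test(n * q^2, n * 2 * q * (1 - q), n * (1 - q)^2)
  expect_equal(at_hwe$chi2, 0)
  expect_equal(at_hwe$p_value, 1)

  expect_equal(hwe_yates_test(0, 0, 410)$p_value, 1)   # monomorphic
})

test_that("the corrected statistic never exceeds the uncorrected Pearson chi-square", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(50:2000, 1)
    q <- runif(1, 0.05, 0.5)
    counts <- as.vector(rmultinom(1, n, c((1 - q)^2, 2 * q * (1 - q), q^2)))
    if (counts[2] + counts[3] == 0) next
    res <- hwe_yates_test(counts[3], counts[2], counts[1])
    qq <- res$allele_freq; pp <- 1 - qq
    e <- n * c(pp^2, 2 * pp * qq, qq^2)
    pearson <- sum((c(counts[1], counts[2], counts[3]) - e)^2 / e)
    expect_lte(res$chi2, pearson + 1e-12)
  }
})

test_that("HWE test is conservative under the null", {
  set.seed(4)
  q <- 0.02; n <- 410
  draws <- rmultinom(2000, n, c((1 - q)^2, 2 * q * (1 - q), q^2))
  pvals <- vapply(seq_len(ncol(draws)), function(i) {
    hwe_yates_test(draws[3, i], draws[2, i], draws[1, i])$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.05)
})

test_that("the maximal shared interval matches an outward brute-force scan", {
  set.seed(6)
  for (i in 1:50) {
    nm <- sample(30:80, 1)
    m <- sample(2:6, 1)
    hap <- matrix(sample(0:1, m * nm, replace = TRUE), m, nm)
    focal <- sample(5:(nm - 5), 1)
    hap[, focal] <- 1L
    pos <- sort(sample.int(1e6, nm))
    sh <- max_shared_haplotype(hap, pos, focal)
    # brute force: expand while columns identical
    same <- apply(hap, 2, function(col) length(unique(col)) == 1)
    l <- focal; while (l > 1 && same[l - 1]) l <- l - 1
    r <- focal; while (r < nm && same[r + 1]) r <- r + 1
    expect_equal(unname(sh$interval), c(pos[l], pos[r]))
    # symmetric in carrier order
    sh2 <- max_shared_haplotype(hap[rev(seq_len(m)), , drop = FALSE], pos,
                                focal)
    expect_equal(sh2$interval, sh$interval)
  }
})

test_that("shared-haplotype edge cases behave", {
  pos <- seq(100L, 1000L, by = 100L)
  hap <- matrix(1L, 3, 10)
  sh <- max_shared_haplotype(hap, pos, 5)
  expect_equal(unname(sh$interval), c(100L, 1000L))   # whole region

  hap2 <- hap; hap2[2, 4] <- 0L
  sh2 <- max_shared_haplotype(hap2, pos, 5)
  expect_equal(unname(sh2$interval[1]), 500L)   # left edge at focal-adjacent

  hap3 <- hap; hap3[2, 5] <- 0L
  expect_error(max_shared_haplotype(hap3, pos, 5), "focal allele")
})

test_that("allele age follows the moment formula and its scalings", {
  age <- estimate_allele_age(0.657, n_chromosomes = 6)
  expect_equal(age$generations, 50.7, tolerance = 0.01)
  expect_true(age$ci_low < age$generations & age$generations < age$ci_high)

  expect_equal(estimate_allele_age(2 * 0.657, n_chromosomes = 6)$generations,
               age$generations / 2)
  # converting bp to cM at a different uniform rate rescales inversely
  pos <- seq(1L, 2000001L, by = 10000L)
  hap <- matrix(1L, 4, length(pos))
  a1 <- estimate_allele_age(max_shared_haplotype(hap, pos, 100, map_rate = 1))
  a2 <- estimate_allele_age(max_shared_haplotype(hap, pos, 100, map_rate = 2))
  expect_equal(a2$generations, a1$generations / 2)

  expect_error(estimate_allele_age(0, n_chromosomes = 6), "zero")
  expect_error(estimate_allele_age(0.5, n_chromosomes = 1), "at least 2")
})

test_that("the founder share relates founder carriers to the subgroup contribution", {
  expect_equal(100 * founder_attributable_share(14, 410, 0.046), 74,
               tolerance = 0.01)
  expect_error(founder_attributable_share(14, 410, 0), "positive")
  rep <- founder_report(list(n_hom_alt = 3, n_het = 11, n_hom_ref = 396))
  expect_equal(rep$allele_frequency, 17 / 820)
  expect_equal(rep$predicted_homozygote_frequency, (17 / 820)^2)
})
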