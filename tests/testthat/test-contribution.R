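test_that("the parental-depletion arithmetic reproduces the contribution table", {
  # damaging, LoF and synonymous rows of the published contribution table
  expect_equal(100 * attributable_fraction(1418.0, 1181, 659.1, 630, 3716),
               2.2, tolerance = 0.01)
  expect_equal(100 * attributable_fraction(156.5, 95, 69.9, 61, 3716),
               0.5, tolerance = 0.01)
  syn <- 100 * attributable_fraction(4122.2, 4135, 1951.5, 1951, 3716)
  expect_lt(abs(syn), 0.2)   # the control class sits at zero
  # exact null identity
  expect_equal(attributable_fraction(100, 80, 50, 50 * 80 / 100, 1000), 0)
  expect_error(attributable_fraction(0, 0, 10, 5, 100), "positive")
})

test_that("expected biallelic counts follow (1-F) Q^2 + F Q", {
  q <- tibble::tibble(gene = c("g1", "g2"), q = c(0.01, 0))
  expect_equal(expected_rg_counts(q, rep(0, 5)), rep(1e-4, 5))
  expect_equal(expected_rg_counts(q, 1), 0.01)
  expect_equal(expected_rg_counts(q, 0.5), 0.5 * 1e-4 + 0.5 * 0.01)
  expect_equal(expected_rg_counts(tibble::tibble(gene = "g", q = 0), 0.2), 0)
  expect_error(expected_rg_counts(q, c(0.1, NA)), "missing")
})

test_that("observed biallelic counting is phase-aware", {
  variants <- tibble::tibble(variant_id = c("a", "b", "c"), gene = "G")
  # trans pair counts; cis pair does not; hom counts
  g <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2", "s3"),
    variant_id = c("a", "b", "a", "b", "c"),
    dosage = c(1L, 1L, 1L, 1L, 2L),
    hap = c(1L, 2L, 1L, 1L, 0L))
  ev <- recburden:::observed_biallelic(g, variants)
  expect_setequal(ev$sample, c("s1", "s3"))
  # without phase, any two carried variants count
  ev2 <- recburden:::observed_biallelic(dplyr::select(g, -hap), variants)
  expect_setequal(ev2$sample, c("s1", "s2", "s3"))
})

test_that("carrier co-occurrence pruning drops the rarer linked variant", {
  variants <- tibble::tibble(variant_id = c("a", "b", "x"), gene = "G")
  # a and b always co-occur (same haplotype across carriers); x independent
  g <- tibble::tibble(
    sample = rep(c("p1", "p2", "p3", "p4"), times = c(2, 2, 1, 1)),
    variant_id = c("a", "b", "a", "b", "a", "x"),
    dosage = 1L, hap = 1L)
  res <- recburden:::in_cohort_q(g, variants, paste0("p", 1:4),
                                 prune_threshold = 0.5)
  expect_equal(res$dropped, "b")   # rarer member (2 carriers vs 3)
  expect_equal(res$q_gene$q, (3 + 1) / 8)   # a: 3 alleles, x: 1, over 2*4
})

test_that("a zero-variance cohort collapses the bootstrap CI to the point", {
  # hand-built cohort: every trio identical, one causal hom each
  nt <- 30
  ped <- tibble::tibble(
    fam = rep(sprintf("F%02d", 1:nt), 3),
    sample = c(sprintf("F%02d_P", 1:nt), sprintf("F%02d_F", 1:nt),
               sprintf("F%02d_M", 1:nt)),
    father = c(sprintf("F%02d_F", 1:nt), rep("0", 2 * nt)),
    mother = c(sprintf("F%02d_M", 1:nt), rep("0", 2 * nt)),
    sex = 1L, phenotype = c(rep(2L, nt), rep(1L, 2 * nt)))
  variants <- classify_variants(tibble::tibble(
    variant_id = "v1", chrom = "1", pos = 100L, gene = "G1",
    consequence = "stopgain", metasvm = NA, cadd = NA,
    af_panel1 = 1e-4, af_panel2 = 1e-4, segdup = FALSE))
  geno <- tibble::tibble(
    sample = c(sprintf("F%02d_P", 1:nt), sprintf("F%02d_F", 1:nt),
               sprintf("F%02d_M", 1:nt)),
    variant_id = "v1",
    dosage = c(rep(2L, nt), rep(1L, 2 * nt)),
    hap = c(rep(0L, nt), rep(1L, 2 * nt)),
    gq = 99L, dp = 50L, mq = 60, alt_reads = 40L)
  cohort <- list(genotypes = geno, pedigree = ped[ped$phenotype == 2L | TRUE, ],
                 variants = variants)
  f <- tibble::tibble(sample = sprintf("F%02d_P", 1:nt), f = 0)
  fit <- estimate_contribution(cohort, f, class = "damaging", B = 200,
                               seed = 3)
  expect_equal(fit$estimate$ci_low, fit$estimate$fraction, tolerance = 1e-12)
  expect_equal(fit$estimate$ci_high, fit$estimate$fraction, tolerance = 1e-12)
  # and the bootstrap is reproducible
  fit2 <- estimate_contribution(cohort, f, class = "damaging", B = 200,
                                seed = 3)
  expect_identical(fit$boot, fit2$boot)
})

test_that("stratified estimates are symmetric and recombine under shared frequencies", {
  cfg <- sim_config(n_trios = 600, n_singletons = 0, n_genes = 200, seed = 31,
                    target_attributable_fraction = 0)
  co <- simulate_trios(cfg, simulate_gene_panel(cfg))
  f_pro <- tibble::tibble(sample = co$truth$sample, f = co$truth$true_f)
  pro <- co$truth$sample
  strata <- tibble::tibble(
    sample = pro, stratum = rep(c("s1", "s2"), length.out = length(pro)))

  res <- stratified_contribution(co, f_pro, strata, B = 0,
                                 shared_frequencies = TRUE)
  whole <- estimate_contribution(co, f_pro, B = 0)$estimate
  # stratum component sums reproduce the whole-cohort estimate exactly
  recomb <- attributable_fraction(
    sum(res$exp_parents), sum(res$obs_parents),
    sum(res$exp_probands), sum(res$obs_probands), sum(res$n_probands))
  expect_equal(recomb, whole$fraction, tolerance = 1e-10)

  # identical strata (same trios twice) give identical fractions
  dup <- dplyr::bind_rows(
    tibble::tibble(sample = pro, stratum = "a"),
    tibble::tibble(sample = pro, stratum = "b"))
  res2 <- stratified_contribution(co, f_pro, dup, B = 0)
  expect_equal(res2$fraction[1], res2$fraction[2])

  expect_warning(
    stratified_contribution(
      co, f_pro, tibble::tibble(sample = pro[1:5], stratum = "tiny"), B = 0),
    "unstable")
})

test_that("planted causal recessive genotypes are recovered from the cohort", {
  cfg <- sim_config(n_trios = 4000, n_singletons = 0, n_genes = 300,
                    seed = 77, target_attributable_fraction = 0.05)
  co <- simulate_trios(cfg, simulate_gene_panel(cfg))
  f_pro <- tibble::tibble(sample = co$truth$sample, f = co$truth$true_f)
  fit <- estimate_contribution(co, f_pro, class = "damaging", B = 200,
                               seed = 5)
  expect_gt(fit$estimate$fraction, 0.02)
  expect_true(fit$estimate$ci_low <= 0.05 & 0.05 <= fit$estimate$ci_high)
  # fraction is invariant to sample order
  co2 <- co
  co2$genotypes <- co$genotypes[rev(seq_len(nrow(co$genotypes))), ]
  fit2 <- estimate_contribution(co2, f_pro, class = "damaging", B = 0)
  expect_equal(fit2$estimate$fraction, fit$estimate$fraction)
})
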