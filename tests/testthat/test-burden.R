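mut_tbl <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(gene = sprintf("g%03d", 1:n),
                 mutability = rlnorm(n, log(1e-5), 1))
}

test_that("the polynomial model recovers noise-free coefficients within 1%", {
  mut <- mut_tbl()
  a <- 0.1; b <- 50
  counts <- tibble::tibble(gene = mut$gene,
                           observed = a * mut$mutability + b * mut$mutability^2)
  fit <- fit_expected_model(counts, mut, n = 5000)
  expect_equal(unname(fit$coefficients[1]), a, tolerance = 0.01)
  expect_equal(unname(fit$coefficients[2]), b, tolerance = 0.01)
  expect_equal(fit$fitted$expected, counts$observed, tolerance = 1e-6)
})

test_that("equal mutabilities make every expected count the mean observed", {
  mut <- tibble::tibble(gene = sprintf("g%03d", 1:150), mutability = 2e-5)
  set.seed(4)
  counts <- tibble::tibble(gene = mut$gene, observed = rpois(150, 2))
  fit <- fit_expected_model(counts, mut, n = 1000)
  expect_equal(fit$fitted$expected, rep(mean(counts$observed), 150),
               tolerance = 1e-8)
})

test_that("rescaling mutability reparameterizes without changing fitted values", {
  mut <- mut_tbl(150, seed = 2)
  set.seed(5)
  counts <- tibble::tibble(gene = mut$gene,
                           observed = rpois(150, 1 + 1e9 * mut$mutability^2))
  f1 <- fit_expected_model(counts, mut, n = 5000)
  mut2 <- dplyr::mutate(mut, mutability = 2 * mutability)
  f2 <- fit_expected_model(counts, mut2, n = 5000)
  expect_equal(f2$fitted$expected, f1$fitted$expected, tolerance = 1e-6)
  expect_equal(unname(f2$coefficients), unname(f1$coefficients) / c(2, 4),
               tolerance = 1e-6)
})

test_that("degenerate inputs are handled explicitly", {
  mut <- mut_tbl(120)
  zero <- tibble::tibble(gene = mut$gene, observed = 0)
  expect_warning(fit <- fit_expected_model(zero, mut, n = 100), "zero")
  expect_true(all(fit$coefficients == 0))
  expect_true(all(fit$fitted$expected == fit$floor))
  expect_error(fit_expected_model(zero, mut[1:50, ], n = 100), "100 genes")
  expect_error(fit_expected_model(
    zero, dplyr::mutate(mut, mutability = -mutability), n = 100), "positive")
})

test_that("one-tailed binomial tests reproduce the published gene p-values", {
  c1 <- binomial_gene_test(5, 5 / 176.8, 5424)
  expect_equal(c1$p_value, 1.5e-10, tolerance = 0.05)
  expect_equal(c1$enrichment, 176.8)
  second_gene <- binomial_gene_test(6, 6 / 51.1, 5424)
  expect_equal(second_gene$p_value, 3.2e-9, tolerance = 0.05)
  expect_equal(binomial_gene_test(0, 0.5, 100)$p_value, 1)
  expect_error(binomial_gene_test(5, 0, 100), "positive")
  expect_error(binomial_gene_test(5, 200, 100), "below")
})

test_that("gene-set expectations are additive and consistent with gene tests", {
  mut <- mut_tbl(150, seed = 3)
  set.seed(6)
  counts <- tibble::tibble(gene = mut$gene, observed = rpois(150, 1))
  fit <- fit_expected_model(counts, mut, n = 2000)

  known <- binomial_gene_test(66, 66 / 3.9, 5424, unit = "known_set")
  expect_lt(known$p_value, 1e-15)

  s1 <- gene_set_test(fit, mut$gene[1:10], observed = 5)
  s2 <- gene_set_test(fit, mut$gene[11:30], observed = 7)
  s12 <- gene_set_test(fit, mut$gene[1:30], observed = 12)
  expect_equal(s12$expected, s1$expected + s2$expected)

  single <- gene_set_test(fit, mut$gene[5], observed = 2)
  direct <- binomial_gene_test(2, fit$fitted$expected[5], 2000)
  expect_equal(single$p_value, direct$p_value)

  z <- gene_set_test(fit, mut$gene[1:10], observed = 0)
  expect_equal(z$p_value, 1)
  expect_equal(z$enrichment, 0)
  expect_error(gene_set_test(fit, character(0), observed = 0), "empty")
  expect_error(gene_set_test(fit, "NOT_A_GENE", observed = 0), "not in")

  rg <- tibble::tibble(sample = c("s1", "s2"), gene = mut$gene[c(1, 1)])
  expect_equal(gene_set_test(fit, mut$gene[1:10], observed = rg)$observed, 2)
})

test_that("multiplicity control matches the genome-wide threshold and BH step-up", {
  expect_equal(bonferroni_threshold(), 0.05 / 19347)
  res <- binomial_gene_test(c(3, 1), c(0.01, 0.5), 1000,
                            unit = c("a", "b"))
  res$p_value <- c(2.5e-6, 2.7e-6)
  adj <- adjust_multiplicity(res)
  expect_equal(adj$bonferroni_significant, c(TRUE, FALSE))

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    fake <- tibble::tibble(p_value = p)
    expect_equal(adjust_multiplicity(fake)$q_value, bh_reference(p))
  }
  allnull <- adjust_multiplicity(tibble::tibble(p_value = rep(1, 10)))
  expect_true(all(allnull$q_value == 1) && !any(allnull$bonferroni_significant))
})

test_that("the recurrent-gene permutation matches exact multinomial enumeration", {
  # 3 genes, equal probabilities, T = 2: P(some gene receives both) = 1/3
  perm <- permutation_recurrent_genes(1, total_rgs = 2, probs = rep(1, 3),
                                      n_perm = 10000, seed = 12)
  p_hat <- mean(attr(perm, "distribution") >= 1)
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)

  zero <- permutation_recurrent_genes(0, total_rgs = 0, probs = rep(1, 5),
                                      n_perm = 100, seed = 1)
  expect_equal(zero$expected, 0)
  expect_equal(zero$p_value, 1)

  pr <- runif(20)
  a <- permutation_recurrent_genes(3, 50, pr, n_perm = 500, seed = 9)
  b <- permutation_recurrent_genes(3, 50, pr, n_perm = 500, seed = 9)
  expect_identical(attr(a, "distribution"), attr(b, "distribution"))
})
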