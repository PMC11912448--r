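small_cfg <- function(...) {
  sim_config(n_trios = 60, n_singletons = 20, n_genes = 120, seed = 11, ...)
}

test_that("zero allele-frequency scale gives an empty cohort downstream", {
  cfg <- small_cfg(af_scale = 0, target_attributable_fraction = 0)
  panel <- simulate_gene_panel(cfg)
  expect_true(all(panel$variants$af_true == 0))
  co <- simulate_trios(cfg, panel)
  rg <- call_recessive_genotypes(co$genotypes, co$variants, co$pedigree)
  expect_equal(nrow(rg), 0L)
})

test_that("a fixed seed reproduces the panel and cohort byte for byte", {
  cfg <- small_cfg()
  p1 <- simulate_gene_panel(cfg)
  p2 <- simulate_gene_panel(cfg)
  expect_identical(p1$variants, p2$variants)
  c1 <- simulate_trios(cfg, p1)
  c2 <- simulate_trios(cfg, p2)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$truth, c2$truth)
})

test_that("damaging allele-frequency mass scales linearly with af_scale", {
  cfg1 <- sim_config(n_trios = 1, n_singletons = 0, n_genes = 1000, seed = 3,
                     af_scale = 50)
  cfg2 <- sim_config(n_trios = 1, n_singletons = 0, n_genes = 1000, seed = 3,
                     af_scale = 100)
  q1 <- simulate_gene_panel(cfg1)$genes$q_damaging
  q2 <- simulate_gene_panel(cfg2)$genes$q_damaging
  expect_equal(mean(q2) / mean(q1), 2, tolerance = 0.05)
})

test_that("the rare pool stays rare and contains every variant kind per gene", {
  panel <- simulate_gene_panel(small_cfg())
  v <- panel$variants
  expect_true(all(v$af_true < 1e-3))
  kinds <- v |>
    dplyr::group_by(gene) |>
    dplyr::summarise(
      has_lof = any(class == "LoF"),
      has_dmis = any(class == "Dmis"),
      has_syn = any(class == "synonymous"),
      has_benign = any(consequence == "missense" & class == "non_damaging"))
  expect_true(all(kinds$has_lof & kinds$has_dmis & kinds$has_syn &
                    kinds$has_benign))
})

test_that("proband alleles are Mendelian-consistent with their parents", {
  cfg <- small_cfg(target_attributable_fraction = 0.05)
  co <- simulate_trios(cfg, simulate_gene_panel(cfg))
  ped <- co$pedigree
  trio <- ped[ped$father != "0", ]
  g <- co$genotypes
  key <- paste(g$sample, g$variant_id)
  dose_of <- function(s, v) {
    d <- g$dosage[match(paste(s, v), key)]
    dplyr::coalesce(d, 0L)
  }
  pro_rows <- g[g$sample %in% trio$sample, ]
  fa <- trio$father[match(pro_rows$sample, trio$sample)]
  mo <- trio$mother[match(pro_rows$sample, trio$sample)]
  fd <- dose_of(fa, pro_rows$variant_id)
  md <- dose_of(mo, pro_rows$variant_id)
  # paternal-haplotype hets come from the father, maternal from the mother;
  # homozygotes (including autozygous and planted) from both
  expect_true(all(fd[pro_rows$hap == 1L] > 0))
  expect_true(all(md[pro_rows$hap == 2L] > 0))
  hom <- pro_rows$dosage == 2L
  expect_true(all(fd[hom] > 0 & md[hom] > 0))
})

test_that("planted causal fraction matches the target within binomial error", {
  cfg <- sim_config(n_trios = 5000, n_singletons = 0, n_genes = 150,
                    seed = 21, target_attributable_fraction = 0.02)
  co <- simulate_trios(cfg, simulate_gene_panel(cfg))
  observed <- mean(co$truth$causal)
  se <- sqrt(0.02 * 0.98 / 5000)
  expect_lt(abs(observed - 0.02), 3 * se)
  expect_true(all(!is.na(co$truth$causal_gene[co$truth$causal])))
})

test_that("co-occurrence pair counts equal a brute-force recount", {
  panel <- simulate_gene_panel(small_cfg())
  coc <- simulate_cooccurrence_panel(panel, n_individuals = 400, seed = 5)
  carr <- coc$carriers
  brute <- merge(carr, carr, by = c("individual", "gene"))
  brute <- brute[brute$variant_id.x < brute$variant_id.y, ]
  brute_counts <- stats::aggregate(
    individual ~ gene + variant_id.x + variant_id.y, brute, length)
  expect_equal(nrow(coc$pairs), nrow(brute_counts))
  m <- merge(coc$pairs, brute_counts,
             by.x = c("gene", "variant1", "variant2"),
             by.y = c("gene", "variant_id.x", "variant_id.y"))
  expect_equal(nrow(m), nrow(coc$pairs))
  expect_equal(m$count, m$individual)
  # pairs never span genes
  v <- panel$variants
  expect_equal(v$gene[match(coc$pairs$variant1, v$variant_id)],
               v$gene[match(coc$pairs$variant2, v$variant_id)])
})

test_that("founder haplotype segments have the exponential lengths they claim", {
  fs1 <- simulate_founder_haplotypes(age = 50, n_chromosomes = 6, seed = 9)
  fs2 <- simulate_founder_haplotypes(age = 50, n_chromosomes = 6, seed = 9)
  expect_identical(fs1$haplotypes, fs2$haplotypes)
  expect_identical(fs1$breakpoints, fs2$breakpoints)

  # mean one-sided length over many draws matches 1/age within 3%
  big <- simulate_founder_haplotypes(age = 50, n_chromosomes = 5000,
                                     marker_spacing_cm = 1, region_cm = 2,
                                     seed = 2)
  sides <- c(big$breakpoints$left_morgans, big$breakpoints$right_morgans)
  expect_equal(mean(sides), 1 / 50, tolerance = 0.03)

  # very old alleles share essentially nothing beyond the focal marker
  old <- simulate_founder_haplotypes(age = 1e6, n_chromosomes = 6, seed = 3)
  sh <- max_shared_haplotype(old$haplotypes, old$positions_bp,
                             old$focal_index)
  expect_lt(sh$length_cm, 0.5)
})

test_that("planted expression-specific genes obey the fold rule by construction", {
  em <- simulate_expression_matrix(
    50, planted_specific = c(PL1 = "notochord", PL2 = "cardiomyocytes"),
    fold = 5, seed = 4)
  sp <- specific_genes(em, fold = 5)
  expect_true(all(sp$specific[sp$gene %in% c("PL1", "PL2")]))
  expect_equal(sp$top_tissue[sp$gene == "PL1"], "notochord")

  weak <- simulate_expression_matrix(5, planted_specific = c(PL = "gut"),
                                     fold = 1.01, seed = 4)
  expect_false(specific_genes(weak, fold = 5)$specific[6])

  flat <- tibble::tibble(gene = "flat", a = 2, b = 2, c = 2)
  expect_false(specific_genes(flat, fold = 5)$specific)
})

test_that("configuration errors are caught at validation time", {
  expect_error(sim_config(n_genes = 1), "n_genes")
  expect_error(sim_config(f_distribution = tibble::tibble(f = 0.5, prop = 0.7)),
               "sum to 1")
  expect_error(sim_config(target_attributable_fraction = 1), "proportion")
  cfg <- small_cfg(causal_genes = tibble::tibble(gene = "NOPE", penetrance = 1),
                   target_attributable_fraction = 0.05)
  panel <- simulate_gene_panel(cfg)
  expect_error(simulate_trios(cfg, panel), "causal genes absent")
})
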